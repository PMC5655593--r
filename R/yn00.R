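## Yang-Nielsen (2000) style counting estimator: transition/transversion bias
## (kappa) and unequal codon usage (F3x4) enter both the site counts and the
## pathway averaging; dS and dN receive a K80-type correction applied to
## synonymous and nonsynonymous transition/transversion proportions; omega is
## iterated to convergence.

## F3x4 codon frequencies from the two sequences of a pair (position-specific
## nucleotide frequencies, normalized over sense codons). Frequencies are
## floored to avoid zero pathway weights on short genes.
.f3x4 <- function(mach, ia, ib, floor_at = 1e-4) {
  nt_mat <- rbind(mach$codon_nt[ia, , drop = FALSE],
                  mach$codon_nt[ib, , drop = FALSE])
  pos_freq <- vapply(1:3, function(p) {
    f <- table(factor(nt_mat[, p], levels = .NT))
    as.numeric(f) / sum(f)
  }, numeric(4))                      # 4 x 3
  pos_freq <- pmax(pos_freq, floor_at)
  pos_freq <- sweep(pos_freq, 2, colSums(pos_freq), "/")
  nt_idx <- matrix(match(mach$codon_nt, .NT), ncol = 3)
  pi61 <- pos_freq[cbind(nt_idx[, 1], 1)] *
    pos_freq[cbind(nt_idx[, 2], 2)] *
    pos_freq[cbind(nt_idx[, 3], 3)]
  pi61 / sum(pi61)
}

## K80 distance components from transition proportion P and transversion
## proportion Q; returns total, transitional and transversional parts
## (Inf when outside the correctable region, i.e. saturated).
.k80 <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) {
    return(list(d = Inf, dts = Inf, dtv = if (b <= 0) Inf else -0.5 * log(b)))
  }
  list(d = -0.5 * log(a) - 0.25 * log(b),
       dts = -0.5 * log(a) + 0.25 * log(b),
       dtv = -0.5 * log(b))
}

## kappa from fourfold-degenerate and nondegenerate codon positions: K80
## transitional/transversional distances per class, pooled weighted by site
## counts; kappa = 2 * dts / dtv (two transversion types per site).
.estimate_kappa <- function(mach, ia, ib) {
  nt_a <- mach$codon_nt[ia, , drop = FALSE]
  nt_b <- mach$codon_nt[ib, , drop = FALSE]
  deg_a <- mach$degen[ia, , drop = FALSE]
  deg_b <- mach$degen[ib, , drop = FALSE]
  usable <- deg_a == deg_b & (deg_a == 4L | deg_a == 0L)
  if (!any(usable)) return(1)
  pur_a <- matrix(nt_a %in% .PURINES, nrow = nrow(nt_a))
  pur_b <- matrix(nt_b %in% .PURINES, nrow = nrow(nt_b))
  differ <- nt_a != nt_b
  is_ts <- differ & (pur_a == pur_b)
  dts_num <- 0; dtv_num <- 0; n_tot <- 0
  for (cls in c(4L, 0L)) {
    sel <- usable & deg_a == cls
    n <- sum(sel)
    if (n < 4L) next
    P <- sum(is_ts[sel]) / n
    Q <- sum(differ[sel] & !is_ts[sel]) / n
    k <- .k80(P, Q)
    if (!is.finite(k$dts) || !is.finite(k$dtv)) next
    dts_num <- dts_num + n * k$dts
    dtv_num <- dtv_num + n * k$dtv
    n_tot <- n_tot + n
  }
  if (n_tot == 0 || dtv_num <= 0) return(1)
  kappa <- 2 * (dts_num / n_tot) / (dtv_num / n_tot)
  min(max(kappa, 0.01), 99)
}

## kappa/frequency-weighted synonymous site count per sense codon, with the
## same per-position normalization as the NG86 fractions so that kappa = 1
## and uniform frequencies reduce to NG86 exactly.
.weighted_sites <- function(mach, pi61, kappa) {
  nb <- mach$nb
  w <- pi61[nb$to] * ifelse(nb$ts, kappa, 1)
  grp <- (nb$from - 1L) * 3L + nb$pos
  syn_w <- rowsum(w * nb$syn, group = grp)
  tot_w <- rowsum(w, group = grp)
  frac <- as.numeric(syn_w) / as.numeric(tot_w)
  as.numeric(rowsum(frac, group = (as.integer(rownames(syn_w)) - 1L) %/% 3L + 1L))
}

#' Yang-Nielsen (2000) dN/dS estimate for a codon alignment
#'
#' Counting method correcting NG86 for transition/transversion bias and
#' unequal codon usage: F3x4 codon frequencies are estimated from the pair,
#' kappa from fourfold-degenerate and nondegenerate sites (K80), synonymous
#' site counts are weighted by kappa and target-codon frequency, pathway
#' averaging weights each surviving pathway by the product of its step rates
#' (frequency x kappa^transition x omega^nonsynonymous), and dS/dN receive a
#' K80 correction from their transition/transversion splits. omega is
#' iterated until `|delta omega| < tol` or `max_iter` iterations.
#'
#' @inheritParams ng86_estimate
#' @param kappa Optional fixed kappa (skips estimation); used e.g. to force
#'   the kappa = 1 reduction to NG86 site counts.
#' @param codon_freqs `"F3x4"` (default), `"uniform"`, or a numeric vector of
#'   frequencies over the sense codons.
#' @param max_iter,tol Iteration control for omega.
#' @return A `dnds_estimate`; `converged` is `FALSE` if the omega iteration
#'   hit `max_iter`.
#' @export
yn00_estimate <- function(ca, code = "11", kappa = NULL, codon_freqs = "F3x4",
                          max_iter = 100L, tol = 1e-6) {
  mach <- codon_machinery(code)
  if (length(ca$codons_a) == 0L) {
    stop("empty codon alignment")
  }
  ia <- .codon_index(ca$codons_a, mach, "codons_a")
  ib <- .codon_index(ca$codons_b, mach, "codons_b")

  pi61 <- if (is.numeric(codon_freqs)) {
    stopifnot(length(codon_freqs) == mach$n_sense)
    codon_freqs / sum(codon_freqs)
  } else if (identical(codon_freqs, "uniform")) {
    rep(1 / mach$n_sense, mach$n_sense)
  } else {
    .f3x4(mach, ia, ib)
  }
  if (is.null(kappa)) kappa <- .estimate_kappa(mach, ia, ib)

  s_site <- .weighted_sites(mach, pi61, kappa)
  S <- (sum(s_site[ia]) + sum(s_site[ib])) / 2
  N <- 3 * length(ia) - S

  pid <- (ia - 1L) * mach$n_sense + ib
  sub <- .pathway_subset(mach, pid)
  pid_loc <- match(pid, sub$upairs)
  omega <- 1
  converged <- FALSE
  cnt <- NULL
  for (it in seq_len(max_iter)) {
    w <- .weighted_counts_sub(sub, pi61, kappa, omega)
    cnt <- list(sts = sum(w[pid_loc, "sts"]), stv = sum(w[pid_loc, "stv"]),
                nts = sum(w[pid_loc, "nts"]), ntv = sum(w[pid_loc, "ntv"]))
    kS <- .k80(cnt$sts / S, cnt$stv / S)
    kN <- .k80(cnt$nts / N, cnt$ntv / N)
    dS <- kS$d
    dN <- kN$d
    omega_new <- if (dS == 0) 999 else if (!is.finite(dS)) 0 else dN / dS
    ## a saturated dS or dN cannot be refined further; the estimate is
    ## emitted as-is and lands in a filter discard bucket downstream
    if (dS == 0 || !is.finite(dS) || !is.finite(dN) ||
        abs(omega_new - omega) < tol) {
      omega <- omega_new
      converged <- TRUE
      break
    }
    omega <- omega_new
  }
  new_dnds_estimate(ca$gene_a, ca$gene_b, "YN00",
                    S = S, N = N,
                    Sd = cnt$sts + cnt$stv, Nd = cnt$nts + cnt$ntv,
                    dS = dS, dN = dN, kappa = kappa, converged = converged)
}
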
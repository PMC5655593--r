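#' Nei-Gojobori (1986) synonymous/nonsynonymous site counts for one codon
#'
#' For each codon position, the synonymous fraction among that position's
#' single-nucleotide changes is computed with mutations to stop codons
#' excluded from the denominator; the three fractions sum to the synonymous
#' site count `s`, and `n = 3 - s`.
#'
#' @param codon A single sense codon (3 characters over ACGT).
#' @param code NCBI genetic code id (default "11", bacterial/archaeal).
#' @return Named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' ng86_count_sites("TTT") # s = 1/3
#' @export
ng86_count_sites <- function(codon, code = "11") {
  mach <- codon_machinery(code)
  i <- .codon_index(codon, mach)
  s <- mach$s_ng86[i]
  c(s = s, n = 3 - s)
}

#' Nei-Gojobori (1986) pathway-averaged difference counts for a codon pair
#'
#' Codons differing at k positions are connected by k! orderings of
#' single-nucleotide steps; synonymous and nonsynonymous step counts are
#' averaged over the orderings, excluding pathways that pass through a stop
#' codon (the average is renormalized over surviving pathways). If every
#' pathway is blocked by a stop the counts fall back to an even k/2 split
#' with a warning.
#'
#' @param codon_a,codon_b Sense codons.
#' @inheritParams ng86_count_sites
#' @return Named numeric vector `c(sd = , nd = )` with `sd + nd` equal to the
#'   Hamming distance of the codons.
#' @examples
#' ng86_count_differences("TTT", "GTA") # (0.5, 1.5)
#' @export
ng86_count_differences <- function(codon_a, codon_b, code = "11") {
  mach <- codon_machinery(code)
  i <- .codon_index(codon_a, mach, "codon_a")
  j <- .codon_index(codon_b, mach, "codon_b")
  pid <- (i - 1L) * mach$n_sense + j
  if (i != j && mach$n_paths[pid] == 0L) {
    warning(sprintf(
      "all mutational pathways between %s and %s pass through stop codons; using even split",
      codon_a, codon_b))
  }
  c(sd = mach$sd_eq[pid], nd = mach$nd_eq[pid])
}

## Jukes-Cantor correction; p >= 3/4 is saturated (Inf)
.jc_correct <- function(p) {
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) dN/dS estimate for a codon alignment
#'
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the two
#' sequences; observed difference counts Sd and Nd are pathway averages per
#' column; proportions pS = Sd/S and pN = Nd/N receive the Jukes-Cantor
#' correction. A proportion of 3/4 or more is saturated and the
#' corresponding rate is reported as `Inf` (the saturation filters then
#' discard it). `dS = 0` yields the sentinel `omega = 999` so that zero
#' synonymous divergence always falls in the `dN/dS > 99` discard bucket.
#'
#' @param ca A codon alignment from [backthread_codon_alignment()] (or any
#'   list with character vectors `codons_a`, `codons_b`).
#' @inheritParams ng86_count_sites
#' @return A `dnds_estimate` (list) with fields `gene_a`, `gene_b`, `method`,
#'   `S`, `N`, `Sd`, `Nd`, `dS`, `dN`, `omega`, `kappa`, `converged`.
#' @export
ng86_estimate <- function(ca, code = "11") {
  mach <- codon_machinery(code)
  if (length(ca$codons_a) == 0L) {
    stop("empty codon alignment")
  }
  ia <- .codon_index(ca$codons_a, mach, "codons_a")
  ib <- .codon_index(ca$codons_b, mach, "codons_b")
  S <- (sum(mach$s_ng86[ia]) + sum(mach$s_ng86[ib])) / 2
  N <- 3 * length(ia) - S
  pid <- (ia - 1L) * mach$n_sense + ib
  Sd <- sum(mach$sd_eq[pid])
  Nd <- sum(mach$nd_eq[pid])
  dS <- if (S > 0) .jc_correct(Sd / S) else NA_real_
  dN <- if (N > 0) .jc_correct(Nd / N) else NA_real_
  new_dnds_estimate(ca$gene_a, ca$gene_b, "NG86",
                    S = S, N = N, Sd = Sd, Nd = Nd, dS = dS, dN = dN,
                    kappa = 1, converged = TRUE)
}

## shared constructor: derives omega (with the dS = 0 sentinel) from dN, dS
new_dnds_estimate <- function(gene_a, gene_b, method, S, N, Sd, Nd, dS, dN,
                              kappa, converged) {
  omega <- if (is.na(dS) || is.na(dN)) {
    NA_real_
  } else if (dS == 0) {
    999
  } else {
    dN / dS
  }
  structure(
    list(gene_a = if (is.null(gene_a)) NA_character_ else gene_a,
         gene_b = if (is.null(gene_b)) NA_character_ else gene_b,
         method = method, S = S, N = N, Sd = Sd, Nd = Nd,
         dS = dS, dN = dN, omega = omega, kappa = kappa,
         converged = converged),
    class = "dnds_estimate")
}

#' @export
as.data.frame.dnds_estimate <- function(x, ...) {
  data.frame(gene_a = x$gene_a, gene_b = x$gene_b, method = x$method,
             S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd,
             dS = x$dS, dN = x$dN, omega = x$omega, kappa = x$kappa,
             converged = x$converged, stringsAsFactors = FALSE)
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("<dnds_estimate %s> %s vs %s: dN = %.4g, dS = %.4g, omega = %.4g\n",
              x$method, x$gene_a, x$gene_b, x$dN, x$dS, x$omega))
  invisible(x)
}

## bind a list of dnds_estimate into one data.frame
dnds_table <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  do.call(rbind, lapply(estimates, as.data.frame))
}
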
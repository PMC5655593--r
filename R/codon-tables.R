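## Codon machinery shared by the counting estimators and the simulator.
## Everything here is derived once per genetic code and cached: the sense
## codon set, single-nucleotide neighbor classification, NG86 site fractions,
## and the full mutational-pathway table for all ordered sense-codon pairs.

.codon_cache <- new.env(parent = emptyenv())

.NT <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

.is_ts <- function(x, y) {
  (x %in% .PURINES) == (y %in% .PURINES)
}

.perms_of <- function(k) {
  switch(k,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
}

#' @noRd
codon_machinery <- function(code = "11") {
  key <- paste0("code_", code)
  cached <- get0(key, envir = .codon_cache)
  if (!is.null(cached)) {
    return(cached)
  }

  gc_map <- Biostrings::getGeneticCode(code)
  all_codons <- names(gc_map)
  sense <- all_codons[gc_map != "*"]
  n_sense <- length(sense)
  aa <- unname(gc_map[sense])
  sense_idx <- stats::setNames(seq_len(n_sense), sense)

  codon_nt <- do.call(rbind, strsplit(sense, ""))

  ## flat table of single-nucleotide neighbors (stop targets dropped, but
  ## counted so the NG86 per-position denominator can exclude them)
  nb_from <- integer(0); nb_pos <- integer(0); nb_to <- integer(0)
  nb_syn <- logical(0); nb_ts <- logical(0)
  n_nonstop <- matrix(0L, n_sense, 3)
  for (i in seq_len(n_sense)) {
    for (p in 1:3) {
      for (nt in setdiff(.NT, codon_nt[i, p])) {
        trip <- codon_nt[i, ]
        trip[p] <- nt
        cod <- paste(trip, collapse = "")
        if (gc_map[[cod]] == "*") next
        j <- sense_idx[[cod]]
        n_nonstop[i, p] <- n_nonstop[i, p] + 1L
        nb_from <- c(nb_from, i); nb_pos <- c(nb_pos, p); nb_to <- c(nb_to, j)
        nb_syn <- c(nb_syn, gc_map[[cod]] == aa[i])
        nb_ts <- c(nb_ts, .is_ts(codon_nt[i, p], nt))
      }
    }
  }
  nb <- data.frame(from = nb_from, pos = nb_pos, to = nb_to,
                   syn = nb_syn, ts = nb_ts)

  ## NG86 synonymous site fractions: per position, synonymous fraction among
  ## single-nucleotide changes with stop targets excluded from the denominator
  syn_by_fp <- rowsum(as.numeric(nb$syn), group = (nb$from - 1L) * 3L + nb$pos)
  frac <- as.numeric(syn_by_fp) / as.numeric(t(n_nonstop))[as.integer(rownames(syn_by_fp))]
  s_ng86 <- as.numeric(rowsum(frac,
    group = (as.integer(rownames(syn_by_fp)) - 1L) %/% 3L + 1L))

  ## per-position degeneracy class (relative to non-stop changes):
  ## 4 = all changes synonymous and none to stop; 0 = all changes
  ## nonsynonymous; 2 = anything else
  degen <- matrix(2L, n_sense, 3)
  for (i in seq_len(n_sense)) {
    for (p in 1:3) {
      rows <- nb$from == i & nb$pos == p
      if (n_nonstop[i, p] == 3L && all(nb$syn[rows])) degen[i, p] <- 4L
      else if (!any(nb$syn[rows])) degen[i, p] <- 0L
    }
  }

  ## mutational pathways for every ordered pair of distinct sense codons:
  ## all orderings of the differing positions, pathways through stop codons
  ## excluded. Step records keep syn/ts class and the target codon (for
  ## frequency-weighted averaging).
  pair_id <- function(i, j) (i - 1L) * n_sense + j
  hamming <- matrix(0L, n_sense, n_sense)
  n_paths <- integer(n_sense * n_sense)
  sd_eq <- numeric(n_sense * n_sense); nd_eq <- numeric(n_sense * n_sense)
  p_pair <- integer(0)
  p_sd <- numeric(0); p_nd <- numeric(0)
  p_sts <- numeric(0); p_stv <- numeric(0)
  p_nts <- numeric(0); p_ntv <- numeric(0)
  st_path <- integer(0); st_syn <- logical(0); st_ts <- logical(0)
  st_to <- integer(0)
  path_counter <- 0L

  for (i in seq_len(n_sense)) {
    for (j in seq_len(n_sense)) {
      if (i == j) next
      diffpos <- which(codon_nt[i, ] != codon_nt[j, ])
      k <- length(diffpos)
      hamming[i, j] <- k
      pid <- pair_id(i, j)
      for (ord in .perms_of(k)) {
        cur <- codon_nt[i, ]
        cur_aa <- aa[i]
        ok <- TRUE
        steps <- vector("list", k)
        for (s in seq_len(k)) {
          p <- diffpos[ord[s]]
          nxt <- cur
          nxt[p] <- codon_nt[j, p]
          cod <- paste(nxt, collapse = "")
          if (gc_map[[cod]] == "*") { ok <- FALSE; break }
          nxt_aa <- gc_map[[cod]]
          steps[[s]] <- list(syn = nxt_aa == cur_aa,
                             ts = .is_ts(cur[p], nxt[p]),
                             to = sense_idx[[cod]])
          cur <- nxt; cur_aa <- nxt_aa
        }
        if (!ok) next
        path_counter <- path_counter + 1L
        n_paths[pid] <- n_paths[pid] + 1L
        syn_v <- vapply(steps, `[[`, logical(1), "syn")
        ts_v <- vapply(steps, `[[`, logical(1), "ts")
        to_v <- vapply(steps, `[[`, integer(1), "to")
        p_pair <- c(p_pair, pid)
        p_sd <- c(p_sd, sum(syn_v)); p_nd <- c(p_nd, sum(!syn_v))
        p_sts <- c(p_sts, sum(syn_v & ts_v)); p_stv <- c(p_stv, sum(syn_v & !ts_v))
        p_nts <- c(p_nts, sum(!syn_v & ts_v)); p_ntv <- c(p_ntv, sum(!syn_v & !ts_v))
        st_path <- c(st_path, rep(path_counter, k))
        st_syn <- c(st_syn, syn_v); st_ts <- c(st_ts, ts_v); st_to <- c(st_to, to_v)
      }
      if (n_paths[pid] > 0L) {
        rows <- p_pair == pid
        sd_eq[pid] <- mean(p_sd[rows]); nd_eq[pid] <- mean(p_nd[rows])
      } else {
        ## every ordering passes through a stop codon: split evenly
        sd_eq[pid] <- k / 2; nd_eq[pid] <- k / 2
      }
    }
  }

  mach <- list(
    code = code, gc_map = gc_map, sense = sense, aa = aa,
    sense_idx = sense_idx, codon_nt = codon_nt, n_sense = n_sense,
    nb = nb, n_nonstop = n_nonstop, s_ng86 = s_ng86, degen = degen,
    hamming = hamming, n_paths = n_paths, sd_eq = sd_eq, nd_eq = nd_eq,
    paths = list(pair = p_pair, sd = p_sd, nd = p_nd,
                 sts = p_sts, stv = p_stv, nts = p_nts, ntv = p_ntv),
    steps = list(path = st_path, syn = st_syn, ts = st_ts, to = st_to)
  )
  assign(key, mach, envir = .codon_cache)
  mach
}

## map a character vector of codons to sense indices; error on anything else
.codon_index <- function(codons, mach, what = "codon") {
  idx <- mach$sense_idx[codons]
  bad <- is.na(idx)
  if (any(bad)) {
    stop(sprintf("%s is not a sense codon under code %s: %s",
                 what, mach$code, paste(unique(codons[bad]), collapse = ", ")))
  }
  unname(idx)
}

## restrict the pathway tables to a set of codon-pair ids so the omega
## iteration only touches the pairs actually present in one alignment
.pathway_subset <- function(mach, pids) {
  upairs <- sort(unique(pids))
  psel <- which(mach$paths$pair %in% upairs)
  ssel <- which(mach$steps$path %in% psel)
  blocked <- mach$n_paths[upairs] == 0L & .pair_hamming(mach, upairs) > 0L
  list(upairs = upairs, n = length(upairs),
       p_pair = match(mach$paths$pair[psel], upairs),
       p_counts = cbind(1, mach$paths$sd[psel], mach$paths$nd[psel],
                        mach$paths$sts[psel], mach$paths$stv[psel],
                        mach$paths$nts[psel], mach$paths$ntv[psel]),
       s_path = match(mach$steps$path[ssel], psel),
       s_ts = mach$steps$ts[ssel], s_syn = mach$steps$syn[ssel],
       s_to = mach$steps$to[ssel],
       blocked = which(blocked),
       blocked_k = .pair_hamming(mach, upairs)[blocked])
}

## pathway-weighted difference counts over a pathway subset. Weight of a
## pathway is the product over its steps of
## pi[target] * kappa^[transition] * omega^[nonsynonymous]; weights
## renormalize within each pair. kappa = 1, omega = 1, uniform pi gives the
## NG86 equal-weight average. Returns a matrix (one row per pair in
## sub$upairs) with columns sd, nd, sts, stv, nts, ntv.
.weighted_counts_sub <- function(sub, pi61, kappa, omega) {
  omega <- min(max(omega, 1e-6), 1e6)
  kappa <- min(max(kappa, 1e-6), 1e6)
  out <- matrix(0, sub$n, 6,
                dimnames = list(NULL, c("sd", "nd", "sts", "stv", "nts", "ntv")))
  if (length(sub$s_path)) {
    lw <- log(pi61[sub$s_to]) + log(kappa) * sub$s_ts + log(omega) * (!sub$s_syn)
    w <- exp(as.numeric(rowsum(lw, group = sub$s_path)))
    agg <- rowsum(w * sub$p_counts, group = sub$p_pair)
    rows <- as.integer(rownames(agg))
    out[rows, ] <- agg[, -1, drop = FALSE] / agg[, 1]
  }
  if (length(sub$blocked)) {
    k <- sub$blocked_k
    out[sub$blocked, ] <- cbind(k / 2, k / 2, k / 4, k / 4, k / 4, k / 4)
  }
  out
}

.pair_hamming <- function(mach, pid) {
  i <- (pid - 1L) %/% mach$n_sense + 1L
  j <- (pid - 1L) %% mach$n_sense + 1L
  mach$hamming[cbind(i, j)]
}
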
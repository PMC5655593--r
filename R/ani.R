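#' Fragment-based average nucleotide identity between two genomes
#'
#' Each genome is cut into consecutive non-overlapping fragments of
#' `fragment_len` bp (default 1020, the Goris convention); each fragment is
#' aligned to its best location in the other genome by local alignment
#' (candidate locations found with exact seed matches, refined by
#' Smith-Waterman; fragments without a seed hit fall back to a full-genome
#' local alignment when `exhaustive = TRUE`). A fragment contributes when it
#' reaches at least `min_identity` percent identity over at least
#' `min_alignable` percent of its length. The reported ANI is the mean
#' identity of contributing fragments, symmetrized as the mean of the
#' a-to-b and b-to-a values, so the result does not depend on argument
#' order. When no fragment passes in either direction the ANI is missing
#' (`NA`), not 0.
#'
#' @param a,b `genome_record` objects.
#' @param fragment_len Fragment length in bp.
#' @param min_identity,min_alignable The acceptance gate (percent).
#' @param both_strands Also try each fragment's reverse complement.
#' @param exhaustive Full-genome local alignment for fragments without any
#'   seed hit (exact but slower); when `FALSE` such fragments simply fail.
#' @param seed_len,seed_step Exact-seed length and spacing used to propose
#'   candidate locations.
#' @return An `ani_result`: list with `genome_a`, `genome_b`, `ani_pct`,
#'   `n_fragments_used`, `n_fragments_total`.
#' @export
compute_ani <- function(a, b, fragment_len = 1020, min_identity = 30,
                        min_alignable = 70, both_strands = TRUE,
                        exhaustive = TRUE, seed_len = 12L, seed_step = 20L) {
  if (sum(Biostrings::width(a$contigs)) == 0L ||
      sum(Biostrings::width(b$contigs)) == 0L) {
    stop("both genomes must be non-empty")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  dir_ab <- .ani_direction(a, b, fragment_len, min_identity, min_alignable,
                           both_strands, exhaustive, seed_len, seed_step, submat)
  dir_ba <- .ani_direction(b, a, fragment_len, min_identity, min_alignable,
                           both_strands, exhaustive, seed_len, seed_step, submat)
  vals <- c(dir_ab$mean_identity, dir_ba$mean_identity)
  ani <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                 ani_pct = ani,
                 n_fragments_used = dir_ab$used + dir_ba$used,
                 n_fragments_total = dir_ab$total + dir_ba$total),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ANI = %s%% (%d/%d fragments)\n",
              x$genome_a, x$genome_b,
              if (is.na(x$ani_pct)) "NA" else sprintf("%.2f", x$ani_pct),
              x$n_fragments_used, x$n_fragments_total))
  invisible(x)
}

.ani_direction <- function(qry, sbj, fragment_len, min_identity,
                           min_alignable, both_strands, exhaustive,
                           seed_len, seed_step, submat) {
  sbj_chr <- lapply(seq_along(sbj$contigs),
                    function(i) as.character(sbj$contigs[[i]]))
  sbj_idx <- lapply(sbj_chr, .kmer_index, k = seed_len)
  identities <- numeric(0)
  total <- 0L
  for (ci in seq_along(qry$contigs)) {
    chr <- as.character(qry$contigs[[ci]])
    n_frag <- nchar(chr) %/% fragment_len
    if (n_frag == 0L) next
    for (f in seq_len(n_frag)) {
      total <- total + 1L
      frag <- substr(chr, (f - 1L) * fragment_len + 1L, f * fragment_len)
      best <- .best_fragment_hit(frag, sbj_chr, sbj_idx, both_strands,
                                 exhaustive, seed_len, seed_step, submat,
                                 fragment_len)
      if (!is.null(best) && best$identity >= min_identity &&
          best$alignable >= min_alignable) {
        identities <- c(identities, best$identity)
      }
    }
  }
  list(mean_identity = if (length(identities)) mean(identities) else NA_real_,
       used = length(identities), total = total)
}

## hashed position lookup of every k-mer in a subject string
.kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(new.env(parent = emptyenv()))
  km <- substring(s, seq_len(n - k + 1L), seq(k, n))
  list2env(split(seq_len(n - k + 1L), km), hash = TRUE,
           parent = emptyenv())
}

## best local alignment of one fragment against indexed subject contigs
.best_fragment_hit <- function(frag, sbj_chr, sbj_idx, both_strands,
                               exhaustive, seed_len, seed_step, submat,
                               fragment_len) {
  variants <- frag
  if (both_strands) {
    variants <- c(variants, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(frag))))
  }
  offsets <- seq(1L, fragment_len - seed_len + 1L, by = seed_step)
  best <- NULL
  any_candidate <- FALSE
  for (fv in variants) {
    seeds <- substring(fv, offsets, offsets + seed_len - 1L)
    for (ci in seq_along(sbj_chr)) {
      idx <- sbj_idx[[ci]]
      implied <- integer(0)
      for (s in seq_along(seeds)) {
        hits <- get0(seeds[s], envir = idx)
        if (!is.null(hits)) implied <- c(implied, hits - offsets[s] + 1L)
      }
      if (length(implied) == 0L) next
      any_candidate <- TRUE
      ## several seeds agreeing on one exact start means a collinear
      ## (gap-free) placement: score it directly without dynamic
      ## programming, falling back to local alignment when the ungapped
      ## identity is unconvincing (possible indel) or seeds disagree
      exact <- table(implied)
      exact_best <- as.integer(names(exact)[which.max(exact)])
      if (max(exact) >= 3L) {
        r <- .ungapped_identity(fv, sbj_chr[[ci]], exact_best, fragment_len)
        if (!is.null(r) && r$identity >= 70) {
          if (is.null(best) || r$score > best$score) best <- r
          next
        }
      }
      ## vote on implied start positions, coarsened to absorb small
      ## shifts; refine the top distinct loci by local alignment in a
      ## window around each
      votes <- table(round(implied / 25) * 25)
      starts <- as.integer(names(sort(votes, decreasing = TRUE)))
      distinct <- starts[1]
      for (st in starts[-1]) {
        if (all(abs(st - distinct) > 100L)) distinct <- c(distinct, st)
      }
      for (st in utils::head(distinct, 2L)) {
        lo <- max(1L, st - 60L)
        hi <- min(nchar(sbj_chr[[ci]]), st + fragment_len + 60L)
        if (hi - lo + 1L < seed_len) next
        win <- substr(sbj_chr[[ci]], lo, hi)
        r <- .local_identity(fv, win, submat, fragment_len)
        if (is.null(best) || r$score > best$score) best <- r
      }
    }
  }
  if (!any_candidate && exhaustive) {
    for (fv in variants) {
      for (ci in seq_along(sbj_chr)) {
        r <- .local_identity(fv, sbj_chr[[ci]], submat, fragment_len)
        if (is.null(best) || r$score > best$score) best <- r
      }
    }
  }
  best
}

## gap-free placement of a fragment at a known subject start; scored on the
## same match/mismatch scale as the local alignment so results compare
.ungapped_identity <- function(frag, sbj, st, fragment_len) {
  lo <- max(1L, st)
  hi <- min(nchar(sbj), st + fragment_len - 1L)
  off <- lo - st
  span <- hi - lo + 1L
  if (span < fragment_len / 2) return(NULL)
  fchars <- strsplit(substr(frag, 1L + off, off + span), "")[[1]]
  schars <- strsplit(substr(sbj, lo, hi), "")[[1]]
  nm <- sum(fchars == schars)
  list(score = 2 * nm - 3 * (span - nm),
       identity = 100 * nm / span,
       alignable = 100 * span / fragment_len)
}

.local_identity <- function(frag, subject, submat, fragment_len) {
  if (is.character(frag)) frag <- Biostrings::DNAString(frag)
  if (is.character(subject)) subject <- Biostrings::DNAString(subject)
  pa <- Biostrings::pairwiseAlignment(frag, subject,
                                      substitutionMatrix = submat,
                                      gapOpening = 5, gapExtension = 2,
                                      type = "local")
  aq <- as.character(Biostrings::alignedPattern(pa))
  aln_len <- nchar(aq)
  frag_span <- nchar(gsub("-", "", aq, fixed = TRUE))
  list(score = Biostrings::score(pa),
       identity = if (aln_len > 0) 100 * Biostrings::nmatch(pa) / aln_len else 0,
       alignable = 100 * frag_span / fragment_len)
}
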
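#' Optimal global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Exact global alignment under BLOSUM62 with affine gap penalties (open 11,
#' extend 1 by default), used both as the search score for bidirectional
#' best hits and as the alignment passed to codon back-threading. Percent
#' identity is computed over aligned residue pairs (gapless columns);
#' coverage is the percent of each sequence's residues sitting in gapless
#' columns.
#'
#' @param a,b Amino-acid sequences (character strings).
#' @param query_id,subject_id Identifiers stored on the result.
#' @param substitution_matrix Name of a scoring matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A `protein_alignment`: list with `query_id`, `subject_id`,
#'   `aligned_query`, `aligned_subject`, `score`, `pct_identity`,
#'   `query_coverage`, `subject_coverage`.
#' @export
align_proteins_global <- function(a, b, query_id = "query",
                                  subject_id = "subject",
                                  substitution_matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  .protein_alignment_from_pa(pa, a, b, query_id, subject_id)
}

.protein_alignment_from_pa <- function(pa, a, b, query_id, subject_id,
                                       i = 1L) {
  st <- .gapped_alignment_strings(pa, i, a, b)
  .protein_alignment_from_strings(st$aq, st$as, Biostrings::score(pa)[i],
                                  nchar(a), nchar(b), query_id, subject_id)
}

## Reconstruct the both-gapped alignment strings of element i of a
## PairwiseAlignments object from its indel ranges (the bulk accessors
## alignedPattern/alignedSubject are prohibitively slow per element). An
## indel range (start, width) on a sequence means: insert `width` gaps
## before that sequence's residue `start`.
.gapped_alignment_strings <- function(pa, i, a, b) {
  pp <- Biostrings::pattern(pa)
  ss <- Biostrings::subject(pa)
  sp <- Biostrings::start(pp)[i]; ep <- Biostrings::end(pp)[i]
  s2 <- Biostrings::start(ss)[i]; e2 <- Biostrings::end(ss)[i]
  Pc <- strsplit(substr(a, sp, ep), "")[[1]]
  Sc <- strsplit(substr(b, s2, e2), "")[[1]]
  ip <- Biostrings::indel(pp)[[i]]
  is_ <- Biostrings::indel(ss)[[i]]
  gp_start <- IRanges::start(ip); gp_w <- IRanges::width(ip)
  gs_start <- IRanges::start(is_); gs_w <- IRanges::width(is_)
  np <- length(Pc); ns <- length(Sc)
  L <- np + sum(gp_w)
  aq <- character(L); as_ <- character(L)
  pi <- 1L; si <- 1L; col <- 0L; kp <- 1L; ks <- 1L
  while (pi <= np || si <= ns) {
    if (kp <= length(gp_start) && pi == gp_start[kp]) {
      w <- gp_w[kp]
      aq[col + seq_len(w)] <- "-"
      as_[col + seq_len(w)] <- Sc[si + seq_len(w) - 1L]
      col <- col + w; si <- si + w; kp <- kp + 1L
    } else if (ks <= length(gs_start) && si == gs_start[ks]) {
      w <- gs_w[ks]
      aq[col + seq_len(w)] <- Pc[pi + seq_len(w) - 1L]
      as_[col + seq_len(w)] <- "-"
      col <- col + w; pi <- pi + w; ks <- ks + 1L
    } else {
      col <- col + 1L
      aq[col] <- Pc[pi]; as_[col] <- Sc[si]
      pi <- pi + 1L; si <- si + 1L
    }
  }
  core_q <- paste(aq[seq_len(col)], collapse = "")
  core_s <- paste(as_[seq_len(col)], collapse = "")
  pre_p <- substr(a, 1L, sp - 1L); pre_s <- substr(b, 1L, s2 - 1L)
  post_p <- substr(a, ep + 1L, nchar(a)); post_s <- substr(b, e2 + 1L, nchar(b))
  list(aq = paste0(pre_p, strrep("-", nchar(pre_s)), core_q,
                   post_p, strrep("-", nchar(post_s))),
       as = paste0(strrep("-", nchar(pre_p)), pre_s, core_s,
                   strrep("-", nchar(post_p)), post_s))
}

.protein_alignment_from_strings <- function(aq, as_, score, len_a, len_b,
                                            query_id, subject_id) {
  qa <- strsplit(aq, "")[[1]]
  sa <- strsplit(as_, "")[[1]]
  paired <- qa != "-" & sa != "-"
  n_pairs <- sum(paired)
  ident <- if (n_pairs > 0) 100 * sum(qa[paired] == sa[paired]) / n_pairs else 0
  structure(list(
    query_id = query_id, subject_id = subject_id,
    aligned_query = aq, aligned_subject = as_,
    score = score, pct_identity = ident,
    query_coverage = 100 * n_pairs / len_a,
    subject_coverage = 100 * n_pairs / len_b),
    class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %s vs %s: score %.1f, identity %.1f%%, coverage %.0f%%/%.0f%%\n",
              x$query_id, x$subject_id, x$score, x$pct_identity,
              x$query_coverage, x$subject_coverage))
  invisible(x)
}

## Shared k-mer counts between two proteomes as a dense base matrix
## (rows = a, cols = b); the cheap prefilter in front of exact alignment.
.shared_kmer_counts <- function(seqs_a, seqs_b, k = 4L) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  ka <- lapply(seqs_a, kmers_of)
  kb <- lapply(seqs_b, kmers_of)
  flat_a <- unlist(ka, use.names = FALSE)
  flat_b <- unlist(kb, use.names = FALSE)
  lev <- unique(c(flat_a, flat_b))
  ia <- match(flat_a, lev)
  ib <- match(flat_b, lev)
  A <- Matrix::sparseMatrix(
    i = rep(seq_along(ka), lengths(ka)), j = ia,
    x = 1, dims = c(length(ka), length(lev)))
  B <- Matrix::sparseMatrix(
    i = rep(seq_along(kb), lengths(kb)), j = ib,
    x = 1, dims = c(length(kb), length(lev)))
  as.matrix(A %*% Matrix::t(B))
}

## Candidate (i, j) index pairs: for each row its top n_candidates columns by
## shared k-mers (nonzero only), unioned with each column's top rows, so the
## candidate set is symmetric in the two proteomes.
.candidate_pairs <- function(counts, n_candidates) {
  top_of <- function(v, ids) {
    nz <- which(v > 0)
    if (length(nz) == 0L) return(integer(0))
    nz[order(-v[nz], ids[nz])][seq_len(min(n_candidates, length(nz)))]
  }
  if (!is.finite(n_candidates)) {
    return(cbind(i = rep(seq_len(nrow(counts)), ncol(counts)),
                 j = rep(seq_len(ncol(counts)), each = nrow(counts))))
  }
  ids_a <- rownames(counts); ids_b <- colnames(counts)
  by_row <- lapply(seq_len(nrow(counts)), function(i) {
    js <- top_of(counts[i, ], ids_b)
    if (length(js)) cbind(i = i, j = js)
  })
  by_col <- lapply(seq_len(ncol(counts)), function(j) {
    is <- top_of(counts[, j], ids_a)
    if (length(is)) cbind(i = is, j = j)
  })
  pairs <- do.call(rbind, c(by_row, by_col))
  if (is.null(pairs)) return(cbind(i = integer(0), j = integer(0)))
  unique(pairs)
}

## Align all candidate pairs, batched by subject to amortize call overhead.
## Only cheap per-element statistics (score, match/mismatch counts) are
## extracted up front; full gapped strings are reconstructed on demand for
## the pairs that survive best-hit selection.
.align_candidates <- function(seqs_a, seqs_b, pairs, substitution_matrix,
                              gap_open, gap_extend) {
  n <- nrow(pairs)
  score <- numeric(n); n_paired <- integer(n); n_match <- integer(n)
  pa_of <- vector("list", n); elt_of <- integer(n)
  for (j in unique(pairs[, "j"])) {
    rows <- which(pairs[, "j"] == j)
    is <- pairs[rows, "i"]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs_a[is]), Biostrings::AAString(seqs_b[[j]]),
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global")
    score[rows] <- Biostrings::score(pa)
    nm <- Biostrings::nmatch(pa)
    n_match[rows] <- nm
    n_paired[rows] <- nm + Biostrings::nmismatch(pa)
    for (r in seq_along(rows)) {
      pa_of[[rows[r]]] <- pa
      elt_of[rows[r]] <- r
    }
  }
  len_a <- nchar(seqs_a)[pairs[, "i"]]
  len_b <- nchar(seqs_b)[pairs[, "j"]]
  list(score = score,
       identity = ifelse(n_paired > 0, 100 * n_match / n_paired, 0),
       coverage_a = 100 * n_paired / len_a,
       coverage_b = 100 * n_paired / len_b,
       build = function(r) {
         i <- pairs[r, "i"]; j <- pairs[r, "j"]
         st <- .gapped_alignment_strings(pa_of[[r]], elt_of[r],
                                         seqs_a[[i]], seqs_b[[j]])
         .protein_alignment_from_strings(st$aq, st$as, score[r],
                                         nchar(seqs_a[[i]]), nchar(seqs_b[[j]]),
                                         names(seqs_a)[i], names(seqs_b)[j])
       })
}

#' Single-linkage paralog clustering of a proteome
#'
#' Two proteins are linked when their global alignment reaches
#' `identity_threshold` percent identity with both coverages at least
#' `coverage_threshold`; clusters are the connected components. Each cluster
#' is represented by its longest member (ties broken by lexicographic id),
#' which collapses recent duplicates before best-hit pairing so paralogs do
#' not break reciprocity.
#'
#' @param proteome Named character vector (or [Biostrings::AAStringSet]) of
#'   protein sequences.
#' @param identity_threshold,coverage_threshold Percent thresholds in
#'   (0, 100].
#' @param substitution_matrix,gap_open,gap_extend Passed to the aligner.
#' @return List with `clusters` (list of member id vectors) and
#'   `representatives` (character vector of representative ids).
#' @export
cluster_paralogs <- function(proteome, identity_threshold = 90,
                             coverage_threshold = 90,
                             substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 100)
  seqs <- .as_named_chars(proteome)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) {
    counts <- .shared_kmer_counts(seqs, seqs)
    ## near-identical sequences share most k-mers; demand a third of the
    ## smaller set before paying for an exact alignment
    nk <- diag(counts)
    thr <- outer(nk, nk, pmin) / 3
    cand <- which(counts >= thr & upper.tri(counts), arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      al <- align_proteins_global(seqs[[i]], seqs[[j]],
                                  names(seqs)[i], names(seqs)[j],
                                  substitution_matrix, gap_open, gap_extend)
      if (al$pct_identity >= identity_threshold &&
          al$query_coverage >= coverage_threshold &&
          al$subject_coverage >= coverage_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(names(seqs), roots)
  names(clusters) <- NULL
  reps <- vapply(clusters, function(ids) {
    lens <- nchar(seqs[ids])
    ids[order(-lens, ids)][1]
  }, character(1))
  list(clusters = clusters, representatives = sort(reps))
}

.as_named_chars <- function(x) {
  if (methods::is(x, "AAStringSet")) x <- as.character(x)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("proteome must have unique sequence names")
  }
  x
}

#' Bidirectional-best-hit ortholog pairs between two proteomes
#'
#' Paralogs are first collapsed to cluster representatives within each
#' genome (see [cluster_paralogs()]); every representative is then scored
#' against its candidate partners (shared k-mer prefilter, exact global
#' alignment) and a pair is emitted when the two genes are each other's
#' best-scoring hit and the alignment passes the identity/coverage gates.
#' Tie-breaking is deterministic: score, then percent identity, then
#' lexicographic id. Each gene appears in at most one pair.
#'
#' @param proteome_a,proteome_b Named character vectors (or
#'   [Biostrings::AAStringSet]) of protein sequences, one per genome.
#' @param min_identity,min_coverage Acceptance gates (percent; coverage must
#'   hold for both sequences).
#' @param n_candidates Candidate partners per gene examined by the shared
#'   k-mer prefilter; `Inf` scores every cross-genome pair (exact
#'   brute-force mode).
#' @param collapse_paralogs Collapse within-genome paralogs (default TRUE).
#' @param cluster_identity,cluster_coverage Thresholds for the paralog
#'   collapse.
#' @inheritParams align_proteins_global
#' @return A `bbh_result`: list with `pairs` (data.frame `gene_a`, `gene_b`,
#'   `score`, `pct_identity`, `coverage_a`, `coverage_b`) and `alignments`
#'   (list of `protein_alignment`, parallel to the rows).
#' @export
find_bbh_pairs <- function(proteome_a, proteome_b,
                           min_identity = 30, min_coverage = 50,
                           n_candidates = 3, collapse_paralogs = TRUE,
                           cluster_identity = 90, cluster_coverage = 90,
                           substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  seqs_a <- .as_named_chars(proteome_a)
  seqs_b <- .as_named_chars(proteome_b)
  if (length(seqs_a) == 0L || length(seqs_b) == 0L) {
    stop("both proteomes must be non-empty")
  }
  if (collapse_paralogs) {
    seqs_a <- seqs_a[cluster_paralogs(seqs_a, cluster_identity,
                                      cluster_coverage, substitution_matrix,
                                      gap_open, gap_extend)$representatives]
    seqs_b <- seqs_b[cluster_paralogs(seqs_b, cluster_identity,
                                      cluster_coverage, substitution_matrix,
                                      gap_open, gap_extend)$representatives]
  }
  counts <- .shared_kmer_counts(seqs_a, seqs_b)
  rownames(counts) <- names(seqs_a); colnames(counts) <- names(seqs_b)
  cand <- .candidate_pairs(counts, n_candidates)
  empty <- list(pairs = data.frame(gene_a = character(0), gene_b = character(0),
                                   score = numeric(0), pct_identity = numeric(0),
                                   coverage_a = numeric(0), coverage_b = numeric(0)),
                alignments = list())
  class(empty) <- "bbh_result"
  if (nrow(cand) == 0L) return(empty)
  als <- .align_candidates(seqs_a, seqs_b, cand, substitution_matrix,
                           gap_open, gap_extend)
  score <- als$score
  ident <- als$identity

  best_in <- function(idx_col, other_ids) {
    ## index into cand rows of the best hit per value of idx_col
    best <- integer(0)
    for (v in unique(cand[, idx_col])) {
      rows <- which(cand[, idx_col] == v)
      r <- rows[order(-score[rows], -ident[rows], other_ids[rows])][1]
      best[[as.character(v)]] <- r
    }
    best
  }
  best_a <- best_in("i", colnames(counts)[cand[, "j"]])
  best_b <- best_in("j", rownames(counts)[cand[, "i"]])

  keep <- integer(0)
  for (i in names(best_a)) {
    r <- best_a[[i]]
    j <- cand[r, "j"]
    if (identical(best_b[[as.character(j)]], r)) keep <- c(keep, r)
  }
  if (length(keep) == 0L) return(empty)
  keep <- keep[als$identity[keep] >= min_identity &
                 als$coverage_a[keep] >= min_coverage &
                 als$coverage_b[keep] >= min_coverage]
  if (length(keep) == 0L) return(empty)
  al_keep <- lapply(keep, als$build)
  pairs <- data.frame(
    gene_a = vapply(al_keep, `[[`, character(1), "query_id"),
    gene_b = vapply(al_keep, `[[`, character(1), "subject_id"),
    score = vapply(al_keep, `[[`, numeric(1), "score"),
    pct_identity = vapply(al_keep, `[[`, numeric(1), "pct_identity"),
    coverage_a = vapply(al_keep, `[[`, numeric(1), "query_coverage"),
    coverage_b = vapply(al_keep, `[[`, numeric(1), "subject_coverage"),
    stringsAsFactors = FALSE)
  ord <- order(pairs$gene_a)
  out <- list(pairs = pairs[ord, , drop = FALSE], alignments = al_keep[ord])
  rownames(out$pairs) <- NULL
  class(out) <- "bbh_result"
  out
}

#' @export
print.bbh_result <- function(x, ...) {
  cat(sprintf("<bbh_result> %d reciprocal best-hit pair(s)\n", nrow(x$pairs)))
  invisible(x)
}

#' Bidirectional best hits from precomputed tabular search results
#'
#' Plug-in path for externally computed similarity searches (BLAST
#' outfmt-6-style tables) on inputs too large for exact alignment. Best hits
#' are taken by bitscore (ties by percent identity, then subject id) and a
#' pair is emitted when reciprocal.
#'
#' @param hits_ab,hits_ba data.frames with columns `qseqid`, `sseqid`,
#'   `pident`, `bitscore` (extra columns ignored): hits of genome A queried
#'   against B, and of B against A.
#' @param min_identity Minimum percent identity.
#' @return data.frame with `gene_a`, `gene_b`, `bitscore`, `pct_identity`.
#' @export
bbh_from_hit_tables <- function(hits_ab, hits_ba, min_identity = 30) {
  best_of <- function(h) {
    h <- h[order(h$qseqid, -h$bitscore, -h$pident, h$sseqid), ]
    h[!duplicated(h$qseqid), ]
  }
  ba <- best_of(hits_ab)
  bb <- best_of(hits_ba)
  m <- match(ba$sseqid, bb$qseqid)
  recip <- !is.na(m) & bb$sseqid[m] == ba$qseqid
  ba <- ba[recip & ba$pident >= min_identity, ]
  data.frame(gene_a = ba$qseqid, gene_b = ba$sseqid,
             bitscore = ba$bitscore, pct_identity = ba$pident,
             stringsAsFactors = FALSE)
}
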
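test_that("global protein alignment scores, identity and coverage are exact", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  # self-alignment: full identity, score = sum of diagonal entries
  al <- align_proteins_global("MKV", "MKV")
  expect_equal(al$pct_identity, 100)
  expect_false(grepl("-", al$aligned_query))
  expect_equal(al$score,
               BLOSUM62["M", "M"] + BLOSUM62["K", "K"] + BLOSUM62["V", "V"])
  # single substitution: identity 2/3, no gaps (verified against the 3x3
  # dynamic-programming table: diagonal beats any gap under open 11)
  al2 <- align_proteins_global("MKV", "MRV")
  expect_equal(al2$pct_identity, 100 * 2 / 3, tolerance = 1e-12)
  expect_false(grepl("-", al2$aligned_query))
  expect_equal(al2$score,
               BLOSUM62["M", "M"] + BLOSUM62["K", "R"] + BLOSUM62["V", "V"])
  # coverage is per-sequence
  al3 <- align_proteins_global("MK", "MKKK")
  expect_equal(al3$query_coverage, 100)
  expect_equal(al3$subject_coverage, 50)
  expect_error(align_proteins_global("", "MK"), "empty")
})

test_that("gapped alignment strings reconstruct both input sequences", {
  set.seed(12)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    a <- paste(sample(aas, sample(20:60, 1), TRUE), collapse = "")
    chars <- strsplit(a, "")[[1]]
    b <- paste(c(chars[runif(nchar(a)) > 0.25],
                 sample(aas, sample(0:8, 1), TRUE)), collapse = "")
    al <- align_proteins_global(a, b)
    expect_identical(gsub("-", "", al$aligned_query), a)
    expect_identical(gsub("-", "", al$aligned_subject), b)
    expect_equal(nchar(al$aligned_query), nchar(al$aligned_subject))
  }
})

test_that("paralog clustering is single linkage with a longest representative", {
  base <- paste(rep("MKVLLWWFDEYHRPQN", 4), collapse = "")
  mutate_at <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  p <- c(x1 = base, x2 = base, x3 = base)
  cl <- cluster_paralogs(p)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(cl$representatives, "x1")   # tie broken lexicographically
  # unrelated sequences stay apart
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  q <- c(u1 = paste(sample(aas, 60, TRUE), collapse = ""),
         u2 = paste(sample(aas, 60, TRUE), collapse = ""))
  cl2 <- cluster_paralogs(q)
  expect_equal(length(cl2$clusters), 2L)
  # chain A~B~C links into one cluster even though A!~C
  a <- base
  b <- a; for (i in seq(1, 60, 10)) b <- mutate_at(b, i, "A")
  c_ <- b; for (i in seq(5, 60, 10)) c_ <- mutate_at(c_, i, "G")
  chain <- c(A = a, B = b, C = c_)
  cl3 <- cluster_paralogs(chain, identity_threshold = 85)
  expect_equal(length(cl3$clusters), 1L)
})

test_that("identical proteomes pair every gene with its copy", {
  set.seed(6)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pa <- vapply(1:8, function(i) paste(sample(aas, 60, TRUE), collapse = ""),
               character(1))
  names(pa) <- sprintf("g%02d", 1:8)
  res <- find_bbh_pairs(pa, pa)
  expect_equal(nrow(res$pairs), 8L)
  expect_identical(res$pairs$gene_a, res$pairs$gene_b)
  expect_true(all(res$pairs$pct_identity == 100))
})

test_that("non-reciprocal hits are not emitted and genes pair at most once", {
  # b1 is closest to a1; but a1's best hit is b2 (a higher-scoring copy of
  # a1): a1<->b2 pair; b1 keeps no partner
  a1 <- paste(rep("MKVLLWWFDEYHRPQN", 4), collapse = "")
  b2 <- a1
  b1 <- a1; substr(b1, 1, 8) <- "AAAAAAAA"
  res <- find_bbh_pairs(c(a1 = a1), c(b1 = b1, b2 = b2),
                        collapse_paralogs = FALSE)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$gene_b, "b2")
  expect_equal(anyDuplicated(c(res$pairs$gene_a)), 0L)
})

test_that("BBH is symmetric and matches the brute-force mutual argmax", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function(n) {
    s <- vapply(seq_len(n), function(i) paste(sample(aas, 50, TRUE), collapse = ""),
                character(1))
    names(s) <- sprintf("s%02d", seq_len(n))
    s
  }
  pa <- mk(6); pb <- mk(7)
  # drift some b sequences from a so there are real homolog pairs
  for (i in 1:4) {
    ch <- strsplit(pa[[i]], "")[[1]]
    mut <- sample(50, 6)
    ch[mut] <- sample(aas, 6, TRUE)
    pb[[i]] <- paste(ch, collapse = "")
  }
  res_ab <- find_bbh_pairs(pa, pb, n_candidates = Inf, min_identity = 0.1,
                           min_coverage = 0.1, collapse_paralogs = FALSE)
  res_ba <- find_bbh_pairs(pb, pa, n_candidates = Inf, min_identity = 0.1,
                           min_coverage = 0.1, collapse_paralogs = FALSE)
  expect_setequal(paste(res_ab$pairs$gene_a, res_ab$pairs$gene_b),
                  paste(res_ba$pairs$gene_b, res_ba$pairs$gene_a))
  # brute-force oracle: mutual argmax of the full score matrix
  scores <- matrix(NA_real_, length(pa), length(pb),
                   dimnames = list(names(pa), names(pb)))
  for (i in names(pa)) for (j in names(pb)) {
    scores[i, j] <- align_proteins_global(pa[[i]], pb[[j]])$score
  }
  mutual <- character(0)
  for (i in names(pa)) {
    j <- colnames(scores)[which.max(scores[i, ])]
    if (rownames(scores)[which.max(scores[, j])] == i) {
      mutual <- c(mutual, paste(i, j))
    }
  }
  expect_setequal(paste(res_ab$pairs$gene_a, res_ab$pairs$gene_b), mutual)
})

test_that("true ortholog pairs are recovered from a simulated genome pair", {
  sp <- shared_sim_pair()
  res <- find_bbh_pairs(sp$genome_a$aa, sp$genome_b$aa)
  truth <- paste(sp$truth$pairing$gene_a, sp$truth$pairing$gene_b)
  found <- paste(res$pairs$gene_a, res$pairs$gene_b)
  recall <- mean(truth %in% found)
  expect_gte(recall, 0.99)
})

test_that("precomputed hit tables yield reciprocal best hits", {
  hits_ab <- data.frame(
    qseqid = c("a1", "a1", "a2"), sseqid = c("b1", "b2", "b1"),
    pident = c(95, 60, 50), bitscore = c(300, 100, 80))
  hits_ba <- data.frame(
    qseqid = c("b1", "b2"), sseqid = c("a1", "a1"),
    pident = c(95, 60), bitscore = c(300, 100))
  out <- bbh_from_hit_tables(hits_ab, hits_ba)
  expect_equal(out$gene_a, "a1")
  expect_equal(out$gene_b, "b1")
})
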
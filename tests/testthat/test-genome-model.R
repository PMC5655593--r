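test_that("read_genome extracts, strand-resolves and translates CDS", {
  set.seed(3)
  gc <- Biostrings::getGeneticCode("11")
  sense <- names(gc)[gc != "*" & gc != "M"]
  body <- paste(sample(sense, 98, replace = TRUE), collapse = "")
  cds_fwd <- paste0("ATG", body)                      # 99 coding codons
  # contig: the 300-bp CDS (with stop) on +, a 4-bp spacer, then the same
  # CDS reverse-complemented (annotated on -)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(cds_fwd, "TAA"))))
  contig <- paste0(cds_fwd, "TAA", "ACGT", rc)
  fa <- tempfile(fileext = ".fna"); tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">c1 test contig", contig), fa)
  write.table(data.frame(gene_id = c("gplus", "gminus", "gbad"),
                         contig_id = "c1",
                         start = c(1, 305, 1),
                         end = c(300, 604, 301),
                         strand = c("+", "-", "+")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_genome(fa, tsv, genome_id = "t1")
  expect_s3_class(g, "genome_record")
  expect_equal(length(g$contigs), 1L)
  expect_equal(nrow(g$cds), 2L)
  # 100 codons with terminal stop -> 99 residues
  expect_equal(nchar(as.character(g$aa[["gplus"]])), 99L)
  # minus-strand CDS recovers the forward coding sequence
  expect_equal(as.character(g$nt[["gminus"]]), paste0(cds_fwd, "TAA"))
  expect_equal(as.character(g$aa[["gminus"]]), as.character(g$aa[["gplus"]]))
  # length-301 CDS is excluded and listed in the skip report
  expect_true("gbad" %in% g$skipped$gene_id)
  expect_match(g$skipped$reason[g$skipped$gene_id == "gbad"], "divisible")
})

test_that("read_genome validates inputs", {
  expect_error(read_genome("nope.fna", "nope.tsv"), "not found")
  fa <- tempfile(fileext = ".fna"); tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">c1", "ATGAAATAA"), fa)
  write.table(data.frame(gene_id = "g1", contig_id = "cX",
                         start = 1, end = 9, strand = "+"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genome(fa, tsv), "unknown contig.*g1")
})

test_that("coding density follows the printed formula in both modes", {
  contig <- strrep("A", 1000)
  cds2 <- data.frame(gene_id = c("g1", "g2"), contig_id = "c1",
                     start = c(1, 1), end = c(300, 300),
                     strand = "+")
  # two fully overlapping 300-bp CDS on a 1000-bp genome
  g <- suppressWarnings(genome_record("t", c(c1 = contig), cds2))
  expect_equal(coding_density(g, "union"), 30)
  expect_equal(coding_density(g, "literal"), 60)
  # no CDS -> 0 with a warning
  g0 <- genome_record("t0", c(c1 = contig), cds2[0, ])
  expect_warning(d0 <- coding_density(g0), "no CDS")
  expect_equal(d0, 0)
})

test_that("union-mode density is invariant to record order and splitting", {
  contig <- strrep("A", 2000)  # poly-Lys, no stops anywhere
  base <- data.frame(gene_id = c("a", "b"), contig_id = "c1",
                     start = c(101, 501), end = c(400, 1100), strand = "+")
  g1 <- suppressWarnings(genome_record("t", c(c1 = contig), base))
  g2 <- suppressWarnings(genome_record("t", c(c1 = contig), base[2:1, ]))
  split_rec <- data.frame(gene_id = c("a1", "a2", "b"), contig_id = "c1",
                          start = c(101, 281, 501), end = c(280, 400, 1100),
                          strand = "+")
  # splitting one CDS into two adjacent records keeps the union identical
  # (split lengths are multiples of 3 so all records survive validation)
  g3 <- suppressWarnings(genome_record("t", c(c1 = contig), split_rec))
  expect_equal(coding_density(g1), coding_density(g2))
  expect_equal(coding_density(g1), coding_density(g3))
  # non-overlapping CDS: union and literal agree exactly
  expect_equal(coding_density(g1, "union"), coding_density(g1, "literal"))
})

test_that("FASTA + GFF3 round trip preserves the genome record", {
  sp <- shared_sim_pair()
  td <- withr::local_tempdir()
  fa <- file.path(td, "a.fna"); gff <- file.path(td, "a.gff3")
  suppressWarnings(write_genome(sp$genome_a, fa, gff))
  g2 <- read_genome(fa, gff, genome_id = sp$genome_a$genome_id)
  expect_identical(as.character(sp$genome_a$contigs), as.character(g2$contigs))
  expect_identical(as.character(sp$genome_a$nt), as.character(g2$nt))
  expect_identical(as.character(sp$genome_a$aa), as.character(g2$aa))
  expect_equal(sp$genome_a$cds[order(sp$genome_a$cds$gene_id), ],
               g2$cds[order(g2$cds$gene_id), ], ignore_attr = TRUE)
})

test_that("genome size metrics report bp, CDS count and density", {
  sp <- shared_sim_pair()
  m <- genome_size_metrics(sp$genome_a)
  expect_equal(m$size_cds, 50L)
  expect_equal(m$size_bp, sum(Biostrings::width(sp$genome_a$contigs)))
  # simulator requested a 20% noncoding fraction
  expect_lt(abs(m$coding_density_pct - 80), 1)
})
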
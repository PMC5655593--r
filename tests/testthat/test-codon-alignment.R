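make_alignment <- function(aq, as_) {
  omegapair:::.protein_alignment_from_strings(
    aq, as_, score = 0,
    len_a = nchar(gsub("-", "", aq)), len_b = nchar(gsub("-", "", as_)),
    query_id = "ga", subject_id = "gb")
}

cds_of <- function(codons, stop = TRUE) {
  paste0(paste(codons, collapse = ""), if (stop) "TAA" else "")
}

test_that("gapless identical alignments thread every codon", {
  cod <- random_sense_codons(99, seed = 91)
  aa <- paste(Biostrings::getGeneticCode("11")[cod], collapse = "")
  al <- make_alignment(aa, aa)
  ca <- backthread_codon_alignment(al, cds_of(cod), cds_of(cod))
  expect_equal(length(ca$codons_a), 99L)
  expect_equal(ca$n_columns_removed, 0L)
  expect_identical(ca$codons_a, unname(cod))
  # a terminal stop on the CDS is tolerated and trimmed
  ca2 <- backthread_codon_alignment(al, cds_of(cod, stop = FALSE), cds_of(cod))
  expect_equal(length(ca2$codons_a), 99L)
})

test_that("gap columns and ambiguous codons are dropped and counted", {
  gc11 <- Biostrings::getGeneticCode("11")
  cod_a <- c("ATG", "AAA", "CCC")
  cod_b <- c("ATG", "CCC")
  aa_a <- paste(gc11[cod_a], collapse = "")
  aa_b <- paste(gc11[cod_b], collapse = "")
  al <- make_alignment("MKP", "M-P")
  ca <- backthread_codon_alignment(al, cds_of(cod_a), cds_of(cod_b))
  expect_equal(length(ca$codons_a), 2L)
  expect_equal(ca$n_columns_removed, 1L)
  # codon containing N in sequence b drops that column
  cod_bn <- c("ATG", "AAA", "CCN")
  al2 <- make_alignment("MKP", "MKX")
  ca2 <- backthread_codon_alignment(al2, cds_of(cod_a),
                                    paste0(paste(cod_bn, collapse = ""), "TAA"))
  expect_equal(length(ca2$codons_a), 2L)
  expect_equal(ca2$n_columns_removed, 1L)
})

test_that("translation mismatches are reported with the gene name", {
  al <- make_alignment("MKP", "MKP")
  expect_error(
    backthread_codon_alignment(al, cds_of(c("ATG", "AAA", "CCC")),
                               cds_of(c("ATG", "AAA", "GGG"))),
    "gb")
  expect_error(
    backthread_codon_alignment(al, cds_of(c("ATG", "AAA")),
                               cds_of(c("ATG", "AAA", "CCC"))),
    "ga")
})
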
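#' Back-thread a protein alignment onto its coding sequences
#'
#' Maps each aligned residue column of a protein alignment to the source
#' codons of the two coding sequences. Columns containing a gap, a codon
#' with an ambiguous base, or a stop codon are dropped and counted in
#' `n_columns_removed`. A terminal stop codon on either CDS is trimmed
#' before threading. The translation of each CDS must match its ungapped
#' aligned residues; a mismatch raises an error naming the gene.
#'
#' @param alignment A `protein_alignment` from [align_proteins_global()].
#' @param cds_a,cds_b Nucleotide coding sequences (character), with or
#'   without the terminal stop codon.
#' @param code NCBI genetic code id.
#' @return A `codon_alignment`: list with `gene_a`, `gene_b`, `codons_a`,
#'   `codons_b` (equal-length character vectors of sense codons) and
#'   `n_columns_removed`.
#' @export
backthread_codon_alignment <- function(alignment, cds_a, cds_b, code = "11") {
  gc_map <- Biostrings::getGeneticCode(code)
  prep <- function(cds, aligned, gene) {
    ungapped <- gsub("-", "", aligned, fixed = TRUE)
    la <- nchar(ungapped)
    if (nchar(cds) == 3L * (la + 1L)) {
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (!is.na(gc_map[last]) && gc_map[[last]] == "*") {
        cds <- substr(cds, 1L, nchar(cds) - 3L)
      }
    }
    if (nchar(cds) != 3L * la) {
      stop(sprintf("CDS length of %s (%d nt) does not match %d aligned residues",
                   gene, nchar(cds), la))
    }
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    aas <- unname(gc_map[codons])
    aas[is.na(aas)] <- "X"          # codon contains an ambiguous base
    got <- strsplit(ungapped, "")[[1]]
    mismatch <- aas != got & aas != "X" & got != "X"
    if (any(mismatch)) {
      stop(sprintf("translation of %s does not match its aligned residues (first mismatch at residue %d)",
                   gene, which(mismatch)[1]))
    }
    codons
  }
  gene_a <- alignment$query_id
  gene_b <- alignment$subject_id
  codons_a_full <- prep(cds_a, alignment$aligned_query, gene_a)
  codons_b_full <- prep(cds_b, alignment$aligned_subject, gene_b)

  qa <- strsplit(alignment$aligned_query, "")[[1]]
  sa <- strsplit(alignment$aligned_subject, "")[[1]]
  ia <- cumsum(qa != "-")
  ib <- cumsum(sa != "-")
  nongap <- qa != "-" & sa != "-"
  aa_a <- gc_map[codons_a_full[pmax(ia, 1L)]]   # NA marks ambiguous codons
  aa_b <- gc_map[codons_b_full[pmax(ib, 1L)]]
  usable <- nongap & !is.na(aa_a) & aa_a != "*" & !is.na(aa_b) & aa_b != "*"
  usable[is.na(usable)] <- FALSE
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = codons_a_full[ia[usable]],
                 codons_b = codons_b_full[ib[usable]],
                 n_columns_removed = length(qa) - sum(usable)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s vs %s: %d codon column(s), %d removed\n",
              x$gene_a, x$gene_b, length(x$codons_a), x$n_columns_removed))
  invisible(x)
}

## convenience constructor used heavily in tests and the simulator-driven
## estimates: a gapless codon alignment straight from two equal-length
## codon vectors
codon_alignment <- function(codons_a, codons_b, gene_a = "a", gene_b = "b") {
  stopifnot(length(codons_a) == length(codons_b))
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = codons_a, codons_b = codons_b,
                 n_columns_removed = 0L),
            class = "codon_alignment")
}
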
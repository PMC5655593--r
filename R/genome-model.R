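#' Construct a genome record from contigs and a CDS table
#'
#' The central container for one genome: contig sequences plus CDS
#' annotations, with every coding sequence extracted (strand-resolved) and
#' translated. CDS whose length is not divisible by 3, or whose translation
#' contains an internal stop codon, are excluded and listed in the skip
#' report (`$skipped`). Codons containing N translate to X and do not count
#' as stops.
#'
#' @param genome_id Genome identifier.
#' @param contigs A named [Biostrings::DNAStringSet] (unique names) or named
#'   character vector of contig sequences.
#' @param cds A data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates, strand `+`/`-`).
#' @param taxon_label Free-text taxon label.
#' @param code NCBI genetic code id used for translation (default "11").
#' @return An object of class `genome_record`: a list with `genome_id`,
#'   `contigs`, `cds` (the accepted annotation rows), `nt` (extracted coding
#'   sequences), `aa` (translations, terminal stop removed), `taxon_label`,
#'   `code` and `skipped` (gene_id + reason).
#' @export
genome_record <- function(genome_id, contigs, cds, taxon_label = "",
                          code = "11") {
  if (!methods::is(contigs, "DNAStringSet")) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must have unique names")
  }
  if (length(contigs) == 0L || sum(Biostrings::width(contigs)) == 0L) {
    stop("genome has zero length")
  }
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(cds))) {
    stop("cds table must have columns: ", paste(need, collapse = ", "))
  }
  cds <- as.data.frame(cds)[, need]
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)

  unknown <- !(cds$contig_id %in% names(contigs))
  if (any(unknown)) {
    stop("CDS references unknown contig: ",
         paste(cds$gene_id[unknown], collapse = ", "))
  }
  clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
  oob <- cds$start < 1L | cds$end > clen[cds$contig_id] | cds$start > cds$end
  if (any(oob)) {
    stop("CDS outside contig bounds: ", paste(cds$gene_id[oob], collapse = ", "))
  }
  if (anyDuplicated(cds$gene_id)) {
    stop("duplicate gene_id in cds table")
  }

  skipped <- data.frame(gene_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(cds))
  len <- cds$end - cds$start + 1L
  bad3 <- len %% 3L != 0L
  if (any(bad3)) {
    skipped <- rbind(skipped, data.frame(gene_id = cds$gene_id[bad3],
                                         reason = "length not divisible by 3"))
    keep <- keep & !bad3
  }

  nt <- Biostrings::DNAStringSet(vapply(which(keep), function(i) {
    s <- Biostrings::subseq(contigs[[cds$contig_id[i]]], cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(nt) <- cds$gene_id[keep]

  aa <- Biostrings::translate(nt, genetic.code = Biostrings::getGeneticCode(code),
                              if.fuzzy.codon = "solve", no.init.codon = TRUE)
  aa_chr <- as.character(aa)
  has_term_stop <- endsWith(aa_chr, "*")
  aa_chr[has_term_stop] <- substr(aa_chr[has_term_stop], 1L,
                                  nchar(aa_chr[has_term_stop]) - 1L)
  internal_stop <- grepl("\\*", aa_chr)
  if (any(internal_stop)) {
    skipped <- rbind(skipped, data.frame(gene_id = names(nt)[internal_stop],
                                         reason = "internal stop codon"))
  }
  nt <- nt[!internal_stop]
  aa <- Biostrings::AAStringSet(aa_chr[!internal_stop])
  names(aa) <- names(nt)
  cds <- cds[cds$gene_id %in% names(nt), , drop = FALSE]
  rownames(cds) <- NULL

  structure(list(genome_id = genome_id, contigs = contigs, cds = cds,
                 nt = nt, aa = aa, taxon_label = taxon_label, code = code,
                 skipped = skipped),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s> %d contig(s), %s bp, %d CDS (%d skipped)\n",
              x$genome_id, length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ","),
              nrow(x$cds), nrow(x$skipped)))
  invisible(x)
}

#' Read a genome from FASTA plus a CDS annotation
#'
#' The annotation is either GFF3 (CDS features; the `ID` attribute, falling
#' back to `Name` or `locus_tag`, provides the gene id) or a simple 5-column
#' TSV (`gene_id`, `contig_id`, `start`, `end`, `strand`).
#'
#' @param fasta_path Path to a (multi-)FASTA of nucleotide contigs.
#' @param annotation_path Path to the GFF3 or CDS-table file.
#' @param genome_id Identifier; defaults to the FASTA basename.
#' @inheritParams genome_record
#' @return A `genome_record`; see [genome_record()].
#' @export
read_genome <- function(fasta_path, annotation_path,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path)),
                        taxon_label = "", code = "11") {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))

  if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(annotation_path)
    gr <- gr[gr$type == "CDS"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) {
      alt <- if (!is.null(gr$Name)) gr$Name else gr$locus_tag
      if (is.null(ids)) ids <- alt else ids[is.na(ids)] <- alt[is.na(ids)]
    }
    if (is.null(ids) || anyNA(ids)) {
      stop("GFF3 CDS features must carry an ID (or Name/locus_tag) attribute")
    }
    cds <- data.frame(gene_id = as.character(ids),
                      contig_id = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  } else {
    cds <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  }
  genome_record(genome_id, contigs, cds, taxon_label = taxon_label, code = code)
}

#' Write a genome record back to FASTA + GFF3
#'
#' @param genome A `genome_record`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(genome$contigs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$cds$contig_id,
    ranges = IRanges::IRanges(genome$cds$start, genome$cds$end),
    strand = genome$cds$strand)
  gr$source <- "omegapair"
  gr$type <- "CDS"
  gr$ID <- genome$cds$gene_id
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(
    Biostrings::width(genome$contigs), names(genome$contigs))
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(genome)
}

#' Percent coding density of a genome
#'
#' `(DNA length of all coding sequences / total DNA length) * 100`. By
#' default the numerator is the number of genome positions covered by at
#' least one CDS (union of CDS intervals), which guarantees a result of at
#' most 100; `mode = "literal"` sums CDS lengths directly, reproducing the
#' naive formula even when CDS overlap.
#'
#' @param genome A `genome_record`.
#' @param mode `"union"` (default) or `"literal"`.
#' @return Percent coding density.
#' @export
coding_density <- function(genome, mode = c("union", "literal")) {
  mode <- match.arg(mode)
  total <- sum(Biostrings::width(genome$contigs))
  if (total == 0L) stop("genome has zero length")
  if (nrow(genome$cds) == 0L) {
    warning("genome has no CDS; coding density is 0")
    return(0)
  }
  covered <- if (mode == "literal") {
    sum(genome$cds$end - genome$cds$start + 1L)
  } else {
    rl <- split(IRanges::IRanges(genome$cds$start, genome$cds$end),
                genome$cds$contig_id)
    sum(vapply(rl, function(ir) sum(IRanges::width(IRanges::reduce(ir))),
               numeric(1)))
  }
  100 * covered / total
}

#' Genome size in base pairs and CDS count, plus coding density
#'
#' Both size measures used for cohort correlations: total length in bp and
#' the number of protein-coding sequences.
#'
#' @param genome A `genome_record`.
#' @return A one-row data.frame with `genome_id`, `size_bp`, `size_cds`,
#'   `coding_density_pct`.
#' @export
genome_size_metrics <- function(genome) {
  dens <- if (nrow(genome$cds) == 0L) 0 else coding_density(genome)
  data.frame(genome_id = genome$genome_id,
             size_bp = sum(Biostrings::width(genome$contigs)),
             size_cds = nrow(genome$cds),
             coding_density_pct = dens,
             stringsAsFactors = FALSE)
}

#' Write the skip report of a genome record to TSV
#'
#' @param genome A `genome_record`.
#' @param path Output TSV path.
#' @return Invisibly, the skip report data.frame.
#' @export
write_skip_report <- function(genome, path) {
  utils::write.table(genome$skipped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genome$skipped)
}
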
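#' Simulation configuration for one genome pair
#'
#' Defaults describe the reference validation condition used throughout:
#' 500 genes of 300 codons, omega 0.2, kappa 2, pairwise divergence t = 0.3
#' expected substitutions per codon, uniform sense-codon frequencies, and a
#' 15% noncoding fraction.
#'
#' @param n_genes Number of genes.
#' @param gene_len_codons Codons per gene (scalar, or `c(min, max)` sampled
#'   uniformly per gene).
#' @param omega dN/dS of the generating process.
#' @param kappa Transition/transversion rate ratio.
#' @param t Pairwise divergence in expected substitutions per codon (split
#'   evenly over the two branches).
#' @param codon_freqs `"uniform"`, a numeric vector over the sense codons,
#'   or a 4 x 3 matrix of position-specific nucleotide frequencies (F3x4).
#' @param noncoding_fraction Fraction of each genome that is noncoding.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param genome_ids Identifiers of the two emitted genomes.
#' @param code NCBI genetic code id.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500L, gene_len_codons = 300L, omega = 0.2,
                       kappa = 2, t = 0.3, codon_freqs = "uniform",
                       noncoding_fraction = 0.15, seed = NULL,
                       genome_ids = c("genomeA", "genomeB"), code = "11") {
  stopifnot(n_genes >= 1L, t >= 0, kappa >= 0, omega >= 0,
            noncoding_fraction >= 0, noncoding_fraction < 1)
  structure(list(n_genes = as.integer(n_genes),
                 gene_len_codons = as.integer(gene_len_codons),
                 omega = omega, kappa = kappa, t = t,
                 codon_freqs = codon_freqs,
                 noncoding_fraction = noncoding_fraction,
                 seed = seed, genome_ids = genome_ids, code = code),
            class = "sim_config")
}

## resolve the codon_freqs field to a probability vector over sense codons
.resolve_codon_freqs <- function(codon_freqs, mach) {
  if (is.matrix(codon_freqs)) {
    stopifnot(nrow(codon_freqs) == 4L, ncol(codon_freqs) == 3L)
    nt_idx <- matrix(match(mach$codon_nt, .NT), ncol = 3)
    pf <- sweep(codon_freqs, 2, colSums(codon_freqs), "/")
    pi61 <- pf[cbind(nt_idx[, 1], 1)] * pf[cbind(nt_idx[, 2], 2)] *
      pf[cbind(nt_idx[, 3], 3)]
    return(pi61 / sum(pi61))
  }
  if (is.numeric(codon_freqs)) {
    stopifnot(length(codon_freqs) == mach$n_sense)
    return(codon_freqs / sum(codon_freqs))
  }
  rep(1 / mach$n_sense, mach$n_sense)
}

#' GY94 codon substitution rate matrix
#'
#' 61 x 61 continuous-time Markov generator over the sense codons: the rate
#' from codon i to codon j is 0 unless they differ at exactly one position,
#' and otherwise `pi_j * kappa^[transition] * omega^[nonsynonymous]`. Rows
#' sum to zero and the matrix is rescaled so the expected number of
#' substitutions per codon per unit time is 1 at stationarity. The model is
#' time-reversible (detailed balance with respect to `codon_freqs`).
#'
#' @inheritParams sim_config
#' @return The scaled rate matrix with the stationary distribution attached
#'   as attribute `"pi"`.
#' @export
build_codon_rate_matrix <- function(kappa, omega, codon_freqs = "uniform",
                                    code = "11") {
  mach <- codon_machinery(code)
  pi61 <- .resolve_codon_freqs(codon_freqs, mach)
  if (any(pi61 <= 0)) stop("codon_freqs must be positive on every sense codon")
  Q <- matrix(0, mach$n_sense, mach$n_sense,
              dimnames = list(mach$sense, mach$sense))
  nb <- mach$nb
  rate <- pi61[nb$to] * ifelse(nb$ts, kappa, 1) * ifelse(nb$syn, 1, omega)
  Q[cbind(nb$from, nb$to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi61 * diag(Q))
  if (scale > 0) Q <- Q / scale
  attr(Q, "pi") <- pi61
  attr(Q, "code") <- code
  Q
}

## transition probability kernel exp(Qt) via the reversible symmetrization
.transition_matrix <- function(Q, t) {
  pi61 <- attr(Q, "pi")
  d <- sqrt(pi61)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(d)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve a codon sequence for time t under a GY94 rate matrix
#'
#' Each codon evolves independently by one draw from the transition kernel
#' `exp(Qt)`. Deterministic for a given seed.
#'
#' @param ancestor Character vector of sense codons.
#' @param t Branch length (expected substitutions per codon).
#' @param rate_matrix From [build_codon_rate_matrix()].
#' @param seed Optional integer seed.
#' @return Character vector of descendant codons, same length.
#' @export
evolve_codon_sequence <- function(ancestor, t, rate_matrix, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mach <- codon_machinery(attr(rate_matrix, "code"))
  idx <- .codon_index(ancestor, mach, "ancestor")
  P <- .transition_matrix(rate_matrix, t)
  mach$sense[.evolve_idx(idx, P)]
}

.evolve_idx <- function(idx, P) {
  out <- integer(length(idx))
  for (s in sort(unique(idx))) {
    pos <- which(idx == s)
    out[pos] <- sample.int(ncol(P), length(pos), replace = TRUE, prob = P[s, ])
  }
  out
}

.random_dna <- function(n) {
  paste(sample(.NT, n, replace = TRUE), collapse = "")
}

## JC mutation of a nucleotide string at per-site distance d
.mutate_dna <- function(s, d) {
  chars <- strsplit(s, "")[[1]]
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(nt) sample(setdiff(.NT, nt), 1L),
                         character(1))
  }
  paste(chars, collapse = "")
}

#' Simulate a pair of closely related coding genomes with known parameters
#'
#' Draws an ancestral gene set from the configured codon frequencies,
#' evolves each gene down two branches of length t/2 under the GY94 model,
#' wraps genes with ATG/TAA, and places them (random strand) on one contig
#' separated by noncoding spacers sized so the genome hits the requested
#' noncoding fraction. Spacers descend from a common ancestral sequence
#' under Jukes-Cantor at the neutral per-site rate (t/3 per pair), and both
#' genomes share the same layout, so annotations correspond gene-for-gene.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome_pair`: list with `genome_a`, `genome_b`
#'   (`genome_record` objects) and `truth` (the hidden parameters: the true
#'   ortholog pairing, omega, kappa, t, realized noncoding fraction and
#'   genome sizes).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mach <- codon_machinery(config$code)
  pi61 <- .resolve_codon_freqs(config$codon_freqs, mach)
  Q <- build_codon_rate_matrix(config$kappa, config$omega, pi61, config$code)
  P_half <- .transition_matrix(Q, config$t / 2)

  n <- config$n_genes
  lens <- if (length(config$gene_len_codons) == 1L) {
    rep(config$gene_len_codons, n)
  } else {
    sample(seq(config$gene_len_codons[1], config$gene_len_codons[2]), n,
           replace = TRUE)
  }
  gene_ids <- sprintf("g%04d", seq_len(n))
  anc <- lapply(lens, function(L) {
    sample.int(mach$n_sense, L, replace = TRUE, prob = pi61)
  })
  desc_a <- lapply(anc, .evolve_idx, P = P_half)
  desc_b <- lapply(anc, .evolve_idx, P = P_half)
  gene_nt <- function(idx) {
    paste0("ATG", paste(mach$sense[idx], collapse = ""), "TAA")
  }
  nt_a <- vapply(desc_a, gene_nt, character(1))
  nt_b <- vapply(desc_b, gene_nt, character(1))

  coding_total <- sum(nchar(nt_a))
  f <- config$noncoding_fraction
  noncoding_total <- round(coding_total * f / (1 - f))
  spacer_len <- as.vector(stats::rmultinom(1, noncoding_total,
                                           rep(1, n + 1L)))
  spacer_anc <- vapply(spacer_len, .random_dna, character(1))
  d_branch <- (config$t / 2) / 3
  spacer_a <- vapply(spacer_anc, .mutate_dna, character(1), d = d_branch,
                     USE.NAMES = FALSE)
  spacer_b <- vapply(spacer_anc, .mutate_dna, character(1), d = d_branch,
                     USE.NAMES = FALSE)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  assemble <- function(genes, spacers, genome_id) {
    parts <- character(2L * n + 1L)
    starts <- integer(n); ends <- integer(n)
    pos <- 0L
    for (g in seq_len(n)) {
      parts[2L * g - 1L] <- spacers[g]
      pos <- pos + nchar(spacers[g])
      placed <- if (strands[g] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(genes[g])))
      } else {
        genes[g]
      }
      parts[2L * g] <- placed
      starts[g] <- pos + 1L
      ends[g] <- pos + nchar(placed)
      pos <- ends[g]
    }
    parts[2L * n + 1L] <- spacers[n + 1L]
    contig <- paste(parts, collapse = "")
    contigs <- Biostrings::DNAStringSet(contig)
    names(contigs) <- paste0(genome_id, "_c1")
    cds <- data.frame(gene_id = gene_ids,
                      contig_id = paste0(genome_id, "_c1"),
                      start = starts, end = ends, strand = strands,
                      stringsAsFactors = FALSE)
    genome_record(genome_id, contigs, cds, taxon_label = "synthetic",
                  code = config$code)
  }
  ga <- assemble(nt_a, spacer_a, config$genome_ids[1])
  gb <- assemble(nt_b, spacer_b, config$genome_ids[2])

  realized_nc <- noncoding_total / (noncoding_total + coding_total)
  truth <- list(
    pairing = data.frame(gene_a = gene_ids, gene_b = gene_ids,
                         stringsAsFactors = FALSE),
    omega = config$omega, kappa = config$kappa, t = config$t,
    noncoding_fraction = realized_nc,
    size_bp = stats::setNames(
      c(sum(Biostrings::width(ga$contigs)), sum(Biostrings::width(gb$contigs))),
      config$genome_ids),
    size_cds = stats::setNames(c(nrow(ga$cds), nrow(gb$cds)),
                               config$genome_ids))
  structure(list(genome_a = ga, genome_b = gb, truth = truth),
            class = "sim_genome_pair")
}

#' Simulate a cohort of genome pairs with a built-in size association
#'
#' Generates `n_pairs` genome pairs whose true omega and noncoding fraction
#' follow one of two regimes. In the archaeal-like regime the generating
#' omega increases with genome size (purifying selection relaxes as genomes
#' grow) and the noncoding fraction increases with size; in the
#' bacterial-like regime omega decreases with size and the noncoding
#' fraction is flat. Divergences are drawn so computed ANI lands mostly in
#' the 75-95% band that delineates congeneric genome pairs.
#'
#' @param regime `"archaeal_like"` or `"bacterial_like"`.
#' @param n_pairs Number of genome pairs (>= 5).
#' @param seed Integer seed for the whole cohort.
#' @param n_genes_range Range of gene counts (genome size in CDS) across the
#'   cohort.
#' @param gene_len_codons Codons per gene.
#' @param t_range Pairwise divergence range (substitutions per codon).
#' @param omega_range Range of generating omega across the size gradient.
#' @param noncoding_range Noncoding-fraction range across the size gradient
#'   (archaeal-like regime).
#' @param noncoding_flat Mean noncoding fraction of the bacterial-like
#'   regime.
#' @param kappa Transition/transversion ratio.
#' @param outdir Optional directory: writes per-genome FASTA + GFF3, a
#'   cohort manifest TSV and a ground-truth JSON.
#' @return A `sim_cohort`: list with `pairs` (list of `sim_genome_pair`),
#'   `manifest` (data.frame), `regime` and `seed`.
#' @export
simulate_cohort <- function(regime = c("archaeal_like", "bacterial_like"),
                            n_pairs, seed,
                            n_genes_range = c(60L, 140L),
                            gene_len_codons = 150L,
                            t_range = c(0.3, 0.6),
                            omega_range = c(0.08, 0.32),
                            noncoding_range = c(0.08, 0.30),
                            noncoding_flat = 0.12,
                            kappa = 2, outdir = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_pairs >= 5L)
  set.seed(seed)
  n_genes <- round(seq(n_genes_range[1], n_genes_range[2],
                       length.out = n_pairs))
  frac <- (n_genes - n_genes_range[1]) /
    max(1, diff(range(n_genes_range)))
  dir_frac <- if (regime == "archaeal_like") frac else 1 - frac
  log_omega <- log(omega_range[1]) +
    dir_frac * (log(omega_range[2]) - log(omega_range[1])) +
    stats::rnorm(n_pairs, 0, 0.08)
  omega <- pmin(pmax(exp(log_omega), 0.02), 0.8)
  noncoding <- if (regime == "archaeal_like") {
    noncoding_range[1] + frac * diff(noncoding_range) +
      stats::rnorm(n_pairs, 0, 0.015)
  } else {
    noncoding_flat + stats::rnorm(n_pairs, 0, 0.02)
  }
  noncoding <- pmin(pmax(noncoding, 0.02), 0.45)
  t_pair <- stats::runif(n_pairs, t_range[1], t_range[2])
  pair_seed <- (abs(seed) + 7919L * seq_len(n_pairs)) %% 2147483647L

  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cfg <- sim_config(n_genes = n_genes[i], gene_len_codons = gene_len_codons,
                      omega = omega[i], kappa = kappa, t = t_pair[i],
                      noncoding_fraction = noncoding[i], seed = pair_seed[i],
                      genome_ids = sprintf("pair%02d_%s", i, c("a", "b")))
    pairs[[i]] <- simulate_genome_pair(cfg)
  }
  manifest <- data.frame(
    pair_id = sprintf("pair%02d", seq_len(n_pairs)),
    genome_a = sprintf("pair%02d_a", seq_len(n_pairs)),
    genome_b = sprintf("pair%02d_b", seq_len(n_pairs)),
    regime = regime, n_genes = n_genes, omega_true = omega,
    kappa = kappa, t = t_pair, noncoding_fraction = noncoding,
    stringsAsFactors = FALSE)
  cohort <- structure(list(pairs = pairs, manifest = manifest,
                           regime = regime, seed = seed),
                      class = "sim_cohort")
  if (!is.null(outdir)) write_cohort(cohort, outdir)
  cohort
}

#' Write a simulated cohort to disk (FASTA + GFF3 + manifest + truth JSON)
#'
#' @param cohort A `sim_cohort`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the manifest with file path columns added.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  ## paths are stored relative to the manifest so a cohort directory is
  ## relocatable (and reruns are byte-identical wherever they land)
  for (col in c("fasta_a", "gff_a", "fasta_b", "gff_b")) man[[col]] <- NA_character_
  for (i in seq_along(cohort$pairs)) {
    p <- cohort$pairs[[i]]
    for (side in c("a", "b")) {
      g <- p[[paste0("genome_", side)]]
      fa <- paste0(g$genome_id, ".fna")
      gff <- paste0(g$genome_id, ".gff3")
      suppressWarnings(write_genome(g, file.path(outdir, fa),
                                    file.path(outdir, gff)))
      man[[paste0("fasta_", side)]][i] <- fa
      man[[paste0("gff_", side)]][i] <- gff
    }
  }
  utils::write.table(man, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- lapply(cohort$pairs, function(p) p$truth)
  names(truth) <- man$pair_id
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read a cohort manifest written by [write_cohort()]
#'
#' Resolves the relative genome file paths against the manifest's own
#' directory, giving a data.frame directly usable by
#' [run_cohort_analysis()].
#'
#' @param path Path to a `manifest.tsv`.
#' @return The manifest data.frame with absolute `fasta_*`/`gff_*` columns.
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  for (col in c("fasta_a", "gff_a", "fasta_b", "gff_b")) {
    man[[col]] <- file.path(base, man[[col]])
  }
  man
}
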
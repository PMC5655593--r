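#' Pipeline configuration
#'
#' Collects every tunable threshold of the pair and cohort analyses with the
#' package defaults: BBH acceptance at >= 30% identity over >= 50% of both
#' lengths, paralog collapsing at 90%/90%, saturation filters dS < 0.1,
#' dS > 1.6, dN/dS > 99, the inclusive 5% coding-capacity retention rule,
#' and Goris-style ANI parameters.
#'
#' @param method `"YN00"` (default) or `"NG86"`.
#' @param min_identity,min_coverage BBH acceptance gates (percent).
#' @param n_candidates Candidate partners per gene in the BBH prefilter
#'   (`Inf` = exact all-vs-all).
#' @param collapse_paralogs,cluster_identity,cluster_coverage Paralog
#'   collapsing controls.
#' @param ds_min,ds_max,omega_max Saturation filter thresholds.
#' @param retention_min Retention rule threshold (fraction of average CDS
#'   count, inclusive).
#' @param compute_ani Compute fragment-based ANI per pair.
#' @param ani_override Optional named numeric vector of precomputed ANI
#'   percent values, keyed `"<genome_a>|<genome_b>"` (mirrors ingesting
#'   externally retrieved ANI); overrides computation.
#' @param fragment_len,ani_both_strands,ani_exhaustive ANI parameters (see
#'   [compute_ani()]).
#' @param pair_size How a pair's single genome size is derived from its two
#'   genomes for correlation panels: `"mean"`, `"min"`, `"max"` or
#'   `"first"`.
#' @param code NCBI genetic code id.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(method = c("YN00", "NG86"),
                            min_identity = 30, min_coverage = 50,
                            n_candidates = 3, collapse_paralogs = TRUE,
                            cluster_identity = 90, cluster_coverage = 90,
                            ds_min = 0.1, ds_max = 1.6, omega_max = 99,
                            retention_min = 0.05,
                            compute_ani = TRUE, ani_override = NULL,
                            fragment_len = 1020, ani_both_strands = TRUE,
                            ani_exhaustive = TRUE,
                            pair_size = c("mean", "min", "max", "first"),
                            code = "11") {
  structure(list(method = match.arg(method), min_identity = min_identity,
                 min_coverage = min_coverage, n_candidates = n_candidates,
                 collapse_paralogs = collapse_paralogs,
                 cluster_identity = cluster_identity,
                 cluster_coverage = cluster_coverage,
                 ds_min = ds_min, ds_max = ds_max, omega_max = omega_max,
                 retention_min = retention_min, compute_ani = compute_ani,
                 ani_override = ani_override, fragment_len = fragment_len,
                 ani_both_strands = ani_both_strands,
                 ani_exhaustive = ani_exhaustive,
                 pair_size = match.arg(pair_size), code = code),
            class = "pipeline_config")
}

.stage_log <- function(pair_label, stage, ...) {
  message(sprintf("[%s] %s: %s", pair_label, stage, sprintf(...)))
}

#' Run the full pair-level analysis on two genomes
#'
#' Orthology (paralog collapse + bidirectional best hit), codon
#' back-threading, dN/dS estimation (YN00 by default, NG86 optional),
#' saturation filtering, ANI, and the per-pair summary with the 5%
#' retention rule. One structured log line per stage goes to the message
#' stream.
#'
#' @param genome_a,genome_b `genome_record` objects.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for the per-ortholog and summary
#'   TSVs.
#' @return List with `summary` (one-row data.frame, see
#'   [summarize_genome_pair()]), `orthologs` (per-ortholog estimates with
#'   `filter_status` and `reason`), and `counts` (named stage counts).
#' @export
run_pair_analysis <- function(genome_a, genome_b, config = pipeline_config(),
                              outdir = NULL) {
  lab <- paste(genome_a$genome_id, genome_b$genome_id, sep = "|")
  bbh <- find_bbh_pairs(genome_a$aa, genome_b$aa,
                        min_identity = config$min_identity,
                        min_coverage = config$min_coverage,
                        n_candidates = config$n_candidates,
                        collapse_paralogs = config$collapse_paralogs,
                        cluster_identity = config$cluster_identity,
                        cluster_coverage = config$cluster_coverage)
  n_orth <- nrow(bbh$pairs)
  .stage_log(lab, "orthology", "%d reciprocal best-hit pair(s)", n_orth)

  estimates <- vector("list", n_orth)
  n_cols_removed <- 0L
  for (i in seq_len(n_orth)) {
    al <- bbh$alignments[[i]]
    ca <- backthread_codon_alignment(
      al, as.character(genome_a$nt[[al$query_id]]),
      as.character(genome_b$nt[[al$subject_id]]), code = config$code)
    n_cols_removed <- n_cols_removed + ca$n_columns_removed
    estimates[[i]] <- if (config$method == "NG86") {
      ng86_estimate(ca, code = config$code)
    } else {
      yn00_estimate(ca, code = config$code)
    }
  }
  .stage_log(lab, "codon_alignment", "%d column(s) removed across %d alignment(s)",
             n_cols_removed, n_orth)

  flt <- apply_saturation_filters(estimates, ds_min = config$ds_min,
                                  ds_max = config$ds_max,
                                  omega_max = config$omega_max)
  by_reason <- table(flt$discarded$reason)
  .stage_log(lab, "filters", "%d retained, %d discarded (%s)",
             nrow(flt$retained), nrow(flt$discarded),
             if (length(by_reason)) {
               paste(names(by_reason), as.integer(by_reason),
                     sep = ": ", collapse = "; ")
             } else "none")

  ani_pct <- NA_real_
  if (!is.null(config$ani_override)) {
    key <- paste(genome_a$genome_id, genome_b$genome_id, sep = "|")
    key_rev <- paste(genome_b$genome_id, genome_a$genome_id, sep = "|")
    v <- config$ani_override[c(key, key_rev)]
    ani_pct <- v[!is.na(v)][1]
    if (length(ani_pct) == 0L) ani_pct <- NA_real_
  } else if (config$compute_ani) {
    ani_pct <- compute_ani(genome_a, genome_b,
                           fragment_len = config$fragment_len,
                           both_strands = config$ani_both_strands,
                           exhaustive = config$ani_exhaustive)$ani_pct
  }
  .stage_log(lab, "ani", "%s",
             if (is.na(ani_pct)) "missing" else sprintf("%.2f%%", ani_pct))

  summary <- summarize_genome_pair(
    flt$retained, n_orthologs = n_orth,
    cds_count_a = nrow(genome_a$cds), cds_count_b = nrow(genome_b$cds),
    ani_pct = ani_pct,
    genome_a = genome_a$genome_id, genome_b = genome_b$genome_id,
    size_a_bp = sum(Biostrings::width(genome_a$contigs)),
    size_b_bp = sum(Biostrings::width(genome_b$contigs)),
    retention_min = config$retention_min)
  .stage_log(lab, "summary", "mean omega %s over %d retained, keep = %s",
             if (is.na(summary$mean_omega)) "NA" else sprintf("%.4f", summary$mean_omega),
             summary$n_retained, summary$keep)

  orthologs <- dnds_table(estimates)
  if (is.null(orthologs)) {
    orthologs <- apply_saturation_filters(list())$retained
    orthologs$filter_status <- character(0)
    orthologs$reason <- character(0)
  } else {
    key <- paste(orthologs$gene_a, orthologs$gene_b)
    retained_key <- paste(flt$retained$gene_a, flt$retained$gene_b)
    orthologs$filter_status <- ifelse(key %in% retained_key, "retained",
                                      "discarded")
    orthologs$reason <- NA_character_
    m <- match(key, paste(flt$discarded$gene_a, flt$discarded$gene_b))
    orthologs$reason[!is.na(m)] <- flt$discarded$reason[m[!is.na(m)]]
  }
  counts <- c(n_orthologs = n_orth, n_retained = nrow(flt$retained),
              n_discarded = nrow(flt$discarded),
              n_columns_removed = n_cols_removed)
  out <- list(summary = summary, orthologs = orthologs, counts = counts)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(outdir, paste(genome_a$genome_id, genome_b$genome_id,
                                    sep = "__"))
    .write_tsv(orthologs, paste0(base, "_orthologs.tsv"))
    .write_tsv(summary, paste0(base, "_summary.tsv"))
  }
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the cohort-level analysis: all pairs plus correlation panels
#'
#' Runs [run_pair_analysis()] on every genome pair and assembles the four
#' correlation panels — mean dN/dS vs genome size in CDS, mean dN/dS vs
#' genome size in bp, coding density vs size in bp, and mean dN/dS vs ANI —
#' over the pairs that survive the retention rule. A pair's single size
#' value is the mean of its two genomes (configurable); its coding density
#' is likewise the mean of the two genomes' densities. Pairs with missing
#' ANI are dropped from the ANI panel only (pairwise deletion).
#'
#' @param cohort A `sim_cohort`, a list of `sim_genome_pair`/two-element
#'   genome lists, or a manifest data.frame with columns `fasta_a`, `gff_a`,
#'   `fasta_b`, `gff_b`.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (`cohort_pairs.tsv`,
#'   `cohort_correlations.tsv`, `run_manifest.json`).
#' @return A `cohort_report`: list with `pairs` (per-pair summaries plus
#'   pair-level size and density columns), `correlations` (one row per
#'   panel: `rs`, `p_two_sided`, `n`, `method`, `note`), `n_dropped`, and
#'   `notes`.
#' @export
run_cohort_analysis <- function(cohort, config = pipeline_config(),
                                outdir = NULL) {
  pairs <- .cohort_genome_pairs(cohort, config)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    res <- run_pair_analysis(pairs[[i]]$genome_a, pairs[[i]]$genome_b, config)
    row <- res$summary
    ga <- pairs[[i]]$genome_a; gb <- pairs[[i]]$genome_b
    agg <- switch(config$pair_size, mean = mean, min = min, max = max,
                  first = function(v) v[1])
    row$pair_size_cds <- agg(c(row$size_a_cds, row$size_b_cds))
    row$pair_size_bp <- agg(c(row$size_a_bp, row$size_b_bp))
    row$pair_coding_density <- mean(c(coding_density(ga), coding_density(gb)))
    rows[[i]] <- row
  }
  pair_df <- do.call(rbind, rows)
  kept <- pair_df[pair_df$keep, , drop = FALSE]
  n_dropped <- nrow(pair_df) - nrow(kept)
  notes <- character(0)
  if (n_dropped > 0) {
    notes <- c(notes, sprintf("%d pair(s) dropped by the retention rule",
                              n_dropped))
  }

  panel <- function(name, x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) >= 3L) {
      res <- tryCatch(spearman(x[ok], y[ok]), error = function(e) NULL)
      if (!is.null(res)) {
        return(data.frame(panel = name, rs = res$rs,
                          p_two_sided = res$p_two_sided, n = res$n,
                          method = res$method, note = "",
                          stringsAsFactors = FALSE))
      }
      note <- "correlation undefined (zero rank variance)"
    } else {
      note <- sprintf("fewer than 3 kept pairs with complete data (n = %d)",
                      sum(ok))
    }
    data.frame(panel = name, rs = NA_real_, p_two_sided = NA_real_,
               n = sum(ok), method = NA_character_, note = note,
               stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    panel("mean_omega_vs_size_cds", kept$pair_size_cds, kept$mean_omega),
    panel("mean_omega_vs_size_bp", kept$pair_size_bp, kept$mean_omega),
    panel("coding_density_vs_size_bp", kept$pair_size_bp,
          kept$pair_coding_density),
    panel("mean_omega_vs_ani", kept$ani_pct, kept$mean_omega))

  report <- structure(list(pairs = pair_df, correlations = correlations,
                           n_dropped = n_dropped, notes = notes),
                      class = "cohort_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(pair_df, file.path(outdir, "cohort_pairs.tsv"))
    .write_tsv(correlations, file.path(outdir, "cohort_correlations.tsv"))
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("omegapair")),
           config = unclass(config), notes = notes),
      file.path(outdir, "run_manifest.json"), auto_unbox = TRUE, null = "null")
  }
  report
}

.cohort_genome_pairs <- function(cohort, config) {
  if (inherits(cohort, "sim_cohort")) return(cohort$pairs)
  if (is.data.frame(cohort)) {
    need <- c("fasta_a", "gff_a", "fasta_b", "gff_b")
    stopifnot(all(need %in% names(cohort)))
    return(lapply(seq_len(nrow(cohort)), function(i) {
      list(genome_a = read_genome(cohort$fasta_a[i], cohort$gff_a[i],
                                  code = config$code),
           genome_b = read_genome(cohort$fasta_b[i], cohort$gff_b[i],
                                  code = config$code))
    }))
  }
  stopifnot(is.list(cohort))
  cohort
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d pair(s), %d dropped by retention rule\n",
              nrow(x$pairs), x$n_dropped))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
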
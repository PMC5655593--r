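#' Discard saturated or unreliable dN/dS estimates
#'
#' An estimate is discarded when `dS < ds_min`, `dS > ds_max`, or
#' `dN/dS > omega_max` (defaults 0.1, 1.6 and 99; all comparisons strict, so
#' the boundary values 0.1, 1.6 and 99 are retained). The `dS = 0` sentinel
#' (`omega = 999`) and saturated rates (`Inf`) always fall in a discard
#' bucket. Each discarded estimate is labeled with the first matching reason
#' in that order.
#'
#' @param estimates A list of `dnds_estimate` objects or a data.frame as
#'   produced by binding them.
#' @param ds_min,ds_max,omega_max Filter thresholds.
#' @return List with `retained` (data.frame) and `discarded` (data.frame
#'   with an extra `reason` column). Input order is preserved within each.
#' @export
apply_saturation_filters <- function(estimates, ds_min = 0.1, ds_max = 1.6,
                                     omega_max = 99) {
  df <- dnds_table(estimates)
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(
      new_dnds_estimate("x", "y", "NG86", 0, 0, 0, 0, 0, 0, 1, TRUE))[0, ]
    discarded <- df
    discarded$reason <- character(0)
    return(list(retained = df, discarded = discarded))
  }
  reason <- rep(NA_character_, nrow(df))
  undef <- is.na(df$dS) | is.na(df$omega)
  reason[undef] <- "undefined estimate"
  sel <- is.na(reason) & df$dS < ds_min
  reason[sel] <- sprintf("dS < %g", ds_min)
  sel <- is.na(reason) & df$dS > ds_max
  reason[sel] <- sprintf("dS > %g", ds_max)
  sel <- is.na(reason) & df$omega > omega_max
  reason[sel] <- sprintf("dN/dS > %g", omega_max)
  keep <- is.na(reason)
  discarded <- df[!keep, , drop = FALSE]
  discarded$reason <- reason[!keep]
  list(retained = df[keep, , drop = FALSE], discarded = discarded)
}

#' Summarize one genome pair: mean dN/dS, SEM, and the retention rule
#'
#' Computes the arithmetic mean and standard error of the mean of the
#' retained per-ortholog omega values, the fraction of the pair's average
#' coding capacity (CDS count) that the retained orthologs represent, and
#' the keep/drop flag: a pair is kept only when the retained orthologs
#' account for no less than `retention_min` (default 5%) of the average
#' capacity. Fewer than two retained orthologs leave the SEM undefined and
#' force `keep = FALSE`.
#'
#' @param retained data.frame of retained estimates (from
#'   [apply_saturation_filters()]).
#' @param n_orthologs Number of ortholog pairs before filtering.
#' @param cds_count_a,cds_count_b CDS counts of the two genomes.
#' @param ani_pct Percent average nucleotide identity of the pair (optional).
#' @param genome_a,genome_b Genome identifiers.
#' @param size_a_bp,size_b_bp Genome sizes in bp (optional).
#' @param retention_min Retention threshold as a fraction (inclusive).
#' @return One-row data.frame with the pair summary (one supplementary-table
#'   row): `genome_a`, `genome_b`, `n_orthologs`, `n_retained`, `mean_omega`,
#'   `sem_omega`, `retained_fraction_of_capacity`, `keep`, `ani_pct`,
#'   `size_a_cds`, `size_b_cds`, `size_a_bp`, `size_b_bp`.
#' @export
summarize_genome_pair <- function(retained, n_orthologs, cds_count_a,
                                  cds_count_b, ani_pct = NA_real_,
                                  genome_a = NA_character_,
                                  genome_b = NA_character_,
                                  size_a_bp = NA_real_, size_b_bp = NA_real_,
                                  retention_min = 0.05) {
  stopifnot(cds_count_a > 0, cds_count_b > 0)
  n_retained <- if (is.null(retained)) 0L else nrow(retained)
  capacity <- (cds_count_a + cds_count_b) / 2
  fraction <- n_retained / capacity
  if (n_retained >= 1L) {
    mean_omega <- mean(retained$omega)
    sem_omega <- if (n_retained >= 2L) sem(retained$omega) else NA_real_
  } else {
    mean_omega <- NA_real_
    sem_omega <- NA_real_
  }
  keep <- n_retained >= 2L && fraction >= retention_min
  data.frame(genome_a = genome_a, genome_b = genome_b,
             n_orthologs = n_orthologs, n_retained = n_retained,
             mean_omega = mean_omega, sem_omega = sem_omega,
             retained_fraction_of_capacity = fraction, keep = keep,
             ani_pct = ani_pct,
             size_a_cds = cds_count_a, size_b_cds = cds_count_b,
             size_a_bp = size_a_bp, size_b_bp = size_b_bp,
             stringsAsFactors = FALSE)
}
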
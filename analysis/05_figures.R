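#!/usr/bin/env Rscript

# Step 5 — scatter plots of the cohort results.
#
# Four panels per cohort: mean dN/dS against genome size in CDS and in Mb,
# coding density against size in Mb, and mean dN/dS against ANI, each
# annotated with the Spearman rs and two-sided P value of step 3.
# Requires results/cohort/<regime>/ from 03_cohort_correlations.R.

suppressPackageStartupMessages({
  library(omegapair)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

panel_plot <- function(pairs, cors, xvar, yvar, panel, xlab, ylab) {
  cr <- cors[cors$panel == panel, ]
  ggplot(pairs[pairs$keep, ], aes(.data[[xvar]], .data[[yvar]])) +
    geom_point(shape = 21, size = 2.5, fill = "grey30") +
    labs(x = xlab, y = ylab,
         subtitle = sprintf("Rs = %.2f, P = %.3g (n = %d)",
                            cr$rs, cr$p_two_sided, cr$n)) +
    theme_classic(base_size = 11)
}

for (regime in c("archaeal_like", "bacterial_like")) {
  dir <- file.path("results/cohort", regime)
  pairs <- read.delim(file.path(dir, "cohort_pairs.tsv"))
  cors <- read.delim(file.path(dir, "cohort_correlations.tsv"))
  pairs$pair_size_mb <- pairs$pair_size_bp / 1e6
  cors_mb <- cors
  plots <- list(
    panel_plot(pairs, cors, "pair_size_cds", "mean_omega",
               "mean_omega_vs_size_cds", "Genome size (CDS)", "mean dN/dS"),
    panel_plot(transform(pairs, pair_size_bp = pair_size_mb), cors_mb,
               "pair_size_bp", "mean_omega", "mean_omega_vs_size_bp",
               "Genome size (Mb)", "mean dN/dS"),
    panel_plot(transform(pairs, pair_size_bp = pair_size_mb), cors_mb,
               "pair_size_bp", "pair_coding_density",
               "coding_density_vs_size_bp", "Genome size (Mb)",
               "Coding density (%)"),
    panel_plot(pairs, cors, "ani_pct", "mean_omega", "mean_omega_vs_ani",
               "ANI (%)", "mean dN/dS"))
  for (i in seq_along(plots)) {
    f <- file.path("results/figures",
                   sprintf("%s_panel%d.png", regime, i))
    ggsave(f, plots[[i]], width = 4, height = 3.2, dpi = 150)
  }
  cat("wrote 4 panels for", regime, "\n")
}
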
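#' Simulation configuration for the synthetic cohort generator
#'
#' Collects every knob of the synthetic study in one validated object.
#' Defaults encode a desk-scale study shaped like a two-pair paired
#' tumor/normal HCC nanopore experiment: genome-background biotype
#' composition of roughly 42% protein-coding and 29% pseudogene, unstable
#' genes drawn preferentially (77%) from protein-coding genes, planted
#' up/down site-count correlations of 0.15 (5mC) and 0.85 (6mA), a 5mC-DE
#' coupling odds ratio of 3 against a neutral 6mA, and survival effects
#' on a handful of top unstable genes.
#'
#' @param seed integer seed; all randomness flows through per-stage
#'   sub-streams derived from it.
#' @param n_genes number of genes to simulate.
#' @param n_chromosomes number of chromosomes genes are spread over.
#' @param gene_length_range numeric length-2, min/max gene length in bp.
#' @param biotype_fractions named numeric summing to 1; genome-background
#'   biotype composition.
#' @param unstable_biotype_fractions named numeric summing to 1; target
#'   biotype composition of the planted unstable gene set (names must be
#'   a subset of `biotype_fractions` names).
#' @param sites_per_gene_mean mean number of differential sites per gene
#'   per mark for genes carrying the mark (split evenly across the up and
#'   down directions).
#' @param bg_sites_per_gene mean number of non-differential background
#'   sites per gene per mark.
#' @param intergenic_site_fraction fraction of all sites placed between
#'   genes.
#' @param n_pairs number of tumor/normal pairs (default 2, the study
#'   design the generator emulates).
#' @param updown_corr_5mC,updown_corr_6mA target Pearson correlation of
#'   per-gene (up, down) differential site counts for each mark, in
#'   `[0, 1]` (see [rbicount()]).
#' @param frac_unstable fraction of genes planted as dual-mark unstable
#'   (up and down sites for both marks).
#' @param frac_5mC_only,frac_6mA_only fraction of genes planted with up
#'   and down sites for one mark only.
#' @param frac_partial fraction of genes given a random incomplete
#'   direction/mark pattern (at least one of the four categories, never
#'   all four).
#' @param de_base_rate baseline probability that a gene is differentially
#'   expressed.
#' @param de_coupling_odds_ratio_5mC,de_coupling_odds_ratio_6mA odds
#'   ratios linking per-mark unstable status (up and down sites of the
#'   mark) to DE status.
#' @param de_fold_change planted expression fold change of DE genes.
#' @param library_size target per-sample sequencing depth in reads.
#' @param nb_dispersion negative-binomial dispersion of counts; 0 gives
#'   the deterministic limit (counts equal their expectations, possibly
#'   non-integer).
#' @param score_noise_sd maximum relative per-sample jitter applied to
#'   methylation scores; must stay below 0.06 so that planted sites keep
#'   satisfying, and background sites keep failing, the calling rules
#'   under every aggregation policy.
#' @param baseline_hazard baseline event rate per day.
#' @param hazard_log_hr log hazard ratio applied to patients in the low
#'   expression group of each planted survival-effect gene.
#' @param n_survival_effect number of survival-effect genes, taken from
#'   the top of the planted unstable ranking so that the default top-N
#'   screen sees them. They are forced to DE-down so they are planted
#'   tumor-suppressor candidates.
#' @param expr_noise_sd lognormal sd of survival-table expression noise;
#'   0 makes non-effect genes constant (the noiseless world, in which
#'   only planted effect genes can be selected by the screen).
#' @param censor_rate fraction of patients independently censored.
#' @param n_patients number of patients in the survival table.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_chromosomes = 4L,
                       gene_length_range = c(2000, 20000),
                       biotype_fractions = c(protein_coding = 0.42,
                                             pseudogene = 0.29,
                                             lncRNA = 0.20,
                                             miRNA = 0.04,
                                             misc_RNA = 0.05),
                       unstable_biotype_fractions = c(protein_coding = 0.77,
                                                      pseudogene = 0.024,
                                                      lncRNA = 0.15,
                                                      miRNA = 0.016,
                                                      misc_RNA = 0.04),
                       sites_per_gene_mean = 10,
                       bg_sites_per_gene = 3,
                       intergenic_site_fraction = 0.2,
                       n_pairs = 2L,
                       updown_corr_5mC = 0.15,
                       updown_corr_6mA = 0.85,
                       frac_unstable = 0.15,
                       frac_5mC_only = 0.10,
                       frac_6mA_only = 0.10,
                       frac_partial = 0.20,
                       de_base_rate = 0.15,
                       de_coupling_odds_ratio_5mC = 3,
                       de_coupling_odds_ratio_6mA = 1,
                       de_fold_change = 4,
                       library_size = 2e6,
                       nb_dispersion = 0.05,
                       score_noise_sd = 0.02,
                       baseline_hazard = 1 / 1000,
                       hazard_log_hr = 1.0,
                       n_survival_effect = 3L,
                       expr_noise_sd = 0.25,
                       censor_rate = 0.2,
                       n_patients = 300L) {
  cfg <- list(seed = seed, n_genes = n_genes, n_chromosomes = n_chromosomes,
              gene_length_range = gene_length_range,
              biotype_fractions = biotype_fractions,
              unstable_biotype_fractions = unstable_biotype_fractions,
              sites_per_gene_mean = sites_per_gene_mean,
              bg_sites_per_gene = bg_sites_per_gene,
              intergenic_site_fraction = intergenic_site_fraction,
              n_pairs = n_pairs,
              updown_corr_5mC = updown_corr_5mC,
              updown_corr_6mA = updown_corr_6mA,
              frac_unstable = frac_unstable,
              frac_5mC_only = frac_5mC_only,
              frac_6mA_only = frac_6mA_only,
              frac_partial = frac_partial,
              de_base_rate = de_base_rate,
              de_coupling_odds_ratio_5mC = de_coupling_odds_ratio_5mC,
              de_coupling_odds_ratio_6mA = de_coupling_odds_ratio_6mA,
              de_fold_change = de_fold_change,
              library_size = library_size,
              nb_dispersion = nb_dispersion,
              score_noise_sd = score_noise_sd,
              baseline_hazard = baseline_hazard,
              hazard_log_hr = hazard_log_hr,
              n_survival_effect = n_survival_effect,
              expr_noise_sd = expr_noise_sd,
              censor_rate = censor_rate,
              n_patients = n_patients)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (inherits(cfg, "sim_config")) return(cfg)
  stopifnot(is.list(cfg))
  for (f in c("n_genes", "n_chromosomes", "n_pairs", "n_patients")) {
    if (!is_count(cfg[[f]])) abort_config("'%s' must be a count >= 1", f)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    abort_config("'seed' must be a single integer")
  glr <- cfg$gene_length_range
  if (!is.numeric(glr) || length(glr) != 2L || glr[1] < 1 || glr[2] < glr[1])
    abort_config("'gene_length_range' must be an increasing pair of lengths >= 1")
  bf <- cfg$biotype_fractions
  if (is.null(names(bf)) || any(!is.finite(bf)) || any(bf < 0) || any(bf > 1))
    abort_config("'biotype_fractions' must be named fractions in [0,1]")
  if (abs(sum(bf) - 1) > 1e-9)
    abort_config("'biotype_fractions' must sum to 1 (got %.12g)", sum(bf))
  ubf <- cfg$unstable_biotype_fractions
  if (abs(sum(ubf) - 1) > 1e-9)
    abort_config("'unstable_biotype_fractions' must sum to 1 (got %.12g)", sum(ubf))
  if (!all(names(ubf) %in% names(bf)))
    abort_config("'unstable_biotype_fractions' names must be a subset of 'biotype_fractions'")
  for (f in c("intergenic_site_fraction", "frac_unstable", "frac_5mC_only",
              "frac_6mA_only", "frac_partial", "de_base_rate", "censor_rate")) {
    if (!is_fraction(cfg[[f]])) abort_config("'%s' must be a fraction in [0,1]", f)
  }
  if (cfg$frac_unstable + cfg$frac_5mC_only + cfg$frac_6mA_only + cfg$frac_partial > 1 + 1e-9)
    abort_config("pattern fractions (unstable + 5mC_only + 6mA_only + partial) exceed 1")
  for (f in c("sites_per_gene_mean", "de_fold_change", "library_size",
              "baseline_hazard")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      abort_config("'%s' must be positive", f)
  }
  for (f in c("bg_sites_per_gene", "nb_dispersion", "expr_noise_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      abort_config("'%s' must be non-negative", f)
  }
  if (!is.numeric(cfg$score_noise_sd) || cfg$score_noise_sd < 0 ||
      cfg$score_noise_sd >= 0.06)
    abort_config("'score_noise_sd' must lie in [0, 0.06) to preserve planted rules")
  for (m in c("updown_corr_5mC", "updown_corr_6mA")) {
    rho <- cfg[[m]]
    if (!is.numeric(rho) || rho < -1 || rho > 1)
      abort_config("'%s' must lie in [-1, 1]", m)
    ## achievability under the shared-gamma Poisson model is checked at
    ## draw time (rbicount) so the message can cite the bound
  }
  if (!is.numeric(cfg$n_survival_effect) || cfg$n_survival_effect < 0 ||
      cfg$n_survival_effect != floor(cfg$n_survival_effect))
    abort_config("'n_survival_effect' must be a non-negative integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes on %d chromosomes, %d tumor/normal pairs, seed %s\n",
              x$n_genes, x$n_chromosomes, x$n_pairs, format(x$seed)))
  cat(sprintf("  planted: %.0f%% dual-unstable, corr(up,down) 5mC=%.2f 6mA=%.2f\n",
              100 * x$frac_unstable, x$updown_corr_5mC, x$updown_corr_6mA))
  cat(sprintf("  DE coupling OR: 5mC=%.2g 6mA=%.2g; fold change %.2g\n",
              x$de_coupling_odds_ratio_5mC, x$de_coupling_odds_ratio_6mA,
              x$de_fold_change))
  invisible(x)
}
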
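test_that("configuration invariants are enforced", {
  expect_error(sim_config(biotype_fractions = c(pc = 0.6, pseudo = 0.5)),
               class = "methinstab_config_error")
  expect_error(sim_config(n_genes = 0), class = "methinstab_config_error")
  expect_error(sim_config(frac_unstable = 1.5), class = "methinstab_config_error")
  expect_error(sim_config(score_noise_sd = 0.2), class = "methinstab_config_error")
  expect_error(sim_config(frac_unstable = 0.6, frac_partial = 0.6),
               class = "methinstab_config_error")
})

test_that("annotation generator: degenerate fractions, packing, non-overlap", {
  cfg <- small_config(n_genes = 10,
                      biotype_fractions = c(protein_coding = 1.0),
                      unstable_biotype_fractions = c(protein_coding = 1.0))
  ann <- gen_annotation(cfg)
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$biotype == "protein_coding"))
  expect_true(all(ann$start < ann$end))
  ## genes within a chromosome never overlap
  by_chrom <- split(ann, ann$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start)]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  ## infeasible packing is a configuration error
  expect_error(gen_annotation(cfg, chromosome_length = 1000),
               class = "methinstab_config_error")
})

test_that("biotype fractions hit their binomial expectation", {
  cfg <- sim_config(seed = 17, n_genes = 1000, n_chromosomes = 2,
                    biotype_fractions = c(pc = 0.5, pseudo = 0.5),
                    unstable_biotype_fractions = c(pc = 1.0))
  ann <- gen_annotation(cfg)
  n_pseudo <- sum(ann$biotype == "pseudo")
  ## binomial 99% interval around 500 at n=1000
  expect_gt(n_pseudo, 500 - 2.58 * sqrt(250))
  expect_lt(n_pseudo, 500 + 2.58 * sqrt(250))
})

test_that("shared-Poisson count model achieves its target correlation", {
  set.seed(18)
  for (rho in c(0, 0.6, 0.95)) {
    x <- rbicount(20000, mu = 5, rho = rho)
    expect_lt(abs(cor(x[, 1], x[, 2]) - rho), 0.03)
    expect_lt(abs(mean(x) - 5), 0.1)
  }
  ## outside the achievable range -> configuration error
  expect_error(rbicount(10, mu = 5, rho = 1.2),
               class = "methinstab_config_error")
  expect_error(rbicount(10, mu = 5, rho = -0.2),
               class = "methinstab_config_error")
})

test_that("ground truth invariants: planted unstable genes carry all four categories", {
  cfg <- small_config(seed = 19)
  ann <- gen_annotation(cfg)
  tr <- gen_truth(cfg, ann)
  g <- tr$genes
  u <- g[unstable == TRUE]
  expect_gt(nrow(u), 0)
  expect_true(all(u$n_up_5mC >= 1 & u$n_down_5mC >= 1 &
                  u$n_up_6mA >= 1 & u$n_down_6mA >= 1))
  expect_equal(g$unstable, g$unstable_5mC & g$unstable_6mA)
  ## survival-effect genes are forced DE-down (planted TSG candidates)
  expect_true(all(g[survival_effect == TRUE, de_direction] == "down"))
  expect_equal(g$tsg_candidate, g$survival_effect & g$de_direction == "down")
})

test_that("every planted site passes and every background site fails the rules", {
  cfg <- small_config(seed = 20)
  ann <- gen_annotation(cfg)
  tr <- gen_truth(cfg, ann)
  meth <- gen_methylome_pair(cfg, ann, tr)
  sheet <- meth$sample_sheet
  tc <- sheet$column_name[sheet$condition == "tumor"]
  nc <- sheet$column_name[sheet$condition == "normal"]
  site_truth <- as.data.frame(meth$site_truth)
  for (mk in c("5mC", "6mA")) {
    s <- meth[[paste0("sites_", mk)]]
    t <- rowMeans(s[, tc, with = FALSE])
    n <- rowMeans(s[, nc, with = FALSE])
    truth_dir <- site_truth$direction[site_truth$mark == mk]
    expect_identical(rule_oracle(t, n), truth_dir)
    ## the same holds within every single pair (per_pair_consensus world)
    for (p in unique(sheet$pair_id)) {
      tp <- s[[paste0(p, "_T")]]
      np <- s[[paste0(p, "_N")]]
      expect_identical(rule_oracle(tp, np), truth_dir)
    }
  }
})

test_that("deterministic-limit counts and survival flags behave", {
  cfg <- noiseless_config(seed = 22, n_genes = 50, n_patients = 30,
                          censor_rate = 0)
  ann <- gen_annotation(cfg)
  tr <- gen_truth(cfg, ann)
  sv <- gen_survival(cfg, tr)
  expect_true(all(sv$event == 1))        # censor_rate = 0
  expect_true(all(sv$time_days > 0))
  ## equal library sizes and equal lengths: RPKM proportional to counts
  counts <- gen_expression(cfg, ann, tr)
  mat <- as.matrix(counts[, -(1:2)])
  r <- compute_rpkm(mat, rep(1000, nrow(mat)), rep(1e6, ncol(mat)))
  expect_equal(r / mat, matrix(1, nrow(mat), ncol(mat)), ignore_attr = TRUE)
})

test_that("simulate_cohort is byte-identical under the same config", {
  cfg <- small_config(seed = 23, n_genes = 60, n_patients = 30)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
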
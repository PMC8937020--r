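test_that("KM estimator closed forms and censoring behaviour", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  ## all censored: S stays 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km2$surv, rep(1, 3))
  ## hand-computed 5-subject set with one censor at t=2:
  ## t=1: 5 at risk, 1 event -> 4/5; t=2: censor only; t=3: 3 at risk,
  ## 1 event -> 4/5*2/3; t=4: 2 at risk, 2 events -> 0
  km3 <- km_estimate(c(1, 2, 3, 4, 4), c(1, 0, 1, 1, 1))
  expect_equal(km3$surv, c(4/5, 4/5, 4/5 * 2/3, 0))
  expect_equal(km3$n_risk, c(5, 4, 3, 2))
  expect_error(km_estimate(numeric(), numeric()),
               class = "methinstab_data_error")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(8)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank symmetry, degenerate errors, and survdiff agreement", {
  t <- c(1, 2, 3, 4, 5, 6); e <- c(1, 1, 0, 1, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(10)
  tA <- rexp(25); eA <- rbinom(25, 1, 0.8)
  tB <- rexp(30) * 2; eB <- rbinom(30, 1, 0.8)
  ab <- logrank_test(tA, eA, tB, eB)
  ba <- logrank_test(tB, eB, tA, eA)
  expect_equal(ab$statistic, ba$statistic)   # label swap invariance
  expect_error(logrank_test(tA, rep(0, 25), tB, rep(0, 30)),
               class = "methinstab_degenerate_error")

  skip_if_not_installed("survival")
  for (i in 1:20) {
    nA <- sample(8:40, 1); nB <- sample(8:40, 1)
    tA <- rexp(nA); eA <- rbinom(nA, 1, 0.7)
    tB <- rexp(nB) * runif(1, 0.5, 2); eB <- rbinom(nB, 1, 0.7)
    if (sum(eA) + sum(eB) == 0) next
    mine <- logrank_test(tA, eA, tB, eB)
    ref <- survival::survdiff(
      survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, c(nA, nB)))
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  }
})

make_sd <- function(time, event, expr_mat) {
  methinstab:::new_survival_dataset(
    data.table::data.table(sample_id = sprintf("S%d", seq_along(time)),
                           time = time, event = event),
    expr_mat)
}

test_that("screen handles degenerate genes without affecting others", {
  set.seed(12)
  n <- 60
  time <- rexp(n, 1 / 100); event <- rbinom(n, 1, 0.8)
  expr <- rbind(gene_ok = rlnorm(n), gene_const = rep(2, n))
  sd <- make_sd(time, event, expr)
  sc <- screen_genes(sd, c("gene_ok", "gene_const"))
  expect_true(is.na(sc$p_value[sc$gene_id == "gene_const"]))
  expect_match(sc$error[sc$gene_id == "gene_const"], "degenerate")
  expect_false(is.na(sc$p_value[sc$gene_id == "gene_ok"]))
  ## gene order invariance
  sc2 <- screen_genes(sd, c("gene_const", "gene_ok"))
  expect_equal(sc[order(gene_id)], sc2[order(gene_id)])
  ## missing gene is a data error naming it
  err <- expect_error(screen_genes(sd, "gene_missing"),
                      class = "methinstab_data_error")
  expect_match(conditionMessage(err), "gene_missing")
})

test_that("median split sends ties to the low group", {
  set.seed(13)
  n <- 30
  expr <- rbind(g = rep(c(1, 1, 2), each = 10))  # median 1; ties -> low
  sd <- make_sd(rexp(n, 1 / 50), rbinom(n, 1, 0.9), expr)
  sc <- suppressWarnings(screen_genes(sd, "g"))
  expect_equal(sc$n_low, 20)
  expect_equal(sc$n_high, 10)
})

test_that("TSG candidates require selection, DE-down and low-expression risk", {
  sc <- data.table::data.table(
    gene_id = c("A", "B", "C", "D"),
    median_expr = 1, n_low = 10, n_high = 10, statistic = 5,
    p_value = c(0.01, 0.01, 0.01, 0.2),
    direction_of_risk = c("low_expression_worse", "low_expression_worse",
                          "high_expression_worse", "low_expression_worse"),
    selected = c(TRUE, TRUE, TRUE, FALSE), error = NA_character_)
  de <- data.table::data.table(gene_id = c("A", "B", "C", "D"),
                               de_direction = c("down", "up", "down", "down"))
  expect_equal(select_tsg_candidates(sc, de), "A")
})

test_that("planted survival effect is detected and flagged as TSG candidate", {
  cfg <- sim_config(seed = 14, n_genes = 60, frac_unstable = 0.3,
                    n_survival_effect = 2, n_patients = 250,
                    hazard_log_hr = 1.2, expr_noise_sd = 0.1)
  ann <- gen_annotation(cfg)
  tr <- gen_truth(cfg, ann)
  sv <- gen_survival(cfg, tr)
  sd <- make_sd(sv$time_days, sv$event, t(as.matrix(sv[, -(1:3)])))
  effect <- tr$genes[survival_effect == TRUE, gene_id]
  sc <- screen_genes(sd, effect)
  expect_true(all(sc$selected))
  expect_true(all(sc$direction_of_risk == "low_expression_worse"))
  de <- tr$genes[, .(gene_id, de_direction)]
  expect_equal(select_tsg_candidates(sc, de), sort(effect))
})
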
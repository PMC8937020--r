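test_that("RPKM formula, zeros, and the conservation identity", {
  counts <- matrix(c(10, 0, 5, 20), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  r <- compute_rpkm(counts, lengths = c(1000, 2000),
                    library_sizes = c(1e6, 1e6))
  expect_equal(r["g1", "s1"], 10)       # 10 * 1e9 / (1e6 * 1000)
  expect_equal(r["g2", "s1"], 0)
  ## conservation: sum_g rpkm * length * lib / 1e9 = column totals
  set.seed(2)
  counts <- matrix(rpois(600, 50), 100, 6)
  len <- sample(200:5000, 100)
  r <- compute_rpkm(counts, len)
  back <- colSums(r * len) * colSums(counts) / 1e9
  expect_equal(back, colSums(counts), tolerance = 1e-12)
  expect_error(compute_rpkm(counts, len, library_sizes = c(0, rep(1, 5))),
               class = "methinstab_data_error")
})

test_that("RPKM matches edgeR's rpkm on random data", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  counts <- matrix(rpois(400, 80), 100, 4,
                   dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:4)))
  len <- sample(500:5000, 100)
  mine <- compute_rpkm(counts, len)
  y <- edgeR::DGEList(counts = counts)
  ref <- edgeR::rpkm(y, gene.length = len, normalized.lib.sizes = FALSE)
  expect_equal(mine, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("DE calling uses strict fold thresholds with pseudocount", {
  rpkm <- matrix(c(20, 10, 1, 5, 5, 1), 3, 2,
                 dimnames = list(c("gA", "gB", "gC"), c("T1", "N1")))
  de <- call_de_genes(rpkm, c("tumor", "normal"), pseudocount = 0)
  expect_equal(de$de_direction, c("up", "none", "none"))  # FC 4, 2 (strict), 1
  expect_true(de$de[1]); expect_false(de$de[2])
  ## down direction
  de2 <- call_de_genes(rpkm[, 2:1], c("tumor", "normal"), pseudocount = 0)
  expect_equal(de2$de_direction, c("down", "none", "none"))
})

test_that("contingency table enumeration and conservation", {
  tab <- build_contingency(class_genes = c("A", "B"), de_genes = c("B", "C"),
                           universe = c("A", "B", "C", "D"))
  expect_equal(unname(as.vector(tab)), c(1, 1, 1, 1))
  expect_false(attr(tab, "degenerate"))
  ## class == universe -> degenerate margin flagged
  tab2 <- build_contingency(c("A", "B"), c("A"), c("A", "B"))
  expect_true(attr(tab2, "degenerate"))
  ## conservation on random labels
  set.seed(4)
  uni <- sprintf("g%d", 1:200)
  tab3 <- build_contingency(sample(uni, 50), sample(uni, 80), uni)
  expect_equal(sum(tab3), 200)
  expect_error(build_contingency("A", "B", character()),
               class = "methinstab_data_error")
})

test_that("chi-square equals closed form, stats::chisq.test, and handles edge cases", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, chi2x2_closed(tab))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # prints as 6.6667
  expect_equal(res$p_value, 9.823e-3, tolerance = 1e-3)
  ## equality with R's implementation, with and without Yates
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  resY <- chi_square_test(tab, correct = TRUE)
  refY <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(resY$statistic, unname(refY$statistic), tolerance = 1e-12)
  ## perfect independence
  expect_equal(chi_square_test(matrix(15, 2, 2))$p_value, 1)
  ## transposition invariance
  set.seed(5)
  m <- matrix(rpois(4, 30) + 5, 2)
  expect_equal(chi_square_test(m)$statistic, chi_square_test(t(m))$statistic)
  ## empty margin is a data error; small expected counts warn
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)),
               class = "methinstab_data_error")
  expect_warning(chi_square_test(matrix(c(1, 2, 2, 1), 2)), "expected")
})

test_that("deterministic-limit expression has exact planted fold change", {
  cfg <- noiseless_config(seed = 6, n_genes = 100, n_patients = 40,
                          de_fold_change = 4)
  ann <- gen_annotation(cfg)
  tr <- gen_truth(cfg, ann)
  counts <- gen_expression(cfg, ann, tr)
  mat <- as.matrix(counts[, -(1:2)])
  rownames(mat) <- counts$gene_id
  ## equal supplied libraries isolate the planted ratio exactly
  r <- compute_rpkm(mat, counts$length_bp,
                    library_sizes = rep(cfg$library_size, ncol(mat)))
  up <- tr$genes[de_direction == "up", gene_id]
  dn <- tr$genes[de_direction == "down", gene_id]
  ratio <- rowMeans(r[, c("P1_T", "P2_T")]) / rowMeans(r[, c("P1_N", "P2_N")])
  expect_equal(unname(ratio[up]), rep(4, length(up)), tolerance = 1e-12)
  expect_equal(unname(ratio[dn]), rep(0.25, length(dn)), tolerance = 1e-12)
  ## with column-sum libraries the DE caller still recovers the planted set
  sheet <- data.frame(column_name = colnames(mat),
                      condition = ifelse(grepl("_T$", colnames(mat)),
                                         "tumor", "normal"),
                      pair_id = sub("_.*", "", colnames(mat)))
  decall <- call_de_genes(compute_rpkm(mat, counts$length_bp), sheet)
  expect_equal(sort(decall$gene_id[decall$de]),
               sort(tr$genes$gene_id[tr$genes$de]))
  expect_equal(decall$de_direction[match(tr$genes$gene_id, decall$gene_id)],
               tr$genes$de_direction)
})

test_that("gene class membership follows the class_spec definitions", {
  l <- data.table::data.table(gene_id = c("A", "B", "C"),
                              has_5mC_up = c(TRUE, TRUE, FALSE),
                              has_5mC_down = c(FALSE, TRUE, TRUE),
                              has_6mA_up = FALSE, has_6mA_down = FALSE)
  expect_equal(gene_class_members(l, "5mC", "mark_up_specific"), "A")
  expect_equal(gene_class_members(l, "5mC", "mark_down_specific"), "C")
  expect_equal(gene_class_members(l, "5mC", "mark_both_updown"), "B")
  expect_equal(gene_class_members(l, "6mA", "mark_both_updown"), character())
})
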
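prof_row <- function(id, u5, d5, u6, d6) {
  data.table::data.table(gene_id = id, biotype = "pc",
                         n_up_5mC = u5, n_down_5mC = d5,
                         n_up_6mA = u6, n_down_6mA = d6,
                         total = u5 + d5 + u6 + d6)
}

test_that("unstable requires all four categories to be non-empty", {
  prof <- rbind(prof_row("A", 2, 1, 3, 1), prof_row("B", 2, 0, 3, 1))
  l <- classify_genes(prof)
  expect_equal(l$unstable, c(TRUE, FALSE))
  ## depends only on positivity: scaling counts changes nothing
  prof2 <- data.table::copy(prof)
  for (cn in grep("^n_", names(prof2), value = TRUE))
    prof2[[cn]] <- prof2[[cn]] * 7L
  expect_equal(classify_genes(prof2)$unstable, l$unstable)
})

test_that("venn regions partition flagged genes and match brute-force enumeration", {
  set.seed(9)
  n <- 50
  l <- data.table::data.table(gene_id = sprintf("G%02d", 1:n),
                              has_5mC_up = runif(n) < 0.5,
                              has_5mC_down = runif(n) < 0.5,
                              has_6mA_up = runif(n) < 0.5,
                              has_6mA_down = runif(n) < 0.5)
  v <- venn_counts(l)
  expect_length(v, 15)
  flagged <- rowSums(as.matrix(l[, -1])) > 0
  expect_equal(sum(v), sum(flagged))
  ## brute force: classify each gene by its 16-way membership pattern
  flags <- c("has_5mC_up", "has_5mC_down", "has_6mA_up", "has_6mA_down")
  key <- apply(as.matrix(l[, ..flags]), 1,
               function(r) paste(flags[r], collapse = "&"))
  for (region in names(v))
    expect_equal(unname(v[region]), sum(key == region), info = region)
})

test_that("single-flag labels collapse into one venn region", {
  l <- data.table::data.table(gene_id = c("A", "B"), has_5mC_up = TRUE,
                              has_5mC_down = FALSE, has_6mA_up = FALSE,
                              has_6mA_down = FALSE)
  v <- venn_counts(l)
  expect_equal(unname(v["has_5mC_up"]), 2L)
  expect_equal(sum(v), 2L)
})

test_that("biotype composition fractions and identity on the whole genome", {
  ann <- data.table::data.table(gene_id = sprintf("G%d", 1:8),
                                chrom = "chr1", start = 1:8 * 100L,
                                end = 1:8 * 100L + 50L, strand = "+",
                                biotype = rep(c("protein_coding", "pseudogene"),
                                              c(6, 2)))
  bc <- biotype_composition(c("G1", "G2", "G3", "G7"), ann)
  expect_equal(unname(bc$set["protein_coding"]), 0.75)
  expect_equal(sum(bc$set), 1)
  expect_equal(sum(bc$background), 1)
  whole <- biotype_composition(ann$gene_id, ann)
  expect_equal(whole$set, whole$background)
  expect_error(biotype_composition("nope", ann), class = "methinstab_data_error")
})

test_that("updown correlation: collinear counts, symmetry, degenerate errors", {
  prof <- rbind(prof_row("A", 1, 2, 0, 0), prof_row("B", 2, 4, 0, 0),
                prof_row("C", 3, 6, 0, 0))
  expect_equal(updown_correlation(prof, "5mC")$r, 1.0)
  ## symmetric in (up, down)
  swapped <- data.table::copy(prof)
  data.table::setnames(swapped, c("n_up_5mC", "n_down_5mC"),
                       c("n_down_5mC", "n_up_5mC"))
  expect_equal(updown_correlation(swapped, "5mC")$r,
               updown_correlation(prof, "5mC")$r)
  ## gene order invariance
  expect_equal(updown_correlation(prof[3:1], "5mC")$r,
               updown_correlation(prof, "5mC")$r)
  ## constant vector is an error, not silently 0
  constant <- rbind(prof_row("A", 1, 2, 0, 0), prof_row("B", 1, 4, 0, 0),
                    prof_row("C", 1, 6, 0, 0))
  expect_error(updown_correlation(constant, "5mC"),
               class = "methinstab_degenerate_error")
  ## support restriction: 6mA has no sites here
  expect_error(updown_correlation(prof, "6mA"),
               class = "methinstab_degenerate_error")
})

test_that("ranking sorts by total with gene_id tie-break", {
  prof <- rbind(prof_row("D", 4, 3, 2, 1), prof_row("B", 3, 2, 1, 1),
                prof_row("A", 2, 2, 2, 1), prof_row("C", 1, 1, 0, 1))
  labels <- classify_genes(prof)
  ## totals: D=10, B=7, A=7, C=3 (C not unstable: no 6mA up)
  top <- rank_unstable_genes(prof, labels, n = 10)
  expect_equal(top, c("D", "A", "B"))
  expect_equal(rank_unstable_genes(prof, labels, n = 2), c("D", "A"))
  ## alternative key: 6mA-only sums are D=3, B=2, A=3 -> tie broken by id
  top6 <- rank_unstable_genes(prof, labels, n = 10, key = "6mA")
  expect_equal(top6, c("A", "D", "B"))
})

test_that("planted unstable set and biotype enrichment are recovered", {
  cfg <- noiseless_config(seed = 21, n_genes = 400, n_patients = 40)
  sim <- simulate_cohort(cfg, file.path(tempdir(), "inst_rec"))
  ann <- sim$annotation
  d5 <- suppressMessages(call_differential_sites(sim_site_table(sim$methylome, "5mC")))
  d6 <- suppressMessages(call_differential_sites(sim_site_table(sim$methylome, "6mA")))
  prof <- build_profiles(d5, d6, ann)
  labels <- classify_genes(prof)
  got <- sort(labels[labels$unstable == TRUE, gene_id])
  expect_equal(got, sort(sim$truth$genes[unstable == TRUE, gene_id]))
  ## unstable genes skew protein-coding relative to background
  bc <- biotype_composition(got, ann)
  expect_gt(bc$set["protein_coding"], bc$background["protein_coding"])
})
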
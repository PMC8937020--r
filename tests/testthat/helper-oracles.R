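## Independent oracles used across the suite. Each is a deliberately
## naive re-statement of a contract, kept free of package internals.

## one-line re-statement of the differential-site rules on aggregated
## (tumor, normal) score pairs
rule_oracle <- function(t, n, fold = 2, thr = 0.6) {
  ifelse(t > 0 & n > 0,
         ifelse(t / n > fold, "up", ifelse(n / t > fold, "down", "none")),
         ifelse(xor(t == 0, n == 0),
                ifelse(t > thr, "up", ifelse(n > thr, "down", "none")),
                "none"))
}

## O(n*m) interval overlap of 1-bp sites against half-open genes
brute_overlap <- function(sites, genes, flank = 0) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      if (sites$chrom[i] == genes$chrom[j] &&
          sites$pos0[i] >= genes$start[j] - flank &&
          sites$pos0[i] < genes$end[j] + flank) {
        k <- k + 1L
        out[[k]] <- data.frame(site_idx = i, gene_id = genes$gene_id[j])
      }
    }
  }
  if (k == 0L) return(data.frame(site_idx = integer(), gene_id = character()))
  res <- do.call(rbind, out)
  res[order(res$site_idx, res$gene_id), ]
}

## closed form for the 2x2 Pearson chi-square statistic
chi2x2_closed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

## build a site_score_table from vectors of aggregated pairs, represented
## as one tumor + one normal sample (aggregation is then the identity)
pair_table <- function(t, n, mark = "5mC", chrom = "chr1") {
  sheet <- data.frame(column_name = c("P1_T", "P1_N"),
                      pair_id = "P1", condition = c("tumor", "normal"))
  methinstab:::new_site_table(
    mark,
    data.table::data.table(chrom = chrom, pos0 = seq_along(t) * 10L,
                           P1_T = t, P1_N = n),
    sheet)
}

## site_score_table straight from generator output
sim_site_table <- function(meth, mark) {
  d <- meth[[paste0("sites_", mark)]]
  methinstab:::new_site_table(mark, d[, !"mark"], meth$sample_sheet)
}

## small default world for module tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 120, n_patients = 80,
         gene_length_range = c(1000, 4000)),
    list(...))
  do.call(sim_config, args)
}

## noiseless world: recovered quantities equal planted ones exactly
noiseless_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, score_noise_sd = 0, nb_dispersion = 0,
         expr_noise_sd = 0),
    list(...))
  do.call(sim_config, args)
}
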
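## Synthetic cohort generator. Plants a known effect structure:
##   - per-gene (up, down) differential site counts with a target Pearson
##     correlation per mark (shared-gamma Poisson mixture),
##   - DE status coupled to per-mark unstable status through odds ratios,
##   - survival hazards raised for the low-expression group of a few top
##     unstable genes (forced DE-down, i.e. planted TSG candidates).
## Every planted site satisfies, and every background site fails, the
## calling rules under both aggregation policies, provided
## score_noise_sd < 0.06 (validated in sim_config).

RULE_MIX <- c(fold_change = 0.85, zero_rescue = 0.15)
BG_MIX <- c(pair_nonzero = 0.75, rescue_fail = 0.10, all_zero = 0.15)

#' Correlated bivariate counts via a shared Poisson component
#'
#' Classic bivariate Poisson construction: `x = s + e1`, `y = s + e2`
#' with independent `s ~ Poisson(rho * mu)` and
#' `e_i ~ Poisson((1 - rho) * mu)`, so both marginals are Poisson with
#' mean `mu` and `cor(x, y) = rho` exactly in the population. The whole
#' range `[0, 1]` is achievable, and the Poisson-light tails keep the
#' sample correlation at `n` genes within the usual Fisher-z sampling
#' band around the target.
#'
#' @param n number of pairs.
#' @param mu marginal mean (> 0).
#' @param rho target Pearson correlation in \[0, 1\].
#' @return integer matrix with columns `up`, `down`.
#' @export
rbicount <- function(n, mu, rho) {
  if (mu <= 0) abort_config("'mu' must be positive")
  if (rho < 0 || rho > 1)
    abort_config(paste0("target correlation %.3f outside achievable range ",
                        "[0, 1] of the shared-Poisson count model"), rho)
  s <- rpois(n, rho * mu)
  cbind(up = s + rpois(n, (1 - rho) * mu),
        down = s + rpois(n, (1 - rho) * mu))
}

## Correlation targeting by construction: redraw (up to max_tries) until
## the sample correlation of the planted counts sits within `tol` of the
## target, keeping the closest draw otherwise. The planted world then
## carries its declared statistical structure rather than one noisy
## realisation of it; deterministic under the caller's seed.
rbicount_calibrated <- function(n, mu, rho, tol = 0.02, max_tries = 50L) {
  best <- NULL
  best_dev <- Inf
  for (i in seq_len(max_tries)) {
    x <- rbicount(n, mu, rho)
    r <- if (stats::var(x[, 1]) == 0 || stats::var(x[, 2]) == 0) NA_real_
         else cor(x[, 1], x[, 2])
    dev <- abs(r - rho)
    if (!is.na(dev) && dev < best_dev) {
      best <- x
      best_dev <- dev
    }
    if (!is.na(dev) && dev <= tol) break
  }
  best %||% x
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes on `n_chromosomes` chromosomes in BED
#' 0-based half-open coordinates, with biotypes drawn from
#' `biotype_fractions`. Deterministic under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param chromosome_length optional fixed chromosome length in bp; the
#'   default sizes each chromosome to fit its genes. If supplied and the
#'   packing does not fit, a configuration error is raised.
#' @return data.table with columns gene_id, chrom, start, end, strand,
#'   biotype (coordinates 0-based half-open).
#' @export
gen_annotation <- function(config, chromosome_length = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, "annotation"))
  n <- cfg$n_genes
  chrom <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), length.out = n)
  len <- round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  gap <- round(runif(n, 500, 5000))
  dt <- data.table(chrom = chrom, len = len, gap = gap)
  dt[, end := cumsum(len + gap), by = chrom]
  dt[, start := end - len]
  if (!is.null(chromosome_length)) {
    maxend <- dt[, max(end), by = chrom]$V1
    if (any(maxend > chromosome_length))
      abort_config("genes do not fit: need %d bp but chromosome_length is %d",
                   max(maxend), as.integer(chromosome_length))
  }
  dt[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  dt[, biotype := sample(names(cfg$biotype_fractions), .N, replace = TRUE,
                         prob = cfg$biotype_fractions)]
  setorder(dt, chrom, start)                 # per-chrom construction order
  dt <- dt[chrom_order(chrom, start)]
  dt[, gene_id := sprintf("G%05d", seq_len(.N))]
  dt[, c("len", "gap") := NULL]
  setcolorder(dt, c("gene_id", "chrom", "start", "end", "strand", "biotype"))
  dt[]
}

## Sample n_pick genes so that the picked set's biotype composition
## approaches `target` (a named fraction vector) regardless of the
## background composition.
biased_gene_sample <- function(annotation, n_pick, target) {
  if (n_pick == 0L) return(character())
  tab <- table(annotation$biotype)
  w <- target[annotation$biotype] / as.numeric(tab[annotation$biotype])
  w[is.na(w)] <- 0
  if (all(w == 0)) w <- rep(1, nrow(annotation))
  sample(annotation$gene_id, n_pick, prob = w)
}

#' Generate the planted ground truth
#'
#' Assigns each gene a mark/direction pattern, planted differential site
#' counts, a DE label coupled to per-mark unstable status through the
#' configured odds ratios, and survival-effect flags.
#'
#' @param config a [sim_config()].
#' @param annotation output of [gen_annotation()].
#' @return a `ground_truth` list with element `genes` (data.table of
#'   per-gene labels and planted counts) and `config`.
#' @export
gen_truth <- function(config, annotation) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, "truth"))
  n <- cfg$n_genes
  ids <- annotation$gene_id
  flags <- matrix(FALSE, n, 4, dimnames = list(ids, c("u5", "d5", "u6", "d6")))

  n_unst <- round(cfg$frac_unstable * n)
  unstable_ids <- biased_gene_sample(annotation, n_unst,
                                     cfg$unstable_biotype_fractions)
  flags[unstable_ids, ] <- TRUE
  rest <- setdiff(ids, unstable_ids)

  take <- function(pool, k) if (k == 0L) character() else sample(pool, min(k, length(pool)))
  ids_5only <- take(rest, round(cfg$frac_5mC_only * n))
  rest <- setdiff(rest, ids_5only)
  ids_6only <- take(rest, round(cfg$frac_6mA_only * n))
  rest <- setdiff(rest, ids_6only)
  ids_part <- take(rest, round(cfg$frac_partial * n))
  flags[ids_5only, c("u5", "d5")] <- TRUE
  flags[ids_6only, c("u6", "d6")] <- TRUE
  if (length(ids_part)) {
    ## any non-empty, non-full subset of the four categories
    pat <- sample(14L, length(ids_part), replace = TRUE)
    for (j in 1:4) flags[ids_part, j] <- bitwAnd(pat, bitwShiftL(1L, j - 1L)) > 0
  }

  mu_dir <- cfg$sites_per_gene_mean / 2
  counts <- matrix(0L, n, 4, dimnames = dimnames(flags))
  for (m in c("5mC", "6mA")) {
    cols <- if (m == "5mC") c("u5", "d5") else c("u6", "d6")
    rho <- if (m == "5mC") cfg$updown_corr_5mC else cfg$updown_corr_6mA
    both <- flags[, cols[1]] & flags[, cols[2]]
    if (any(both)) {
      bc <- rbicount_calibrated(sum(both), mu_dir, rho)
      counts[both, cols] <- bc + 1L          # shift keeps >=1, corr unchanged
    }
    for (j in 1:2) {
      only <- flags[, cols[j]] & !flags[, cols[3 - j]]
      if (any(only))
        counts[only, cols[j]] <- 1L + rpois(sum(only), max(mu_dir - 1, 0))
    }
  }

  g <- data.table(gene_id = ids,
                  biotype = annotation$biotype,
                  n_up_5mC = counts[, "u5"], n_down_5mC = counts[, "d5"],
                  n_up_6mA = counts[, "u6"], n_down_6mA = counts[, "d6"])
  g[, unstable_5mC := n_up_5mC > 0 & n_down_5mC > 0]
  g[, unstable_6mA := n_up_6mA > 0 & n_down_6mA > 0]
  g[, unstable := unstable_5mC & unstable_6mA]

  p_de <- plogis(qlogis(cfg$de_base_rate) +
                 log(cfg$de_coupling_odds_ratio_5mC) * g$unstable_5mC +
                 log(cfg$de_coupling_odds_ratio_6mA) * g$unstable_6mA)
  g[, de := rbinom(.N, 1L, p_de) == 1L]
  g[, de_direction := ifelse(de, sample(c("up", "down"), .N, replace = TRUE),
                             "none")]

  ## survival effects on the top planted unstable genes (forced DE-down,
  ## i.e. planted tumor-suppressor candidates)
  g[, survival_effect := FALSE]
  if (cfg$n_survival_effect > 0 && any(g$unstable)) {
    tot <- g$n_up_5mC + g$n_down_5mC + g$n_up_6mA + g$n_down_6mA
    cand <- g[unstable == TRUE][order(-tot[g$unstable], gene_id)]
    eff <- head(cand$gene_id, cfg$n_survival_effect)
    g[gene_id %in% eff,
      `:=`(survival_effect = TRUE, de = TRUE, de_direction = "down")]
  }
  g[, tsg_candidate := survival_effect & de_direction == "down"]
  structure(list(genes = g[], config = cfg), class = "ground_truth")
}

## condition-level base scores for one planted direction under one rule
planted_bases <- function(k, direction, rule) {
  t0 <- n0 <- numeric(k)
  fc <- rule == "fold_change"
  lo <- runif(sum(fc), 0.08, 0.28)
  hi <- lo * runif(sum(fc), 2.3, 3.2)
  if (direction == "up") { t0[fc] <- hi; n0[fc] <- lo }
  else                   { t0[fc] <- lo; n0[fc] <- hi }
  zr <- !fc
  big <- runif(sum(zr), 0.68, 0.92)
  if (direction == "up") { t0[zr] <- big; n0[zr] <- 0 }
  else                   { t0[zr] <- 0;   n0[zr] <- big }
  list(t0 = t0, n0 = n0)
}

## condition-level base scores for background (never call-able) sites
background_bases <- function(k) {
  cls <- sample(names(BG_MIX), k, replace = TRUE, prob = BG_MIX)
  t0 <- n0 <- numeric(k)
  nz <- cls == "pair_nonzero"
  t0[nz] <- n0[nz] <- runif(sum(nz), 0.10, 0.85)
  rf <- cls == "rescue_fail"
  side <- runif(sum(rf)) < 0.5
  v <- runif(sum(rf), 0.05, 0.50)
  t0[rf] <- ifelse(side, v, 0)
  n0[rf] <- ifelse(side, 0, v)
  list(t0 = t0, n0 = n0)          # all_zero stays (0, 0)
}

## expand condition bases to jittered per-sample columns; zeros stay zero
sample_scores <- function(t0, n0, n_pairs, noise) {
  out <- list()
  for (p in seq_len(n_pairs)) {
    jt <- 1 + runif(length(t0), -noise, noise)
    jn <- 1 + runif(length(n0), -noise, noise)
    out[[sprintf("P%d_T", p)]] <- pmin(1, t0 * jt)
    out[[sprintf("P%d_N", p)]] <- pmin(1, n0 * jn)
  }
  out
}

#' Generate the paired tumor/normal methylomes for both marks
#'
#' For each mark, planted differential sites are laid down inside their
#' gene bodies with tumor/normal score pairs that satisfy the calling
#' rules in the planted direction; background sites (genic and
#' intergenic) are constructed so that no calling rule can fire on them
#' (score ratio within \[1/2, 2\], and a zero score never faces a score
#' above 0.6).
#'
#' @param config a [sim_config()].
#' @param annotation output of [gen_annotation()].
#' @param truth output of [gen_truth()].
#' @return list with `sites_5mC`, `sites_6mA` (data.tables: chrom, pos0,
#'   mark, one score column per sample), `site_truth` (per-site planted
#'   direction) and `sample_sheet`.
#' @export
gen_methylome_pair <- function(config, annotation, truth) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, "methylome"))
  ann <- as.data.table(annotation)
  g <- truth$genes
  noise <- cfg$score_noise_sd
  np <- cfg$n_pairs
  sample_cols <- as.vector(t(outer(sprintf("P%d", seq_len(np)), c("T", "N"),
                                   paste, sep = "_")))
  sheet <- data.table(column_name = sample_cols,
                      pair_id = sub("_[TN]$", "", sample_cols),
                      condition = ifelse(grepl("_T$", sample_cols),
                                         "tumor", "normal"))

  gaps <- ann[, {
    gs <- c(0, end); ge <- c(start, max(end) + 10000)
    list(gstart = gs[ge > gs], gend = ge[ge > gs])
  }, by = chrom]

  make_mark <- function(mark) {
    upcol <- paste0("n_up_", mark); dncol <- paste0("n_down_", mark)
    rows <- list()
    tr <- list()
    for (dir in c("up", "down")) {
      cnt <- g[[if (dir == "up") upcol else dncol]]
      idx <- rep(seq_len(nrow(g)), cnt)
      k <- length(idx)
      if (k == 0) next
      rule <- sample(names(RULE_MIX), k, replace = TRUE, prob = RULE_MIX)
      b <- planted_bases(k, dir, rule)
      rows[[dir]] <- data.table(gene_idx = idx, direction = dir, rule = rule,
                                t0 = b$t0, n0 = b$n0)
    }
    bgk <- rpois(nrow(g), cfg$bg_sites_per_gene)
    if (sum(bgk) > 0) {
      idx <- rep(seq_len(nrow(g)), bgk)
      b <- background_bases(length(idx))
      rows[["bg"]] <- data.table(gene_idx = idx, direction = "none",
                                 rule = NA_character_, t0 = b$t0, n0 = b$n0)
    }
    genic <- rbindlist(rows)
    if (nrow(genic)) {
      genic[, chrom := ann$chrom[gene_idx]]
      genic[, gene_id := ann$gene_id[gene_idx]]
      ## unique positions within each gene body
      setorder(genic, gene_idx)
      genic[, pos0 := {
        st <- ann$start[gene_idx[1]]; en <- ann$end[gene_idx[1]]
        if (.N > en - st)
          abort_config("gene %s too short for %d sites", gene_id[1], .N)
        st + sample.int(en - st, .N) - 1L
      }, by = gene_idx]
    } else {
      genic <- data.table(gene_idx = integer(), direction = character(),
                          rule = character(), t0 = numeric(), n0 = numeric(),
                          chrom = character(), gene_id = character(),
                          pos0 = integer())
    }
    f <- cfg$intergenic_site_fraction
    n_inter <- if (f >= 1) abort_config("intergenic_site_fraction must be < 1")
               else round(nrow(genic) * f / (1 - f))
    if (n_inter > 0 && nrow(gaps) > 0) {
      gi <- sample(nrow(gaps), n_inter, replace = TRUE,
                   prob = gaps$gend - gaps$gstart)
      b <- background_bases(n_inter)
      inter <- data.table(gene_idx = NA_integer_, direction = "none",
                          rule = NA_character_, t0 = b$t0, n0 = b$n0,
                          chrom = gaps$chrom[gi], gene_id = NA_character_,
                          pos0 = NA_integer_, gap_i = gi)
      inter[, pos0 := {
        w <- gaps$gend[gap_i[1]] - gaps$gstart[gap_i[1]]
        gaps$gstart[gap_i[1]] + sample.int(w, .N, replace = .N > w) - 1L
      }, by = gap_i]
      inter[, gap_i := NULL]
      genic <- rbind(genic, inter)
    }
    sites <- genic[!duplicated(paste(chrom, pos0))]
    sc <- sample_scores(sites$t0, sites$n0, np, noise)
    out <- data.table(chrom = sites$chrom, pos0 = sites$pos0, mark = mark)
    for (cn in sample_cols) out[[cn]] <- sc[[cn]]
    st <- data.table(chrom = sites$chrom, pos0 = sites$pos0, mark = mark,
                     gene_id = sites$gene_id, direction = sites$direction,
                     rule = sites$rule)
    o <- chrom_order(out$chrom, out$pos0)
    list(sites = out[o], truth = st[o])
  }

  m5 <- make_mark("5mC")
  m6 <- make_mark("6mA")
  list(sites_5mC = m5$sites, sites_6mA = m6$sites,
       site_truth = rbind(m5$truth, m6$truth),
       sample_sheet = sheet)
}

#' Generate a gene-level count table with planted differential expression
#'
#' Negative-binomial counts for `2 * n_pairs` samples. Planted DE genes
#' have their tumor-condition mean multiplied (direction up) or divided
#' (direction down) by `de_fold_change`. With `nb_dispersion = 0` the
#' deterministic limit is returned: counts equal their expectations
#' (possibly non-integer), so planted ratios are exact.
#'
#' @param config a [sim_config()].
#' @param annotation output of [gen_annotation()] (provides lengths).
#' @param truth output of [gen_truth()] (provides DE labels).
#' @return data.table: gene_id, length_bp, one count column per sample.
#' @export
gen_expression <- function(config, annotation, truth) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, "expression"))
  g <- truth$genes
  n <- nrow(g)
  np <- cfg$n_pairs
  base <- rlnorm(n, meanlog = log(100), sdlog = 1)
  fc <- rep(1, n)
  fc[g$de_direction == "up"] <- cfg$de_fold_change
  fc[g$de_direction == "down"] <- 1 / cfg$de_fold_change
  mu_t <- base * fc
  mu_n <- base
  mu <- cbind(matrix(mu_t, n, np), matrix(mu_n, n, np))
  colnames(mu) <- c(sprintf("P%d_T", seq_len(np)), sprintf("P%d_N", seq_len(np)))
  mu <- mu * cfg$library_size / mean(colSums(mu))   # global depth scaling
  counts <- if (cfg$nb_dispersion == 0) mu else
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           n, ncol(mu), dimnames = dimnames(mu))
  ord <- c(as.vector(t(outer(sprintf("P%d", seq_len(np)), c("T", "N"),
                             paste, sep = "_"))))
  dt <- data.table(gene_id = g$gene_id,
                   length_bp = annotation$end - annotation$start)
  for (cn in ord) dt[[cn]] <- counts[, cn]
  dt[]
}

#' Generate a synthetic survival table
#'
#' Exponential event times with per-patient hazard `baseline_hazard *
#' exp(hazard_log_hr * n_low)` where `n_low` counts planted effect genes
#' for which the patient sits in the low-expression half. Effect-gene
#' expression is two-valued (1 = low half, 2 = high half) times lognormal
#' noise; non-effect genes are lognormal noise around a per-gene
#' baseline (constant when `expr_noise_sd = 0`). Censoring is
#' independent: with probability `censor_rate` a patient is censored at a
#' uniform fraction of their event time.
#'
#' @param config a [sim_config()].
#' @param truth output of [gen_truth()].
#' @return data.table: sample_id, time_days, event, one expression column
#'   per included gene (all dual-unstable genes plus planted effect
#'   genes; the first 50 genes if neither exists).
#' @export
gen_survival <- function(config, truth) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, "survival"))
  g <- truth$genes
  genes <- union(g[unstable == TRUE, gene_id], g[survival_effect == TRUE, gene_id])
  if (length(genes) == 0) genes <- head(g$gene_id, min(50L, nrow(g)))
  genes <- sort(genes)
  n <- cfg$n_patients
  loghaz_extra <- numeric(n)
  expr <- matrix(NA_real_, n, length(genes), dimnames = list(NULL, genes))
  effect <- g[survival_effect == TRUE, gene_id]
  for (gene in genes) {
    if (gene %in% effect) {
      low <- rep(FALSE, n)
      low[sample.int(n, floor(n / 2))] <- TRUE
      expr[, gene] <- ifelse(low, 1, 2) * exp(rnorm(n, 0, cfg$expr_noise_sd))
      loghaz_extra <- loghaz_extra + cfg$hazard_log_hr * low
    } else {
      expr[, gene] <- rlnorm(1, log(10), 1) * exp(rnorm(n, 0, cfg$expr_noise_sd))
    }
  }
  hazard <- cfg$baseline_hazard * exp(loghaz_extra)
  t_event <- rexp(n, rate = hazard)
  censored <- runif(n) < cfg$censor_rate
  time <- ifelse(censored, runif(n) * t_event, t_event)
  time <- pmax(time, 1e-6)
  dt <- data.table(sample_id = sprintf("PT%03d", seq_len(n)),
                   time_days = time, event = as.integer(!censored))
  for (gene in genes) dt[[gene]] <- expr[, gene]
  dt[]
}

#' Simulate a complete synthetic study to disk
#'
#' Runs annotation, truth, methylome, expression and survival generation
#' and writes `genes.bed`, `sites_5mC.tsv`, `sites_6mA.tsv`,
#' `counts.tsv`, `survival.tsv`, `sample_sheet.tsv`, `truth.json` and
#' `config.json` into `outdir`. Byte-identical across runs with the same
#' configuration.
#'
#' @param config a [sim_config()] (or a plain list of its fields).
#' @param outdir output directory, created if missing.
#' @return (invisibly) a list with all in-memory objects and file paths.
#' @export
simulate_cohort <- function(config, outdir) {
  cfg <- validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- gen_annotation(cfg)
  truth <- gen_truth(cfg, ann)
  meth <- gen_methylome_pair(cfg, ann, truth)
  counts <- gen_expression(cfg, ann, truth)
  surv <- gen_survival(cfg, truth)

  p <- function(f) file.path(outdir, f)
  bed <- data.table(ann$chrom, ann$start, ann$end, ann$gene_id, 0L,
                    ann$strand, ann$biotype)
  fwrite(bed, p("genes.bed"), sep = "\t", col.names = FALSE)
  fwrite(meth$sites_5mC, p("sites_5mC.tsv"), sep = "\t")
  fwrite(meth$sites_6mA, p("sites_6mA.tsv"), sep = "\t")
  fwrite(meth$sample_sheet, p("sample_sheet.tsv"), sep = "\t")
  fwrite(counts, p("counts.tsv"), sep = "\t")
  fwrite(surv, p("survival.tsv"), sep = "\t")
  truth_out <- list(genes = truth$genes, sites = meth$site_truth)
  jsonlite::write_json(truth_out, p("truth.json"), digits = NA, na = "null")
  jsonlite::write_json(unclass(cfg), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, annotation = ann, truth = truth,
                 methylome = meth, counts = counts, survival = surv,
                 outdir = outdir,
                 files = vapply(c("genes.bed", "sites_5mC.tsv", "sites_6mA.tsv",
                                  "sample_sheet.tsv", "counts.tsv",
                                  "survival.tsv", "truth.json", "config.json"),
                                p, character(1))))
}
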
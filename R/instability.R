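## Gene-level instability statistics: the dual-mark "unstable methylation
## gene" classification (up and down sites for both 5mC and 6mA), the
## four-set intersection counts, biotype composition against the genome
## background, per-mark up/down site-count correlation, and the ranked
## top-N list.

FLAG_COLS <- c("has_5mC_up", "has_5mC_down", "has_6mA_up", "has_6mA_down")

#' Classify genes by methylation-change pattern
#'
#' Each flag is strict positivity of the corresponding profile count; a
#' gene is `unstable` when all four flags hold (up- and down-regulated
#' sites of both marks).
#'
#' @param profiles data.table from [build_profiles()].
#' @return data.table: gene_id, has_5mC_up, has_5mC_down, has_6mA_up,
#'   has_6mA_down, unstable.
#' @export
classify_genes <- function(profiles) {
  p <- as.data.table(profiles)
  out <- data.table(gene_id = p$gene_id,
                    has_5mC_up = p$n_up_5mC > 0,
                    has_5mC_down = p$n_down_5mC > 0,
                    has_6mA_up = p$n_up_6mA > 0,
                    has_6mA_down = p$n_down_6mA > 0)
  out[, unstable := has_5mC_up & has_5mC_down & has_6mA_up & has_6mA_down]
  out[]
}

#' Four-set intersection (Venn) counts of the flag sets
#'
#' Counts genes in each of the 15 non-empty regions of the 4-set Venn
#' diagram over the flags (has_5mC_up, has_5mC_down, has_6mA_up,
#' has_6mA_down). Region names join member sets with `&`. The counts
#' partition the genes carrying at least one flag.
#'
#' @param labels data.table from [classify_genes()].
#' @return named integer vector of length 15.
#' @export
venn_counts <- function(labels) {
  l <- as.data.table(labels)
  all_regions <- unlist(lapply(1:4, function(k)
    utils::combn(FLAG_COLS, k, paste, collapse = "&", simplify = FALSE)))
  counts <- setNames(integer(length(all_regions)), all_regions)
  if (nrow(l) == 0) return(counts)
  m <- as.matrix(l[, FLAG_COLS, with = FALSE])
  region <- apply(m, 1, function(r) paste(FLAG_COLS[r], collapse = "&"))
  tab <- table(region[region != ""])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Biotype composition of a gene set versus the genome background
#'
#' @param gene_set character vector of gene ids.
#' @param annotation annotation data.table (all genes = background).
#' @return list with `set` and `background`, each a named fraction vector
#'   over all biotypes present in the annotation (both sum to 1), plus
#'   `set_size` and `background_size`.
#' @export
biotype_composition <- function(gene_set, annotation) {
  ann <- as.data.table(annotation)
  missing <- setdiff(gene_set, ann$gene_id)
  if (length(missing))
    abort_data("gene(s) absent from annotation: %s",
               paste(head(missing, 5), collapse = ", "))
  if (length(gene_set) == 0) abort_data("empty gene set")
  biotypes <- sort(unique(ann$biotype))
  frac <- function(b) {
    tab <- table(factor(b, levels = biotypes))
    as.numeric(tab) / length(b)
  }
  set_b <- ann[gene_id %in% gene_set, biotype]
  list(set = setNames(frac(set_b), biotypes),
       background = setNames(frac(ann$biotype), biotypes),
       set_size = length(gene_set), background_size = nrow(ann))
}

#' Pearson correlation of per-gene up and down site counts for one mark
#'
#' Computed over the mark's support: genes with at least one differential
#' site of that mark (set `include_zero = TRUE` to use every profiled
#' gene instead).
#'
#' @param profiles data.table from [build_profiles()].
#' @param mark `"5mC"` or `"6mA"`.
#' @param include_zero include genes with zero sites of the mark.
#' @return list with `r` and `n`.
#' @export
updown_correlation <- function(profiles, mark = c("5mC", "6mA"),
                               include_zero = FALSE) {
  mark <- match.arg(mark)
  p <- as.data.table(profiles)
  up <- p[[paste0("n_up_", mark)]]
  dn <- p[[paste0("n_down_", mark)]]
  if (!include_zero) {
    keep <- up + dn > 0
    up <- up[keep]; dn <- dn[keep]
  }
  if (length(up) < 3)
    abort_degenerate("need >= 3 genes to correlate (have %d)", length(up))
  if (stats::var(up) == 0 || stats::var(dn) == 0)
    abort_degenerate("constant %s count vector: correlation undefined", mark)
  list(r = cor(up, dn, method = "pearson"), n = length(up))
}

#' Rank unstable genes by instability load
#'
#' Unstable genes sorted by the ranking key descending, ties broken by
#' gene_id ascending; returns at most `n` genes.
#'
#' @param profiles data.table from [build_profiles()].
#' @param labels data.table from [classify_genes()].
#' @param n list length (default 100).
#' @param key `"total"` (all four counts, default), `"5mC"` / `"6mA"`
#'   (one mark's counts), or `"max_mark"` (the larger per-mark sum).
#' @return character vector of gene ids, ranked.
#' @export
rank_unstable_genes <- function(profiles, labels, n = 100,
                                key = c("total", "5mC", "6mA", "max_mark")) {
  key <- match.arg(key)
  if (n < 1) abort_config("'n' must be >= 1")
  p <- as.data.table(profiles)
  l <- as.data.table(labels)
  p <- merge(p, l[, .(gene_id, unstable)], by = "gene_id")[unstable == TRUE]
  if (nrow(p) == 0) return(character())
  s5 <- p$n_up_5mC + p$n_down_5mC
  s6 <- p$n_up_6mA + p$n_down_6mA
  score <- switch(key, total = s5 + s6, `5mC` = s5, `6mA` = s6,
                  max_mark = pmax(s5, s6))
  ord <- order(-score, p$gene_id)
  head(p$gene_id[ord], n)
}
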
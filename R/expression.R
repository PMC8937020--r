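## RPKM normalization, fold-change DE calling, and the chi-square
## association between methylation gene classes and DE status.

#' Compute per-sample RPKM
#'
#' `rpkm = count * 1e9 / (library_size * length_bp)`.
#'
#' @param counts numeric matrix (genes x samples) or a counts data.table
#'   with gene_id/length_bp columns.
#' @param lengths gene lengths in bp (ignored when `counts` carries a
#'   `length_bp` column).
#' @param library_sizes per-sample library sizes; defaults to column sums.
#' @return numeric matrix of RPKM values (genes x samples) with the same
#'   dimnames as the counts.
#' @export
compute_rpkm <- function(counts, lengths = NULL, library_sizes = NULL) {
  if (is.data.frame(counts)) {
    dt <- as.data.table(counts)
    lengths <- dt$length_bp
    ids <- dt$gene_id
    counts <- as.matrix(dt[, setdiff(names(dt), c("gene_id", "length_bp")),
                           with = FALSE])
    rownames(counts) <- ids
  }
  counts <- as.matrix(counts)
  if (is.null(lengths)) abort_data("gene lengths required")
  if (length(lengths) != nrow(counts)) abort_data("lengths do not match counts")
  if (any(lengths <= 0)) abort_data("gene lengths must be positive")
  if (any(counts < 0)) abort_data("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) abort_data("zero or negative library size")
  counts * 1e9 / outer(as.numeric(lengths), as.numeric(library_sizes))
}

#' Call differentially expressed genes by condition-mean fold change
#'
#' `fold_change = (mean_rpkm_tumor + c) / (mean_rpkm_normal + c)` with
#' pseudocount `c`; a gene is DE when the fold change is strictly above
#' `fold_threshold` (direction up) or strictly below its reciprocal
#' (direction down).
#'
#' @param rpkm matrix from [compute_rpkm()] (genes x samples).
#' @param conditions character vector (`tumor`/`normal`) parallel to the
#'   columns, or a sample sheet data.frame with `column_name`/`condition`.
#' @param fold_threshold strict threshold (default 2).
#' @param pseudocount added to both means (default 0.01 RPKM) so that
#'   zero-expression genes have a defined fold change.
#' @return data.table: gene_id, mean_rpkm_tumor, mean_rpkm_normal,
#'   fold_change, de, de_direction.
#' @export
call_de_genes <- function(rpkm, conditions, fold_threshold = 2,
                          pseudocount = 0.01) {
  if (fold_threshold <= 0) abort_config("'fold_threshold' must be positive")
  if (is.data.frame(conditions)) {
    sheet <- as.data.table(conditions)
    conditions <- sheet$condition[match(colnames(rpkm), sheet$column_name)]
  }
  if (length(conditions) != ncol(rpkm) || anyNA(conditions))
    abort_config("conditions do not cover all rpkm columns")
  if (!any(conditions == "tumor") || !any(conditions == "normal"))
    abort_config("need >= 1 tumor and >= 1 normal sample")
  mt <- rowMeans(rpkm[, conditions == "tumor", drop = FALSE])
  mn <- rowMeans(rpkm[, conditions == "normal", drop = FALSE])
  fc <- (mt + pseudocount) / (mn + pseudocount)
  dir <- ifelse(fc > fold_threshold, "up",
         ifelse(fc < 1 / fold_threshold, "down", "none"))
  data.table(gene_id = rownames(rpkm) %||% sprintf("g%d", seq_along(mt)),
             mean_rpkm_tumor = mt, mean_rpkm_normal = mn,
             fold_change = fc, de = dir != "none", de_direction = dir)
}

#' Members of a methylation gene class
#'
#' `mark_up_specific`: genes with up- but no down-regulated sites of the
#' mark; `mark_down_specific`: the converse; `mark_both_updown`: genes
#' with both directions (the per-mark unstable class).
#'
#' @param labels data.table from [classify_genes()].
#' @param mark `"5mC"` or `"6mA"`.
#' @param class_spec one of the three class definitions.
#' @return character vector of gene ids.
#' @export
gene_class_members <- function(labels, mark = c("5mC", "6mA"),
                               class_spec = c("mark_both_updown",
                                              "mark_up_specific",
                                              "mark_down_specific")) {
  mark <- match.arg(mark)
  class_spec <- match.arg(class_spec)
  l <- as.data.table(labels)
  up <- l[[paste0("has_", mark, "_up")]]
  dn <- l[[paste0("has_", mark, "_down")]]
  keep <- switch(class_spec,
                 mark_up_specific = up & !dn,
                 mark_down_specific = dn & !up,
                 mark_both_updown = up & dn)
  l$gene_id[keep]
}

#' Build the 2x2 class-membership x DE-status contingency table
#'
#' @param class_genes gene ids in the methylation class.
#' @param de_genes gene ids called DE.
#' @param universe gene ids defining the denominator (e.g. all annotated
#'   genes, or all genes with any methylation/expression signal).
#' @return 2x2 integer matrix (rows: in class / not; columns: DE / not)
#'   with attribute `degenerate` flagging an empty margin.
#' @export
build_contingency <- function(class_genes, de_genes, universe) {
  if (length(universe) == 0) abort_data("empty gene universe")
  in_class <- universe %in% class_genes
  is_de <- universe %in% de_genes
  tab <- matrix(c(sum(in_class & is_de), sum(in_class & !is_de),
                  sum(!in_class & is_de), sum(!in_class & !is_de)),
                nrow = 2, byrow = FALSE,
                dimnames = list(class = c("in_class", "not_in_class"),
                                de = c("de", "not_de")))
  attr(tab, "degenerate") <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  tab
}

#' Pearson chi-square test of independence
#'
#' Statistic `sum((O - E)^2 / E)` with `E` the product-margin
#' expectations; no continuity correction by default. For 2x2 tables
#' this equals the closed form `n (ad - bc)^2 / (r1 r2 c1 c2)`.
#'
#' @param table integer matrix (r x c).
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) abort_data("negative cell count")
  n <- sum(table)
  if (n == 0) abort_data("empty contingency table")
  E <- outer(rowSums(table), colSums(table)) / n
  if (any(E == 0))
    abort_data("expected cell count of 0 (empty margin): test undefined")
  if (any(E < 5))
    warning("expected cell count < 5: chi-square approximation is poor")
  dev <- abs(table - E)
  if (correct) {
    if (!all(dim(table) == c(2, 2)))
      abort_config("Yates correction applies to 2x2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

## sample odds ratio with Haldane correction for zero cells
odds_ratio <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Per-mark association between methylation classes and DE genes
#'
#' For each mark, builds the 2x2 contingency tables and chi-square tests
#' for the direction-specific classes (up-specific and down-specific)
#' and for the both-up-and-down class, over a chosen gene universe. Also
#' reports the fraction of dual-mark unstable genes that are DE.
#'
#' @param labels data.table from [classify_genes()].
#' @param de_results data.table from [call_de_genes()].
#' @param universe `"annotated_genes"` (default; requires `annotation`)
#'   or `"genes_with_any_signal"` (genes appearing in the labels or the
#'   DE table).
#' @param annotation annotation data.table (needed for the default
#'   universe).
#' @param correct Yates correction flag, passed through.
#' @return nested list: per mark and class_spec a list with `table`,
#'   `statistic`, `df`, `p_value`, `odds_ratio`, `degenerate`; plus
#'   `frac_unstable_de` and `universe_size`.
#' @export
association_report <- function(labels, de_results,
                               universe = c("annotated_genes",
                                            "genes_with_any_signal"),
                               annotation = NULL, correct = FALSE) {
  universe <- match.arg(universe)
  l <- as.data.table(labels)
  de <- as.data.table(de_results)
  uni <- if (universe == "annotated_genes") {
    if (is.null(annotation))
      abort_config("'annotation' required for universe = annotated_genes")
    as.data.table(annotation)$gene_id
  } else union(l$gene_id, de$gene_id)
  de_genes <- de[de == TRUE, gene_id]
  out <- list(universe = universe, universe_size = length(uni), marks = list())
  for (mark in c("5mC", "6mA")) {
    mres <- list()
    for (spec in c("mark_up_specific", "mark_down_specific",
                   "mark_both_updown")) {
      cls <- gene_class_members(l, mark, spec)
      tab <- build_contingency(cls, de_genes, uni)
      res <- list(table = tab, class_size = length(cls),
                  degenerate = attr(tab, "degenerate"))
      if (res$degenerate) {
        res$statistic <- res$p_value <- res$odds_ratio <- NA_real_
        res$df <- NA_integer_
      } else {
        ct <- suppressWarnings(chi_square_test(tab, correct = correct))
        res[c("statistic", "df", "p_value")] <-
          ct[c("statistic", "df", "p_value")]
        res$odds_ratio <- odds_ratio(tab)
      }
      mres[[spec]] <- res
    }
    out$marks[[mark]] <- mres
  }
  unstable_genes <- l[unstable == TRUE, gene_id]
  out$n_unstable <- length(unstable_genes)
  out$frac_unstable_de <- if (length(unstable_genes) == 0) NA_real_ else
    mean(unstable_genes %in% de_genes)
  out
}
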
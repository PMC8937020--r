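## Differential-site calling. Three rules, applied to per-condition
## aggregated scores in [0,1]:
##   1. sites with all-zero scores across every sample are removed first;
##   2. fold-change rule: both scores positive and one exceeds the other
##      by strictly more than `fold` (default 2);
##   3. zero-rescue rule: exactly one score is zero and the other is
##      strictly above `zero_rescue` (default 0.6).
## Both thresholds are strict, so ratio exactly 2 and score exactly 0.6
## are excluded.

#' Remove sites whose scores are zero in every sample
#'
#' @param table a `site_score_table` from [read_site_scores()].
#' @return the table with all-zero rows removed.
#' @export
drop_all_zero_sites <- function(table) {
  stopifnot(inherits(table, "site_score_table"))
  cols <- table$samples$column_name
  if (nrow(table$data) == 0) return(table)
  keep <- rowSums(as.matrix(table$data[, cols, with = FALSE]) != 0) > 0
  table$data <- table$data[keep]
  table
}

#' Aggregate per-sample scores to per-condition scores
#'
#' The `mean_by_condition` policy (default) takes the arithmetic mean of
#' the sample scores within each condition.
#'
#' @param table a `site_score_table`.
#' @param policy aggregation policy; only `mean_by_condition` produces a
#'   single aggregated pair per site (`per_pair_consensus` defers
#'   aggregation to [call_differential_sites()], but the per-condition
#'   means returned here are still used as the reported scores).
#' @return data.table: chrom, pos0, tumor_score, normal_score.
#' @export
aggregate_scores <- function(table,
                             policy = c("mean_by_condition", "per_pair_consensus")) {
  stopifnot(inherits(table, "site_score_table"))
  policy <- match.arg(policy)
  tcols <- table$samples[condition == "tumor", column_name]
  ncols <- table$samples[condition == "normal", column_name]
  if (length(tcols) == 0 || length(ncols) == 0)
    abort_config("aggregation requires >=1 sample in each condition")
  d <- table$data
  data.table(chrom = d$chrom, pos0 = d$pos0,
             tumor_score = rowMeans(d[, tcols, with = FALSE]),
             normal_score = rowMeans(d[, ncols, with = FALSE]))
}

#' Apply the calling rules to one (or a vector of) aggregated score pairs
#'
#' @param tumor_score,normal_score numeric vectors in \[0,1\].
#' @param fold fold-change threshold (strict, default 2).
#' @param zero_rescue zero-rescue score threshold (strict, default 0.6).
#' @return data.table with `direction` (`up`, `down`, `none`) and `rule`
#'   (`fold_change` when both scores are positive, `zero_rescue` when
#'   exactly one is zero, `NA` when both are zero).
#' @export
call_site <- function(tumor_score, normal_score, fold = 2, zero_rescue = 0.6) {
  t <- as.numeric(tumor_score); n <- as.numeric(normal_score)
  if (length(t) != length(n)) abort_data("score vectors differ in length")
  if (any(is.na(t) | is.na(n) | t < 0 | t > 1 | n < 0 | n > 1))
    abort_data("scores must lie in [0,1]")
  direction <- rep("none", length(t))
  rule <- rep(NA_character_, length(t))
  both <- t > 0 & n > 0
  rule[both] <- "fold_change"
  direction[both & t / n > fold] <- "up"
  direction[both & n / t > fold] <- "down"
  one <- xor(t == 0, n == 0)
  rule[one] <- "zero_rescue"
  direction[one & n == 0 & t > zero_rescue] <- "up"
  direction[one & t == 0 & n > zero_rescue] <- "down"
  data.table(direction = direction, rule = rule)
}

#' Call differential methylation sites for one mark
#'
#' Applies [drop_all_zero_sites()] (idempotent if already applied), then
#' calls each site. Under `mean_by_condition` the rules are applied to
#' the per-condition mean scores. Under `per_pair_consensus` the rules
#' are applied separately within each tumor/normal pair and a site is
#' reported only when every pair calls the same non-`none` direction;
#' the reported scores are still the per-condition means.
#'
#' @param table a `site_score_table`.
#' @param policy `"mean_by_condition"` (default) or `"per_pair_consensus"`.
#' @param fold,zero_rescue thresholds, see [call_site()].
#' @return data.table: chrom, pos0, mark, direction, tumor_score,
#'   normal_score, rule; sorted by (natural chromosome order, pos0).
#' @export
call_differential_sites <- function(table,
                                    policy = c("mean_by_condition",
                                               "per_pair_consensus"),
                                    fold = 2, zero_rescue = 0.6) {
  stopifnot(inherits(table, "site_score_table"))
  policy <- match.arg(policy)
  if (fold <= 0 || zero_rescue <= 0)
    abort_config("thresholds must be positive")
  table <- drop_all_zero_sites(table)
  agg <- aggregate_scores(table, "mean_by_condition")
  empty <- data.table(chrom = character(), pos0 = integer(),
                      mark = character(), direction = character(),
                      tumor_score = numeric(), normal_score = numeric(),
                      rule = character())
  if (nrow(agg) == 0) return(empty)

  if (policy == "mean_by_condition") {
    call <- call_site(agg$tumor_score, agg$normal_score, fold, zero_rescue)
    keep <- call$direction != "none"
    out <- data.table(chrom = agg$chrom[keep], pos0 = agg$pos0[keep],
                      mark = table$mark, direction = call$direction[keep],
                      tumor_score = agg$tumor_score[keep],
                      normal_score = agg$normal_score[keep],
                      rule = call$rule[keep])
  } else {
    pairs <- unique(table$samples$pair_id)
    dirs <- matrix("none", nrow(agg), length(pairs))
    for (j in seq_along(pairs)) {
      tc <- table$samples[pair_id == pairs[j] & condition == "tumor", column_name]
      nc <- table$samples[pair_id == pairs[j] & condition == "normal", column_name]
      if (length(tc) == 0 || length(nc) == 0)
        abort_config("pair %s lacks a tumor or normal sample", pairs[j])
      ts <- rowMeans(table$data[, tc, with = FALSE])
      ns <- rowMeans(table$data[, nc, with = FALSE])
      dirs[, j] <- call_site(ts, ns, fold, zero_rescue)$direction
    }
    consensus <- dirs[, 1]
    agree <- rowSums(dirs == consensus) == length(pairs) & consensus != "none"
    ## rule of the consensus call derived from the aggregated scores
    call <- call_site(agg$tumor_score, agg$normal_score, fold, zero_rescue)
    out <- data.table(chrom = agg$chrom[agree], pos0 = agg$pos0[agree],
                      mark = table$mark, direction = consensus[agree],
                      tumor_score = agg$tumor_score[agree],
                      normal_score = agg$normal_score[agree],
                      rule = call$rule[agree])
  }
  if (nrow(out) == 0) return(empty)
  out <- out[chrom_order(chrom, pos0)]
  message(sprintf("call_differential_sites[%s]: %d up, %d down of %d sites",
                  table$mark, sum(out$direction == "up"),
                  sum(out$direction == "down"), nrow(agg)))
  out[]
}
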
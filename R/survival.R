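## Kaplan-Meier product-limit estimation, the two-group log-rank test,
## and the median-split screen that selects survival-associated genes and
## tumor-suppressor candidates among them.

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' times with only censoring reduce the risk set but leave S unchanged.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (1 = event).
#' @return data.table: time (distinct observed times, ascending), n_risk,
#'   n_event, n_censor, surv.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort_data("empty survival input")
  if (length(times) != length(events)) abort_data("times/events length mismatch")
  if (any(times <= 0)) abort_data("times must be positive")
  if (!all(events %in% c(0, 1))) abort_data("events must be 0/1")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.table(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

## S(t) from a km_estimate table by right-continuous step lookup
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' Statistic `(O_A - E_A)^2 / V` with the hypergeometric variance summed
#' over distinct pooled event times; p-value from chi-square with 1 df.
#'
#' @param timeA,eventA follow-up and 0/1 event indicator for group A.
#' @param timeB,eventB same for group B.
#' @return list with `statistic`, `p_value`, `observed` (c(A, B)) and
#'   `expected` (c(A, B)).
#' @export
logrank_test <- function(timeA, eventA, timeB, eventB) {
  if (length(timeA) == 0 || length(timeB) == 0)
    abort_data("both groups must be non-empty")
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grpA <- rep(c(TRUE, FALSE), c(length(timeA), length(timeB)))
  if (sum(event) == 0) abort_degenerate("no events: log-rank undefined")
  o <- order(time)
  tt <- time[o]; ee <- event[o]; gA <- grpA[o]
  ut <- unique(tt)
  first <- match(ut, tt)
  n_at <- length(tt) - first + 1                   # at risk (time >= t)
  nA_at <- rev(cumsum(rev(gA)))[first]             # group-A at risk
  d <- rowsum(ee, tt)[, 1]                         # events at t (time-sorted)
  dA <- rowsum(as.numeric(ee & gA), tt)[, 1]
  keep <- d > 0
  n <- n_at[keep]; nA <- nA_at[keep]; d <- d[keep]; dA <- dA[keep]
  OA <- sum(dA)
  EA <- sum(d * nA / n)
  V <- sum(ifelse(n > 1, d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1), 0))
  if (V == 0) abort_degenerate("zero log-rank variance")
  stat <- (OA - EA)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE),
       observed = c(A = OA, B = sum(event) - OA),
       expected = c(A = EA, B = sum(event) - EA))
}

#' Median-split survival screen over a gene list
#'
#' For each gene, patients are split at the median expression (ties go to
#' the low group), the two groups are compared with the log-rank test,
#' and the risk direction is read off the KM curves at the largest time
#' observed in both groups. Genes with a degenerate split (constant
#' expression, or an empty group) are reported with `error` set and do
#' not affect the others.
#'
#' @param survival a `survival_dataset` from [read_survival()].
#' @param gene_list character vector of genes to screen; all must be
#'   present in the dataset.
#' @param alpha selection threshold (strict, default 0.05).
#' @return data.table: gene_id, median_expr, n_low, n_high, statistic,
#'   p_value, direction_of_risk, selected, error.
#' @export
screen_genes <- function(survival, gene_list, alpha = 0.05) {
  stopifnot(inherits(survival, "survival_dataset"))
  missing <- setdiff(gene_list, rownames(survival$expression))
  if (length(missing))
    abort_data("gene(s) absent from survival table: %s",
               paste(head(missing, 5), collapse = ", "))
  cl <- survival$clinical
  rows <- lapply(gene_list, function(gene) {
    expr <- survival$expression[gene, ]
    med <- median(expr)
    low <- expr <= med             # ties -> low group
    base <- data.table(gene_id = gene, median_expr = med,
                       n_low = sum(low), n_high = sum(!low),
                       statistic = NA_real_, p_value = NA_real_,
                       direction_of_risk = "none", selected = FALSE,
                       error = NA_character_)
    res <- tryCatch({
      if (all(low) || !any(low))
        abort_degenerate("degenerate median split for gene %s", gene)
      lr <- logrank_test(cl$time[low], cl$event[low],
                         cl$time[!low], cl$event[!low])
      km_lo <- km_estimate(cl$time[low], cl$event[low])
      km_hi <- km_estimate(cl$time[!low], cl$event[!low])
      tstar <- min(max(cl$time[low]), max(cl$time[!low]))
      s_lo <- km_surv_at(km_lo, tstar)
      s_hi <- km_surv_at(km_hi, tstar)
      base$statistic <- lr$statistic
      base$p_value <- lr$p_value
      base$direction_of_risk <-
        if (s_lo < s_hi) "low_expression_worse"
        else if (s_hi < s_lo) "high_expression_worse" else "none"
      base$selected <- lr$p_value < alpha
      base
    }, methinstab_error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
    res
  })
  rbindlist(rows)[]
}

#' Select tumor-suppressor candidates
#'
#' A candidate is a screened gene that is (1) selected (log-rank p below
#' alpha), (2) down-regulated in tumor expression, and (3) has worse
#' survival in its low-expression group.
#'
#' @param screen_results data.table from [screen_genes()].
#' @param de_results data.table from [call_de_genes()].
#' @return character vector of candidate gene ids (sorted).
#' @export
select_tsg_candidates <- function(screen_results, de_results) {
  s <- as.data.table(screen_results)
  de <- as.data.table(de_results)
  m <- merge(s, de[, .(gene_id, de_direction)], by = "gene_id")
  sort(m[selected == TRUE & de_direction == "down" &
         direction_of_risk == "low_expression_worse", gene_id])
}
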
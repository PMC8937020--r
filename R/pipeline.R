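## One reproducible run: call-sites -> map-genes -> classify -> associate
## -> screen, with a machine-readable JSON report as the single source of
## truth for downstream checks.

pipeline_defaults <- function() {
  list(genes = NULL, sites_5mC = NULL, sites_6mA = NULL, sample_sheet = NULL,
       counts = NULL, survival = NULL, outdir = NULL,
       fold = 2.0, zero_rescue = 0.6, policy = "mean_by_condition",
       flank = 0, de_fold = 2.0, pseudocount = 0.01,
       universe = "annotated_genes", alpha = 0.05, top_n = 100,
       rank_key = "total", yates = FALSE, seed = NULL)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON file path or a plain list; fills defaults, checks
#' types, and rejects unknown keys.
#'
#' @param config path to a JSON configuration or a named list.
#' @return normalized `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_config("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort_config("configuration must be a list or JSON file")
  def <- pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    abort_config("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  for (f in c("fold", "zero_rescue", "de_fold", "alpha", "pseudocount")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      abort_config("'%s' must be a positive number", f)
  }
  if (!is_count(cfg$top_n)) abort_config("'top_n' must be a count >= 1")
  if (!is.numeric(cfg$flank) || cfg$flank < 0) abort_config("'flank' must be >= 0")
  if (!cfg$policy %in% c("mean_by_condition", "per_pair_consensus"))
    abort_config("unknown aggregation policy '%s'", cfg$policy)
  if (!cfg$universe %in% c("annotated_genes", "genes_with_any_signal"))
    abort_config("unknown universe '%s'", cfg$universe)
  if (!cfg$rank_key %in% c("total", "5mC", "6mA", "max_mark"))
    abort_config("unknown rank_key '%s'", cfg$rank_key)
  if (!is.logical(cfg$yates) || length(cfg$yates) != 1L)
    abort_config("'yates' must be TRUE/FALSE")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes site calling (both marks), gene mapping, instability
#' classification, expression association and the survival screen, writes
#' every stage output plus `report.json` into `config$outdir`, and
#' returns the report. Deterministic: rerunning with the same inputs
#' yields an identical report up to the `timestamp` field. On error,
#' stage outputs already written are renamed with a `.partial` suffix.
#'
#' @param config a [validate_config()] result, a list, or a JSON path.
#' @return the run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  for (f in c("genes", "sites_5mC", "sites_6mA", "sample_sheet", "counts",
              "outdir")) {
    if (is.null(cfg[[f]])) abort_config("pipeline requires '%s'", f)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(f) file.path(cfg$outdir, f)
  emit <- function(obj, f) {
    fwrite(obj, out(f), sep = "\t")
    written <<- c(written, out(f))
  }
  stage <- "setup"
  report <- list(tool = "methinstab",
                 version = as.character(utils::packageVersion("methinstab")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = unclass(cfg))
  log_stage <- function(s, fmt, ...) {
    stage <<- s
    message(sprintf("[%s] %s", s, sprintf(fmt, ...)))
  }
  tryCatch({
    log_stage("annotation", "reading %s", cfg$genes)
    ann <- read_gene_annotation(cfg$genes)

    diffs <- list()
    for (mark in c("5mC", "6mA")) {
      log_stage(paste0("call-sites:", mark), "reading %s",
                cfg[[paste0("sites_", mark)]])
      tab <- read_site_scores(cfg[[paste0("sites_", mark)]], mark,
                              cfg$sample_sheet)
      n_in <- nrow(tab$data)
      tab <- drop_all_zero_sites(tab)
      d <- call_differential_sites(tab, cfg$policy, cfg$fold, cfg$zero_rescue)
      diffs[[mark]] <- d
      emit(d, sprintf("diff_%s.tsv", mark))
      report$sites[[mark]] <- list(n_input = n_in,
                                   n_after_drop_zero = nrow(tab$data),
                                   n_dropped_all_zero = n_in - nrow(tab$data),
                                   n_up = sum(d$direction == "up"),
                                   n_down = sum(d$direction == "down"))
    }

    log_stage("map-genes", "building per-gene profiles")
    prof <- build_profiles(diffs[["5mC"]], diffs[["6mA"]], ann, cfg$flank)
    emit(prof, "profiles.tsv")
    report$profiles <- list(n_genes_profiled = nrow(prof))

    log_stage("classify", "classifying %d profiled genes", nrow(prof))
    labels <- classify_genes(prof)
    emit(labels, "labels.tsv")
    unstable_genes <- labels[unstable == TRUE, gene_id]
    report$classes <- list(
      n_unstable = length(unstable_genes),
      venn = as.list(venn_counts(labels)))
    report$biotype <- if (length(unstable_genes))
      biotype_composition(unstable_genes, ann) else NULL
    for (mark in c("5mC", "6mA")) {
      report$correlation[[mark]] <- tryCatch(
        updown_correlation(prof, mark),
        methinstab_degenerate_error = function(e)
          list(r = NA_real_, n = NA_integer_, error = conditionMessage(e)))
    }
    top <- rank_unstable_genes(prof, labels, cfg$top_n, cfg$rank_key)
    report$top_unstable <- as.list(top)
    writeLines(top, out("top_unstable.txt"))
    written <- c(written, out("top_unstable.txt"))

    log_stage("associate", "reading %s", cfg$counts)
    counts <- read_counts(cfg$counts)
    rpkm <- compute_rpkm(counts)
    sheet <- read_sample_sheet(cfg$sample_sheet)
    de <- call_de_genes(rpkm, sheet, cfg$de_fold, cfg$pseudocount)
    emit(de, "de.tsv")
    report$expression <- list(n_genes = nrow(de), n_de = sum(de$de),
                              n_de_up = sum(de$de_direction == "up"),
                              n_de_down = sum(de$de_direction == "down"))
    report$association <- association_report(labels, de, cfg$universe,
                                             annotation = ann,
                                             correct = cfg$yates)

    if (!is.null(cfg$survival)) {
      log_stage("screen", "reading %s", cfg$survival)
      surv <- read_survival(cfg$survival)
      screenable <- intersect(top, rownames(surv$expression))
      report$screen_missing <- setdiff(top, screenable)
      if (length(report$screen_missing))
        message(sprintf("[screen] %d top gene(s) absent from survival table",
                        length(report$screen_missing)))
      if (length(screenable)) {
        sc <- screen_genes(surv, screenable, cfg$alpha)
        emit(sc, "screen.tsv")
        tsg <- select_tsg_candidates(sc, de)
        report$screen <- list(
          n_screened = nrow(sc),
          n_selected = sum(sc$selected),
          selected = as.list(sc[selected == TRUE, gene_id]),
          tsg_candidates = as.list(tsg))
      } else {
        report$screen <- list(n_screened = 0L, n_selected = 0L,
                              selected = list(), tsg_candidates = list())
      }
    }

    log_stage("report", "writing %s", out("report.json"))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    invisible(report)
  }, methinstab_error = function(e) {
    for (f in written)
      if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    e$message <- sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e))
    stop(e)
  })
}
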
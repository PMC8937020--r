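## Readers and writers for every format the pipeline touches. All internal
## coordinates are 0-based half-open (BED convention); conversion from
## 1-based closed GFF3 happens here and nowhere else.

#' Read a per-site methylation score table
#'
#' Expects a TSV with header `chrom  pos0  mark  <sample columns...>` (the
#' `mark` column is optional; when present it must match `mark`). Sample
#' columns are mapped to (pair, condition) through the sample sheet.
#'
#' @param path TSV file.
#' @param mark `"5mC"` or `"6mA"`.
#' @param sample_sheet data.frame with columns `column_name`, `pair_id`,
#'   `condition` (`tumor`/`normal`), or the path of such a TSV.
#' @return a `site_score_table`: list with `mark`, `data` (data.table
#'   chrom, pos0, one numeric score column per sample) and `samples`
#'   (the sample sheet restricted to present columns).
#' @export
read_site_scores <- function(path, mark = c("5mC", "6mA"), sample_sheet) {
  mark <- match.arg(mark)
  if (!file.exists(path)) abort_data("site score file not found: %s", path)
  sheet <- read_sample_sheet(sample_sheet)
  dt <- fread(path, sep = "\t", header = TRUE)
  if (nrow(dt) == 0) {
    warning(sprintf("empty site table (header only): %s", path))
    score_cols <- intersect(names(dt), sheet$column_name)
    return(new_site_table(mark,
                          dt[, c("chrom", "pos0", score_cols), with = FALSE],
                          sheet[sheet$column_name %in% score_cols, ]))
  }
  if (!all(c("chrom", "pos0") %in% names(dt)))
    abort_data("site table %s lacks 'chrom'/'pos0' columns", path)
  if ("mark" %in% names(dt)) {
    if (!all(dt$mark == mark))
      abort_data("file %s contains marks other than %s", path, mark)
    dt[, mark := NULL]
  }
  score_cols <- setdiff(names(dt), c("chrom", "pos0"))
  unmapped <- setdiff(score_cols, sheet$column_name)
  if (length(unmapped))
    abort_config("sample column(s) not in sample sheet: %s",
                 paste(unmapped, collapse = ", "))
  for (cn in score_cols) {
    v <- dt[[cn]]
    if (!is.numeric(v)) abort_data("non-numeric scores in column '%s'", cn)
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad))
      abort_data("score outside [0,1] in column '%s', line %d of %s",
                 cn, bad[1] + 1L, path)   # +1 for the header line
  }
  dup <- which(duplicated(dt, by = c("chrom", "pos0")))
  if (length(dup))
    abort_data("duplicate (chrom,pos0) at line %d of %s", dup[1] + 1L, path)
  sheet <- sheet[sheet$column_name %in% score_cols, ]
  new_site_table(mark, dt, sheet)
}

new_site_table <- function(mark, data, samples) {
  samples <- as.data.table(samples)
  if (!all(samples$condition %in% c("tumor", "normal")))
    abort_config("sample sheet conditions must be 'tumor' or 'normal'")
  if (nrow(samples) > 0 &&
      (!any(samples$condition == "tumor") || !any(samples$condition == "normal")))
    abort_config("need at least one tumor and one normal sample")
  structure(list(mark = mark, data = as.data.table(data), samples = samples),
            class = "site_score_table")
}

#' @export
print.site_score_table <- function(x, ...) {
  cat(sprintf("<site_score_table> mark=%s, %d sites, %d samples (%d tumor / %d normal)\n",
              x$mark, nrow(x$data), nrow(x$samples),
              sum(x$samples$condition == "tumor"),
              sum(x$samples$condition == "normal")))
  invisible(x)
}

read_sample_sheet <- function(sheet) {
  if (is.character(sheet) && length(sheet) == 1L) {
    if (!file.exists(sheet)) abort_data("sample sheet not found: %s", sheet)
    sheet <- fread(sheet, sep = "\t", header = TRUE)
  }
  sheet <- as.data.table(sheet)
  need <- c("column_name", "pair_id", "condition")
  if (!all(need %in% names(sheet)))
    abort_config("sample sheet must have columns: %s", paste(need, collapse = ", "))
  sheet[, (need) := lapply(.SD, as.character), .SDcols = need]
  sheet
}

#' Read a gene annotation (BED6+biotype or GFF3)
#'
#' The dialect is chosen from the file extension: `.bed` expects BED6
#' with the biotype in column 7; `.gff`/`.gff3` expects GFF3 from which
#' `gene` features are taken, with the biotype read from the
#' `gene_biotype`/`biotype` attribute and the gene id from `gene_id`/`ID`.
#' GFF3 1-based closed coordinates are converted to 0-based half-open.
#'
#' @param path annotation file.
#' @return data.table: gene_id, chrom, start, end, strand, biotype.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) abort_data("annotation file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  ann <- if (ext %in% c("gff", "gff3")) read_gff3_genes(path) else read_bed_genes(path)
  if (any(ann$start >= ann$end))
    abort_data("annotation %s: start >= end for gene %s", path,
               ann$gene_id[which(ann$start >= ann$end)[1]])
  if (anyDuplicated(ann$gene_id))
    abort_data("annotation %s: duplicate gene_id %s", path,
               ann$gene_id[duplicated(ann$gene_id)][1])
  ann[chrom_order(chrom, start)]
}

read_bed_genes <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 7)
    abort_data("BED annotation %s needs 7 columns (BED6 + biotype), got %d",
               path, ncol(dt))
  out <- dt[, .(gene_id = as.character(V4), chrom = as.character(V1),
                start = as.integer(V2), end = as.integer(V3),
                strand = as.character(V6), biotype = as.character(V7))]
  if (any(is.na(out$start) | is.na(out$end)))
    abort_data("BED annotation %s: non-integer coordinates", path)
  out
}

read_gff3_genes <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE, skip = "#",
              col.names = c("seqid", "source", "type", "start", "end",
                            "score", "strand", "phase", "attributes"))
  dt <- dt[type == "gene"]
  if (nrow(dt) == 0) abort_data("GFF3 %s contains no gene features", path)
  attr_get1 <- function(attrs, key) {
    m <- regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs)
    vapply(regmatches(attrs, m),
           function(g) if (length(g) >= 2) g[2] else NA_character_,
           character(1))
  }
  attr_get <- function(attrs, keys) {
    for (k in keys) {
      v <- attr_get1(attrs, k)
      if (any(!is.na(v))) return(v)
    }
    rep(NA_character_, length(attrs))
  }
  gid <- attr_get(dt$attributes, c("gene_id", "ID"))
  bio <- attr_get(dt$attributes, c("gene_biotype", "biotype"))
  if (any(is.na(bio)))
    abort_data("GFF3 %s: missing biotype attribute on gene feature", path)
  if (any(is.na(gid)))
    abort_data("GFF3 %s: missing gene_id/ID attribute", path)
  data.table(gene_id = gid, chrom = as.character(dt$seqid),
             start = as.integer(dt$start) - 1L,   # 1-based closed -> 0-based half-open
             end = as.integer(dt$end),
             strand = as.character(dt$strand), biotype = bio)
}

#' Write called differential sites as a BED-like TSV
#'
#' Columns: chrom, pos0, end (= pos0 + 1), mark, direction, tumor_score,
#' normal_score, rule; rows sorted by (natural chromosome order, pos0,
#' mark).
#'
#' @param sites data.table as returned by [call_differential_sites()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_differential_sites <- function(sites, path) {
  sites <- as.data.table(sites)
  out <- data.table(chrom = sites$chrom, pos0 = sites$pos0,
                    end = sites$pos0 + 1L, mark = sites$mark,
                    direction = sites$direction,
                    tumor_score = sites$tumor_score,
                    normal_score = sites$normal_score, rule = sites$rule)
  out <- out[chrom_order(chrom, pos0, mark)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read back a differential-site TSV written by [write_differential_sites()]
#' @param path TSV file.
#' @return data.table: chrom, pos0, mark, direction, tumor_score,
#'   normal_score, rule.
#' @export
read_differential_sites <- function(path) {
  if (!file.exists(path)) abort_data("differential site file not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos0", "mark", "direction", "tumor_score",
            "normal_score", "rule")
  if (!all(need %in% names(dt)))
    abort_data("%s is not a differential-site table", path)
  dt[, need, with = FALSE]
}

#' Read a gene-level count table (featureCounts-like)
#' @param path TSV with columns gene_id, length_bp, then one count column
#'   per sample.
#' @return data.table.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort_data("count table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "length_bp") %in% names(dt)))
    abort_data("%s must have gene_id and length_bp columns", path)
  if (any(dt$length_bp <= 0)) abort_data("non-positive gene length in %s", path)
  dt
}

#' Read a survival table
#'
#' @param path TSV with columns sample_id, time_days, event, then one
#'   expression column per gene.
#' @return a `survival_dataset`: list with `clinical` (data.table
#'   sample_id, time, event) and `expression` (genes x patients matrix).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort_data("survival table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(dt)))
    abort_data("%s must have columns %s", path, paste(need, collapse = ", "))
  if (any(dt$time_days <= 0)) abort_data("non-positive follow-up time in %s", path)
  if (!all(dt$event %in% c(0L, 1L))) abort_data("event must be 0/1 in %s", path)
  genes <- setdiff(names(dt), need)
  expr <- t(as.matrix(dt[, genes, with = FALSE]))
  colnames(expr) <- dt$sample_id
  new_survival_dataset(dt[, .(sample_id, time = time_days, event)], expr)
}

new_survival_dataset <- function(clinical, expression) {
  structure(list(clinical = as.data.table(clinical), expression = expression),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> %d patients (%d events), %d genes\n",
              nrow(x$clinical), sum(x$clinical$event), nrow(x$expression)))
  invisible(x)
}
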
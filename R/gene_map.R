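## Gene-body interval assignment with bedtools-intersect semantics: a
## 1-bp site [pos0, pos0+1) is assigned to every gene whose (optionally
## flanked) body overlaps it by >= 1 bp; strand is ignored; sites hitting
## several overlapping genes count once per gene.

#' Assign differential sites to overlapping genes
#'
#' @param sites data.table with columns chrom, pos0 (1-bp intervals).
#' @param genes annotation data.table (gene_id, chrom, start, end, ...),
#'   0-based half-open.
#' @param flank bp added on both sides of each gene body (default 0, the
#'   plain gene-body analysis; > 0 allows a promoter-inclusive rerun).
#' @return data.table: site_idx (row index into `sites`), gene_id. Sites
#'   in no gene are absent. A chromosome present in `sites` but missing
#'   from the annotation triggers a warning; its sites are intergenic.
#' @export
assign_sites_to_genes <- function(sites, genes, flank = 0) {
  sites <- as.data.table(sites)
  genes <- as.data.table(genes)
  if (flank < 0) abort_config("'flank' must be >= 0")
  empty <- data.table(site_idx = integer(), gene_id = character())
  if (nrow(sites) == 0 || nrow(genes) == 0) return(empty)
  missing_chrom <- setdiff(unique(sites$chrom), unique(genes$chrom))
  if (length(missing_chrom))
    warning(sprintf("chromosome(s) absent from annotation, sites treated as intergenic: %s",
                    paste(missing_chrom, collapse = ", ")))
  out <- vector("list", 0L)
  for (ch in intersect(unique(sites$chrom), unique(genes$chrom))) {
    si <- which(sites$chrom == ch)
    gi <- which(genes$chrom == ch)
    ## half-open [start, end) as closed integer ranges [start, end-1]
    q <- IRanges::IRanges(start = sites$pos0[si], width = 1L)
    s <- IRanges::IRanges(start = genes$start[gi] - flank,
                          end = genes$end[gi] - 1L + flank)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits))
      out[[ch]] <- data.table(site_idx = si[S4Vectors::queryHits(hits)],
                              gene_id = genes$gene_id[gi[S4Vectors::subjectHits(hits)]])
  }
  if (length(out) == 0) return(empty)
  res <- rbindlist(out)
  setorder(res, site_idx, gene_id)
  res[]
}

#' Build per-gene methylation instability profiles
#'
#' Tallies assigned differential sites by mark and direction. A site
#' overlapping k genes contributes to all k profiles. Genes with no
#' assigned site are absent from the result.
#'
#' @param diff_5mC,diff_6mA differential-site tables (either may be
#'   empty) as returned by [call_differential_sites()].
#' @param genes annotation data.table.
#' @param flank passed to [assign_sites_to_genes()].
#' @return data.table: gene_id, biotype, n_up_5mC, n_down_5mC, n_up_6mA,
#'   n_down_6mA, total.
#' @export
build_profiles <- function(diff_5mC, diff_6mA, genes, flank = 0) {
  genes <- as.data.table(genes)
  tally <- function(sites, mark) {
    if (is.null(sites) || nrow(sites) == 0)
      return(data.table(gene_id = character(), direction = character(),
                        mark = character()))
    a <- assign_sites_to_genes(sites, genes, flank)
    if (nrow(a) == 0)
      return(data.table(gene_id = character(), direction = character(),
                        mark = character()))
    data.table(gene_id = a$gene_id,
               direction = sites$direction[a$site_idx], mark = mark)
  }
  long <- rbind(tally(as.data.table(diff_5mC), "5mC"),
                tally(as.data.table(diff_6mA), "6mA"))
  prof <- data.table(gene_id = character(), n_up_5mC = integer(),
                     n_down_5mC = integer(), n_up_6mA = integer(),
                     n_down_6mA = integer())
  if (nrow(long) > 0) {
    cnt <- long[, .N, by = .(gene_id, mark, direction)]
    wide <- dcast(cnt, gene_id ~ mark + direction, value.var = "N", fill = 0L)
    for (cn in c("5mC_up", "5mC_down", "6mA_up", "6mA_down"))
      if (!cn %in% names(wide)) wide[[cn]] <- 0L
    prof <- wide[, .(gene_id,
                     n_up_5mC = `5mC_up`, n_down_5mC = `5mC_down`,
                     n_up_6mA = `6mA_up`, n_down_6mA = `6mA_down`)]
  }
  prof[, total := n_up_5mC + n_down_5mC + n_up_6mA + n_down_6mA]
  prof <- merge(prof, genes[, .(gene_id, biotype)], by = "gene_id",
                all.x = TRUE, sort = FALSE)
  setcolorder(prof, c("gene_id", "biotype", "n_up_5mC", "n_down_5mC",
                      "n_up_6mA", "n_down_6mA", "total"))
  setorder(prof, gene_id)
  prof[]
}
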
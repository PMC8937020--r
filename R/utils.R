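#' Natural chromosome ordering rank
#'
#' Ranks chromosome names in the human "natural" order chr1..chr22, chrX,
#' chrY, chrM. Names that do not parse are placed after all recognised
#' chromosomes, ordered alphabetically among themselves.
#'
#' @param chrom character vector of chromosome names (with or without a
#'   `chr` prefix).
#' @return numeric rank usable as a sort key (ties broken by name).
#' @export
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.integer(core))
  rk <- ifelse(!is.na(num), num,
        ifelse(core == "X", 23L,
        ifelse(core == "Y", 24L,
        ifelse(core %in% c("M", "MT"), 25L, NA_integer_))))
  ifelse(is.na(rk), Inf, rk)
}

## order() permutation for (chrom natural, then extra keys)
chrom_order <- function(chrom, ...) {
  order(chrom_rank(chrom), chrom, ...)
}

## Deterministic per-stage sub-seed so each generator stage is
## individually reproducible. Kept well below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(annotation = 1L, truth = 2L, methylome = 3L,
               expression = 4L, survival = 5L, generic = 6L)
  off <- offsets[[stage]]
  (as.integer(seed) %% 65011703L) * 31L + off
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

`%||%` <- function(a, b) if (is.null(a)) b else a
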
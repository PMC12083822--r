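#' @importFrom stats cor cor.test median prcomp pnorm pt p.adjust quantile
#'   rnorm rnbinom runif sd setNames t.test var aggregate as.dist cutree
#'   hclust kmeans lm coef resid
#' @importFrom utils head tail read.csv read.delim write.csv write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## key for a (cell line, compound) grid cell
cell_key <- function(cell_line, compound) paste(cell_line, compound, sep = "|")

## key identifying a genomic interval in BED (0-based half-open) coordinates
peak_key <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

## strip a leading "chr" so "chr1" and "1" compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x))

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## four-parameter logistic evaluated at dose d (molar)
fourpl <- function(d, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}
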
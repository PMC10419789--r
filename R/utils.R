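## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats dhyper pbinom phyper p.adjust rbeta rbinom rnorm rpois
#'   cor.test runif setNames
#' @importFrom utils read.table write.table
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

## Derive a reproducible sub-seed (< 2^31) from a user seed and a stream tag,
## so independent simulation stages draw from independent streams.
sub_seed <- function(seed, tag) {
  (as.numeric(seed) * 48271 + 7907 * as.numeric(tag)) %% 2147483629 + 1
}

## complement of A/C/G/T/N character vectors
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## key for (chrom, pos, strand) site identity
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = "\r")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Tiling bins [0, bin), [bin, 2 bin), ... covering a chromosome; the last
## (possibly partial) bin is kept.
tile_bins <- function(chrom_len, bin_size) {
  if (bin_size <= 0) stopf("bin_size must be positive, got %s", bin_size)
  starts <- seq.int(0L, max(0L, chrom_len - 1L), by = bin_size)
  ends <- pmin(starts + bin_size, chrom_len)
  data.frame(start = starts, end = ends,
             partial = ends - starts < bin_size)
}

## data.frame of regions -> GRanges (0-based half-open -> 1-based closed)
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = ifelse(regions$strand %in% c("+", "-"), regions$strand, "*")
  )
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
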
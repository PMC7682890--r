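#' Parse a genomic region string
#'
#' Regions are written `"chrom:start-end"` with 1-based inclusive
#' coordinates, e.g. `"III:4664-597553"`. Commas in the numbers are
#' tolerated.
#'
#' @param region character scalar.
#' @return list with elements `chrom`, `start`, `end` (numeric, 1-based).
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) {
    stop("malformed region string (expected 'chrom:start-end'): ", region)
  }
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (end < start) stop("region end < start: ", region)
  list(chrom = m[2], start = start, end = end)
}

#' Length of a 1-based inclusive genomic interval
#'
#' Both endpoints count, so `interval_length(x, x)` is 1 bp. The 111 bp
#' deletion in the CB4856 allele of *sqst-5* spans chrIII:147,076-147,186,
#' i.e. `interval_length(147076, 147186) == 111`.
#'
#' @param start,end 1-based coordinates with `end >= start`.
#' @return interval length in bp.
#' @export
interval_length <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (any(end < start)) stop("end < start")
  end - start + 1
}

# clamp x into [lo, hi]
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a reproducible child seed from a root seed; kept below 2^31 so the
# result is a valid R integer
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 10007) %% 2147483629)
}
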
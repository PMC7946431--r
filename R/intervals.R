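#' Genomic interval
#'
#' Lightweight 0-based half-open interval record. All coordinates inside the
#' package use this convention; 1-based inclusive formats (GTF) are converted
#' at the I/O boundary.
#'
#' @param contig Contig/chromosome name.
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `"gi"`.
#' @export
gi <- function(contig, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(is.character(contig), length(contig) == 1L)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be one of '+', '-', '.'")
  }
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "gi")
}

#' @exportS3Method base::format
format.gi <- function(x, ...) {
  sprintf("%s:%d-%d:%s", x$contig, x$start, x$end, x$strand)
}

#' @export
print.gi <- function(x, ...) {
  cat("<gi> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Interval width in nucleotides
#' @param x A [gi()] interval.
#' @return Integer width.
#' @export
gi_width <- function(x) x$end - x$start

# strand-aware comparison: returns negative when a is upstream of b in
# transcript orientation (coordinates, not intervals)
tx_cmp <- function(a, b, strand) {
  d <- a - b
  if (identical(strand, "-")) -d else d
}

# TRUE when intervals on the same contig share at least one base
gi_overlaps <- function(a, b) {
  a$contig == b$contig && a$start < b$end && b$start < a$end
}

# TRUE when inner lies fully within outer (same contig)
gi_within <- function(inner, outer) {
  inner$contig == outer$contig &&
    inner$start >= outer$start && inner$end <= outer$end
}
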
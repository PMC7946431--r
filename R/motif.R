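## UG-dinucleotide scoring of intronic windows (TDP-43's consensus binding
## motif) and overlap with CLIP peak intervals.

#' UG-richness score of a genomic window
#'
#' Scores the transcribed-strand sequence of the window (T read as U):
#' overlapping UG dinucleotide occurrences, their density over the
#' `length - 1` possible positions, and the longest perfect (UG)n run.
#'
#' @param genome `DNAStringSet`.
#' @param window A [gi()] interval; its strand is the transcribed strand.
#' @return List of class `"motif_score"`: `window`, `ug_count`,
#'   `ug_density`, `longest_ug_run`.
#' @export
ug_score <- function(genome, window) {
  if (gi_width(window) < 2L) stop("window shorter than 2 nt")
  s <- get_seq(genome, window)       # transcript orientation
  hits <- gregexpr("(?=TG)", s, perl = TRUE)[[1L]]
  ug_count <- if (hits[1L] == -1L) 0L else length(hits)
  runs <- regmatches(s, gregexpr("(TG)+", s))[[1L]]
  longest <- if (length(runs)) max(nchar(runs)) %/% 2L else 0L
  structure(list(window = window, ug_count = ug_count,
                 ug_density = ug_count / (nchar(s) - 1L),
                 longest_ug_run = as.integer(longest)),
            class = "motif_score")
}

#' Overlap of a window with CLIP peaks
#'
#' Peaks on the window's contig are merged (union) before summing the base
#' pair intersection with the window extended by `flank` on both sides, so
#' mutually overlapping peaks are not double counted.
#'
#' @param window A [gi()] interval.
#' @param peaks data.frame from [read_peaks_bed()].
#' @param flank Extension in nt on each side (default 0).
#' @return List with `overlap_bp` and `hit` (`overlap_bp > 0`).
#' @export
clip_overlap <- function(window, peaks, flank = 0L) {
  pk <- peaks[peaks$contig == window$contig, , drop = FALSE]
  if (!nrow(pk)) return(list(overlap_bp = 0L, hit = FALSE))
  merged <- IRanges::reduce(IRanges::IRanges(start = pk$start + 1L,
                                             end = pk$end))
  win <- IRanges::IRanges(start = max(0L, window$start - flank) + 1L,
                          end = window$end + flank)
  ov <- IRanges::intersect(merged, win)
  bp <- sum(IRanges::width(ov))
  list(overlap_bp = as.integer(bp), hit = bp > 0L)
}

#' Default motif-scoring window downstream of a cryptic donor
#'
#' The region 10-210 nt downstream of the donor in transcript orientation
#' (length 200 by default), where the UG-rich TDP-43-binding tract of a
#' repressed cryptic exon is expected to sit.
#'
#' @param contig Contig name.
#' @param donor Donor boundary coordinate (transcript orientation).
#' @param strand Transcribed strand.
#' @param offset Gap between donor and window start (default 10 nt).
#' @param width Window width (default 200 nt).
#' @return A [gi()] interval.
#' @export
motif_window <- function(contig, donor, strand, offset = 10L, width = 200L) {
  if (strand == "+") {
    gi(contig, donor + offset, donor + offset + width, strand)
  } else {
    gi(contig, donor - offset - width, donor - offset, strand)
  }
}
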
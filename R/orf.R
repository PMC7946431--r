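## Splicing exon chains into mature transcripts, ORF scanning, premature
## termination codon / NMD classification, and truncated-protein mass.

# standard genetic code, DNA alphabet; "*" = stop
GENETIC_CODE_TAB <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

# average (not monoisotopic) residue masses, Da; free protein adds one water
RESIDUE_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS_AVG <- 18.01528

#' Splice an exon chain into a mature transcript
#'
#' Concatenates the strand-correct sequences of an ordered exon chain and
#' records the exon-exon junction offsets in transcript coordinates.
#'
#' @param gene A [gene_model()] supplying strand, contig and (by default)
#'   the CDS genomic span.
#' @param chain data.frame of exon intervals (`start`, `end`, 0-based
#'   half-open) in transcript 5'->3' order.
#' @param genome `DNAStringSet`.
#' @param cds Genomic CDS span `c(start, end)`; defaults to the gene's
#'   annotated span. `NULL` leaves the CDS start unset.
#' @return Object of class `"mature_transcript"`: `seq`, `junctions`
#'   (transcript nt offsets, strictly increasing), `cds_start` (transcript
#'   offset of the first CDS base or `NA`), `chain`, `strand`.
#' @export
splice_transcript <- function(gene, chain, genome,
                              cds = gene_cds_span(gene)) {
  strand <- gene$strand
  stopifnot(nrow(chain) >= 1L, all(chain$start < chain$end))
  gen <- chain[order(chain$start), , drop = FALSE]
  if (nrow(gen) > 1L && any(gen$start[-1L] < gen$end[-nrow(gen)])) {
    stop("overlapping exons in chain")
  }
  expected <- order(chain$start)
  if (strand == "-") expected <- rev(expected)
  if (!identical(expected, seq_len(nrow(chain)))) {
    stop("chain is not in transcript 5'->3' order for strand ", strand)
  }
  seqs <- vapply(seq_len(nrow(chain)), function(k) {
    get_seq(genome, gi(gene$contig, chain$start[k], chain$end[k], strand))
  }, character(1L))
  widths <- chain$end - chain$start
  junctions <- if (nrow(chain) > 1L) cumsum(widths)[-nrow(chain)] else
    integer()
  cds_start <- NA_integer_
  if (!is.null(cds)) {
    # first CDS base in transcript orientation
    gpos <- if (strand == "+") cds[1L] else cds[2L] - 1L
    cds_start <- genome_to_transcript(chain, strand, gpos)
  }
  structure(list(seq = paste(seqs, collapse = ""),
                 junctions = as.integer(junctions),
                 cds_start = cds_start, chain = chain, strand = strand,
                 contig = gene$contig),
            class = "mature_transcript")
}

#' Map a genomic position to transcript coordinates
#'
#' @param chain Exon chain data.frame in transcript 5'->3' order.
#' @param strand `"+"` or `"-"`.
#' @param gpos 0-based genomic position of the base.
#' @return 0-based transcript offset, or `NA` if `gpos` is not exonic.
#' @export
genome_to_transcript <- function(chain, strand, gpos) {
  off <- 0L
  for (k in seq_len(nrow(chain))) {
    s <- chain$start[k]; e <- chain$end[k]
    if (gpos >= s && gpos < e) {
      within <- if (strand == "+") gpos - s else e - 1L - gpos
      return(off + within)
    }
    off <- off + (e - s)
  }
  NA_integer_
}

#' Map a transcript offset back to a genomic position
#' @param tx A `"mature_transcript"`.
#' @param offset 0-based transcript offset.
#' @return 0-based genomic position of that base.
#' @export
transcript_to_genome <- function(tx, offset) {
  chain <- tx$chain
  off <- offset
  for (k in seq_len(nrow(chain))) {
    w <- chain$end[k] - chain$start[k]
    if (off < w) {
      return(if (tx$strand == "+") chain$start[k] + off else
        chain$end[k] - 1L - off)
    }
    off <- off - w
  }
  stop("offset beyond transcript length")
}

#' Scan the open reading frame of a mature transcript
#'
#' Translates the standard genetic code from the CDS start and records the
#' first in-frame stop codon. Transcripts without an in-frame stop are
#' flagged non-stop.
#'
#' @param tx A `"mature_transcript"` with `cds_start` set (or use
#'   `use_first_atg = TRUE` to fall back to the first AUG).
#' @param use_first_atg Locate the CDS start at the first AUG when the
#'   annotation supplies none. Off by default: silent ORF misassignment is
#'   worse than an error.
#' @return Object of class `"orf_annotation"`: `stop_tx` (0-based offset of
#'   the stop codon's first base or `NA`), `non_stop`, `peptide`,
#'   `peptide_length`, `cds_start`; NMD fields are added by
#'   [classify_nmd()].
#' @export
scan_orf <- function(tx, use_first_atg = FALSE) {
  cds_start <- tx$cds_start
  if (is.na(cds_start) && use_first_atg) {
    hit <- regexpr("ATG", tx$seq, fixed = TRUE)
    if (hit > 0L) cds_start <- as.integer(hit) - 1L
  }
  if (is.na(cds_start)) stop("CDS start unknown; set cds or use_first_atg")
  n <- nchar(tx$seq)
  if (cds_start >= n) stop("CDS start beyond transcript end")
  codons_nt <- substring(tx$seq, seq(cds_start + 1L, n, by = 3L),
                         pmin(seq(cds_start + 3L, n + 2L, by = 3L), n))
  codons_nt <- codons_nt[nchar(codons_nt) == 3L]
  aa <- unname(GENETIC_CODE_TAB[codons_nt])
  aa[is.na(aa)] <- "X"
  stop_i <- which(aa == "*")
  if (length(stop_i)) {
    k <- stop_i[1L]
    peptide <- paste(aa[seq_len(k - 1L)], collapse = "")
    stop_tx <- cds_start + 3L * (k - 1L)
    non_stop <- FALSE
  } else {
    peptide <- paste(aa, collapse = "")
    stop_tx <- NA_integer_
    non_stop <- TRUE
  }
  structure(list(stop_tx = stop_tx, non_stop = non_stop, peptide = peptide,
                 peptide_length = nchar(peptide), cds_start = cds_start),
            class = "orf_annotation")
}

#' Classify premature termination and NMD susceptibility
#'
#' Applies the canonical 50-nt rule: a stop codon lying strictly more than
#' `rule_distance` nt upstream of the final exon-exon junction predicts
#' nonsense-mediated decay. The distance is measured from the end of the
#' stop codon to the junction. Single-exon transcripts are never NMD
#' substrates. A stop is premature (`is_ptc`) when its genomic position
#' lies strictly upstream, in transcript orientation, of the reference
#' (annotated-chain) stop.
#'
#' @param orf An `"orf_annotation"` from [scan_orf()].
#' @param tx The `"mature_transcript"` it was scanned from.
#' @param reference_stop_genomic Genomic position (0-based, first base) of
#'   the annotated stop codon, e.g. from scanning the reference chain;
#'   `NULL` leaves `is_ptc` as `NA`.
#' @param rule_distance NMD rule distance in nt (default 50; strict
#'   inequality triggers NMD).
#' @return The `orf` with fields `distance_to_last_junction`,
#'   `nmd_predicted` and `is_ptc` filled in.
#' @export
classify_nmd <- function(orf, tx, reference_stop_genomic = NULL,
                         rule_distance = 50L) {
  if (orf$non_stop) {
    orf$distance_to_last_junction <- NA_integer_
    orf$nmd_predicted <- FALSE
    orf$is_ptc <- NA
    return(orf)
  }
  if (!length(tx$junctions)) {
    message("single-exon transcript: no junction, NMD false by definition")
    orf$distance_to_last_junction <- NA_integer_
    orf$nmd_predicted <- FALSE
  } else {
    last_j <- max(tx$junctions)
    d <- last_j - (orf$stop_tx + 3L)
    orf$distance_to_last_junction <- as.integer(d)
    orf$nmd_predicted <- d > rule_distance
  }
  orf$is_ptc <- if (is.null(reference_stop_genomic)) NA else {
    gstop <- transcript_to_genome(tx, orf$stop_tx)
    tx_cmp(gstop, reference_stop_genomic, tx$strand) < 0
  }
  orf
}

#' Average-mass molecular weight of a peptide
#'
#' Sum of standard average residue masses plus one water (18.01528 Da);
#' unmodified chain, no glycosylation.
#'
#' @param peptide Character scalar over the 20 standard residues.
#' @param empty `"water"` (default) returns 18.01528 Da for the empty
#'   peptide; `"zero"` returns 0.
#' @return Mass in Da.
#' @export
protein_mass <- function(peptide, empty = c("water", "zero")) {
  empty <- match.arg(empty)
  if (!nchar(peptide)) {
    return(if (empty == "water") WATER_MASS_AVG else 0)
  }
  aa <- strsplit(peptide, "")[[1L]]
  unknown <- setdiff(aa, names(RESIDUE_MASS_AVG))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  }
  sum(RESIDUE_MASS_AVG[aa]) + WATER_MASS_AVG
}

#' Locate the annotated stop codon of a reference chain
#'
#' Splices the given transcript's annotated exon chain and scans its ORF;
#' returns the genomic position of the stop codon's first base, for use as
#' `reference_stop_genomic` in [classify_nmd()].
#'
#' @param gene A [gene_model()] (the transcript must carry a CDS).
#' @param genome `DNAStringSet`.
#' @param transcript_id Which transcript to use; default the first with a
#'   CDS.
#' @return Genomic position (0-based) or `NA` if the reference has no stop.
#' @export
annotated_stop_position <- function(gene, genome, transcript_id = NULL) {
  txs <- gene$transcripts
  if (!is.null(transcript_id)) {
    txs <- Filter(function(t) t$transcript_id == transcript_id, txs)
  }
  txs <- Filter(function(t) !is.null(t$cds), txs)
  if (!length(txs)) stop("no transcript with a CDS in ", gene$gene_id)
  t0 <- txs[[1L]]
  mt <- splice_transcript(gene, t0$exons, genome, cds = t0$cds)
  orf <- scan_orf(mt)
  if (orf$non_stop) return(NA_integer_)
  transcript_to_genome(mt, orf$stop_tx)
}
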
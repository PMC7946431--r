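## Readers/writers for GTF, FASTA, junction BED12 (regtools dialect), peak
## BED and TSV reports. Everything is normalised to 0-based half-open
## coordinates on the way in.

parse_gtf_attributes <- function(s) {
  # Ensembl dialect: key "value"; key "value"; ...
  parts <- regmatches(s, gregexpr('(\\w+) "([^"]*)"', s))[[1L]]
  keys <- sub('^(\\w+) .*$', "\\1", parts)
  vals <- sub('^\\w+ "([^"]*)"$', "\\1", parts)
  stats::setNames(as.list(vals), keys)
}

#' Read gene models from a GTF file
#'
#' Consumes the Ensembl GTF dialect (tab-separated, attributes
#' `gene_id`/`transcript_id`/`exon_number`). Only `gene`, `transcript`,
#' `exon` and `CDS` features are used; everything else is ignored. GTF
#' 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention. Exon ordinals are taken from the `exon_number`
#' attribute when present; otherwise they are assigned by transcript order
#' and the model is flagged `ordinals_provisional`.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects, keyed by `gene_id`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    }
    feature <- f[3L]
    if (!feature %in% c("gene", "transcript", "exon", "CDS")) next
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 < start1) {
      stop("malformed GTF line ", i, ": bad coordinates '", f[4L], "'..'",
           f[5L], "'")
    }
    if (!f[7L] %in% c("+", "-")) {
      stop("malformed GTF line ", i, ": strand must be '+' or '-'")
    }
    at <- parse_gtf_attributes(f[9L])
    if (is.null(at$gene_id)) stop("malformed GTF line ", i, ": missing gene_id")
    rows[[length(rows) + 1L]] <- list(
      contig = f[1L], feature = feature, start = start1 - 1L, end = end1,
      strand = f[7L], gene_id = at$gene_id,
      gene_name = if (is.null(at$gene_name)) at$gene_id else at$gene_name,
      transcript_id = at$transcript_id,
      exon_number = if (is.null(at$exon_number)) NA_integer_ else
        as.integer(at$exon_number),
      line = i)
  }
  if (!length(rows)) stop("no usable GTF records in ", path)
  by_gene <- split(rows, vapply(rows, `[[`, "", "gene_id"))
  models <- lapply(by_gene, function(gr) {
    strand <- gr[[1L]]$strand
    contig <- gr[[1L]]$contig
    gene_name <- gr[[1L]]$gene_name
    tx_rows <- Filter(function(r) !is.null(r$transcript_id), gr)
    by_tx <- split(tx_rows, vapply(tx_rows, `[[`, "", "transcript_id"))
    tx_spans <- lapply(by_tx, function(tr) {
      sp <- Filter(function(r) r$feature == "transcript", tr)
      if (length(sp)) c(sp[[1L]]$start, sp[[1L]]$end) else NULL
    })
    transcripts <- lapply(by_tx, function(tr) {
      exr <- Filter(function(r) r$feature == "exon", tr)
      if (!length(exr)) return(NULL)
      ex <- data.frame(start = vapply(exr, `[[`, 0L, "start"),
                       end = vapply(exr, `[[`, 0L, "end"))
      num <- vapply(exr, `[[`, NA_integer_, "exon_number")
      tid <- tr[[1L]]$transcript_id
      span <- tx_spans[[tid]]
      if (!is.null(span)) {
        bad <- which(ex$start < span[1L] | ex$end > span[2L])
        if (length(bad)) {
          stop("exon outside its transcript span in transcript ", tid,
               " (GTF line ", exr[[bad[1L]]]$line, ")")
        }
      }
      o <- order(ex$start)
      if (strand == "-") o <- rev(o)
      ex <- ex[o, , drop = FALSE]
      rownames(ex) <- NULL
      num <- num[o]
      if (anyNA(num)) {
        num <- seq_len(nrow(ex))
        provisional <- TRUE
      } else {
        provisional <- FALSE
      }
      cdr <- Filter(function(r) r$feature == "CDS", tr)
      cds <- if (length(cdr)) {
        c(min(vapply(cdr, `[[`, 0L, "start")),
          max(vapply(cdr, `[[`, 0L, "end")))
      } else NULL
      list(transcript_id = tid, exons = ex, exon_number = num, cds = cds,
           ordinals_provisional = provisional)
    })
    transcripts <- Filter(Negate(is.null), transcripts)
    if (!length(transcripts)) return(NULL)
    provisional <- any(vapply(transcripts, `[[`, FALSE,
                              "ordinals_provisional"))
    gene_model(gene_id = gr[[1L]]$gene_id, gene_name = gene_name,
               contig = contig, strand = strand, transcripts = transcripts,
               ordinals_provisional = provisional)
  })
  Filter(Negate(is.null), models)
}

#' Write gene models to GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` lines in the Ensembl
#' attribute dialect, converting back to 1-based inclusive coordinates, so
#' `read_gtf(write_gtf(x))` reproduces coordinates and strand exactly.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(models, path) {
  out <- character()
  fmt <- function(contig, feature, start, end, strand, attrs) {
    paste(contig, "crypticsplice", feature, start + 1L, end, ".", strand, ".",
          attrs, sep = "\t")
  }
  for (g in models) {
    sp <- gene_span(g)
    ga <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    out <- c(out, fmt(g$contig, "gene", sp$start, sp$end, g$strand, ga))
    for (tx in g$transcripts) {
      ex <- tx$exons
      ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                    g$gene_id, tx$transcript_id, g$gene_name)
      out <- c(out, fmt(g$contig, "transcript", min(ex$start), max(ex$end),
                        g$strand, ta))
      for (k in seq_len(nrow(ex))) {
        ea <- sprintf('%s exon_number "%d";', ta, tx$exon_number[k])
        out <- c(out, fmt(g$contig, "exon", ex$start[k], ex$end[k],
                          g$strand, ea))
      }
      if (!is.null(tx$cds)) {
        out <- c(out, fmt(g$contig, "CDS", tx$cds[1L], tx$cds[2L],
                          g$strand, ta))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read splice junctions from a regtools-style BED12 file
#'
#' The dialect written by `regtools junctions extract`: each line is one
#' intron, the two BED blocks are the maximal read anchors flanking it, and
#' the score column is the number of junction-spanning reads. The intron in
#' 0-based half-open coordinates is
#' `[chromStart + blockSize1, chromEnd - blockSize2)`.
#'
#' Duplicate lines for the same intron are summed with a warning. Anchor
#' block sizes are retained so [write_junctions_bed()] can reproduce input
#' lines.
#'
#' @param path Path to a 12-column BED file.
#' @param sample_id Sample label attached to every record.
#' @param condition Condition label (e.g. `"WT"`, `"cKO"`).
#' @return data.frame with columns `contig`, `start`, `end` (the intron),
#'   `strand`, `count`, `sample_id`, `condition`, `name`, `anchor1`,
#'   `anchor2`.
#' @export
read_junctions_bed <- function(path, sample_id, condition) {
  if (!file.exists(path)) stop("junction BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  n <- length(lines)
  if (!n) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      count = integer(), sample_id = character(),
                      condition = character(), name = character(),
                      anchor1 = integer(), anchor2 = integer()))
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) {
      stop("junction BED line ", i, ": expected 12 columns, got ", length(f))
    }
    sizes <- suppressWarnings(as.integer(strsplit(f[11L], ",")[[1L]]))
    sizes <- sizes[!is.na(sizes)]
    if (length(sizes) != 2L) {
      stop("junction BED line ", i, ": expected exactly 2 blocks, got ",
           length(sizes))
    }
    cs <- as.integer(f[2L]); ce <- as.integer(f[3L])
    istart <- cs + sizes[1L]
    iend <- ce - sizes[2L]
    if (iend - istart < 4L) {
      stop("junction BED line ", i, ": intron [", istart, ",", iend,
           ") shorter than 4 nt after removing anchors")
    }
    recs[[i]] <- data.frame(contig = f[1L], start = istart, end = iend,
                            strand = f[6L], count = as.integer(f[5L]),
                            sample_id = sample_id, condition = condition,
                            name = f[4L], anchor1 = sizes[1L],
                            anchor2 = sizes[2L])
  }
  jx <- do.call(rbind, recs)
  key <- paste(jx$contig, jx$start, jx$end, jx$strand)
  if (anyDuplicated(key)) {
    warning("duplicate junction lines for the same intron in ", path,
            "; counts summed")
    agg <- stats::aggregate(count ~ key, data = cbind(jx, key = key), sum)
    jx <- jx[!duplicated(key), , drop = FALSE]
    jx$count <- agg$count[match(paste(jx$contig, jx$start, jx$end, jx$strand),
                                agg$key)]
  }
  rownames(jx) <- NULL
  jx
}

#' Write junction records back to regtools-style BED12
#'
#' Uses the stored anchor sizes (default 8 nt when absent), so a
#' read/write/read round trip is the identity on intron coordinates, strand
#' and counts.
#'
#' @param jx data.frame as returned by [read_junctions_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junctions_bed <- function(jx, path) {
  a1 <- if ("anchor1" %in% names(jx)) jx$anchor1 else rep(8L, nrow(jx))
  a2 <- if ("anchor2" %in% names(jx)) jx$anchor2 else rep(8L, nrow(jx))
  nm <- if ("name" %in% names(jx)) jx$name else sprintf("JUNC%05d", seq_len(nrow(jx)))
  cs <- jx$start - a1
  ce <- jx$end + a2
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
                   jx$contig, cs, ce, nm, jx$count, jx$strand, cs, ce,
                   a1, a2, jx$end - cs)
  writeLines(lines, path)
  invisible(path)
}

#' Load a FASTA file as a sequence store
#'
#' @param path FASTA path.
#' @return A `DNAStringSet` (Biostrings) with names truncated at the first
#'   whitespace; use [get_seq()] for strand-aware slicing.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Strand-aware sequence slice
#'
#' Extracts the sequence of a [gi()] interval from a genome; minus-strand
#' intervals return the reverse complement, so the result always reads in
#' transcript orientation. Bases are upper-cased.
#'
#' @param genome A `DNAStringSet` from [read_fasta()].
#' @param interval A [gi()] interval.
#' @return Character scalar.
#' @export
get_seq <- function(genome, interval) {
  ctg <- interval$contig
  if (!ctg %in% names(genome)) stop("contig not found: ", ctg)
  len <- length(genome[[ctg]])
  if (interval$end > len) {
    stop("interval ", format(interval), " beyond contig end (", len, ")")
  }
  s <- Biostrings::subseq(genome[[ctg]], start = interval$start + 1L,
                          end = interval$end)
  if (identical(interval$strand, "-")) s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Read CLIP/peak intervals from BED
#'
#' Standard BED with at least 3 columns; column 5 is the peak score when
#' present (0 otherwise).
#'
#' @param path BED path.
#' @param source Label recorded on every record; defaults to the file name.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `score`, `source`.
#' @export
read_peaks_bed <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("peak BED not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), source = character()))
  }
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("peak BED line ", i, ": fewer than 3 columns")
    st <- suppressWarnings(as.integer(f[2L]))
    en <- suppressWarnings(as.integer(f[3L]))
    if (is.na(st) || is.na(en) || st >= en) {
      stop("peak BED line ", i, ": invalid interval")
    }
    data.frame(contig = f[1L], start = st, end = en,
               strand = if (length(f) >= 6L) f[6L] else ".",
               score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L]))
                       else 0,
               source = source)
  })
  out <- do.call(rbind, recs)
  out$score[is.na(out$score)] <- 0
  rownames(out) <- NULL
  out
}

# fixed float formatting used by every report writer: 6 significant digits
format_report_value <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    as.character(ifelse(is.na(x), ".", formatC(x, digits = 6L, format = "g")))
  } else {
    y <- as.character(x)
    as.character(ifelse(is.na(y), ".", y))
  }
}

#' Write a deterministic TSV report
#'
#' UTF-8, header row, tab separator, `"."` for missing values. Rows are
#' sorted lexicographically over all columns and floats rendered at 6
#' significant digits so identical inputs yield identical bytes.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param sort_rows Sort rows deterministically (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(rows, path, sort_rows = TRUE) {
  df <- as.data.frame(rows)
  if (sort_rows && nrow(df) > 1L) {
    df <- df[do.call(order, lapply(df, as.character)), , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, format_report_value, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TSV report written by [write_report_tsv()]
#' @param path Path to the TSV.
#' @return data.frame with `"."` restored to `NA`.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
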
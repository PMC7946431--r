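## Junction-led discovery of unannotated cassette exons inside annotated
## introns, CE1/CE2/CE3 classification, junction-based exon-usage flags and
## isoform calls, and local spliceform enumeration.

#' Build a donor/acceptor junction index for one gene
#'
#' Assigns every junction donor and acceptor roles in transcript
#' orientation: on the plus strand the donor is the intron's low-coordinate
#' boundary, on the minus strand its high-coordinate boundary. Junctions
#' falling outside the gene span, or whose strand does not match the gene
#' (`"."`-strand junctions included), are excluded and reported via the
#' `"excluded"` attribute. Counts for the same site pair and sample are
#' aggregated.
#'
#' @param junctions data.frame from [read_junctions_bed()] (possibly several
#'   samples row-bound).
#' @param gene A [gene_model()].
#' @return data.frame of class `"junction_index"` with columns `donor`,
#'   `acceptor`, `start`, `end`, `sample_id`, `condition`, `count`,
#'   `donor_annotated`, `acceptor_annotated`; gene kept as attribute.
#' @export
build_junction_index <- function(junctions, gene) {
  span <- gene_span(gene)
  jx <- junctions
  ok <- jx$contig == gene$contig & jx$strand == gene$strand &
    jx$start >= span$start & jx$end <= span$end
  excluded <- jx[!ok, , drop = FALSE]
  if (nrow(excluded)) {
    message(nrow(excluded), " junction record(s) outside gene span or ",
            "strand-mismatched for ", gene$gene_id, "; excluded")
  }
  jx <- jx[ok, , drop = FALSE]
  if (nrow(jx)) {
    if (gene$strand == "+") {
      jx$donor <- jx$start; jx$acceptor <- jx$end
    } else {
      jx$donor <- jx$end; jx$acceptor <- jx$start
    }
    agg <- stats::aggregate(
      count ~ donor + acceptor + start + end + sample_id + condition,
      data = jx, FUN = sum)
  } else {
    agg <- data.frame(donor = integer(), acceptor = integer(),
                      start = integer(), end = integer(),
                      sample_id = character(), condition = character(),
                      count = integer())
  }
  sites <- annotated_sites(gene)
  agg$donor_annotated <- agg$donor %in% sites$donors
  agg$acceptor_annotated <- agg$acceptor %in% sites$acceptors
  agg <- agg[order(agg$donor, agg$acceptor, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("junction_index", "data.frame"),
            gene = gene, excluded = excluded)
}

index_gene <- function(index) attr(index, "gene", exact = TRUE)

# per (donor, acceptor) total counts across samples
.pair_totals <- function(index) {
  if (!nrow(index)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      start = integer(), end = integer(), count = integer()))
  }
  stats::aggregate(count ~ donor + acceptor + start + end,
                   data = as.data.frame(index), FUN = sum)
}

# per-condition "a|b" support string, deterministic condition order
.support_by_condition <- function(index, donor, acceptor) {
  sub <- index[index$donor == donor & index$acceptor == acceptor, ,
               drop = FALSE]
  agg <- stats::aggregate(count ~ condition, data = as.data.frame(sub), sum)
  agg <- agg[order(agg$condition), , drop = FALSE]
  stats::setNames(agg$count, agg$condition)
}

#' Call unannotated cassette exons from a junction index
#'
#' A candidate cassette is emitted when an annotated donor splices to an
#' unannotated acceptor lying inside an annotated intron, and an unannotated
#' donor downstream of that acceptor (transcript orientation) splices back
#' to an annotated acceptor, with the enclosed segment overlapping no
#' annotated exon. The novel intron boundaries are checked for canonical
#' GT/AG in transcript orientation; non-canonical calls are retained and
#' flagged, not filtered.
#'
#' Classification: the candidate with the highest entry+exit support, if it
#' reaches `min_major_support`, is the major cassette `CE1`; sub-threshold
#' candidates sharing CE1's acceptor but using donors further downstream are
#' `CE2`, `CE3`, ... in increasing donor order (transcript orientation);
#' remaining sub-threshold candidates are `minor`. Entry junctions with no
#' detectable exit are reported with `exit = "readthrough"` and exit support
#' `NA`.
#'
#' @param index A junction index from [build_junction_index()].
#' @param genome `DNAStringSet` for splice-site dinucleotide checks.
#' @param min_major_support Minimum entry+exit read support for a major
#'   call; default 5, mirroring the convention that junctions seen at fewer
#'   than 5 reads per species are minor.
#' @return data.frame, one row per call: `gene_id`, `segment_start`,
#'   `segment_end`, `strand`, `ce_class`, `acceptor_site`, `donor_site`
#'   (dinucleotides), `canonical`, `entry_count`, `exit_count`, `support`,
#'   per-condition support string, `exit`, host intron coordinates.
#' @export
call_cassette_exons <- function(index, genome, min_major_support = 5L) {
  gene <- index_gene(index)
  if (is.null(gene)) stop("index carries no gene annotation")
  if (!nrow(index)) return(empty_calls())
  tot <- .pair_totals(index)
  introns <- annotated_introns(gene)
  exons <- annotated_exons(gene)
  strand <- gene$strand
  entries <- tot[tot$donor %in% annotated_sites(gene)$donors &
                   !(tot$acceptor %in% annotated_sites(gene)$acceptors), ,
                 drop = FALSE]
  exits <- tot[!(tot$donor %in% annotated_sites(gene)$donors) &
                 tot$acceptor %in% annotated_sites(gene)$acceptors, ,
               drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(entries))) {
    en <- entries[i, ]
    # cassette start boundary = the unannotated acceptor coordinate
    host <- NULL
    for (k in seq_len(nrow(introns))) {
      acc_pos <- en$acceptor
      if (acc_pos > introns$start[k] && acc_pos < introns$end[k]) {
        host <- c(introns$start[k], introns$end[k]); break
      }
    }
    if (is.null(host)) next
    matched_exit <- FALSE
    for (j in seq_len(nrow(exits))) {
      ex_j <- exits[j, ]
      # exit donor must be strictly downstream of the entry acceptor
      if (tx_cmp(ex_j$donor, en$acceptor, strand) <= 0) next
      seg_start <- min(en$acceptor, ex_j$donor)
      seg_end <- max(en$acceptor, ex_j$donor)
      seg <- gi(gene$contig, seg_start, seg_end, strand)
      if (any(exons$start < seg$end & seg$start < exons$end)) next
      # dinucleotides of the two novel introns, transcript orientation
      entry_iv <- gi(gene$contig, en$start, en$end, strand)
      exit_iv <- gi(gene$contig, ex_j$start, ex_j$end, strand)
      di <- function(iv) {
        s <- get_seq(genome, iv)
        c(substr(s, 1L, 2L), substr(s, nchar(s) - 1L, nchar(s)))
      }
      d_entry <- di(entry_iv); d_exit <- di(exit_iv)
      canonical <- identical(d_entry[1L], "GT") &&
        identical(d_entry[2L], "AG") && identical(d_exit[1L], "GT") &&
        identical(d_exit[2L], "AG")
      sup_en <- .support_by_condition(index, en$donor, en$acceptor)
      sup_ex <- .support_by_condition(index, ex_j$donor, ex_j$acceptor)
      conds <- sort(unique(c(names(sup_en), names(sup_ex))))
      per_cond <- vapply(conds, function(cc) {
        sum(sup_en[cc], sup_ex[cc], na.rm = TRUE)
      }, numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, contig = gene$contig,
        segment_start = seg$start, segment_end = seg$end, strand = strand,
        ce_class = NA_character_,
        entry_acceptor = en$acceptor, exit_donor = ex_j$donor,
        acceptor_site = d_entry[2L], donor_site = d_exit[1L],
        canonical = canonical,
        entry_count = en$count, exit_count = ex_j$count,
        support = en$count + ex_j$count,
        support_by_condition = paste(sprintf("%s=%d", conds,
                                             as.integer(per_cond)),
                                     collapse = ";"),
        exit = "spliced",
        host_start = host[1L], host_end = host[2L])
      matched_exit <- TRUE
    }
    if (!matched_exit) {
      host_end_tx <- if (strand == "+") host[2L] else host[1L]
      seg_start <- min(en$acceptor, host_end_tx)
      seg_end <- max(en$acceptor, host_end_tx)
      entry_iv <- gi(gene$contig, en$start, en$end, strand)
      s <- get_seq(genome, entry_iv)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, contig = gene$contig,
        segment_start = seg_start, segment_end = seg_end, strand = strand,
        ce_class = NA_character_,
        entry_acceptor = en$acceptor, exit_donor = NA_integer_,
        acceptor_site = substr(s, nchar(s) - 1L, nchar(s)),
        donor_site = NA_character_, canonical = NA,
        entry_count = en$count, exit_count = NA_integer_,
        support = en$count,
        support_by_condition = "", exit = "readthrough",
        host_start = host[1L], host_end = host[2L])
    }
  }
  if (!length(rows)) return(empty_calls())
  calls <- do.call(rbind, rows)
  # classify
  spliced <- which(calls$exit == "spliced")
  calls$ce_class <- "minor"
  if (length(spliced)) {
    best <- spliced[which.max(calls$support[spliced])]
    if (calls$support[best] >= min_major_support) {
      calls$ce_class[best] <- "CE1"
      # extensions: same acceptor as CE1 but a downstream donor whose exit
      # junction stays below the threshold in every sample ("<5 reads per
      # species"); the shared entry junction does not count against them
      exit_max <- vapply(spliced, function(i) {
        sub <- index[index$donor == calls$exit_donor[i], , drop = FALSE]
        if (nrow(sub)) max(sub$count) else 0L
      }, numeric(1L))
      sib <- spliced[calls$entry_acceptor[spliced] ==
                       calls$entry_acceptor[best] &
                       spliced != best &
                       exit_max < min_major_support]
      if (length(sib)) {
        dtx <- vapply(calls$exit_donor[sib], function(d) {
          tx_cmp(d, calls$exit_donor[best], gene$strand)
        }, numeric(1L))
        sib <- sib[order(dtx)]
        calls$ce_class[sib] <- paste0("CE", seq_along(sib) + 1L)
      }
    }
  }
  o <- order(calls$segment_start, calls$segment_end)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(gene_id = character(), contig = character(),
             segment_start = integer(), segment_end = integer(),
             strand = character(), ce_class = character(),
             entry_acceptor = integer(), exit_donor = integer(),
             acceptor_site = character(), donor_site = character(),
             canonical = logical(), entry_count = integer(),
             exit_count = integer(), support = integer(),
             support_by_condition = character(), exit = character(),
             host_start = integer(), host_end = integer())
}

#' Derive exon-usage flags from junction evidence
#'
#' Mirrors junction-spanning primer logic: a junction landing on an exon's
#' acceptor or leaving its donor is inclusion evidence; a junction spanning
#' the whole exon is exclusion (skipping) evidence. An exon with both kinds
#' of evidence, or neither, gets `NA`.
#'
#' @param index Junction index from [build_junction_index()].
#' @param ordinals Integer exon ordinals to flag.
#' @return Named logical vector (`TRUE` included, `FALSE` skipped, `NA`
#'   indeterminate), names `"ex<ordinal>"`.
#' @export
exon_usage_flags <- function(index, ordinals) {
  gene <- index_gene(index)
  tot <- .pair_totals(index)
  out <- stats::setNames(rep(NA, length(ordinals)),
                         paste0("ex", ordinals))
  for (i in seq_along(ordinals)) {
    iv <- exon_by_ordinal(gene, ordinals[i])
    if (is.null(iv)) next
    if (gene$strand == "+") {
      acc <- iv$start; don <- iv$end
    } else {
      acc <- iv$end; don <- iv$start
    }
    incl <- any(tot$acceptor == acc | tot$donor == don)
    skip <- any(tot$start < iv$start + 1L & tot$end > iv$end - 1L &
                  tot$start <= iv$start & tot$end >= iv$end)
    out[i] <- if (incl && !skip) TRUE else if (skip && !incl) FALSE else NA
  }
  out
}

#' Classify a neurofascin-style isoform from alternative-exon flags
#'
#' Glial NF155 carries exons 23 and 24 and lacks exons 28-30; neuronal
#' NF186 the reverse; NF140 carries neither block and is suffixed by its
#' exon-27 status. Both blocks present is a contradiction.
#'
#' @param flags Named logical list/vector with `ex23`, `ex24`, `ex28_30`
#'   and optionally `ex27` (`NA` allowed).
#' @return One of `"NF155"`, `"NF186"`, `"NF140+ex27"`, `"NF140-ex27"`,
#'   `"NF140"`, `"conflict"`, `"indeterminate"`.
#' @export
classify_isoform <- function(flags) {
  f <- function(nm) {
    v <- flags[[nm]]
    if (is.null(v)) NA else as.logical(v)
  }
  ex23 <- f("ex23"); ex24 <- f("ex24"); ex2830 <- f("ex28_30")
  ex27 <- f("ex27")
  if (is.na(ex23) || is.na(ex24) || is.na(ex2830)) return("indeterminate")
  has2324 <- ex23 && ex24
  none2324 <- !ex23 && !ex24
  if (!has2324 && !none2324) return("conflict")  # mixed 23/24 evidence
  if (has2324 && ex2830) return("conflict")
  if (has2324 && !ex2830) return("NF155")
  if (none2324 && ex2830) return("NF186")
  if (is.na(ex27)) return("NF140")
  if (ex27) "NF140+ex27" else "NF140-ex27"
}

#' Enumerate junction-supported spliceform paths through a region
#'
#' Walks the junction graph from an upstream constitutive exon to a
#' downstream one, through annotated exons and cryptic calls, returning
#' every supported exon chain with its per-condition support (the count of
#' the path's first junction, i.e. the read flow leaving the anchor donor).
#'
#' @param index Junction index.
#' @param calls Cassette calls from [call_cassette_exons()] (may be empty).
#' @param from_ordinal,to_ordinal Paper-style ordinals of the flanking
#'   constitutive exons.
#' @return data.frame: `path` (labels joined by `-`), one column of counts
#'   per condition, `n_junctions`.
#' @export
enumerate_spliceforms <- function(index, calls, from_ordinal, to_ordinal) {
  gene <- index_gene(index)
  strand <- gene$strand
  from_iv <- exon_by_ordinal(gene, from_ordinal)
  to_iv <- exon_by_ordinal(gene, to_ordinal)
  if (is.null(from_iv) || is.null(to_iv)) {
    stop("flanking exon ordinals not present in the gene model")
  }
  # nodes: annotated exons between the flanks (transcript orientation) plus
  # spliced cryptic segments
  ex <- annotated_exons(gene)
  labs <- character(); acc <- integer(); don <- integer()
  node_add <- function(label, a, d) {
    labs <<- c(labs, label); acc <<- c(acc, a); don <<- c(don, d)
  }
  exon_sites <- function(iv) {
    if (strand == "+") c(iv$start, iv$end) else c(iv$end, iv$start)
  }
  fs <- exon_sites(from_iv); ts <- exon_sites(to_iv)
  node_add(paste0("E", from_ordinal), fs[1L], fs[2L])
  for (k in seq_len(nrow(ex))) {
    iv <- gi(gene$contig, ex$start[k], ex$end[k], strand)
    es <- exon_sites(iv)
    if (tx_cmp(es[1L], fs[2L], strand) >= 0 &&
        tx_cmp(es[2L], ts[1L], strand) <= 0) {
      ords <- unlist(lapply(gene$transcripts, function(tx) {
        hit <- which(tx$exons$start == iv$start & tx$exons$end == iv$end)
        if (length(hit)) tx$exon_number[hit[1L]] else NULL
      }))
      lab <- if (length(ords)) paste0("E", ords[1L]) else
        sprintf("E?%d", iv$start)
      node_add(lab, es[1L], es[2L])
    }
  }
  if (nrow(calls)) {
    sp <- calls[calls$exit == "spliced", , drop = FALSE]
    for (k in seq_len(nrow(sp))) {
      node_add(sp$ce_class[k], sp$entry_acceptor[k], sp$exit_donor[k])
    }
  }
  node_add(paste0("E", to_ordinal), ts[1L], ts[2L])
  labs <- make.unique(labs, sep = "_")
  n <- length(labs)
  tot <- .pair_totals(index)
  conds <- sort(unique(index$condition))
  jx_count <- function(d, a, cond) {
    sub <- index[index$donor == d & index$acceptor == a &
                   index$condition == cond, , drop = FALSE]
    sum(sub$count)
  }
  has_edge <- function(i, j) {
    any(tot$donor == don[i] & tot$acceptor == acc[j])
  }
  paths <- list()
  walk <- function(i, chain) {
    if (labs[i] == labs[n] && i == n) {
      paths[[length(paths) + 1L]] <<- chain
      return()
    }
    for (j in seq_len(n)[-1L]) {
      if (j == i) next
      if (tx_cmp(acc[j], don[i], strand) < 0) next
      if (has_edge(i, j)) walk(j, c(chain, j))
    }
  }
  walk(1L, 1L)
  if (!length(paths)) {
    out <- data.frame(path = character(), n_junctions = integer())
    for (cc in conds) out[[cc]] <- integer()
    return(out)
  }
  rows <- lapply(paths, function(pp) {
    row <- data.frame(path = paste(labs[pp], collapse = "-"),
                      n_junctions = length(pp) - 1L)
    for (cc in conds) {
      row[[cc]] <- jx_count(don[pp[1L]], acc[pp[2L]], cc)
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}
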
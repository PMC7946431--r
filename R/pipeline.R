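## End-to-end orchestration: discovery -> PSI -> ORF/NMD -> motif, with
## deterministic TSV reports and a Sashimi-style junction arc table.

#' Read a flat pipeline configuration file
#'
#' DCF-style `key: value` text. Recognised keys: `gtf`, `fasta`, `peaks`,
#' `cq`, `gene`, `outdir`, `min_major_support`, `nmd_rule`,
#' `motif_offset`, `motif_width`, `pooling`, `seed`, and `junctions` (one
#' or more whitespace-separated `path,sample_id,condition` triples,
#' possibly over continuation lines).
#'
#' @param path Config file path.
#' @return Named list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  m <- read.dcf(path)
  cfg <- as.list(m[1L, ])
  if (!is.null(cfg$junctions)) {
    trip <- strsplit(trimws(strsplit(cfg$junctions, "\\s+")[[1L]]), ",")
    trip <- Filter(function(x) length(x) == 3L, trip)
    cfg$junctions <- data.frame(
      path = vapply(trip, `[[`, "", 1L),
      sample_id = vapply(trip, `[[`, "", 2L),
      condition = vapply(trip, `[[`, "", 3L))
  }
  for (k in c("min_major_support", "nmd_rule", "motif_offset",
              "motif_width", "seed")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, class = "pipeline_config")
}

log_line <- function(con, stage, msg) {
  writeLines(sprintf("%s\t[%s]\t%s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), stage, msg),
             con)
}

#' Run the full cryptic-exon pipeline
#'
#' Stages in order: junction indexing and cassette discovery, donor-anchored
#' PSI at every cryptic entry donor, spliceform enumeration across the host
#' intron's flanking exons, ORF/PTC/NMD annotation of each spliceform,
#' UG-motif scoring (and CLIP-peak overlap when peaks are given) downstream
#' of each cryptic donor, and optional delta-delta-Cq if a Cq table is
#' configured. Reports are deterministic: fixed sorts, 6-significant-digit
#' floats.
#'
#' @param config A `"pipeline_config"` (or a plain named list with the same
#'   fields; `gtf`, `fasta`, `junctions` and `outdir` are required).
#' @return Invisibly, a named list of report paths (`calls`, `psi`, `orf`,
#'   `motif`, `spliceforms`, optionally `expression`, plus `log`).
#' @export
run_pipeline <- function(config) {
  req <- c("gtf", "fasta", "junctions", "outdir")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys)) {
    stop("pipeline config missing: ", paste(missing_keys, collapse = ", "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  con <- file(log_path, open = "w")
  on.exit(close(con))
  stage <- "setup"
  result <- tryCatch({
    models <- read_gtf(config$gtf)
    genome <- read_fasta(config$fasta)
    jxs <- do.call(rbind, lapply(seq_len(nrow(config$junctions)), function(i) {
      read_junctions_bed(config$junctions$path[i],
                         config$junctions$sample_id[i],
                         config$junctions$condition[i])
    }))
    genes <- if (!is.null(config$gene)) {
      models[strsplit(config$gene, "[,\\s]+")[[1L]]]
    } else models
    mms <- if (is.null(config$min_major_support)) 5L else
      config$min_major_support
    nmd_rule <- if (is.null(config$nmd_rule)) 50L else config$nmd_rule
    pooling <- if (is.null(config$pooling)) "pool_counts" else config$pooling
    calls_all <- list(); psi_all <- list(); orf_all <- list()
    motif_all <- list(); forms_all <- list()
    for (g in genes) {
      stage <- "discovery"
      idx <- build_junction_index(jxs, g)
      log_line(con, stage, sprintf("%s: %d junction records indexed, %d excluded",
                                   g$gene_id, nrow(idx),
                                   nrow(attr(idx, "excluded"))))
      calls <- call_cassette_exons(idx, genome, min_major_support = mms)
      if (nrow(calls)) calls_all[[g$gene_id]] <- calls
      log_line(con, stage, sprintf("%s: %d cassette call(s)", g$gene_id,
                                   nrow(calls)))
      sp <- calls[calls$exit == "spliced", , drop = FALSE]
      stage <- "psi"
      for (k in seq_len(nrow(sp))) {
        entry_donor <- if (g$strand == "+") {
          tot <- .pair_totals(idx)
          tot$donor[tot$acceptor == sp$entry_acceptor[k]][1L]
        } else {
          tot <- .pair_totals(idx)
          tot$donor[tot$acceptor == sp$entry_acceptor[k]][1L]
        }
        set <- competing_junctions(idx, entry_donor, anchor = "donor")
        pr <- psi(set, sp$entry_acceptor[k], pooling = pooling)
        pr$ce_class <- sp$ce_class[k]
        pr$gene_id <- g$gene_id
        psi_all[[length(psi_all) + 1L]] <- pr
      }
      # spliceforms across the host intron of the top call
      stage <- "spliceforms"
      if (nrow(sp)) {
        tot <- .pair_totals(idx)
        entry_don <- tot$donor[tot$acceptor == sp$entry_acceptor[1L]][1L]
        exit_acc <- tot$acceptor[tot$donor == sp$exit_donor[1L]][1L]
        ords <- c(ordinal_for_site(g, entry_don, "donor"),
                  ordinal_for_site(g, exit_acc, "acceptor"))
        if (!anyNA(ords)) {
          forms <- tryCatch(
            enumerate_spliceforms(idx, calls, ords[1L], ords[2L]),
            error = function(e) NULL)
          if (!is.null(forms) && nrow(forms)) {
            forms$gene_id <- g$gene_id
            forms_all[[length(forms_all) + 1L]] <- forms
            stage <- "orf"
            ref_stop <- tryCatch(annotated_stop_position(g, genome),
                                 error = function(e) NULL)
            orf_rows <- annotate_spliceform_orfs(g, genome, idx, calls,
                                                 ords, ref_stop, nmd_rule)
            if (nrow(orf_rows)) orf_all[[length(orf_all) + 1L]] <- orf_rows
          }
        }
      }
      stage <- "motif"
      peaks <- if (!is.null(config$peaks)) read_peaks_bed(config$peaks) else
        NULL
      for (k in seq_len(nrow(sp))) {
        don <- sp$exit_donor[k]
        win <- motif_window(g$contig, don, g$strand,
                            offset = config$motif_offset %||% 10L,
                            width = config$motif_width %||% 200L)
        sc <- ug_score(genome, win)
        row <- data.frame(gene_id = g$gene_id, ce_class = sp$ce_class[k],
                          window = format(win), ug_count = sc$ug_count,
                          ug_density = sc$ug_density,
                          longest_ug_run = sc$longest_ug_run,
                          clip_overlap_bp = NA_integer_, clip_hit = NA)
        if (!is.null(peaks)) {
          ov <- clip_overlap(win, peaks)
          row$clip_overlap_bp <- ov$overlap_bp
          row$clip_hit <- ov$hit
        }
        motif_all[[length(motif_all) + 1L]] <- row
      }
    }
    paths <- list(log = log_path)
    bind_or_empty <- function(lst, empty) {
      if (length(lst)) do.call(rbind, lst) else empty
    }
    stage <- "report"
    paths$calls <- file.path(config$outdir, "calls.tsv")
    write_report_tsv(bind_or_empty(calls_all, empty_calls()), paths$calls)
    paths$psi <- file.path(config$outdir, "psi.tsv")
    write_report_tsv(bind_or_empty(psi_all, data.frame()), paths$psi)
    paths$orf <- file.path(config$outdir, "orf.tsv")
    write_report_tsv(bind_or_empty(orf_all, data.frame()), paths$orf)
    paths$motif <- file.path(config$outdir, "motif.tsv")
    write_report_tsv(bind_or_empty(motif_all, data.frame()), paths$motif)
    paths$spliceforms <- file.path(config$outdir, "spliceforms.tsv")
    write_report_tsv(bind_or_empty(forms_all, data.frame()),
                     paths$spliceforms)
    if (!is.null(config$cq)) {
      stage <- "expression"
      cq <- read_report_tsv(config$cq)
      ex <- relative_expression_ddcq(cq, calibrator = config$calibrator %||%
                                       "WT")
      paths$expression <- file.path(config$outdir, "expression.tsv")
      write_report_tsv(ex, paths$expression)
    }
    log_line(con, "done", "pipeline complete")
    paths
  }, error = function(e) {
    log_line(con, stage, paste("FAILED:", conditionMessage(e)))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ordinal of the annotated exon whose donor/acceptor boundary sits at `site`
ordinal_for_site <- function(gene, site, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  for (tx in gene$transcripts) {
    ex <- tx$exons
    for (k in seq_len(nrow(ex))) {
      boundary <- if ((role == "donor") == (gene$strand == "+")) ex$end[k]
        else ex$start[k]
      if (boundary == site) return(tx$exon_number[k])
    }
  }
  NA_integer_
}

# ORF/NMD annotation for every junction-supported spliceform path
annotate_spliceform_orfs <- function(gene, genome, idx, calls, ords,
                                     ref_stop, nmd_rule) {
  forms <- enumerate_spliceforms(idx, calls, ords[1L], ords[2L])
  if (!nrow(forms)) return(data.frame())
  rows <- list()
  for (i in seq_len(nrow(forms))) {
    chain <- chain_for_path(gene, calls, forms$path[i])
    if (is.null(chain)) next
    full_chain <- extend_chain_to_gene_ends(gene, chain)
    mt <- tryCatch(splice_transcript(gene, full_chain, genome),
                   error = function(e) NULL)
    if (is.null(mt) || is.na(mt$cds_start)) next
    orf <- scan_orf(mt)
    orf <- classify_nmd(orf, mt, reference_stop_genomic = ref_stop,
                        rule_distance = nmd_rule)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id, path = forms$path[i],
      stop_tx = orf$stop_tx, is_ptc = orf$is_ptc,
      distance_to_last_junction = orf$distance_to_last_junction,
      nmd_predicted = orf$nmd_predicted,
      peptide_length = orf$peptide_length,
      mass_da = if (orf$non_stop) NA_real_ else protein_mass(orf$peptide),
      mass_kda = if (orf$non_stop) NA_real_ else
        protein_mass(orf$peptide) / 1000)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

# exon chain (genomic intervals, transcript order) for a path label like
# "E17-CE1-E19"
chain_for_path <- function(gene, calls, path) {
  labels <- strsplit(path, "-", fixed = TRUE)[[1L]]
  iv <- list()
  for (lab in labels) {
    if (grepl("^E[0-9]+$", lab)) {
      e <- exon_by_ordinal(gene, as.integer(sub("^E", "", lab)))
      if (is.null(e)) return(NULL)
      iv[[length(iv) + 1L]] <- c(e$start, e$end)
    } else {
      hit <- which(calls$ce_class == lab)
      if (!length(hit)) return(NULL)
      iv[[length(iv) + 1L]] <- c(calls$segment_start[hit[1L]],
                                 calls$segment_end[hit[1L]])
    }
  }
  m <- do.call(rbind, iv)
  data.frame(start = m[, 1L], end = m[, 2L])
}

# prepend/append the remaining annotated exons of the CDS transcript so the
# ORF has its genuine start and reference 3' end
extend_chain_to_gene_ends <- function(gene, chain) {
  txs <- Filter(function(t) !is.null(t$cds), gene$transcripts)
  if (!length(txs)) return(chain)
  ref <- txs[[1L]]$exons
  strand <- gene$strand
  first <- chain[1L, ]; last <- chain[nrow(chain), ]
  before <- ref[apply(ref, 1L, function(r) {
    tx_cmp(if (strand == "+") r[["end"]] else r[["start"]],
           if (strand == "+") first$start else first$end, strand) <= 0
  }), , drop = FALSE]
  after <- ref[apply(ref, 1L, function(r) {
    tx_cmp(if (strand == "+") r[["start"]] else r[["end"]],
           if (strand == "+") last$end else last$start, strand) >= 0
  }), , drop = FALSE]
  out <- rbind(before, chain, after)
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sashimi-style junction arc table
#'
#' One row per junction and condition with the spanning-read count (arc
#' width in a Sashimi plot) and its share of all reads leaving the same
#' donor, which sum to 1 per donor and condition. Rows are sorted by donor,
#' then count descending.
#'
#' @param index Junction index from [build_junction_index()].
#' @param region Optional [gi()] restricting the table.
#' @return data.frame: `donor`, `acceptor`, `start`, `end`, `condition`,
#'   `count`, `share`.
#' @export
sashimi_summary <- function(index, region = NULL) {
  df <- as.data.frame(index)
  if (!is.null(region)) {
    df <- df[df$start >= region$start & df$end <= region$end, , drop = FALSE]
  }
  if (!nrow(df)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      start = integer(), end = integer(),
                      condition = character(), count = integer(),
                      share = numeric()))
  }
  agg <- stats::aggregate(count ~ donor + acceptor + start + end + condition,
                          data = df, FUN = sum)
  totals <- stats::aggregate(count ~ donor + condition, data = agg, FUN = sum)
  names(totals)[names(totals) == "count"] <- "donor_total"
  agg <- merge(agg, totals, by = c("donor", "condition"))
  agg$share <- agg$count / agg$donor_total
  agg$donor_total <- NULL
  agg <- agg[order(agg$donor, agg$condition, -agg$count, agg$acceptor), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
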
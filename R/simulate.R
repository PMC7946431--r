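## Seeded generator of a toy multi-exon locus carrying one intronic cassette
## exon with canonical splice sites, an in-frame stop codon and a downstream
## UG tract, emulating a TDP-43-repressed cryptic exon. Junction read counts
## are drawn binomially from stated true PSI values.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codons that are neither stop codons nor start a run that could complete one
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L, paste,
                collapse = "")
  setdiff(all3, STOP_CODONS)
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_codons <- function(n_nt) {
  stopifnot(n_nt %% 3L == 0L)
  paste(sample(sense_codons(), n_nt / 3L, replace = TRUE), collapse = "")
}

#' Simulation configuration for a synthetic cryptic-exon locus
#'
#' Defaults emulate the neurofascin intron-17 situation: a four-exon window
#' (ordinals 17-20) whose first intron hosts a 104-nt cassette exon with
#' canonical splice sites, an in-frame stop codon and a downstream UG-rich
#' tract; an annotated skip transcript joins exon 17 directly to exon 19.
#' Default conditions carry the true splice-acceptor usage the estimator is
#' meant to recover (WT 0.253, cKO 0.931), three replicates each at donor
#' depth 200 junction-spanning reads.
#'
#' @param seed Integer master seed.
#' @param strand `"+"` or `"-"` for the simulated gene.
#' @param exon_lengths Lengths (nt) of the annotated exons, 5'->3'.
#' @param intron_lengths Lengths (nt) of the introns between them.
#' @param cryptic_exon_length Cassette exon length, default 104 nt.
#' @param cryptic_offset Offset (nt) of the cassette start into the host
#'   intron, transcript orientation.
#' @param host_intron Index of the intron hosting the cassette (default 1,
#'   i.e. between the first two exons).
#' @param ptc_frame_offset 0, 1 or 2: frame of the planted stop codon
#'   relative to the upstream CDS frame. 0 (default) yields a genuine
#'   in-frame premature termination codon.
#' @param ptc_position Offset (nt) of the planted stop within the cassette,
#'   before the frame adjustment.
#' @param ug_run_units Number of UG units in the tract planted 10 nt
#'   downstream of the cassette donor.
#' @param utr5_length 5' UTR length (nt) inside the first exon.
#' @param exon_ordinals Integer ordinals attached to the annotated exons.
#' @param conditions data.frame with columns `condition`, `true_psi`,
#'   `n_replicates`, `donor_depth`.
#' @param emit_minor Also plant two weak downstream donors and emit their
#'   exit junctions with counts in 1..4, exercising the sub-threshold
#'   CE2/CE3 classification.
#' @param background_depth Constant read count emitted on every consecutive
#'   annotated junction of the full transcript (default 0). Non-zero values
#'   support spliceform-path enumeration but add competing acceptors at the
#'   anchor donor, so the cassette acceptor PSI is then below `true_psi` by
#'   construction.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       strand = "+",
                       exon_lengths = c(150L, 90L, 120L, 180L),
                       intron_lengths = c(400L, 250L, 250L),
                       cryptic_exon_length = 104L,
                       cryptic_offset = 120L,
                       host_intron = 1L,
                       ptc_frame_offset = 0L,
                       ptc_position = 45L,
                       ug_run_units = 12L,
                       utr5_length = 30L,
                       exon_ordinals = 17:20,
                       conditions = data.frame(
                         condition = c("WT", "cKO"),
                         true_psi = c(0.253, 0.931),
                         n_replicates = c(3L, 3L),
                         donor_depth = c(200L, 200L)),
                       emit_minor = FALSE,
                       background_depth = 0L) {
  cfg <- list(seed = as.integer(seed), strand = strand,
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              cryptic_exon_length = as.integer(cryptic_exon_length),
              cryptic_offset = as.integer(cryptic_offset),
              host_intron = as.integer(host_intron),
              ptc_frame_offset = as.integer(ptc_frame_offset),
              ptc_position = as.integer(ptc_position),
              ug_run_units = as.integer(ug_run_units),
              utr5_length = as.integer(utr5_length),
              exon_ordinals = as.integer(exon_ordinals),
              conditions = conditions, emit_minor = isTRUE(emit_minor),
              background_depth = as.integer(background_depth))
  stopifnot(strand %in% c("+", "-"),
            length(cfg$intron_lengths) == length(cfg$exon_lengths) - 1L,
            cfg$host_intron >= 1L,
            cfg$host_intron <= length(cfg$intron_lengths),
            all(c("condition", "true_psi", "n_replicates", "donor_depth")
                %in% names(conditions)),
            all(conditions$true_psi >= 0), all(conditions$true_psi <= 1),
            all(conditions$donor_depth > 0),
            cfg$ptc_frame_offset %in% 0:2)
  host_len <- cfg$intron_lengths[cfg$host_intron]
  # geometry: intron GT | ... AG | cassette | GT + 10 nt + UG tract ... AG
  tail_needed <- 2L + 10L + 2L * cfg$ug_run_units + 2L +
    (if (cfg$emit_minor) 60L else 0L)
  if (cfg$cryptic_offset < 4L ||
      cfg$cryptic_offset + cfg$cryptic_exon_length + tail_needed > host_len) {
    stop("cryptic segment does not fit in the host intron with the ",
         "required splice-site and UG-tract clearance")
  }
  if (cfg$ptc_position + 3L + cfg$ptc_frame_offset > cfg$cryptic_exon_length) {
    stop("ptc_position outside the cassette")
  }
  cds_nt <- sum(cfg$exon_lengths) - cfg$utr5_length
  structure(cfg, class = "sim_config")
}

#' Simulate the genome, annotation and truth geometry of a cryptic-exon locus
#'
#' Builds the locus in transcript orientation, then reverse-complements onto
#' the genome for minus-strand configurations. All annotated introns carry
#' canonical GT..AG ends in transcript orientation; the cassette is flanked
#' by its own AG acceptor and GT donor; a (UG)n tract starts 10 nt downstream
#' of the cassette donor on the transcribed strand. The annotation (two
#' transcripts: the full exon chain and a skip isoform joining exons 1 and 3
#' of the window) omits the cassette.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (DNAStringSet), `gene` ([gene_model()]), and
#'   `truth` (geometry: cassette interval, host intron, splice sites, PTC
#'   transcript offset for the inclusion chain, UG-tract interval, CDS span).
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ne <- length(config$exon_lengths)
  flank <- 60L
  # ---- build working (transcribed) strand ----
  # exon sequences with a stop-free ORF: UTR5 + ATG + codons ... stop in last
  # exon + UTR3
  exon_seq <- character(ne)
  cds_rem <- sum(config$exon_lengths) - config$utr5_length - 3L - 30L
  stopifnot(cds_rem %% 3L == 0L, cds_rem > 0L)
  # exon 1: utr5 | ATG | codons to exon end (exon1 CDS part must be multiple
  # of 3 for the cassette frame arithmetic; enforced here)
  e1_cds <- config$exon_lengths[1L] - config$utr5_length
  stopifnot(e1_cds %% 3L == 0L)
  exon_seq[1L] <- paste0(rand_bases(config$utr5_length), "ATG",
                         rand_codons(e1_cds - 3L))
  for (k in 2:(ne - 1L)) exon_seq[k] <- rand_codons(config$exon_lengths[k])
  last_cds <- config$exon_lengths[ne] - 30L - 3L
  stopifnot(last_cds %% 3L == 0L)
  exon_seq[ne] <- paste0(rand_codons(last_cds), "TAA", rand_bases(30L))
  # cassette: codons in the upstream frame, stop planted at ptc_position (+
  # frame offset); exon 1 CDS part is a codon multiple so the cassette enters
  # in frame 0
  ce_len <- config$cryptic_exon_length
  ce <- strsplit(paste0(rand_codons(3L * (ce_len %/% 3L)),
                        rand_bases(ce_len %% 3L)), "")[[1L]]
  p <- config$ptc_position + config$ptc_frame_offset
  ce[(p + 1L):(p + 3L)] <- strsplit("TAA", "")[[1L]]
  if (config$ptc_frame_offset > 0L) {
    # out-of-frame plant: scrub any frame-0 stop the overwrite created
    for (q in seq(0L, ce_len - 3L, by = 3L)) {
      cod <- paste(ce[(q + 1L):(q + 3L)], collapse = "")
      if (cod %in% STOP_CODONS && q != p) {
        keep <- intersect((q + 1L):(q + 3L), setdiff(seq_len(ce_len),
                                                     (p + 1L):(p + 3L)))
        ce[keep[1L]] <- "C"
      }
    }
  }
  ce_seq <- paste(ce, collapse = "")
  # introns: GT ... AG; host intron additionally AG|cassette|GT + UG tract
  intron_seq <- character(ne - 1L)
  ce_rel <- NA_integer_  # cassette start relative to host intron start
  ug_rel <- NA_integer_
  minor_rel <- integer()
  for (k in seq_len(ne - 1L)) {
    L <- config$intron_lengths[k]
    body <- strsplit(rand_bases(L), "")[[1L]]
    body[1:2] <- c("G", "T")
    body[(L - 1L):L] <- c("A", "G")
    if (k == config$host_intron) {
      off <- config$cryptic_offset
      body[(off - 1L):off] <- c("A", "G")            # cassette acceptor
      body[(off + 1L):(off + ce_len)] <- strsplit(ce_seq, "")[[1L]]
      body[(off + ce_len + 1L):(off + ce_len + 2L)] <- c("G", "T")  # donor
      ug_start <- off + ce_len + 2L + 10L
      ug <- rep(c("T", "G"), config$ug_run_units)
      body[(ug_start + 1L):(ug_start + length(ug))] <- ug
      ce_rel <- off
      ug_rel <- ug_start
      if (config$emit_minor) {
        m1 <- ug_start + 2L * config$ug_run_units + 10L
        m2 <- m1 + 20L
        body[(m1 + 1L):(m1 + 2L)] <- c("G", "T")
        body[(m2 + 1L):(m2 + 2L)] <- c("G", "T")
        minor_rel <- c(m1, m2)
      }
      # the cassette must not carry a spurious terminal AG/GT confusion; the
      # planted sites take precedence and the discovery stage is junction-led
    }
    intron_seq[k] <- paste(body, collapse = "")
  }
  working <- paste0(rand_bases(flank),
                    paste0(exon_seq[-ne],
                           intron_seq[seq_len(ne - 1L)], collapse = ""),
                    exon_seq[ne], rand_bases(flank))
  L <- nchar(working)
  # working-strand coordinates (0-based half-open)
  ex_start <- integer(ne); ex_end <- integer(ne)
  pos <- flank
  in_start <- integer(ne - 1L)
  for (k in seq_len(ne)) {
    ex_start[k] <- pos
    pos <- pos + config$exon_lengths[k]
    ex_end[k] <- pos
    if (k < ne) {
      in_start[k] <- pos
      pos <- pos + config$intron_lengths[k]
    }
  }
  host0 <- in_start[config$host_intron]
  ce_w <- c(host0 + ce_rel, host0 + ce_rel + ce_len)
  ug_w <- c(host0 + ug_rel, host0 + ug_rel + 2L * config$ug_run_units)
  minor_w <- host0 + minor_rel
  cds_w <- c(ex_start[1L] + config$utr5_length, ex_end[ne] - 30L)
  # ---- place on genome ----
  if (config$strand == "+") {
    genome_seq <- working
    w2g <- function(iv) iv            # [s,e) unchanged
  } else {
    genome_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(working)))
    w2g <- function(iv) c(L - iv[2L], L - iv[1L])
  }
  conv <- function(s, e) {
    iv <- w2g(c(s, e)); list(start = iv[1L], end = iv[2L])
  }
  exons_g <- do.call(rbind, lapply(seq_len(ne), function(k) {
    as.data.frame(conv(ex_start[k], ex_end[k]))
  }))
  ce_g <- conv(ce_w[1L], ce_w[2L])
  ug_g <- conv(ug_w[1L], ug_w[2L])
  host_g <- conv(host0, host0 + config$intron_lengths[config$host_intron])
  cds_g <- conv(cds_w[1L], cds_w[2L])
  minor_g <- if (length(minor_w)) {
    vapply(minor_w, function(m) if (config$strand == "+") m else L - m,
           numeric(1L))
  } else numeric()
  contig <- "chrSim"
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, contig))
  # transcripts: full chain + skip isoform (exon1 -> exon3 of the window)
  tx_order <- function(df) {
    o <- order(df$start)
    if (config$strand == "-") o <- rev(o)
    df[o, , drop = FALSE]
  }
  full_ex <- tx_order(exons_g)
  rownames(full_ex) <- NULL
  skip_idx <- setdiff(seq_len(ne), 2L)
  skip_ex <- tx_order(exons_g[skip_idx, , drop = FALSE])
  rownames(skip_ex) <- NULL
  ord_full <- config$exon_ordinals
  ord_skip <- config$exon_ordinals[skip_idx]
  gene <- gene_model(
    gene_id = "SIMG0001", gene_name = "NfascSim", contig = contig,
    strand = config$strand,
    transcripts = list(
      tx_full = list(transcript_id = "SIMT0001", exons = full_ex,
                     exon_number = ord_full, cds = unlist(cds_g,
                                                          use.names = FALSE)),
      tx_skip = list(transcript_id = "SIMT0002", exons = skip_ex,
                     exon_number = ord_skip, cds = NULL)))
  truth <- list(
    contig = contig, strand = config$strand,
    cryptic = gi(contig, ce_g$start, ce_g$end, config$strand),
    host_intron = gi(contig, host_g$start, host_g$end, config$strand),
    ug_tract = gi(contig, ug_g$start, ug_g$end, config$strand),
    cds = unlist(cds_g, use.names = FALSE),
    # inclusion-chain transcript offset of the planted stop (first base):
    # exon1 length + position within cassette
    ptc_tx = config$exon_lengths[1L] + config$ptc_position +
      config$ptc_frame_offset,
    minor_donor_ends = sort(minor_g),
    exon_ordinals = config$exon_ordinals,
    exons = exons_g[order(exons_g$start), , drop = FALSE])
  list(genome = genome, gene = gene, truth = truth)
}

# deterministic per-sample stream: mix master seed with a polynomial hash of
# the sample id so adding samples never perturbs existing ones
sample_stream_seed <- function(seed, sample_id) {
  h <- 0
  for (cp in utf8ToInt(sample_id)) h <- (h * 131 + cp) %% 2147483647
  as.integer((seed * 48271 + h) %% 2147483647)
}

# transcript-orientation junction endpoints -> genomic intron interval
.junction_iv <- function(d, a, strand) {
  if (strand == "+") c(d, a) else c(a, d)
}

#' Draw per-sample junction read counts for a simulated locus
#'
#' For each replicate, the inclusion count at the upstream donor is drawn
#' `Binomial(donor_depth, true_psi)`; the remaining reads go to the annotated
#' skip junction; the cassette-donor to downstream-acceptor exit junction
#' mirrors the inclusion count exactly (fully coupled two-junction
#' inclusion). Junctions with zero reads are not emitted, as in real
#' junction-extraction output. With `emit_minor`, each planted weak donor's
#' exit junction receives a count drawn uniformly from 1..4.
#'
#' @param config A [sim_config()].
#' @param locus Result of [simulate_locus()] for the same config.
#' @return List with `junctions` (data.frame in [read_junctions_bed()]
#'   layout) and `truth` (one row per sample: `sample_id`, `condition`,
#'   `true_psi`, `inclusion_count`, `exclusion_count`, cassette coordinates,
#'   `ptc_tx`).
#' @export
simulate_junction_counts <- function(config, locus = simulate_locus(config)) {
  tr <- locus$truth
  g <- locus$gene
  strand <- config$strand
  ex <- tr$exons                       # genomic-ascending annotated exons
  ne <- nrow(ex)
  # transcript-orientation boundary coordinates
  if (strand == "+") {
    don1 <- ex$end[1L]; acc2 <- ex$start[2L]
    acc3 <- ex$start[3L]
    ce_acc <- tr$cryptic$start; ce_don <- tr$cryptic$end
  } else {
    don1 <- ex$start[ne]; acc2 <- ex$end[ne - 1L]
    acc3 <- ex$end[ne - 2L]
    ce_acc <- tr$cryptic$end; ce_don <- tr$cryptic$start
  }
  jx_rows <- list(); truth_rows <- list()
  for (ci in seq_len(nrow(config$conditions))) {
    cond <- config$conditions$condition[ci]
    psi_true <- config$conditions$true_psi[ci]
    depth <- config$conditions$donor_depth[ci]
    for (r in seq_len(config$conditions$n_replicates[ci])) {
      sid <- sprintf("%s_rep%d", cond, r)
      set.seed(sample_stream_seed(config$seed, sid))
      incl <- stats::rbinom(1L, depth, psi_true)
      excl <- depth - incl
      add <- function(d, a, count) {
        if (count <= 0L) return()
        iv <- .junction_iv(d, a, strand)
        jx_rows[[length(jx_rows) + 1L]] <<- data.frame(
          contig = tr$contig, start = iv[1L], end = iv[2L], strand = strand,
          count = as.integer(count), sample_id = sid, condition = cond,
          name = sprintf("J%s_%d_%d", sid, iv[1L], iv[2L]),
          anchor1 = 8L, anchor2 = 8L)
      }
      add(don1, ce_acc, incl)          # entry: annotated donor -> cassette
      add(ce_don, acc3, incl)          # exit: cassette donor -> exon 3
      add(don1, acc3, excl)            # annotated skip junction
      if (config$background_depth > 0L) {
        # constant support for every consecutive annotated junction
        for (k in seq_len(ne - 1L)) {
          if (strand == "+") {
            add(ex$end[k], ex$start[k + 1L], config$background_depth)
          } else {
            add(ex$start[k + 1L], ex$end[k], config$background_depth)
          }
        }
      }
      if (config$emit_minor && length(tr$minor_donor_ends)) {
        for (md in tr$minor_donor_ends) {
          mdon <- if (strand == "+") md else md  # genomic GT position marker
          add(mdon, acc3, sample.int(4L, 1L))
        }
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample_id = sid, condition = cond, true_psi = psi_true,
        inclusion_count = incl, exclusion_count = excl,
        cryptic_start = tr$cryptic$start, cryptic_end = tr$cryptic$end,
        ptc_tx = tr$ptc_tx)
    }
  }
  jx <- if (length(jx_rows)) do.call(rbind, jx_rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), count = integer(),
               sample_id = character(), condition = character(),
               name = character(), anchor1 = integer(), anchor2 = integer())
  rownames(jx) <- NULL
  list(junctions = jx, truth = do.call(rbind, truth_rows))
}

#' Write a complete fixture bundle to disk
#'
#' Emits the genome FASTA, annotation GTF, one regtools-style junction BED
#' per sample, a CLIP-like peak BED covering the planted UG tract, the truth
#' TSV and a manifest (file, md5, seed echo). Re-running with the same
#' config reproduces the manifest checksums byte for byte.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return data.frame manifest (invisibly written to `manifest.tsv` too).
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  locus <- simulate_locus(config)
  sim <- simulate_junction_counts(config, locus)
  paths <- character()
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(locus$genome, fa)
  paths <- c(paths, fa)
  gtf <- file.path(outdir, "annotation.gtf")
  write_gtf(list(locus$gene), gtf)
  paths <- c(paths, gtf)
  for (sid in unique(sim$junctions$sample_id)) {
    p <- file.path(outdir, paste0(sid, ".junc.bed"))
    write_junctions_bed(sim$junctions[sim$junctions$sample_id == sid, ], p)
    paths <- c(paths, p)
  }
  pk <- file.path(outdir, "clip_peaks.synthetic.bed")
  ug <- locus$truth$ug_tract
  writeLines(sprintf("%s\t%d\t%d\tug_tract_peak\t%d\t%s", ug$contig,
                     max(0L, ug$start - 20L), ug$end + 20L, 100L, ug$strand),
             pk)
  paths <- c(paths, pk)
  tt <- file.path(outdir, "truth.tsv")
  write_report_tsv(sim$truth, tt)
  paths <- c(paths, tt)
  cfgp <- file.path(outdir, "config.txt")
  scal <- config[!vapply(config, is.data.frame, TRUE)]
  writeLines(c(paste0(names(scal), " = ",
                      vapply(scal, function(v) paste(v, collapse = ","), "")),
               paste0("conditions = ",
                      paste(apply(config$conditions, 1L, paste,
                                  collapse = ":"), collapse = ";"))), cfgp)
  paths <- c(paths, cfgp)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         seed = config$seed)
  write_report_tsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}
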
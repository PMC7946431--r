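## Donor-anchored percent spliced in (PSI) from junction counts, condition
## contrasts, and delta-delta-Cq relative quantification for RT-qPCR.

#' Competing junctions at an anchor splice site
#'
#' All acceptors reachable from a donor (or, with `anchor = "acceptor"`,
#' all donors feeding an acceptor) with per-sample counts.
#'
#' @param index Junction index from [build_junction_index()].
#' @param site Anchor coordinate (transcript-orientation boundary).
#' @param anchor `"donor"` (default; splice-acceptor usage questions) or
#'   `"acceptor"` (donor-usage questions, e.g. cassette extensions).
#' @return data.frame of class `"competition_set"` (subset of the index)
#'   with attributes `anchor_site` and `anchor_type`; empty with a warning
#'   when the site is absent.
#' @export
competing_junctions <- function(index, site, anchor = c("donor", "acceptor")) {
  anchor <- match.arg(anchor)
  col <- if (anchor == "donor") index$donor else index$acceptor
  sub <- index[col == site, , drop = FALSE]
  if (!nrow(sub)) {
    warning("anchor site ", site, " not present in junction index")
  }
  structure(as.data.frame(sub), class = c("competition_set", "data.frame"),
            anchor_site = site, anchor_type = anchor,
            gene = index_gene(index))
}

#' Percent spliced in for a target splice site
#'
#' PSI is the ratio of inclusion reads (reads spliced to the site of
#' interest) to the sum of inclusion and exclusion reads (reads spliced
#' from the same anchor to any other site). With the default
#' `pool_counts`, counts are summed across a condition's samples before
#' the ratio; `mean_of_samples` averages per-sample PSI instead (samples
#' with zero coverage at the anchor are dropped). PSI with a zero
#' denominator is undefined (`NA`), never 0 or 1.
#'
#' @param set A `"competition_set"` from [competing_junctions()].
#' @param target Coordinate of the target site (acceptor for a
#'   donor-anchored set).
#' @param pooling `"pool_counts"` (default) or `"mean_of_samples"`.
#' @return data.frame, one row per condition: `anchor`, `target`,
#'   `condition`, `inclusion`, `exclusion`, `psi`, `n_samples`, `pooling`.
#' @export
psi <- function(set, target, pooling = c("pool_counts", "mean_of_samples")) {
  pooling <- match.arg(pooling)
  anchor_site <- attr(set, "anchor_site", exact = TRUE)
  anchor_type <- attr(set, "anchor_type", exact = TRUE)
  tcol <- if (identical(anchor_type, "acceptor")) set$donor else set$acceptor
  if (!any(tcol == target)) {
    stop("target site ", target, " absent from the competition set ",
         "(distinct from an undefined PSI)")
  }
  conds <- sort(unique(set$condition))
  rows <- lapply(conds, function(cc) {
    sub <- set[set$condition == cc, , drop = FALSE]
    tc <- if (identical(anchor_type, "acceptor")) sub$donor else sub$acceptor
    samples <- unique(sub$sample_id)
    incl <- sum(sub$count[tc == target])
    excl <- sum(sub$count[tc != target])
    if (pooling == "pool_counts") {
      p <- if (incl + excl > 0L) incl / (incl + excl) else NA_real_
    } else {
      per <- vapply(samples, function(s) {
        i <- sum(sub$count[sub$sample_id == s & tc == target])
        e <- sum(sub$count[sub$sample_id == s & tc != target])
        if (i + e > 0L) i / (i + e) else NA_real_
      }, numeric(1L))
      per <- per[!is.na(per)]
      p <- if (length(per)) mean(per) else NA_real_
    }
    data.frame(anchor = anchor_site, target = target, condition = cc,
               inclusion = incl, exclusion = excl, psi = p,
               n_samples = length(samples), pooling = pooling)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PSI difference between two conditions
#'
#' @param a,b Single rows of the data.frame returned by [psi()], sharing
#'   anchor and target.
#' @return `psi(a) - psi(b)`; `NA` (undefined) propagates.
#' @export
delta_psi <- function(a, b) {
  if (a$anchor != b$anchor || a$target != b$target) {
    stop("delta PSI requires matching anchor and target")
  }
  a$psi - b$psi
}

#' Relative expression by the delta-delta-Cq method
#'
#' Per sample, `dCq = Cq_target - Cq_reference`; `ddCq` subtracts the mean
#' `dCq` of the calibrator condition (per target gene); the relative level
#' is `efficiency^(-ddCq)` with the canonical `efficiency = 2` (primer
#' efficiencies assumed ~100%, no correction). The geometric mean of
#' calibrator-condition levels is 1 by construction.
#'
#' @param records data.frame with columns `sample_id`, `condition`,
#'   `gene`, `cq_target`, `cq_reference`.
#' @param calibrator Condition used as the baseline (e.g. `"WT"`).
#' @param efficiency Amplification base, default 2.
#' @return data.frame with `dcq`, `ddcq`, `level` appended; samples missing
#'   a reference Cq are dropped with a warning.
#' @export
relative_expression_ddcq <- function(records, calibrator, efficiency = 2) {
  req <- c("sample_id", "condition", "gene", "cq_target", "cq_reference")
  stopifnot(all(req %in% names(records)))
  drop <- is.na(records$cq_reference) | is.na(records$cq_target)
  if (any(drop)) {
    warning(sum(drop), " sample(s) missing a Cq value; dropped")
    records <- records[!drop, , drop = FALSE]
  }
  if (!any(records$condition == calibrator)) {
    stop("no samples in calibrator condition '", calibrator, "'")
  }
  records$dcq <- records$cq_target - records$cq_reference
  out <- lapply(split(records, records$gene), function(gr) {
    cal_mean <- mean(gr$dcq[gr$condition == calibrator])
    gr$ddcq <- gr$dcq - cal_mean
    gr$level <- efficiency^(-gr$ddcq)
    gr
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$condition, res$sample_id), , drop = FALSE]
}
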
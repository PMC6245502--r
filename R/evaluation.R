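# Ground-truth assignment and demultiplexing metrics: confusion
# matrices, precision/recall in the binned-read sense, q-score
# stratification and consensus binning across demultiplexers.

#' Assign ground-truth labels from alignments
#'
#' Implements the amplicon ground-truthing rules: a read's label is its
#' primary (longest-alignment) reference, provided the primary alignment
#' covers at least `min(100, 0.10 * read_len)` bases of the read;
#' otherwise the read is `unknown`. A read whose alignment to any
#' secondary reference covers at least `max(50, 0.05 * read_len)` bases
#' is a cross-reference `chimera`. Secondary alignments to the primary
#' reference never trigger the chimera rule (within-reference chimeras
#' are undetectable this way). Reads listed in `read_ids` without any
#' alignment are `unknown`.
#'
#' @param paf A [read_paf()] data.frame.
#' @param read_ids Optional character vector of all read ids (to label
#'   unaligned reads); defaults to the reads present in `paf`.
#' @return `data.frame` with columns `read_id`, `label` (a reference id,
#'   `"unknown"` or `"chimera"`).
#' @export
assign_ground_truth <- function(paf, read_ids = NULL) {
  read_ids <- read_ids %||% unique(paf$read_id)
  labels <- rep("unknown", length(read_ids))
  names(labels) <- read_ids
  for (id in unique(paf$read_id)) {
    rows <- paf[paf$read_id == id, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    len <- rows$read_len[1]
    primary <- rows[1, ]
    if (primary$alignment_len_on_read < min(100, 0.10 * len)) next
    secondary <- rows[rows$target_id != primary$target_id, , drop = FALSE]
    if (nrow(secondary) > 0 &&
        any(secondary$alignment_len_on_read >= max(50, 0.05 * len))) {
      labels[id] <- "chimera"
    } else {
      labels[id] <- primary$target_id
    }
  }
  data.frame(read_id = read_ids, label = unname(labels[read_ids]),
             stringsAsFactors = FALSE)
}

#' Ground truth from simulation truth
#'
#' Maps a simulator truth table to ground-truth labels: barcoded reads
#' get their insert reference, cross-barcode chimeras `"chimera"`, and
#' barcode-less reads `"unknown"` (their barcode cannot be verified).
#'
#' @param truth Truth table from [simulate_library()].
#' @return `data.frame` with `read_id`, `label`.
#' @export
truth_to_ground_truth <- function(truth) {
  label <- ifelse(truth$is_chimera, "chimera",
                  ifelse(is.na(truth$barcode_id), "unknown",
                         truth$insert_source))
  data.frame(read_id = truth$read_id, label = label,
             stringsAsFactors = FALSE)
}

#' Score a demultiplexing run
#'
#' Computes the standard demultiplexing report: a truth x predicted
#' confusion matrix (including the none bin), the binned fraction over
#' all reads, precision (correctly assigned / binned, among reads with
#' known ground truth), recall (correctly assigned / all known-truth
#' reads), the 2.5th-97.5th percentile range of binned reads' mean
#' q-scores, and the fractions of unknown and chimeric reads that were
#' nevertheless binned.
#'
#' @param calls A [demultiplex()] calls table.
#' @param truths Ground-truth table ([assign_ground_truth()] /
#'   [truth_to_ground_truth()]); every call must have a truth record.
#' @param quals Optional data.frame with `read_id`, `mean_q` (e.g. from
#'   [read_fastq()]) for the q-score range.
#' @param ref_map Named character vector mapping barcode id to reference
#'   label (default `ref<barcode>`).
#' @return List of class `demux_report`.
#' @export
score_demux <- function(calls, truths, quals = NULL, ref_map = NULL) {
  missing <- setdiff(calls$read_id, truths$read_id)
  if (length(missing) > 0) {
    stopf("calls without ground truth: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  truth <- truths$label[match(calls$read_id, truths$read_id)]
  max_bc <- suppressWarnings(max(calls$final, na.rm = TRUE))
  if (!is.finite(max_bc)) max_bc <- 0L
  ref_map <- ref_map %||%
    stats::setNames(paste0("ref", seq_len(max(max_bc, 1))),
                    seq_len(max(max_bc, 1)))
  pred_ref <- ifelse(is.na(calls$final), "none",
                     unname(ref_map[as.character(calls$final)]))

  known <- !truth %in% c("unknown", "chimera")
  binned <- !is.na(calls$final)
  correct <- known & binned & pred_ref == truth

  n_known <- sum(known)
  n_binned_known <- sum(binned & known)
  precision <- if (n_binned_known == 0) {
    warnf("no known-truth reads were binned; precision undefined")
    NA_real_
  } else sum(correct) / n_binned_known
  recall <- if (n_known == 0) NA_real_ else sum(correct) / n_known

  q_range <- c(NA_real_, NA_real_)
  if (!is.null(quals) && any(binned)) {
    mq <- quals$mean_q[match(calls$read_id[binned], quals$read_id)]
    q_range <- unname(stats::quantile(mq, c(0.025, 0.975), na.rm = TRUE))
  }
  frac_of <- function(which_truth) {
    m <- truth == which_truth
    if (!any(m)) NA_real_ else sum(binned & m) / sum(m)
  }
  confusion <- table(truth = truth, predicted = pred_ref)
  structure(list(confusion = confusion,
                 n_reads = nrow(calls), n_known = n_known,
                 binned_fraction = sum(binned) / nrow(calls),
                 precision = precision, recall = recall,
                 q_range = q_range,
                 binned_unknown_fraction = frac_of("unknown"),
                 binned_chimeric_fraction = frac_of("chimera")),
            class = "demux_report")
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf("<demux_report: %d reads (%d known truth)>\n",
              x$n_reads, x$n_known))
  cat(sprintf("  binned %.1f%% | precision %.1f%% | recall %.1f%%\n",
              100 * x$binned_fraction, 100 * x$precision, 100 * x$recall))
  if (!is.na(x$q_range[1])) {
    cat(sprintf("  q-score range (2.5th-97.5th pct of binned): %.1f-%.1f\n",
                x$q_range[1], x$q_range[2]))
  }
  cat(sprintf("  binned unknown %.1f%% | binned chimeric %.1f%%\n",
              100 * x$binned_unknown_fraction,
              100 * x$binned_chimeric_fraction))
  invisible(x)
}

#' Precision and recall stratified by read q-score
#'
#' @param calls,truths,quals As in [score_demux()].
#' @param bin_edges Q-score bin edges (half-open bins, last bin closed).
#' @param ref_map As in [score_demux()].
#' @param min_reads Bins with fewer reads are flagged low-confidence.
#' @return `data.frame` with one row per bin: `q_lo`, `q_hi`, `n`,
#'   `precision`, `recall`, `low_confidence`.
#' @export
metrics_by_qscore <- function(calls, truths, quals,
                              bin_edges = seq(0, 30, by = 5),
                              ref_map = NULL, min_reads = 20) {
  mq <- quals$mean_q[match(calls$read_id, quals$read_id)]
  out <- data.frame(q_lo = utils::head(bin_edges, -1),
                    q_hi = utils::tail(bin_edges, -1),
                    n = 0L, precision = NA_real_, recall = NA_real_,
                    low_confidence = TRUE)
  for (i in seq_len(nrow(out))) {
    inbin <- mq >= out$q_lo[i] &
      (mq < out$q_hi[i] | (i == nrow(out) & mq <= out$q_hi[i]))
    out$n[i] <- sum(inbin, na.rm = TRUE)
    if (out$n[i] > 0) {
      rep_i <- suppressWarnings(
        score_demux(calls[inbin, , drop = FALSE], truths,
                    ref_map = ref_map))
      out$precision[i] <- rep_i$precision
      out$recall[i] <- rep_i$recall
    }
    out$low_confidence[i] <- out$n[i] < min_reads
  }
  out
}

#' Consensus binning across demultiplexers
#'
#' A read keeps its bin only when every calls table assigns it the same
#' (non-none) barcode; any disagreement or missing call sends it to the
#' none bin. The consensus binned set is therefore the intersection of
#' the inputs' binned sets, trading recall for precision.
#'
#' @param call_tables List of two or more calls tables over the same
#'   reads.
#' @return Calls-style `data.frame` with `read_id` and `final`.
#' @export
consensus_bins <- function(call_tables) {
  if (length(call_tables) < 2) stopf("need at least 2 call tables")
  ids <- call_tables[[1]]$read_id
  for (tab in call_tables[-1]) {
    if (!setequal(tab$read_id, ids)) {
      stopf("call tables cover different read sets")
    }
  }
  finals <- vapply(call_tables, function(tab) {
    tab$final[match(ids, tab$read_id)]
  }, integer(length(ids)))
  agree <- apply(finals, 1, function(v) {
    if (anyNA(v) || length(unique(v)) > 1) NA_integer_ else v[1]
  })
  data.frame(read_id = ids, final = as.integer(agree),
             stringsAsFactors = FALSE)
}
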
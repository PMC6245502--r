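# Read classification: windowing, probability merging across windows,
# the probability-gap calling rule, start/end combination with chimera
# detection, and whole-library demultiplexing.

#' Window scheme configuration
#'
#' The barcode signal usually sits in the first 1024 samples of a read,
#' but long open-pore stretches can push it further in, so several
#' overlapping windows are examined: `n_windows` windows of
#' `window_len` samples offset by `stride` (defaults 11 x 1024 with
#' stride 512, spanning 6144 samples).
#'
#' @param window_len Window length in samples.
#' @param stride Offset between consecutive windows; must not exceed
#'   `window_len`.
#' @param n_windows Maximum number of windows examined per read end.
#' @return A list of class `window_config` with the derived `span`.
#' @export
window_config <- function(window_len = 1024, stride = 512, n_windows = 11) {
  if (stride > window_len) stopf("stride must not exceed window_len")
  structure(list(window_len = window_len, stride = stride,
                 n_windows = n_windows,
                 span = window_len + (n_windows - 1) * stride),
            class = "window_config")
}

#' Extract classification windows from a read signal
#'
#' Cuts up to `n_windows` half-open windows `[i*stride, i*stride +
#' window_len)` from the read start; for `end = "end"` the trailing span
#' is reversed first (the orientation the end model is trained on) and
#' windows are cut from the reversed signal. Reads shorter than one
#' window yield zero windows. Each window is z-normalised independently,
#' so windows that still contain open-pore remnants do not skew the
#' scale of the others.
#'
#' @param values Numeric read signal (open-pore trimmed).
#' @param end `"start"` or `"end"`.
#' @param config A [window_config()].
#' @return Matrix with one window per row (possibly 0 rows).
#' @export
extract_windows <- function(values, end = c("start", "end"),
                            config = window_config()) {
  end <- match.arg(end)
  L <- length(values)
  if (end == "end") {
    span <- min(L, config$span)
    values <- rev(values[(L - span + 1):L])
    L <- span
  }
  offs <- (seq_len(config$n_windows) - 1L) * config$stride
  offs <- offs[offs + config$window_len <= min(L, config$span)]
  if (length(offs) == 0) return(matrix(numeric(0), 0, config$window_len))
  out <- matrix(0, length(offs), config$window_len)
  for (i in seq_along(offs)) {
    out[i, ] <- suppressWarnings(
      znormalize(values[(offs[i] + 1):(offs[i] + config$window_len)]))
  }
  out
}

#' Merge per-window class probabilities
#'
#' Combines the probability rows of all windows of one read end:
#' each barcode class keeps its maximum across windows (the windows are
#' alternative locations for the barcode, so the best-scoring window is
#' the evidence that counts), the no-barcode class keeps its minimum
#' (no-barcode is supported only when no window shows a barcode), and
#' the result is renormalised to sum to 1. Permutation-invariant in the
#' rows and the identity on a single row.
#'
#' @param rows Matrix of class probabilities, one row per window; the
#'   last column is the no-barcode class.
#' @return Named numeric vector of merged probabilities.
#' @export
merge_window_probs <- function(rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  if (nrow(rows) == 0) stopf("no probability rows to merge")
  mx <- apply(rows, 2, max)
  mx[length(mx)] <- min(rows[, ncol(rows)])
  mx / sum(mx)
}

#' Probability-gap barcode call
#'
#' Assigns the arg-max barcode only when its probability exceeds the
#' second-highest probability by strictly more than `gap_threshold` and
#' the arg-max class is not the no-barcode class; otherwise no call is
#' made. At a gap of exactly the threshold the call is none.
#'
#' @param probs Class probability vector (last class = no-barcode).
#' @param gap_threshold Required probability gap (default 0.5).
#' @return Integer barcode id, or `NA` for none.
#' @export
call_barcode <- function(probs, gap_threshold = 0.5) {
  ord <- order(probs, decreasing = TRUE)
  best <- ord[1]
  gap <- probs[best] - probs[ord[2]]
  no_barcode <- length(probs)
  if (best == no_barcode || gap <= gap_threshold) return(NA_integer_)
  as.integer(best)
}

#' Combine start- and end-of-read calls
#'
#' Default mode bins a read when either end gives a call, flags reads
#' whose two ends give different barcodes as chimeras (binned as none);
#' stringent mode requires both ends to agree on the same barcode;
#' start-only mode ignores the end call.
#'
#' @param start_call,end_call Integer barcode ids or `NA` (none).
#' @param mode `"default"`, `"stringent"` or `"start_only"`.
#' @return List with `final_bin` (integer or `NA`) and `chimera_flag`.
#' @export
combine_ends <- function(start_call, end_call,
                         mode = c("default", "stringent", "start_only")) {
  mode <- match.arg(mode)
  if (mode == "start_only") {
    return(list(final_bin = start_call, chimera_flag = FALSE))
  }
  s <- start_call
  e <- end_call
  if (mode == "stringent") {
    ok <- !is.na(s) && !is.na(e) && s == e
    return(list(final_bin = if (ok) s else NA_integer_,
                chimera_flag = FALSE))
  }
  if (!is.na(s) && !is.na(e) && s != e) {
    return(list(final_bin = NA_integer_, chimera_flag = TRUE))
  }
  final <- if (!is.na(s)) s else e
  list(final_bin = final, chimera_flag = FALSE)
}

#' Demultiplex a set of reads
#'
#' Full signal-space classification: each read is open-pore trimmed,
#' windowed at both ends, classified window-by-window, merged
#' (max-then-renormalise), called with the probability-gap rule and
#' combined across ends. Reads too short for a single window are
#' assigned none.
#'
#' @param squiggles List of [squiggle] objects.
#' @param model_start Trained model for read-start windows.
#' @param model_end Trained model for read-end windows; required unless
#'   `mode = "start_only"`.
#' @param mode `"default"`, `"stringent"` or `"start_only"`.
#' @param wconfig A [window_config()].
#' @param gap_threshold Probability gap for [call_barcode()].
#' @param trim_threshold Open-pore trim cutoff (NULL = robust per-read
#'   cutoff, see [trim_open_pore()]).
#' @param out_dir Optional directory: per-bin signal files plus
#'   `calls.tsv` are written there.
#' @param verbose Attach the merged per-end probability matrices as
#'   attributes `start_probs` / `end_probs`.
#' @param chunk_size Reads classified per prediction batch.
#' @return `data.frame` with one row per read: `read_id`, `start_call`,
#'   `end_call`, `final` (integer barcode or `NA` = none bin) and
#'   `chimera`.
#' @export
demultiplex <- function(squiggles, model_start, model_end = NULL,
                        mode = c("default", "stringent", "start_only"),
                        wconfig = window_config(), gap_threshold = 0.5,
                        trim_threshold = NULL, out_dir = NULL,
                        verbose = FALSE, chunk_size = 100) {
  mode <- match.arg(mode)
  if (mode != "start_only" && is.null(model_end)) {
    stopf("mode '%s' requires an end model", mode)
  }
  n <- length(squiggles)
  ends <- if (mode == "start_only") "start" else c("start", "end")
  calls <- data.frame(read_id = vapply(squiggles, function(s) s$read_id,
                                       character(1)),
                      start_call = NA_integer_, end_call = NA_integer_,
                      final = NA_integer_, chimera = FALSE,
                      stringsAsFactors = FALSE)
  nc <- model_start$config$n_classes
  sp <- matrix(NA_real_, n, nc)
  ep <- matrix(NA_real_, n, nc)

  for (chunk in split(seq_len(n), ceiling(seq_len(n) / chunk_size))) {
    for (side in ends) {
      model <- if (side == "start") model_start else model_end
      wins <- vector("list", length(chunk))
      for (k in seq_along(chunk)) {
        v <- trim_open_pore(squiggles[[chunk[k]]]$values,
                            threshold = trim_threshold, ends = "both")
        wins[[k]] <- extract_windows(v, end = side, config = wconfig)
      }
      counts <- vapply(wins, nrow, integer(1))
      if (sum(counts) > 0) {
        probs <- predict_probs(model, do.call(rbind, wins))
        at <- 0
        for (k in seq_along(chunk)) {
          if (counts[k] == 0) next
          merged <- merge_window_probs(probs[at + seq_len(counts[k]), ,
                                             drop = FALSE])
          at <- at + counts[k]
          cl <- call_barcode(merged, gap_threshold)
          i <- chunk[k]
          if (side == "start") {
            calls$start_call[i] <- cl
            sp[i, ] <- merged
          } else {
            calls$end_call[i] <- cl
            ep[i, ] <- merged
          }
        }
      }
    }
  }
  for (i in seq_len(n)) {
    r <- combine_ends(calls$start_call[i], calls$end_call[i], mode)
    calls$final[i] <- r$final_bin
    calls$chimera[i] <- r$chimera_flag
  }
  if (verbose) {
    colnames(sp) <- colnames(ep) <- class_labels(nc - 1L)
    attr(calls, "start_probs") <- sp
    attr(calls, "end_probs") <- ep
  }
  if (!is.null(out_dir)) write_bins(squiggles, calls, out_dir)
  calls
}

# Per-bin output directories plus calls.tsv; the none bin collects
# unclassified and chimeric reads.
write_bins <- function(squiggles, calls, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bins <- ifelse(is.na(calls$final), "none",
                 paste0("barcode", sprintf("%02d", calls$final)))
  for (b in unique(bins)) {
    bd <- file.path(out_dir, b)
    dir.create(bd, showWarnings = FALSE)
    write_raw_signal(squiggles[bins == b], file.path(bd, "signals.txt"))
  }
  write_calls(calls, file.path(out_dir, "calls.tsv"))
  invisible(out_dir)
}

#' Write / read a calls table
#'
#' Tab-separated `read_id  start_call  end_call  final  chimera`, with
#' `none` for unassigned calls.
#'
#' @param calls A [demultiplex()] result.
#' @param path TSV path.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  for (col in c("start_call", "end_call", "final")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "none", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("start_call", "end_call", "final")) {
    df[[col]] <- suppressWarnings(as.integer(ifelse(df[[col]] == "none",
                                                    NA, df[[col]])))
  }
  df
}
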
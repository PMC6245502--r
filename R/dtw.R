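# Semi-global dynamic time warping: subsequence search in signal space.
# The expected (template) signal for a barcode construct must align
# end-to-end, while the read signal has free, unpenalised ends — this
# locates short known elements (adapters, barcodes) inside long reads.

#' Semi-global DTW between a template and a read signal
#'
#' Aligns `template` end-to-end against any contiguous stretch of `read`
#' with unpenalised read prefix/suffix. The local distance is `|a - b|`
#' and the step pattern is the symmetric three-step (diagonal, advance
#' template, advance read) without slope weighting. Both signals should
#' be z-normalised before alignment.
#'
#' @param template Numeric template signal (must not be longer than the
#'   read).
#' @param read Numeric read signal.
#' @return A list of class `dtw_result`: `cost` (path-summed local
#'   distance), `read_start`/`read_end` (matched interval, 0-based
#'   half-open), `norm_cost` (cost per template sample) and `path`
#'   (matrix of 1-based (template, read) index pairs covering every
#'   template index, monotone in both coordinates).
#' @export
semiglobal_dtw <- function(template, read) {
  if (length(template) == 0 || length(read) == 0) {
    stopf("template and read must be non-empty")
  }
  if (length(template) > length(read)) {
    stopf("template (%d) longer than read (%d)",
          length(template), length(read))
  }
  res <- cpp_semiglobal_dtw(as.numeric(template), as.numeric(read))
  res$norm_cost <- res$cost / length(template)
  class(res) <- "dtw_result"
  res
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result: cost %.4g (%.4g/sample), read interval [%d, %d)>\n",
              x$cost, x$norm_cost, x$read_start, x$read_end))
  invisible(x)
}

#' Locate a barcode signal inside a read
#'
#' Runs semi-global DTW of every barcode template against the read
#' signal and reports the best-scoring barcode, provided the match is
#' "clear": its cost per template sample must beat `cost_threshold`
#' *and* the matched read interval must have a physically plausible
#' duration, between `len_ratio[1]` and `len_ratio[2]` times the
#' template length. The duration gate is what rejects featureless
#' signal: warping lets any template align into pure noise at a
#' moderate cost, but only by compressing drastically — noise matches
#' of a ~315-sample construct template typically span under a quarter
#' of its length, whereas a genuine construct passage at ~9
#' samples/base spans 0.7-1.1 times it. Reads without a clear match
#' return no call — only clear instances should be used to harvest
#' training labels.
#'
#' Templates must be in pore-model units ([barcode_templates()]): model
#' levels are already standardised (mean 0, sd 1 across k-mers), and
#' re-normalising a single 40 bp template by its own 35-level sample sd
#' would distort its amplitude relative to the read. The read is
#' z-normalised internally, after trimming leading open-pore signal
#' (the reported interval is in the original read coordinates).
#'
#' @param read_signal Numeric read signal (raw; trimmed and
#'   z-normalised internally).
#' @param templates Named list of model-unit templates (names = barcode
#'   ids) from [barcode_templates()].
#' @param cost_threshold Maximum normalised cost for a clear match
#'   (default 0.30, in z-units per template sample; calibrated on
#'   simulated positives and negatives).
#' @param len_ratio Admissible matched-interval length as a fraction of
#'   the template length (default 0.6-2: dwell variation rarely
#'   compresses or stretches a passage beyond these bounds, while noise
#'   matches compress far below the lower one).
#' @param search_len Restrict the search to this many samples after the
#'   trimmed read start (NULL = whole read); barcode signals sit near
#'   the read ends, so a bounded search is much faster.
#' @param trim Trim leading open-pore signal before matching.
#' @return `NULL` when no clear match exists, else a list with
#'   `barcode_id`, `interval` (0-based half-open, original read
#'   coordinates), `norm_cost` and `margin` (cost gap to the runner-up
#'   template, informational).
#' @export
locate_barcode <- function(read_signal, templates, cost_threshold = 0.30,
                           len_ratio = c(0.6, 2), search_len = NULL,
                           trim = TRUE) {
  if (length(templates) == 0) stopf("no barcode templates supplied")
  offset <- 0L
  if (trim) {
    offset <- leading_open_pore_run(read_signal)
    read_signal <- read_signal[(offset + 1):length(read_signal)]
  }
  if (!is.null(search_len)) {
    read_signal <- read_signal[seq_len(min(search_len, length(read_signal)))]
  }
  read_z <- znormalize(read_signal)
  costs <- rep(Inf, length(templates))
  best <- NULL
  best_len <- 0L
  for (k in seq_along(templates)) {
    tm <- templates[[k]]
    if (length(tm) > length(read_z)) next
    r <- semiglobal_dtw(tm, read_z)
    costs[k] <- r$norm_cost
    if (is.null(best) || r$norm_cost < best$norm_cost) {
      best <- list(barcode_id = names(templates)[k],
                   interval = c(r$read_start, r$read_end) + offset,
                   norm_cost = r$norm_cost)
      best_len <- (r$read_end - r$read_start) / length(tm)
    }
  }
  if (is.null(best) || best$norm_cost >= cost_threshold) return(NULL)
  if (best_len < len_ratio[1] || best_len > len_ratio[2]) return(NULL)
  best$margin <- if (length(templates) > 1) {
    sort(costs)[2] - best$norm_cost
  } else NA_real_
  best
}

#' Build DTW templates for a barcode set
#'
#' Noise-free expected signals of the 40 bp constructs, in pore-model
#' units (not re-normalised; see [locate_barcode()]).
#'
#' @param barcodes A [barcode_set()].
#' @param model A [build_pore_model()].
#' @return Named list of expected-signal templates, one per barcode.
#' @export
barcode_templates <- function(barcodes, model) {
  out <- lapply(barcodes$construct, sequence_to_expected_signal,
                model = model)
  names(out) <- as.character(barcodes$barcode_id)
  out
}
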
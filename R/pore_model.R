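# Synthetic k-mer pore model and squiggle synthesis.
#
# A pore model maps every k-mer that can occupy the pore to an expected
# current level. The simulator works in normalised current units: k-mer
# levels are drawn from a standard normal, so the inter-k-mer level
# spread is 1 and all noise magnitudes are expressed relative to it.

#' Build a synthetic pore model
#'
#' Assigns every one of the `4^k` k-mers an expected current level drawn
#' from a standard normal distribution, plus a per-sample measurement
#' noise sd. Levels are deterministic for a fixed `(k, seed)` pair and
#' their spread (sd 1) keeps distinct k-mers distinguishable above the
#' default noise.
#'
#' @param k K-mer size (nanopore R9-style pores read ~6 bases at once).
#' @param seed Integer seed for the level table.
#' @param noise_sd Per-sample Gaussian measurement noise sd, in units of
#'   the inter-k-mer level spread (default 0.25).
#' @param dwell_mean Mean samples per base: sampling rate / translocation
#'   speed, 4000/450 ~ 8.9 samples/base by default.
#' @return Object of class `pore_model`.
#' @export
build_pore_model <- function(k = 6, seed = 101, noise_sd = 0.25,
                             dwell_mean = 4000 / 450) {
  if (k < 1) stopf("k must be >= 1")
  if (dwell_mean <= 0) stopf("dwell_mean must be positive")
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  levels <- with_seed(seed, stats::rnorm(length(kmers)))
  names(levels) <- kmers
  structure(list(k = k, levels = levels, noise_sd = noise_sd,
                 dwell_mean = dwell_mean, seed = seed),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model k=%d (%d k-mers), noise sd %.3g, dwell %.3g samples/base>\n",
              x$k, length(x$levels), x$noise_sd, x$dwell_mean))
  invisible(x)
}

# Expected current level for each base of `seq`: the level of the k-mer
# starting at that base, clamped at the last complete k-mer so every base
# contributes one level.
base_levels <- function(seq, model) {
  n <- nchar(seq)
  if (n < model$k) stopf("sequence shorter than k = %d", model$k)
  starts <- pmin(seq_len(n), n - model$k + 1L)
  kmers <- substring(seq, starts, starts + model$k - 1L)
  unname(model$levels[kmers])
}

#' Noise-free expected signal for a sequence
#'
#' Converts a base sequence into its idealised squiggle: one current
#' level per k-mer window, each repeated `dwell` times. These expected
#' signals are the templates used by semi-global DTW to locate adapters
#' and barcodes inside read signals.
#'
#' @param seq Base sequence (length >= k).
#' @param model A [build_pore_model()] object.
#' @param dwell Integer samples per level; defaults to the model's
#'   rounded mean dwell.
#' @return Numeric vector of length `(nchar(seq) - k + 1) * dwell`.
#' @export
sequence_to_expected_signal <- function(seq, model, dwell = NULL) {
  dwell <- dwell %||% round(model$dwell_mean)
  n <- nchar(seq)
  if (n < model$k) stopf("sequence shorter than k = %d", model$k)
  starts <- seq_len(n - model$k + 1L)
  kmers <- substring(seq, starts, starts + model$k - 1L)
  rep(unname(model$levels[kmers]), each = dwell)
}

#' Simulate a noisy squiggle for a sequence
#'
#' Each base dwells in the pore for a random number of samples (shifted
#' geometric, minimum 1, mean `dwell_mean`), then i.i.d. Gaussian
#' measurement noise is added per sample. At the default 4000/450
#' samples/base a 40 bp barcode construct yields a signal in the typical
#' 250-600 sample range.
#'
#' @param seq Base sequence.
#' @param model A [build_pore_model()] object.
#' @param seed Optional seed (NULL = caller's RNG stream).
#' @param noise_sd Per-sample noise sd; defaults to the model's.
#' @return Numeric vector of simulated current samples.
#' @export
simulate_squiggle <- function(seq, model, seed = NULL, noise_sd = NULL) {
  noise_sd <- noise_sd %||% model$noise_sd
  with_seed(seed, {
    lv <- base_levels(seq, model)
    # shifted geometric with mean dwell_mean: 1 + Geom(p), p = 1/dwell_mean
    dwell <- 1L + stats::rgeom(length(lv), prob = 1 / model$dwell_mean)
    sig <- rep(lv, times = dwell)
    sig + stats::rnorm(length(sig), sd = noise_sd)
  })
}
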
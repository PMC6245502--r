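# Shared fixtures, built once per test run and memoised. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Toy single-base pore model with known levels, handy for hand-checkable
# expected signals.
toy_model <- function() {
  pm <- build_pore_model(k = 1, seed = 1)
  pm$levels <- c(A = -1, C = 0, G = 1, T = 2)
  pm
}

# A small 4-barcode library at the simulator's default noise.
small_lib <- function() {
  memo("small_lib", function() {
    simulate_library(120, barcodes = barcode_set(4), seed = 77)
  })
}

# A clear-signal (low measurement noise) 12-barcode library for DTW
# localisation tests: the regime in which barcode signals are "clear"
# enough to harvest training labels from.
clean_lib <- function() {
  memo("clean_lib", function() {
    simulate_library(30, barcodes = barcode_set(12),
                     model = build_pore_model(noise_sd = 0.1),
                     noise_mult_range = c(1, 1), error_range = c(0.02, 0.05),
                     no_barcode_rate = 0, chimera_rate = 0, seed = 88)
  })
}

# Brute-force semi-global DTW oracle: recursive enumeration of all
# monotone alignments with free read ends. Exponential; only for tiny
# instances.
brute_dtw_cost <- function(template, read) {
  m <- length(template)
  n <- length(read)
  best <- Inf
  # cost of the best alignment currently at (i, j), having just matched
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible(NULL))
    if (i == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    # advance both / template only / read only
    if (j < n) rec(i + 1, j + 1, acc + abs(template[i + 1] - read[j + 1]))
    rec(i + 1, j, acc + abs(template[i + 1] - read[j]))
    if (j < n) rec(i, j + 1, acc + abs(template[i] - read[j + 1]))
    invisible(NULL)
  }
  for (j0 in seq_len(n)) {
    rec(1, j0, abs(template[1] - read[j0]))
  }
  best
}

# Separable synthetic window set for network/refinement tests: each
# class is a distinct smooth waveform plus noise, at a configurable
# window length so small-model tests stay fast.
separable_set <- function(n_per_class, n_classes = 4, window_len = 128,
                          noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    templates <- lapply(seq_len(n_classes), function(k) {
      cumsum(stats::rnorm(window_len))
    })
    n <- n_per_class * n_classes
    X <- matrix(0, n, window_len)
    labels <- rep(seq_len(n_classes), each = n_per_class)
    for (i in seq_len(n)) {
      X[i, ] <- znormalize(templates[[labels[i]]] +
                             stats::rnorm(window_len, sd = noise_sd))
    }
    ord <- sample.int(n)
    training_set(X[ord, , drop = FALSE], labels[ord], n_classes,
                 provenance = rep("synthetic", n))
  })
}
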
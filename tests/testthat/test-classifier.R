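# Read classification rules: the window scheme, max-then-renormalise
# merging, the probability-gap call, start/end combination and the
# structural guarantees of demultiplexing.

test_that("the default window scheme covers 6144 samples in 11 windows", {
  wc <- window_config()
  expect_equal(wc$span, 6144)
  W <- extract_windows(rnorm(6144) + 10, config = wc)
  expect_equal(nrow(W), 11)
  # the window offsets are 0, 512, ..., 5120, and a longer read still
  # yields only n_windows windows
  v <- as.numeric(seq_len(8000))
  Wi <- extract_windows(v, config = wc)
  expect_equal(nrow(Wi), 11)
  expect_equal(Wi[11, ], znormalize(v[5121:6144]))
})

test_that("short reads yield only the windows that fit", {
  expect_equal(nrow(extract_windows(rnorm(2000))), 2)
  expect_equal(nrow(extract_windows(rnorm(1000))), 0)
  expect_equal(nrow(extract_windows(rnorm(1024))), 1)
  # window offsets follow i * stride
  v <- as.numeric(seq_len(2000))
  W <- extract_windows(v, config = window_config())
  expect_equal(W[1, ], znormalize(v[1:1024]))
  expect_equal(W[2, ], znormalize(v[513:1536]))
  # end windows are cut from the reversed trailing span
  We <- extract_windows(v, end = "end")
  expect_equal(We[1, ], znormalize(rev(v)[1:1024]))
})

test_that("window probabilities merge by max then renormalise", {
  rows <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(merge_window_probs(rows), c(0.4375, 0.5, 0.0625))
  one <- c(0.3, 0.45, 0.25)
  expect_equal(merge_window_probs(matrix(one, 1)), one)
  withr::with_seed(51, {
    for (i in 1:10) {
      R <- matrix(runif(5 * 13), 5)
      R <- R / rowSums(R)
      m <- merge_window_probs(R)
      expect_equal(sum(m), 1)
      expect_equal(merge_window_probs(R[sample(5), ]), m)
    }
  })
  expect_error(merge_window_probs(matrix(numeric(0), 0, 13)), "no probability")
})

test_that("the probability-gap rule requires a strict >0.5 margin", {
  p <- function(...) {
    v <- c(...)
    c(v, rep((1 - sum(v)) / (13 - length(v)), 13 - length(v)))
  }
  probs <- rep(0.05 / 10, 13)
  probs[3] <- 0.90
  probs[13] <- 0.05
  expect_equal(call_barcode(probs / sum(probs)), 3L)

  probs <- c(0.60, 0.35, rep(0.05 / 11, 11))
  expect_true(is.na(call_barcode(probs)))          # gap 0.25

  probs <- c(rep(0.05 / 12, 12), 0.95)
  expect_true(is.na(call_barcode(probs)))          # best is no-barcode

  # boundary: gap of exactly 0.5 is not enough
  probs <- c(0.75, 0.25, rep(0, 11))
  expect_true(is.na(call_barcode(probs)))
  probs <- c(0.76, 0.24, rep(0, 11))
  expect_equal(call_barcode(probs), 1L)
  # exact tie between two maxima is never called
  probs <- c(0.5, 0.5, rep(0, 11))
  expect_true(is.na(call_barcode(probs)))
})

test_that("start/end combination follows the either/both/chimera rules", {
  expect_equal(combine_ends(3L, 3L, "default"),
               list(final_bin = 3L, chimera_flag = FALSE))
  expect_equal(combine_ends(3L, NA_integer_, "default"),
               list(final_bin = 3L, chimera_flag = FALSE))
  expect_equal(combine_ends(NA_integer_, 5L, "default"),
               list(final_bin = 5L, chimera_flag = FALSE))
  expect_equal(combine_ends(3L, 7L, "default"),
               list(final_bin = NA_integer_, chimera_flag = TRUE))
  expect_equal(combine_ends(NA_integer_, NA_integer_, "default"),
               list(final_bin = NA_integer_, chimera_flag = FALSE))

  expect_equal(combine_ends(3L, NA_integer_, "stringent"),
               list(final_bin = NA_integer_, chimera_flag = FALSE))
  expect_equal(combine_ends(3L, 3L, "stringent"),
               list(final_bin = 3L, chimera_flag = FALSE))
  expect_equal(combine_ends(3L, 7L, "stringent"),
               list(final_bin = NA_integer_, chimera_flag = FALSE))

  expect_equal(combine_ends(NA_integer_, 7L, "start_only"),
               list(final_bin = NA_integer_, chimera_flag = FALSE))
  expect_equal(combine_ends(2L, 7L, "start_only"),
               list(final_bin = 2L, chimera_flag = FALSE))
  expect_error(combine_ends(1L, 1L, "both"), "arg")
})

test_that("demultiplexing assigns every read to exactly one bin", {
  lib <- small_lib()
  model <- build_model(desk_network_config(5), seed = 61)
  out_dir <- withr::local_tempdir()
  calls <- demultiplex(lib$squiggles[1:40], model, model,
                       out_dir = out_dir, verbose = TRUE)
  expect_equal(nrow(calls), 40)
  expect_true(all(is.na(calls$final) | calls$final %in% 1:4))
  expect_true(all(!calls$chimera | is.na(calls$final)))
  # bin directories partition the reads
  binned <- read_calls(file.path(out_dir, "calls.tsv"))
  expect_equal(nrow(binned), 40)
  bin_dirs <- list.dirs(out_dir, recursive = FALSE)
  n_per_bin <- vapply(bin_dirs, function(d) {
    length(read_raw_signal(file.path(d, "signals.txt")))
  }, numeric(1))
  expect_equal(sum(n_per_bin), 40)
  # verbose probabilities are valid distributions
  sp <- attr(calls, "start_probs")
  expect_equal(dim(sp), c(40, 5))
  expect_equal(rowSums(sp), rep(1, 40), tolerance = 1e-6)
  # a read shorter than one window is assigned none
  short <- list(squiggle("tiny", rnorm(500)))
  expect_true(is.na(demultiplex(short, model, model)$final))
  expect_error(demultiplex(short, model, NULL, mode = "default"),
               "requires an end model")

  # stringent mode is exactly the both-end recombination of the same
  # per-end calls
  calls_str <- demultiplex(lib$squiggles[1:40], model, model,
                           mode = "stringent")
  recomb <- mapply(function(s, e) combine_ends(s, e, "stringent")$final_bin,
                   calls$start_call, calls$end_call)
  expect_equal(calls_str$final, as.integer(recomb))
})
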
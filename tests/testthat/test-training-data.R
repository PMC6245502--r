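# Training-window extraction, no-barcode classes, temporal-distortion
# augmentation, set assembly and cross-split refinement.

test_that("extracted windows always contain the barcode interval", {
  withr::with_seed(41, {
    values <- rnorm(5000)
    W <- extract_training_windows(values, c(300, 700), n_windows = 8,
                                  seed = 1)
    expect_equal(dim(W), c(8, 1024))
    starts <- attr(W, "starts")
    expect_true(all(starts <= 300))
    expect_true(all(starts + 1024 >= 700))
    # jitter: different seeds give different offsets, same containment
    W2 <- extract_training_windows(values, c(300, 700), n_windows = 8,
                                   seed = 2)
    expect_false(identical(attr(W2, "starts"), starts))
    # window content is the z-normalised slice of the read
    s <- starts[1]
    expect_equal(W[1, ], znormalize(values[(s + 1):(s + 1024)]))
    # read-end windows are reversed
    We <- extract_training_windows(values, c(4000, 4400), end = "end",
                                   n_windows = 1, seed = 3)
    s <- attr(We, "starts")[1]
    expect_equal(We[1, ], znormalize(rev(values[(s + 1):(s + 1024)])))
  })
})

test_that("degenerate reads and intervals are skipped with a warning", {
  expect_warning(W <- extract_training_windows(rnorm(900), c(100, 500)),
                 "shorter than window")
  expect_equal(nrow(W), 0)
  expect_warning(W <- extract_training_windows(rnorm(3000), c(100, 1500)),
                 "exceeds window")
  expect_equal(nrow(W), 0)
})

test_that("no-barcode samples follow the requested subtype mix", {
  flat_only <- make_no_barcode_samples(50, mix = c(flat = 1), seed = 1)
  expect_equal(dim(flat_only), c(50, 1024))
  expect_true(all(flat_only == 0))  # z-normalised flat signal is all zeros

  nb <- make_no_barcode_samples(600, seed = 2)
  expect_equal(dim(nb), c(600, 1024))
  counts <- table(factor(attr(nb, "subtype"),
                         levels = c("read", "adapter", "flat", "gaussian",
                                    "perlin")))
  p <- stats::chisq.test(counts,
                         p = c(0.3, 0.2, 0.1, 0.2, 0.2))$p.value
  expect_gt(p, 0.01)
  expect_error(make_no_barcode_samples(10, mix = c(flat = 0.5)), "sum to 1")
})

test_that("temporal distortion preserves length and value multiset", {
  withr::with_seed(42, {
    for (i in 1:10) {
      x <- rnorm(sample(c(64, 100, 1024), 1))
      y <- augment_signal(x, seed = i)
      expect_length(y, length(x))
      expect_false(identical(y, x))
      # only duplication/deletion: no new values
      expect_true(all(y %in% x))
      # duplicated values appear at most twice
      expect_true(all(table(match(y, x)) <= 2))
      # first-order amplitude statistics preserved
      expect_lt(abs(mean(y) - mean(x)), 3 * stats::sd(x) / sqrt(length(x)))
    }
  })
  x <- rnorm(100)
  expect_identical(augment_signal(x, distortion = 0), x)
})

test_that("set assembly injects no-barcode samples at the stated fraction", {
  withr::with_seed(43, {
    ext <- training_set(matrix(rnorm(300 * 1024), 300),
                        sample(1:4, 300, replace = TRUE), 5)
    set <- assemble_training_set(ext, no_barcode_fraction = 0.25, seed = 1)
    expect_equal(nrow(set$X), 400)
    expect_equal(unname(class_counts(set)["no_barcode"]), 100)

    aug <- assemble_training_set(ext, no_barcode_fraction = 0.25,
                                 augmentation_factor = 2, seed = 1)
    expect_equal(nrow(aug$X), 800)
    noaug <- assemble_training_set(ext, no_barcode_fraction = 0,
                                   augmentation_factor = 1, seed = 1)
    expect_equal(nrow(noaug$X), 300)
    expect_error(assemble_training_set(
      training_set(matrix(numeric(0), 0, 16), integer(0), 5)),
      "no extracted samples")
  })
})

test_that("harvested training sets track the simulator's class balance", {
  lib <- small_lib()
  ext <- harvest_training_windows(lib$squiggles, end = "start",
                                  truth = lib$truth, n_classes = 5,
                                  seed = 9)
  expect_true(all(ext$labels %in% 1:5))
  n_bc <- sum(!is.na(lib$truth$barcode_id))
  # two barcode-labelled windows per barcoded read, plus the read-derived
  # no-barcode windows
  expect_equal(sum(ext$labels < 5), 2 * n_bc)
  expect_equal(sum(ext$labels == 5),
               sum(ext$provenance == "read_negative"))
  expect_gt(sum(ext$labels == 5), 0)
  # per-barcode window counts match the simulated assignment (uniform)
  counts <- table(factor(ext$labels[ext$labels < 5], levels = 1:4))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  expect_true(all(abs(rowMeans(ext$X)) < 1e-9))

  # no harvest route at all is an error
  expect_error(harvest_training_windows(lib$squiggles[1]), "truth table")
})

test_that("cross-split refinement returns a subset and keeps clean data", {
  set <- separable_set(40, n_classes = 4, window_len = 128, seed = 3)
  refined <- refine_by_cross_split(set, n_folds = 4, seed = 4)
  expect_lte(nrow(refined$X), nrow(set$X))
  expect_equal(nrow(refined$X) + attr(refined, "discarded"), nrow(set$X))
  # every retained row existed in the input
  key <- function(M) apply(M, 1, function(r) paste(head(r, 8), collapse = ","))
  expect_true(all(key(refined$X) %in% key(set$X)))
  # a separable set is nearly fully retained
  expect_gte(nrow(refined$X) / nrow(set$X), 0.95)
})

test_that("training sets round-trip through the on-disk format", {
  set <- separable_set(5, n_classes = 3, window_len = 32, seed = 6)
  prefix <- file.path(withr::local_tempdir(), "ts")
  write_training_set(set, prefix)
  back <- read_training_set(prefix, 3)
  expect_equal(back$labels, set$labels)
  expect_equal(back$X, set$X, tolerance = 1e-10)
})
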
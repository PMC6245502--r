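# Squiggle and library simulation: pore model, expected signals, dwell
# calibration, composition rates and the no-barcode signal generators.

test_that("pore model covers all k-mers and is seed-deterministic", {
  expect_length(build_pore_model(k = 1, seed = 3)$levels, 4)
  m6 <- build_pore_model(k = 6, seed = 3)
  expect_length(m6$levels, 4096)
  expect_identical(m6$levels, build_pore_model(k = 6, seed = 3)$levels)
  expect_false(identical(m6$levels, build_pore_model(k = 6, seed = 4)$levels))
})

test_that("expected signal repeats one level per k-mer window", {
  pm <- toy_model()
  expect_equal(sequence_to_expected_signal("ACG", pm, dwell = 2),
               c(-1, -1, 0, 0, 1, 1))
  expect_length(sequence_to_expected_signal("ACGT", pm, dwell = 9), 36)
  s1 <- sequence_to_expected_signal("ACGTACGT", build_pore_model(seed = 9, k = 3))
  s2 <- sequence_to_expected_signal("ACGTACGT", build_pore_model(seed = 9, k = 3))
  expect_identical(s1, s2)
  expect_error(sequence_to_expected_signal("AC", build_pore_model(k = 6)),
               "shorter than k")
})

test_that("simulated dwell matches the 4 kHz / 450 b/s sampling regime", {
  pm <- build_pore_model()
  seq100 <- paste(rep("ACGT", 25), collapse = "")
  lens <- vapply(1:300, function(i) {
    length(simulate_squiggle(seq100, pm, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(lens) - 100 * 4000 / 450), 0.05 * 100 * 4000 / 450)

  bs <- barcode_set()
  clens <- vapply(1:200, function(i) {
    length(simulate_squiggle(bs$construct[1 + (i %% 12)], pm, seed = i))
  }, numeric(1))
  expect_gte(mean(clens), 250)
  expect_lte(mean(clens), 600)

  expect_identical(simulate_squiggle("ACGTACGT", pm, seed = 11),
                   simulate_squiggle("ACGTACGT", pm, seed = 11))
})

test_that("barcode constructs are 24 bp cores with 8 bp flanks", {
  bs <- barcode_set()
  expect_equal(nrow(bs), 12)
  expect_true(all(nchar(bs$core_seq) == 24))
  expect_true(all(nchar(bs$left_flank) == 8))
  expect_true(all(nchar(bs$right_flank) == 8))
  expect_true(all(construct_length(bs) == 40))
  expect_equal(anyDuplicated(bs$core_seq), 0)
})

test_that("library composition follows the requested rates", {
  bcs <- barcode_set(4)
  lib0 <- simulate_library(60, barcodes = bcs, chimera_rate = 0,
                           no_barcode_rate = 0, seed = 1)
  expect_false(any(lib0$truth$is_chimera))
  expect_false(anyNA(lib0$truth$barcode_id))

  libn <- simulate_library(40, barcodes = bcs, no_barcode_rate = 1,
                           chimera_rate = 0, seed = 2)
  expect_true(all(is.na(libn$truth$barcode_id)))

  expect_error(simulate_library(10, barcodes = bcs, no_barcode_rate = 0.9,
                                chimera_rate = 0.2, seed = 3),
               "sum to")

  # chimera count binomially consistent with n * rate
  lib <- simulate_library(1000, barcodes = bcs, chimera_rate = 0.003,
                          no_barcode_rate = 0, seed = 4)
  n_chim <- sum(lib$truth$is_chimera)
  expect_gte(n_chim, 0)
  expect_lte(n_chim, qbinom(0.9999, 1000, 0.003))

  # per-barcode fractions within binomial tolerance of uniform assignment
  counts <- table(factor(lib$truth$barcode_id, levels = 1:4))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("truth intervals delimit the barcode constructs in the signal", {
  lib <- small_lib()
  tr <- lib$truth
  for (i in which(!is.na(tr$barcode_id))) {
    L <- length(lib$squiggles[[i]]$values)
    expect_lt(tr$start_from[i], tr$start_to[i])
    expect_lte(tr$end_to[i], L)
    expect_lt(tr$end_from[i], tr$end_to[i])
    # interval length consistent with a 40 bp construct's typical signal
    expect_gt(tr$start_to[i] - tr$start_from[i], 100)
    expect_lt(tr$start_to[i] - tr$start_from[i], 1024)
  }
  # determinism of the whole library
  lib2 <- simulate_library(120, barcodes = barcode_set(4), seed = 77)
  expect_identical(lib2$squiggles[[7]]$values, lib$squiggles[[7]]$values)
  expect_identical(lib2$truth, lib$truth)
})

test_that("library files round-trip through the on-disk formats", {
  lib <- small_lib()
  dir <- withr::local_tempdir()
  write_sim_library(lib, dir)
  back <- read_raw_signal(file.path(dir, "signals.txt"))
  expect_length(back, nrow(lib$truth))
  expect_identical(back[[3]]$values, lib$squiggles[[3]]$values)
  tr <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(tr$barcode_id, lib$truth$barcode_id)
  fq <- read_fastq(file.path(dir, "reads.fastq"))
  expect_equal(fq$read_id, lib$reads$read_id)
  expect_equal(fq$mean_q, lib$reads$mean_q, tolerance = 1e-6)
})

test_that("no-barcode signal generators have their defining properties", {
  expect_equal(stats::var(gen_flat(1024)), 0)
  expect_identical(gen_gaussian(100, seed = 5), gen_gaussian(100, seed = 5))

  p <- gen_perlin(4096, seed = 3, scale = 64)
  expect_true(all(abs(p) <= 1))
  expect_equal(p[seq(1, 4096, by = 64)], rep(0, 64))
  g <- gen_gaussian(4096, seed = 3)
  lag1 <- function(x) stats::cor(x[-1], x[-length(x)])
  expect_gt(lag1(p), lag1(g))
  expect_gt(lag1(p), 0.9)   # coherent noise is smooth, not white
})
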
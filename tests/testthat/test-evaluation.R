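# Ground-truth assignment thresholds, the binned/precision/recall metric
# definitions, q-score stratification and consensus binning.

paf_row <- function(id, len, target, aln, rank) {
  data.frame(read_id = id, read_len = len, target_id = target,
             alignment_len_on_read = aln, rank = rank,
             stringsAsFactors = FALSE)
}

test_that("ground truth follows the min(100, 10%) / max(50, 5%) rules", {
  paf <- rbind(
    paf_row("a", 2000, "refA", 150, 1),               # passes min(100, 200)
    paf_row("b", 500, "refB", 40, 1),                 # fails min(100, 50)
    paf_row("c", 1000, "refA", 800, 1),               # chimera via secondary
    paf_row("c", 1000, "refB", 60, 2),                #   60 >= max(50, 50)
    paf_row("d", 1000, "refA", 800, 1),               # secondary too short
    paf_row("d", 1000, "refB", 40, 2),
    paf_row("e", 4000, "refC", 900, 1),               # within-ref secondary
    paf_row("e", 4000, "refC", 700, 2))
  gt <- assign_ground_truth(paf, read_ids = c("a", "b", "c", "d", "e", "f"))
  lab <- setNames(gt$label, gt$read_id)
  expect_equal(unname(lab["a"]), "refA")
  expect_equal(unname(lab["b"]), "unknown")
  expect_equal(unname(lab["c"]), "chimera")
  expect_equal(unname(lab["d"]), "refA")
  expect_equal(unname(lab["e"]), "refC")   # same-reference secondary ignored
  expect_equal(unname(lab["f"]), "unknown") # no alignments at all
  # pure function: identical output on identical input
  expect_identical(gt, assign_ground_truth(paf,
                                           read_ids = c("a", "b", "c", "d",
                                                        "e", "f")))
})

test_that("simulation truth maps onto ground-truth labels", {
  lib <- small_lib()
  gt <- truth_to_ground_truth(lib$truth)
  expect_equal(nrow(gt), nrow(lib$truth))
  is_bc <- !is.na(lib$truth$barcode_id)
  expect_true(all(grepl("^ref", gt$label[is_bc])))
  expect_true(all(gt$label[lib$truth$is_chimera] == "chimera"))
})

test_that("score_demux reproduces hand-computed precision and recall", {
  # 20 known-truth reads; 18 binned, 17 of them correctly
  calls <- data.frame(read_id = sprintf("r%02d", 1:20),
                      final = c(rep(1L, 9), rep(2L, 9), NA, NA),
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = sprintf("r%02d", 1:20),
                      label = c(rep("ref1", 9), rep("ref2", 8), "ref1",
                                "ref1", "ref2"),
                      stringsAsFactors = FALSE)
  rep_ <- score_demux(calls, truth)
  expect_equal(rep_$precision, 17 / 18)
  expect_equal(rep_$recall, 17 / 20)
  expect_equal(rep_$binned_fraction, 18 / 20)
  expect_equal(sum(rep_$confusion), 20)
  expect_equal(unname(rep_$confusion["ref1", "ref1"]), 9)
  # the single error: a truth-ref1 read (r18) predicted as barcode 2
  expect_equal(unname(rep_$confusion["ref1", "ref2"]), 1)

  # perfect assignment
  perfect <- calls[1:9, ]
  rep_p <- score_demux(perfect, truth)
  expect_equal(rep_p$precision, 1)
  expect_equal(rep_p$recall, 1)

  # nothing binned: precision undefined, with a warning
  none <- data.frame(read_id = "r01", final = NA_integer_)
  expect_warning(rep_n <- score_demux(none, truth), "undefined")
  expect_true(is.na(rep_n$precision))
  expect_equal(rep_n$binned_fraction, 0)

  # calls without any truth record are an error
  expect_error(score_demux(data.frame(read_id = "zz", final = 1L), truth),
               "zz")
})

test_that("q-score range and unknown/chimeric fractions are tracked", {
  calls <- data.frame(read_id = c("a", "b", "c", "d"),
                      final = c(1L, 1L, NA, 2L))
  truth <- data.frame(read_id = c("a", "b", "c", "d"),
                      label = c("ref1", "unknown", "chimera", "chimera"))
  quals <- data.frame(read_id = c("a", "b", "c", "d"),
                      mean_q = c(10, 8, 12, 6))
  rep_ <- score_demux(calls, truth, quals = quals)
  expect_equal(rep_$binned_unknown_fraction, 1)
  expect_equal(rep_$binned_chimeric_fraction, 0.5)
  expect_equal(rep_$q_range,
               unname(quantile(c(10, 8, 6), c(0.025, 0.975))))
})

test_that("a single q bin reproduces the overall metrics", {
  calls <- data.frame(read_id = sprintf("r%02d", 1:20),
                      final = c(rep(1L, 9), rep(2L, 9), NA, NA))
  truth <- data.frame(read_id = sprintf("r%02d", 1:20),
                      label = c(rep("ref1", 9), rep("ref2", 8), "ref1",
                                "ref1", "ref2"))
  quals <- data.frame(read_id = sprintf("r%02d", 1:20),
                      mean_q = runif(20, 5, 15))
  tab <- metrics_by_qscore(calls, truth, quals, bin_edges = c(0, 20))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$precision, 17 / 18)
  expect_equal(tab$recall, 17 / 20)
  expect_false(tab$low_confidence)
  # empty bins are emitted with zero counts
  tab2 <- metrics_by_qscore(calls, truth, quals,
                            bin_edges = c(0, 20, 30))
  expect_equal(tab2$n[2], 0)
  expect_true(is.na(tab2$precision[2]))
  expect_true(tab2$low_confidence[2])
})

test_that("consensus binning is the agreement intersection", {
  t1 <- data.frame(read_id = c("a", "b", "c"), final = c(3L, NA, 5L))
  expect_equal(consensus_bins(list(t1, t1))$final, t1$final)
  t2 <- data.frame(read_id = c("a", "b", "c"), final = c(3L, 2L, 7L))
  cons <- consensus_bins(list(t1, t2))
  expect_equal(cons$final, c(3L, NA, NA))
  # consensus binned set is a subset of each input's binned set
  expect_true(all(which(!is.na(cons$final)) %in% which(!is.na(t1$final))))
  expect_true(all(which(!is.na(cons$final)) %in% which(!is.na(t2$final))))
  expect_error(consensus_bins(list(t1)), "at least 2")
  t3 <- data.frame(read_id = c("a", "b"), final = c(1L, 1L))
  expect_error(consensus_bins(list(t1, t3)), "different read sets")
})
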
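# Library simulation: whole reads with known barcode ground truth.
#
# Each simulated read mimics a native-barcoding 1D library molecule in
# signal space:
#   open-pore pad | adapter | flank+core+flank | insert | flank+core+flank
#   | adapter | open-pore pad
# Barcode-less reads omit the constructs; cross-barcode chimeras join two
# inserts from different barcodes (start barcode from one, end barcode
# from the other). A matching base-space FASTQ with a per-read error rate
# tied to the read's signal noise is emitted so q-score-stratified
# evaluation can be exercised.

# Fixed 30 bp stand-in for the sequencing adapter.
default_adapter <- function() "ATGCTAAGGTTAACCGTACCTTCGTGCAGG"

#' Synthetic reference sequences
#'
#' One random reference ("amplicon") per barcode, used as read inserts.
#'
#' @param n Number of references.
#' @param length Reference length in bases.
#' @param seed Integer seed.
#' @return Named character vector (`ref1`..`refn`).
#' @export
make_references <- function(n, length = 500, seed = 23) {
  with_seed(seed, {
    refs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
    names(refs) <- paste0("ref", seq_len(n))
    refs
  })
}

#' Simulate a barcoded nanopore library
#'
#' Generates `n_reads` squiggles with known per-read truth: the barcode
#' (or none), the exact sample intervals of the start/end barcode
#' constructs, the insert's source reference and a chimera flag. Each
#' read draws a quality factor that scales both its signal noise and its
#' base-space error rate, so low-q reads are genuinely harder in both
#' spaces.
#'
#' @param n_reads Number of reads.
#' @param barcodes A [barcode_set()].
#' @param model A [build_pore_model()].
#' @param references Named character vector of insert sequences, one per
#'   barcode (default: [make_references()] of matching size).
#' @param negative_references Insert sequences for barcode-less reads
#'   (each read samples one). In a real experiment the negative control
#'   is a separate barcode-less library of unrelated, diverse DNA, so
#'   these reads must not carry a barcode-associated insert (that would
#'   let a classifier identify "their" barcode from the insert alone).
#'   Default: four independent random references.
#' @param no_barcode_rate Fraction of reads carrying no barcode.
#' @param chimera_rate Fraction of cross-barcode chimeric reads.
#' @param barcode_props Barcode assignment proportions (default uniform).
#' @param pad_range Leading open-pore pad length range, samples.
#' @param trail_pad_range Trailing open-pore pad length range, samples.
#' @param noise_mult_range Per-read signal-noise multiplier range applied
#'   to the model's noise sd. The default `c(1, 1)` keeps every read at
#'   the model's per-sample noise sd (0.25 of the level spread); widen
#'   it (e.g. `c(1, 2.5)`) to couple signal noise to read quality for
#'   q-score-stratified evaluation.
#' @param error_range Per-read base-space substitution rate range (the
#'   per-read rate always tracks the read's quality factor, so mean
#'   q-scores vary even at a fixed signal noise).
#' @param open_pore_level Open-pore current level (model levels have sd 1).
#' @param seed Integer seed; the whole library is reproducible from it.
#' @return A list of class `sim_library` with elements `squiggles` (list
#'   of [squiggle]), `reads` (FASTQ-style data.frame with `read_id`,
#'   `sequence`, `quals`, `mean_q`) and `truth` (data.frame with
#'   `read_id`, `barcode_id`, `insert_source`, `is_chimera`, `start_from`,
#'   `start_to`, `end_from`, `end_to`; intervals are 0-based half-open
#'   sample ranges of the barcode constructs).
#' @export
simulate_library <- function(n_reads,
                             barcodes = barcode_set(),
                             model = build_pore_model(),
                             references = NULL,
                             negative_references = NULL,
                             no_barcode_rate = 0.05,
                             chimera_rate = 0.003,
                             barcode_props = NULL,
                             pad_range = c(50, 2000),
                             trail_pad_range = c(50, 500),
                             noise_mult_range = c(1, 1),
                             error_range = c(0.02, 0.20),
                             open_pore_level = 5,
                             seed = NULL) {
  rates <- c(no_barcode_rate, chimera_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stopf("no_barcode_rate and chimera_rate must lie in [0,1] and sum to <= 1")
  }
  nb <- nrow(barcodes)
  references <- references %||% make_references(nb, seed = 23)
  if (length(references) < nb) stopf("need one reference per barcode")
  negative_references <- negative_references %||%
    make_references(4, length = nchar(references[[1]]), seed = 29)
  names(negative_references) <- paste0("neg", seq_along(negative_references))
  props <- barcode_props %||% rep(1 / nb, nb)
  props <- props / sum(props)
  adapter <- default_adapter()

  with_seed(seed, {
    sqs <- vector("list", n_reads)
    seqs <- character(n_reads)
    quals <- vector("list", n_reads)
    truth <- data.frame(read_id = sprintf("read_%05d", seq_len(n_reads)),
                        barcode_id = NA_integer_,
                        insert_source = NA_character_,
                        is_chimera = FALSE,
                        start_from = NA_real_, start_to = NA_real_,
                        end_from = NA_real_, end_to = NA_real_,
                        stringsAsFactors = FALSE)

    for (i in seq_len(n_reads)) {
      u <- stats::runif(1)
      kind <- if (u < no_barcode_rate) "none"
              else if (u < no_barcode_rate + chimera_rate) "chimera"
              else "barcoded"
      f <- stats::runif(1)   # quality factor: 0 = clean, 1 = noisy
      nsd <- model$noise_sd *
        (noise_mult_range[1] + f * diff(noise_mult_range))
      err <- error_range[1] + f * diff(error_range)

      pad_n <- round(stats::runif(1, pad_range[1], pad_range[2]))
      trail_n <- round(stats::runif(1, trail_pad_range[1], trail_pad_range[2]))
      pad <- open_pore_level + stats::rnorm(pad_n, sd = 0.2)
      trail <- open_pore_level + stats::rnorm(trail_n, sd = 0.2)
      sim <- function(s) simulate_squiggle(s, model, noise_sd = nsd)

      if (kind == "barcoded") {
        b <- sample.int(nb, 1, prob = props)
        ins_seq <- references[[b]]
        parts <- list(pad, sim(adapter), sim(barcodes$construct[b]),
                      sim(ins_seq), sim(barcodes$construct[b]),
                      sim(adapter), trail)
        base_seq <- paste0(adapter, barcodes$construct[b], ins_seq,
                           barcodes$construct[b], adapter)
        truth$barcode_id[i] <- b
        truth$insert_source[i] <- names(references)[b]
      } else if (kind == "chimera") {
        ab <- sample.int(nb, 2)
        parts <- list(pad, sim(adapter), sim(barcodes$construct[ab[1]]),
                      sim(references[[ab[1]]]), sim(references[[ab[2]]]),
                      sim(barcodes$construct[ab[2]]), sim(adapter), trail)
        base_seq <- paste0(adapter, barcodes$construct[ab[1]],
                           references[[ab[1]]], references[[ab[2]]],
                           barcodes$construct[ab[2]], adapter)
        truth$is_chimera[i] <- TRUE
        truth$insert_source[i] <- paste(names(references)[ab], collapse = "+")
      } else {
        k <- sample.int(length(negative_references), 1)
        parts <- list(pad, sim(adapter), sim(negative_references[[k]]),
                      sim(adapter), trail)
        base_seq <- paste0(adapter, negative_references[[k]], adapter)
        truth$insert_source[i] <- names(negative_references)[k]
      }

      lens <- vapply(parts, length, integer(1))
      offs <- cumsum(c(0, lens))
      if (kind != "none") {
        bc_pos <- if (kind == "chimera") c(3L, 6L) else c(3L, 5L)
        truth$start_from[i] <- offs[bc_pos[1]]
        truth$start_to[i] <- offs[bc_pos[1] + 1L]
        truth$end_from[i] <- offs[bc_pos[2]]
        truth$end_to[i] <- offs[bc_pos[2] + 1L]
      }
      sqs[[i]] <- squiggle(truth$read_id[i], unlist(parts, use.names = FALSE),
                           source = "simulated")

      # base-space copy with uniform substitutions at the read's error rate
      bases <- strsplit(base_seq, "")[[1]]
      hit <- stats::runif(length(bases)) < err
      if (any(hit)) {
        bases[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      }
      seqs[i] <- paste(bases, collapse = "")
      q_true <- -10 * log10(err)
      quals[[i]] <- pmax(1L, as.integer(round(
        q_true + stats::rnorm(length(bases), sd = 2))))
    }

    reads <- data.frame(read_id = truth$read_id, sequence = seqs,
                        quals = I(quals),
                        mean_q = vapply(quals, mean_qscore, numeric(1)),
                        stringsAsFactors = FALSE)
    structure(list(squiggles = sqs, reads = reads, truth = truth,
                   barcodes = barcodes, model = model,
                   references = references),
              class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library: %d reads, %d barcodes (%d barcode-less, %d chimeric)>\n",
              nrow(x$truth), nrow(x$barcodes),
              sum(is.na(x$truth$barcode_id) & !x$truth$is_chimera),
              sum(x$truth$is_chimera)))
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Emits `signals.txt` (plain-text raw signal), `reads.fastq` and
#' `truth.tsv` under `dir`.
#'
#' @param lib A [simulate_library()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raw_signal(lib$squiggles, file.path(dir, "signals.txt"))
  write_fastq(lib$reads$read_id, lib$reads$sequence, lib$reads$quals,
              file.path(dir, "reads.fastq"))
  write_truth(lib$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Write / read a simulation truth table
#'
#' Tab-separated, one row per read, with the 0-based half-open barcode
#' construct intervals.
#'
#' @param truth Truth data.frame as produced by [simulate_library()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
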
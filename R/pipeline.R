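# End-to-end pipeline: simulate -> prep -> train -> classify -> evaluate,
# driven by a single JSON-serialisable run configuration with one global
# seed from which every stage seed is derived.

#' Run configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param n_reads Simulated library size.
#' @param n_barcodes Barcode count.
#' @param no_barcode_rate,chimera_rate Library composition rates.
#' @param n_windows_per_read Training windows harvested per read end.
#' @param no_barcode_fraction No-barcode fraction of the training sets.
#' @param refine Run cross-split refinement on the training sets.
#' @param epochs,samples_per_epoch,augmentation_factor Training settings
#'   (see [train_config()]).
#' @param mode Demultiplexing mode (see [demultiplex()]).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("squiggleplex_run_"),
                       seed = 42, n_reads = 2000, n_barcodes = 12,
                       no_barcode_rate = 0.05, chimera_rate = 0.003,
                       n_windows_per_read = 2,
                       no_barcode_fraction = 0.45, refine = FALSE,
                       epochs = 14, samples_per_epoch = 5000,
                       augmentation_factor = 2,
                       mode = "default") {
  structure(list(out_dir = out_dir, seed = seed, n_reads = n_reads,
                 n_barcodes = n_barcodes,
                 no_barcode_rate = no_barcode_rate,
                 chimera_rate = chimera_rate,
                 n_windows_per_read = n_windows_per_read,
                 no_barcode_fraction = no_barcode_fraction,
                 refine = refine, epochs = epochs,
                 samples_per_epoch = samples_per_epoch,
                 augmentation_factor = augmentation_factor,
                 mode = mode),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The JSON round trip is lossless, so a configuration can be stored
#' next to its results and re-run later.
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Harvest labelled training windows from a read set
#'
#' Labels come either from a simulation truth table (exact barcode
#' intervals) or, for real reads, from semi-global DTW localisation
#' against the barcode templates.
#'
#' @param squiggles List of [squiggle] objects.
#' @param end `"start"` or `"end"`.
#' @param truth Simulation truth table (preferred when available).
#' @param templates [barcode_templates()] list for DTW labelling (used
#'   when `truth` is NULL).
#' @param cost_threshold DTW normalised-cost threshold for a clear match.
#' @param search_len Samples searched from the relevant read end for the
#'   DTW route.
#' @param n_windows,window_len,seed See [extract_training_windows()].
#' @param neg_per_read Expected number of no-barcode windows harvested
#'   per read from the read's own non-barcode regions (open-pore
#'   boundary, adapter, insert and partial-barcode signal): these
#'   confounders are what the classifier sees in most deployment
#'   windows, so the no-barcode class must be trained on them.
#' @param n_classes Total class count (barcodes + 1).
#' @return A [training_set()] of labelled windows (barcode classes plus
#'   read-derived no-barcode windows).
#' @export
harvest_training_windows <- function(squiggles, end = c("start", "end"),
                                     truth = NULL, templates = NULL,
                                     cost_threshold = 0.4,
                                     search_len = 4000,
                                     n_windows = 2, window_len = 1024,
                                     neg_per_read = 1,
                                     n_classes = 13, seed = NULL) {
  end <- match.arg(end)
  if (is.null(truth) && is.null(templates)) {
    stopf("need either a truth table or DTW templates")
  }
  Xs <- list()
  labels <- integer(0)
  with_seed(seed, {
    for (sq in squiggles) {
      if (!is.null(truth)) {
        row <- truth[truth$read_id == sq$read_id, , drop = FALSE]
        if (nrow(row) == 0) next
        if (is.na(row$barcode_id)) {
          # barcode-less read: its whole signal is no-barcode material.
          # Every deployment window of such a read must read as
          # no-barcode, so sample twice as many windows as for a
          # barcode-labelled read, anywhere along the read.
          if (!row$is_chimera && length(sq$values) >= window_len) {
            L <- length(sq$values)
            starts <- sample.int(L - window_len + 1L, 2L * n_windows,
                                 replace = TRUE) - 1L
            W <- t(vapply(starts, function(s) {
              w <- sq$values[(s + 1):(s + window_len)]
              if (end == "end") w <- rev(w)
              suppressWarnings(znormalize(w))
            }, numeric(window_len)))
            Xs[[length(Xs) + 1]] <- W
            labels <- c(labels, rep(n_classes, nrow(W)))
          }
          next
        }
        ivl <- if (end == "start") c(row$start_from, row$start_to)
               else c(row$end_from, row$end_to)
        label <- row$barcode_id
      } else {
        L <- length(sq$values)
        if (end == "start") {
          loc <- locate_barcode(sq$values, templates, cost_threshold,
                                search_len = search_len)
          if (is.null(loc)) next
          ivl <- loc$interval
        } else {
          off <- max(0L, L - search_len)
          seg <- sq$values[(off + 1):L]
          # drop the trailing open-pore run before matching
          tail_run <- leading_open_pore_run(rev(seg))
          if (tail_run >= length(seg)) next
          seg <- seg[seq_len(length(seg) - tail_run)]
          loc <- locate_barcode(seg, templates, cost_threshold)
          if (is.null(loc)) next
          ivl <- loc$interval + off
        }
        label <- as.integer(loc$barcode_id)
      }
      W <- suppressWarnings(
        extract_training_windows(sq$values, ivl, end = end,
                                 n_windows = n_windows,
                                 window_len = window_len))
      if (nrow(W) > 0) {
        Xs[[length(Xs) + 1]] <- W
        labels <- c(labels, rep(label, nrow(W)))
      }
      # no-barcode windows from the same read, away from the barcode
      n_neg <- stats::rbinom(1, 1, min(1, neg_per_read)) +
        floor(max(0, neg_per_read - 1))
      if (n_neg > 0 && length(sq$values) >= window_len) {
        N <- negative_windows(sq$values, ivl, n_neg, window_len, end)
        if (nrow(N) > 0) {
          Xs[[length(Xs) + 1]] <- N
          labels <- c(labels, rep(n_classes, nrow(N)))
        }
      }
    }
  })
  if (length(Xs) == 0) {
    return(training_set(matrix(numeric(0), 0, window_len), integer(0),
                        n_classes, end = end, provenance = character(0)))
  }
  prov <- ifelse(labels == n_classes, "read_negative", "extracted")
  training_set(do.call(rbind, Xs), labels, n_classes, end = end,
               provenance = prov)
}

# No-barcode windows from a barcoded read. Deployment windows slide at
# a fixed stride, so the classifier constantly sees windows that
# overlap the barcode only partially; those must be trained as
# no-barcode (only full containment identifies a barcode — the window
# scheme guarantees some window fully contains it). Half the negatives
# are therefore drawn from the partial-overlap band (25-90% of the
# barcode inside the window), half from far regions (open-pore
# boundary, adapter, insert; overlap < 25%). Orientation matches the
# requested read end.
negative_windows <- function(values, ivl, n, window_len, end) {
  L <- length(values)
  len_b <- ivl[2] - ivl[1]
  out <- matrix(0, 0, window_len)
  for (k in seq_len(n)) {
    s <- NA
    if (stats::runif(1) < 0.5) {
      # partial overlap: barcode sticks out of a window edge
      ov <- stats::runif(1, 0.25, 0.9) * len_b
      s <- if (stats::runif(1) < 0.5) {
        round(ivl[1] + ov - window_len)   # barcode tail at window end
      } else {
        round(ivl[2] - ov)                # barcode head at window start
      }
      s <- max(0, min(s, L - window_len))
    } else {
      for (try in 1:20) {
        cand <- sample.int(L - window_len + 1L, 1) - 1L
        ov <- min(cand + window_len, ivl[2]) - max(cand, ivl[1])
        if (ov <= 0.25 * len_b) { s <- cand; break }
      }
    }
    if (is.na(s)) next
    # clipping a partial draw can restore full containment; skip those
    if (s <= ivl[1] && s + window_len >= ivl[2]) next
    w <- values[(s + 1):(s + window_len)]
    if (end == "end") w <- rev(w)
    out <- rbind(out, suppressWarnings(znormalize(w)))
  }
  out
}

#' Run the full pipeline
#'
#' Executes simulate -> prep -> train -> classify -> evaluate, writing
#' each stage's artifacts under `config$out_dir` (`sim/`, `prep/`,
#' `models/`, `bins/`, `report.json`) and logging per-stage timing and
#' the seeds in use. Any stage failure aborts with a message naming the
#' stage.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the library, training sets, models,
#'   calls and the final [score_demux()] report.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "run_config.json"))
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    say(name, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  n_classes <- config$n_barcodes + 1L
  barcodes <- barcode_set(config$n_barcodes)
  model <- build_pore_model()

  say("simulate", "seed %d: %d reads, %d barcodes",
      config$seed, config$n_reads, config$n_barcodes)
  lib <- stage("simulate", {
    l <- simulate_library(config$n_reads, barcodes = barcodes,
                          model = model,
                          no_barcode_rate = config$no_barcode_rate,
                          chimera_rate = config$chimera_rate,
                          seed = derive_seed(config$seed, 1))
    write_sim_library(l, file.path(config$out_dir, "sim"))
    l
  })

  sets <- stage("prep", {
    out <- lapply(c("start", "end"), function(side) {
      ext <- harvest_training_windows(lib$squiggles, end = side,
                                      truth = lib$truth,
                                      n_classes = n_classes,
                                      seed = derive_seed(config$seed, 2))
      set <- assemble_training_set(ext,
                                   no_barcode_fraction = config$no_barcode_fraction,
                                   model = model,
                                   seed = derive_seed(config$seed, 3))
      if (isTRUE(config$refine)) {
        set <- refine_by_cross_split(set, seed = derive_seed(config$seed, 4))
      }
      set
    })
    names(out) <- c("start", "end")
    dir.create(file.path(config$out_dir, "prep"), showWarnings = FALSE)
    write_training_set(out$start, file.path(config$out_dir, "prep", "start"))
    write_training_set(out$end, file.path(config$out_dir, "prep", "end"))
    out
  })

  models <- stage("train", {
    dir.create(file.path(config$out_dir, "models"), showWarnings = FALSE)
    out <- lapply(c("start", "end"), function(side) {
      say("train", "%s model (%d samples, %d epochs, seed %d)",
          side, nrow(sets[[side]]$X), config$epochs,
          derive_seed(config$seed, 5))
      net <- build_model(desk_network_config(n_classes),
                         seed = derive_seed(config$seed, 5))
      fit <- train_model(net, sets[[side]],
                         train_config(epochs = config$epochs,
                                      samples_per_epoch = config$samples_per_epoch,
                                      augmentation_factor = config$augmentation_factor,
                                      seed = derive_seed(config$seed, 6)))
      say("train", "%s model: final val acc %.3f", side,
          utils::tail(fit$history$val_acc, 1))
      save_model(fit$model,
                 file.path(config$out_dir, "models", paste0(side, ".rds")))
      fit$model
    })
    names(out) <- c("start", "end")
    out
  })

  calls <- stage("classify", {
    demultiplex(lib$squiggles, models$start, models$end,
                mode = config$mode,
                out_dir = file.path(config$out_dir, "bins"))
  })

  report <- stage("evaluate", {
    gt <- truth_to_ground_truth(lib$truth)
    rep <- score_demux(calls, gt,
                       quals = lib$reads[, c("read_id", "mean_q")])
    jsonlite::write_json(
      list(binned_fraction = rep$binned_fraction,
           precision = rep$precision, recall = rep$recall,
           q_range = rep$q_range,
           binned_unknown_fraction = rep$binned_unknown_fraction,
           binned_chimeric_fraction = rep$binned_chimeric_fraction),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    rep
  })

  invisible(list(library = lib, training_sets = sets, models = models,
                 calls = calls, report = report))
}
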
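# Labelled 1024-sample training windows: extraction around located
# barcode intervals, synthetic no-barcode classes, temporal-distortion
# augmentation, and cross-split label refinement.

#' Construct a training set
#'
#' @param X Matrix with one z-normalised window per row.
#' @param labels Integer class labels, 1..`n_classes` (class `n_classes`
#'   is the no-barcode class).
#' @param n_classes Total class count (barcodes + 1).
#' @param end Which read end the windows came from (`"start"` windows
#'   are in read orientation; `"end"` windows are reversed).
#' @param provenance Character vector recording each sample's origin
#'   (e.g. `"extracted"`, `"flat"`, `"perlin"`).
#' @return Object of class `training_set`.
#' @export
training_set <- function(X, labels, n_classes,
                         end = c("start", "end"),
                         provenance = rep("extracted", nrow(X))) {
  end <- match.arg(end)
  if (nrow(X) != length(labels)) stopf("one label per window required")
  if (any(labels < 1 | labels > n_classes)) {
    stopf("labels must lie in 1..%d", n_classes)
  }
  structure(list(X = X, labels = as.integer(labels),
                 n_classes = as.integer(n_classes), end = end,
                 provenance = provenance),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set (%s): %d samples x %d, %d classes>\n",
              x$end, nrow(x$X), ncol(x$X), x$n_classes))
  print(table(factor(x$labels, levels = seq_len(x$n_classes),
                     labels = class_labels(x$n_classes - 1L))))
  invisible(x)
}

#' Class counts of a training set
#' @param set A [training_set()].
#' @return Named integer vector of per-class counts.
#' @export
class_counts <- function(set) {
  tab <- tabulate(set$labels, nbins = set$n_classes)
  names(tab) <- class_labels(set$n_classes - 1L)
  tab
}

#' Extract training windows around a barcode interval
#'
#' Cuts `n_windows` windows of `window_len` samples from a read signal,
#' each fully containing the barcode interval, with the barcode's
#' position jittered uniformly within the window so position cannot be
#' memorised. Read-end windows are reversed so both ends share one
#' signal orientation. The signal must already be open-pore trimmed;
#' every emitted window is z-normalised.
#'
#' @param values Numeric read signal (open-pore trimmed).
#' @param interval Barcode interval `c(from, to)`, 0-based half-open
#'   sample coordinates (from simulation truth or [locate_barcode()]).
#' @param end `"start"` or `"end"`.
#' @param n_windows Windows to cut per read.
#' @param window_len Window length in samples.
#' @param seed Optional seed for the jitter.
#' @return Matrix with one window per row (0 rows, with a warning, when
#'   the read is shorter than a window or the interval exceeds it).
#' @export
extract_training_windows <- function(values, interval,
                                     end = c("start", "end"),
                                     n_windows = 2, window_len = 1024,
                                     seed = NULL) {
  end <- match.arg(end)
  L <- length(values)
  from <- interval[1]
  to <- interval[2]
  if (L < window_len) {
    warnf("read of %d samples shorter than window (%d); skipped", L, window_len)
    return(matrix(numeric(0), 0, window_len))
  }
  if (to - from > window_len) {
    warnf("barcode interval of %d samples exceeds window (%d); skipped",
          to - from, window_len)
    return(matrix(numeric(0), 0, window_len))
  }
  lo <- max(0, to - window_len)         # leftmost start keeping containment
  hi <- min(from, L - window_len)       # rightmost start
  if (hi < lo) {
    warnf("no window can contain interval [%d, %d); skipped", from, to)
    return(matrix(numeric(0), 0, window_len))
  }
  with_seed(seed, {
    starts <- round(stats::runif(n_windows, lo, hi))
    out <- matrix(0, n_windows, window_len)
    for (i in seq_len(n_windows)) {
      w <- values[(starts[i] + 1):(starts[i] + window_len)]
      if (end == "end") w <- rev(w)
      out[i, ] <- suppressWarnings(znormalize(w))
    }
    attr(out, "starts") <- starts
    out
  })
}

#' Generate no-barcode training samples
#'
#' Windows that carry no barcode signal, labelled with the no-barcode
#' class: signal from barcode-free simulated reads, adapter-only signal,
#' flat signal, white Gaussian noise and smooth gradient (Perlin) noise.
#'
#' @param n Number of samples.
#' @param mix Named fractions over the subtypes `read`, `adapter`,
#'   `flat`, `gaussian`, `perlin`; must sum to 1.
#' @param model Pore model used for the `read`/`adapter` subtypes.
#' @param window_len Window length.
#' @param seed Optional seed.
#' @return Matrix of `n` z-normalised windows with attribute `subtype`.
#' @export
make_no_barcode_samples <- function(n,
                                    mix = c(read = 0.3, adapter = 0.2,
                                            flat = 0.1, gaussian = 0.2,
                                            perlin = 0.2),
                                    model = build_pore_model(),
                                    window_len = 1024, seed = NULL) {
  if (abs(sum(mix) - 1) > 1e-8) stopf("mix fractions must sum to 1")
  subtypes <- names(mix)
  with_seed(seed, {
    pick <- sample(subtypes, n, replace = TRUE, prob = mix)
    out <- matrix(0, n, window_len)
    n_bases <- ceiling(window_len / 4) + 60  # enough even at short dwells
    for (i in seq_len(n)) {
      v <- switch(pick[i],
        read = {
          s <- paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
                     collapse = "")
          simulate_squiggle(s, model)
        },
        adapter = {
          pre <- paste(sample(c("A", "C", "G", "T"), n_bases %/% 2,
                              replace = TRUE), collapse = "")
          post <- paste(sample(c("A", "C", "G", "T"), n_bases %/% 2,
                               replace = TRUE), collapse = "")
          simulate_squiggle(paste0(pre, default_adapter(), post), model)
        },
        flat = gen_flat(window_len),
        gaussian = gen_gaussian(window_len),
        perlin = gen_perlin(window_len))
      if (length(v) < window_len) {
        v <- c(v, gen_gaussian(window_len - length(v), sd = model$noise_sd))
      }
      s0 <- sample.int(length(v) - window_len + 1L, 1)
      out[i, ] <- suppressWarnings(znormalize(v[s0:(s0 + window_len - 1L)]))
    }
    attr(out, "subtype") <- pick
    out
  })
}

#' Temporal-distortion augmentation
#'
#' Distorts a signal along the time axis by duplicating the values at a
#' quarter of its positions (randomly chosen) and deleting the values at
#' a different quarter. The result has the same length, elongated in
#' some places and shortened in others, and contains no value absent
#' from the input. Amplitude is left untouched (the network's own
#' Gaussian-noise layer covers amplitude variation).
#'
#' @param values Numeric signal (length >= 8 for a meaningful
#'   distortion).
#' @param distortion Fraction of positions duplicated (and, disjointly,
#'   deleted); 0 returns the input unchanged.
#' @param seed Optional seed.
#' @return Numeric vector of the same length as `values`.
#' @export
augment_signal <- function(values, distortion = 0.25, seed = NULL) {
  L <- length(values)
  m <- floor(L * distortion)
  if (m == 0) return(values)
  with_seed(seed, {
    idx <- sample.int(L, 2L * m)        # disjoint duplicate/delete sets
    times <- rep(1L, L)
    times[idx[seq_len(m)]] <- 2L
    times[idx[m + seq_len(m)]] <- 0L
    rep(values, times = times)
  })
}

#' Assemble a full training set
#'
#' Tops the set up with synthetic no-barcode samples until the
#' no-barcode class makes up `no_barcode_fraction` of the
#' pre-augmentation set (no-barcode windows already present — e.g.
#' harvested from non-barcode parts of reads — count towards the
#' fraction), optionally appends temporally distorted copies
#' (`augmentation_factor` 2 = exactly one augmented copy per original)
#' and shuffles.
#'
#' @param extracted A [training_set()] of labelled windows.
#' @param no_barcode_fraction Fraction of the assembled set that should
#'   be no-barcode samples (default 0.25); must be in `[0, 1)`.
#' @param augmentation_factor Total copies per sample (>= 1).
#' @param model Pore model for the synthetic no-barcode subtypes.
#' @param mix Subtype mix passed to [make_no_barcode_samples()].
#' @param seed Optional seed.
#' @return A [training_set()].
#' @export
assemble_training_set <- function(extracted, no_barcode_fraction = 0.25,
                                  augmentation_factor = 1,
                                  model = build_pore_model(),
                                  mix = c(read = 0.3, adapter = 0.2,
                                          flat = 0.1, gaussian = 0.2,
                                          perlin = 0.2),
                                  seed = NULL) {
  if (nrow(extracted$X) == 0) stopf("no extracted samples to assemble")
  if (no_barcode_fraction < 0 || no_barcode_fraction >= 1) {
    stopf("no_barcode_fraction must be in [0, 1)")
  }
  if (augmentation_factor < 1) stopf("augmentation_factor must be >= 1")
  with_seed(seed, {
    n_ext <- nrow(extracted$X)
    n_nb_have <- sum(extracted$labels == extracted$n_classes)
    # solve (have + add) / (n + add) = fraction for the top-up count
    n_nb <- max(0, round((no_barcode_fraction * n_ext - n_nb_have) /
                           (1 - no_barcode_fraction)))
    X <- extracted$X
    labels <- extracted$labels
    prov <- extracted$provenance
    if (n_nb > 0) {
      nb <- make_no_barcode_samples(n_nb, mix = mix, model = model,
                                    window_len = ncol(X))
      X <- rbind(X, nb)
      labels <- c(labels, rep(extracted$n_classes, n_nb))
      prov <- c(prov, attr(nb, "subtype"))
    }
    if (augmentation_factor >= 2) {
      n0 <- nrow(X)
      for (r in seq_len(augmentation_factor - 1L)) {
        X <- rbind(X, t(apply(X[seq_len(n0), , drop = FALSE], 1,
                              augment_signal)))
        labels <- c(labels, labels[seq_len(n0)])
        prov <- c(prov, paste0(prov[seq_len(n0)], "+augmented"))
      }
    }
    ord <- sample.int(nrow(X))
    training_set(X[ord, , drop = FALSE], labels[ord], extracted$n_classes,
                 end = extracted$end, provenance = prov[ord])
  })
}

#' Refine a training set by cross-split reclassification
#'
#' Splits the set into `n_folds` random folds, classifies each fold with
#' a model trained on the other folds, and discards samples whose
#' predicted label disagrees with their training label. This purges
#' ambiguous or mislabelled samples; the result is always a subset of
#' the input.
#'
#' @param set A [training_set()].
#' @param trainer Function `(training_set) -> model` returning a trained
#'   model whose [predict_probs()] output matches the set's classes;
#'   defaults to a reduced network trained briefly.
#' @param n_folds Number of folds (default 4).
#' @param seed Optional seed (fold assignment and default trainer).
#' @return The refined [training_set()], with attribute `discarded`
#'   giving the number of samples removed.
#' @export
refine_by_cross_split <- function(set, trainer = NULL, n_folds = 4,
                                  seed = NULL) {
  trainer <- trainer %||% default_refine_trainer(seed)
  with_seed(seed, {
    n <- nrow(set$X)
    fold <- sample(rep(seq_len(n_folds), length.out = n))
    keep <- logical(n)
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      if (length(unique(set$labels[tr])) < 2) {
        stopf("fold %d leaves fewer than 2 classes to train on", f)
      }
      sub <- training_set(set$X[tr, , drop = FALSE], set$labels[tr],
                          set$n_classes, end = set$end,
                          provenance = set$provenance[tr])
      model <- trainer(sub)
      pred <- max.col(predict_probs(model, set$X[te, , drop = FALSE]))
      keep[te] <- pred == set$labels[te]
    }
    out <- training_set(set$X[keep, , drop = FALSE], set$labels[keep],
                        set$n_classes, end = set$end,
                        provenance = set$provenance[keep])
    attr(out, "discarded") <- sum(!keep)
    out
  })
}

# Reduced-size trainer used by refine_by_cross_split: a small network
# and a short training run are enough to flag label/signal disagreement.
default_refine_trainer <- function(seed = NULL) {
  function(set) {
    cfg <- network_config(input_len = ncol(set$X),
                          n_classes = set$n_classes,
                          base_filters = 12, n_groups = 3, n_conv = 1,
                          kernel = 9, pools = c(4, 4, 4),
                          inception_after = 2)
    model <- build_model(cfg, seed = derive_seed(seed, 17) %||% 17L)
    fit <- train_model(model, set,
                       train_config(epochs = 6, augmentation_factor = 1,
                                    seed = derive_seed(seed, 29) %||% 29L))
    fit$model
  }
}

#' Write / read a training set
#'
#' Windows are stored as a plain-text matrix (one window per row,
#' tab-separated) next to a TSV label index, a portable representation
#' that round-trips across platforms.
#'
#' @param set A [training_set()].
#' @param prefix Path prefix; writes `<prefix>_windows.tsv` and
#'   `<prefix>_labels.tsv`.
#' @export
write_training_set <- function(set, prefix) {
  utils::write.table(set$X, paste0(prefix, "_windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(label = set$labels, end = set$end,
               provenance = set$provenance),
    paste0(prefix, "_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_training_set
#' @param n_classes Class count for the reconstructed set.
#' @export
read_training_set <- function(prefix, n_classes) {
  X <- as.matrix(utils::read.table(paste0(prefix, "_windows.tsv"),
                                   sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  lab <- utils::read.table(paste0(prefix, "_labels.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  training_set(X, lab$label, n_classes, end = lab$end[1],
               provenance = lab$provenance)
}
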
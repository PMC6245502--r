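# Raw-signal, FASTQ and PAF input/output plus the signal utilities
# (z-normalisation, open-pore trimming, mean q-score) shared by all
# downstream stages.

#' Construct a squiggle
#'
#' A squiggle is one read's raw nanopore current trace: an ordered vector
#' of current samples recorded (by default) at 4 kHz as the DNA strand
#' translocates the pore.
#'
#' @param read_id Read identifier.
#' @param values Numeric vector of current samples (device units or
#'   normalised); must be non-empty.
#' @param sample_rate Sampling rate in samples/second.
#' @param source One of `"text"`, `"simulated"`.
#' @return An object of class `squiggle`: a list with fields `read_id`,
#'   `values`, `sample_rate`, `source`.
#' @export
squiggle <- function(read_id, values, sample_rate = 4000,
                     source = c("simulated", "text")) {
  source <- match.arg(source)
  if (length(values) == 0) stopf("squiggle '%s' has no samples", read_id)
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  structure(list(read_id = as.character(read_id),
                 values = as.numeric(values),
                 sample_rate = sample_rate,
                 source = source),
            class = "squiggle")
}

#' @export
print.squiggle <- function(x, ...) {
  cat(sprintf("<squiggle %s: %d samples @ %g Hz (%s)>\n",
              x$read_id, length(x$values), x$sample_rate, x$source))
  invisible(x)
}

#' Read raw-signal reads
#'
#' Reads a raw-signal container into a list of [squiggle] objects. The
#' supported container is a plain-text format with one read per line:
#' `read_id<TAB>comma-separated sample values`. Reads without any samples
#' are skipped with a warning; the read order of the file is preserved.
#'
#' @param path File to read.
#' @param format Container format; currently `"text"`.
#' @return List of [squiggle] objects.
#' @seealso [write_raw_signal()]
#' @export
read_raw_signal <- function(path, format = "text") {
  format <- match.arg(format, "text")
  if (!file.exists(path)) stopf("raw-signal file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warnf("no reads in %s", path)
    return(list())
  }
  out <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[[2]])) {
      warnf("read '%s' in %s has no raw-signal samples; skipped",
            parts[[1]] %||% "?", path)
      next
    }
    vals <- as.numeric(strsplit(parts[[2]], ",", fixed = TRUE)[[1]])
    if (anyNA(vals)) {
      warnf("read '%s' in %s has unparseable samples; skipped", parts[[1]], path)
      next
    }
    out[[i]] <- squiggle(parts[[1]], vals, source = "text")
    keep[i] <- TRUE
  }
  out[keep]
}

#' Write raw-signal reads
#'
#' Writes squiggles in the plain-text container read by
#' [read_raw_signal()]. Sample values are written with 17 significant
#' digits so that a write/read round trip reproduces every double exactly.
#'
#' @param squiggles List of [squiggle] objects.
#' @param path Output file.
#' @export
write_raw_signal <- function(squiggles, path) {
  lines <- vapply(squiggles, function(s) {
    paste0(s$read_id, "\t", paste(sprintf("%.17g", s$values), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Z-normalise a signal
#'
#' Centres to mean 0 and scales to variance 1 (population variance, i.e.
#' dividing by n). A constant signal cannot be scaled and is returned as
#' all zeros with a warning, so that flat synthetic training signals pass
#' through the same code path as real signal.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of the same length.
#' @export
znormalize <- function(values) {
  n <- length(values)
  if (n == 0) stopf("cannot z-normalise an empty signal")
  mu <- mean(values)
  sd_pop <- sqrt(sum((values - mu)^2) / n)
  if (sd_pop == 0) {
    warnf("constant signal: z-normalisation returns zeros")
    return(rep(0, n))
  }
  (values - mu) / sd_pop
}

#' Trim open-pore signal
#'
#' Open-pore signal is the run of high current values recorded when no DNA
#' occupies the pore; it precedes (and can follow) the true read signal.
#' This removes the maximal leading run of samples above `threshold`, and
#' with `ends = "both"` also the maximal trailing run. Interior samples
#' are never touched: the result is a contiguous slice of the input.
#'
#' @param values Numeric signal.
#' @param threshold Cutoff in the same units as `values`. When `NULL`, a
#'   robust cutoff is derived from the signal itself: the midpoint
#'   between the 10th percentile and the maximum. Open-pore current is a
#'   high, narrow mode well above the DNA signal, so the midpoint falls
#'   cleanly between the two; a median-plus-scaled-MAD rule would fail
#'   here because a long pad shifts both the centre and the spread.
#' @param ends Trim the leading run only (`"start"`) or both ends
#'   (`"both"`).
#' @return The trimmed signal. When every sample exceeds the threshold the
#'   result is empty and carries attribute `unusable = TRUE`.
#' @export
trim_open_pore <- function(values, threshold = NULL,
                           ends = c("start", "both")) {
  ends <- match.arg(ends)
  if (is.null(threshold)) {
    threshold <- open_pore_cutoff(values)
  }
  above <- values > threshold
  if (all(above)) {
    out <- numeric(0)
    attr(out, "unusable") <- TRUE
    return(out)
  }
  first <- which(!above)[1]
  last <- if (ends == "both") max(which(!above)) else length(values)
  values[first:last]
}

# Data-derived open-pore cutoff: midpoint of the low signal quantile and
# the maximum (see trim_open_pore).
open_pore_cutoff <- function(values) {
  unname((stats::quantile(values, 0.10) + max(values)) / 2)
}

# Length of the leading run of samples above the open-pore cutoff.
leading_open_pore_run <- function(values, threshold = NULL) {
  threshold <- threshold %||% open_pore_cutoff(values)
  below <- which(values <= threshold)
  if (length(below) == 0) return(length(values))
  below[1] - 1L
}

#' Mean read q-score
#'
#' The mean Phred quality of a read, computed in error-probability space:
#' per-base qualities are converted to error probabilities, averaged, and
#' converted back, `q = -10 * log10(mean(10^(-q_i/10)))`. This is the
#' standard read-level q-score and is always less than or equal to the
#' arithmetic mean of the per-base values.
#'
#' @param per_base_quals Non-empty numeric vector of Phred scores.
#' @return Scalar mean q-score.
#' @export
mean_qscore <- function(per_base_quals) {
  if (length(per_base_quals) == 0) stopf("no quality values")
  if (any(per_base_quals < 0)) stopf("Phred scores must be non-negative")
  -10 * log10(mean(10^(-per_base_quals / 10)))
}

#' Read a FASTQ file
#'
#' Minimal 4-line-record FASTQ reader (Phred+33). Returns one row per
#' read with the per-base qualities as a list column and the mean q-score
#' precomputed via [mean_qscore()].
#'
#' @param path FASTQ file (uncompressed).
#' @return `data.frame` with columns `read_id`, `sequence`, `quals`
#'   (list), `mean_q`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stopf("truncated FASTQ: %s", path)
  n <- length(lines) / 4
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, by = 4, length.out = n)]))
  seqs <- lines[seq(2, by = 4, length.out = n)]
  quals <- lapply(lines[seq(4, by = 4, length.out = n)], function(q) {
    as.integer(charToRaw(q)) - 33L
  })
  data.frame(read_id = ids, sequence = seqs,
             quals = I(quals),
             mean_q = vapply(quals, mean_qscore, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param read_ids,sequences,quals Parallel vectors/list: identifiers,
#'   base sequences and integer Phred score vectors.
#' @param path Output file.
#' @export
write_fastq <- function(read_ids, sequences, quals, path) {
  recs <- vapply(seq_along(read_ids), function(i) {
    paste0("@", read_ids[[i]], "\n", sequences[[i]], "\n+\n",
           rawToChar(as.raw(pmin(quals[[i]], 93L) + 33L)))
  }, character(1))
  writeLines(recs, path)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses minimap2-style PAF (12+ tab-separated fields). Alignments are
#' grouped per read and ranked by alignment length on the read (rank 1 =
#' longest), which is the ordering used for ground-truth assignment.
#' Malformed lines are skipped with a warning naming the line number.
#'
#' @param path PAF file.
#' @return `data.frame` with columns `read_id`, `read_len`, `target_id`,
#'   `alignment_len_on_read`, `rank`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stopf("PAF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      warnf("PAF line %d has %d fields (12 required); skipped", i, length(f))
      next
    }
    rows[[i]] <- data.frame(read_id = f[1],
                            read_len = as.numeric(f[2]),
                            target_id = f[6],
                            alignment_len_on_read = as.numeric(f[4]) - as.numeric(f[3]),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(read_id = character(), read_len = numeric(),
                      target_id = character(),
                      alignment_len_on_read = numeric(), rank = integer()))
  }
  df <- do.call(rbind, rows)
  ord <- order(df$read_id, -df$alignment_len_on_read)
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(df$alignment_len_on_read, df$read_id,
                        FUN = function(x) seq_along(x))
  rownames(df) <- NULL
  df
}
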
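# Barcode definitions: each barcode ligated in a native-barcoding style
# library is a 24 bp core flanked by 8 bp on each side, a 40 bp construct
# in total. The flanks are shared across the set (as in real kits), so
# barcodes are distinguished by their core alone.

#' Build a synthetic barcode set
#'
#' Generates `n` distinct random 24 bp barcode cores plus one shared pair
#' of 8 bp flanks, deterministically from `seed`.
#'
#' @param n Number of barcodes (default 12, the native-barcoding kit size).
#' @param seed Integer seed.
#' @return `data.frame` of class `barcode_set` with columns `barcode_id`,
#'   `core_seq` (24 bp), `left_flank`, `right_flank` (8 bp each) and
#'   `construct` (the full 40 bp).
#' @export
barcode_set <- function(n = 12, seed = 7) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rand_seq <- function(len) paste(sample(bases, len, replace = TRUE),
                                    collapse = "")
    left <- rand_seq(8)
    right <- rand_seq(8)
    cores <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
      repeat {
        s <- rand_seq(24)
        if (!s %in% seen) break
      }
      cores[i] <- s
      seen <- c(seen, s)
    }
    out <- data.frame(barcode_id = seq_len(n), core_seq = cores,
                      left_flank = left, right_flank = right,
                      construct = paste0(left, cores, right),
                      stringsAsFactors = FALSE)
    class(out) <- c("barcode_set", "data.frame")
    out
  })
}

#' Barcode construct length in bases
#'
#' @param bc A [barcode_set()] row or data.frame.
#' @return Integer vector of construct lengths (24 + 8 + 8 = 40).
#' @export
construct_length <- function(bc) {
  nchar(bc$construct)
}

# Class labels used throughout: barcodes 1..n plus a final no-barcode
# class, so a 12-barcode set has 13 classes.
class_labels <- function(n_barcodes) {
  c(paste0("barcode", seq_len(n_barcodes)), "no_barcode")
}
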
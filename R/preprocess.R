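#' Read filtering parameters
#'
#' Defaults keep reads with an average Phred score of at least 10 and a
#' length between 500 and 800 nt inclusive — the window matching a
#' full-length fish barcode amplicon.
#'
#' @param min_mean_q Minimum arithmetic-mean Phred score.
#' @param min_len,max_len Inclusive read length bounds in nt.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_mean_q = 10, min_len = 500L, max_len = 800L) {
  stopifnot(min_mean_q >= 0, min_len <= max_len)
  structure(list(min_mean_q = min_mean_q, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "filter_params")
}

#' Mean Phred quality of a read
#'
#' Arithmetic mean of the per-base Phred scores (the convention of standard
#' read-filtering tools), not the mean of the implied error probabilities.
#'
#' @param read A [read_set] (one mean per read) or an integer vector of
#'   per-base Phred scores.
#' @return Numeric vector of mean scores.
#' @export
mean_quality <- function(read) {
  quals <- if (inherits(read, "read_set")) read$qual else list(read)
  if (any(lengths(quals) == 0L)) {
    stop("cannot compute the mean quality of an empty read")
  }
  vapply(quals, mean, numeric(1))
}

#' Quality and length filtering of reads
#'
#' A read is kept iff its mean Phred score is at least `min_mean_q` and its
#' length lies inside `[min_len, max_len]` (inclusive bounds).  Reads
#' failing both checks are counted under the quality reason.
#'
#' @param reads A [read_set].
#' @param params A [filter_params].
#' @return A list with elements `reads` (the kept [read_set]) and `stats`
#'   (counts `input`, `kept`, `dropped_quality`, `dropped_length`).
#' @export
filter_reads <- function(reads, params = filter_params()) {
  stopifnot(inherits(reads, "read_set"))
  len <- nchar(reads$seq)
  mq <- vapply(reads$qual, function(q) if (length(q)) mean(q) else 0, numeric(1))
  ok_q <- mq >= params$min_mean_q
  ok_l <- len >= params$min_len & len <= params$max_len
  keep <- ok_q & ok_l
  list(
    reads = reads[keep],
    stats = list(
      input = length(reads),
      kept = sum(keep),
      dropped_quality = sum(!ok_q),
      dropped_length = sum(ok_q & !ok_l)
    )
  )
}

#' Trim terminal sequencing adapters from a read
#'
#' Searches each adapter within `window` nt of either read end using the
#' error-tolerant primer matcher and removes the best-matching occurrence
#' together with everything outward of it.  Adapters are ligation products
#' and therefore terminal; the search window avoids spurious mid-read hits.
#' Qualities are trimmed in register.  A read with no adapter hit is
#' returned unchanged.
#'
#' @param read A single-read [read_set] (or an element view of one).
#' @param adapters Character vector of adapter sequences.
#' @param max_error_rate Maximum edit fraction of the matched adapter length.
#' @param min_overlap Minimum matched adapter length in nt.
#' @param window Search window from each read end, in nt.
#' @return The trimmed single-read [read_set].
#' @export
trim_terminal_adapters <- function(read, adapters, max_error_rate = 0.2,
                                   min_overlap = 15L, window = 150L) {
  stopifnot(inherits(read, "read_set"), length(read) == 1L)
  seq <- read$seq[1]
  n <- nchar(seq)
  lo <- 1L          # first kept position
  hi <- n           # last kept position
  w <- min(window, n)
  head_txt <- substr(seq, 1L, w)
  tail_off <- n - w
  tail_txt <- substr(seq, tail_off + 1L, n)
  for (ad in adapters) {
    for (pat in unique(c(toupper(ad), revcomp(toupper(ad))))) {
      h <- cpp_find_primer(head_txt, pat, max_error_rate, min_overlap)
      if (isTRUE(h$found)) lo <- max(lo, h$read_end + 1L)
      t <- cpp_find_primer(tail_txt, pat, max_error_rate, min_overlap)
      if (isTRUE(t$found)) hi <- min(hi, tail_off + t$read_start)
    }
  }
  if (lo > hi) {
    return(read_set(read$id[1], "", list(integer())))
  }
  read_set(read$id[1], substr(seq, lo, hi), list(read$qual[[1]][lo:hi]))
}
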
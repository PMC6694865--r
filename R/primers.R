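#' Primer pair (or cocktail) for one barcode marker
#'
#' @param marker Marker name, e.g. `"cytb"` or `"COI"`.
#' @param forward,reverse Character vectors of IUPAC primer sequences; more
#'   than one alternative per side forms a cocktail.
#' @return An object of class `marker_primer_set`.
#' @export
marker_primer_set <- function(marker, forward, reverse) {
  forward <- toupper(as.character(forward))
  reverse <- toupper(as.character(reverse))
  stopifnot(length(forward) >= 1L, length(reverse) >= 1L, nzchar(marker))
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", c(forward, reverse))
  if (!all(ok)) stop("primers must be IUPAC nucleotide strings")
  structure(list(marker = marker, forward = as.list(forward),
                 reverse = as.list(reverse)),
            class = "marker_primer_set")
}

#' Primer matching parameters
#'
#' @param max_error_rate Maximum edits as a fraction of the matched primer
#'   length; the integer threshold is `floor(rate * matched_len)`.
#' @param min_overlap Minimum number of primer bases inside the read.
#' @return An object of class `primer_params`.
#' @export
primer_params <- function(max_error_rate = 0.20, min_overlap = 15L) {
  stopifnot(max_error_rate >= 0, max_error_rate <= 1, min_overlap >= 1)
  structure(list(max_error_rate = max_error_rate,
                 min_overlap = as.integer(min_overlap)),
            class = "primer_params")
}

#' Find the best occurrence of a primer in a sequence
#'
#' Semi-global edit-distance search with free ends on the read: the primer
#' may sit anywhere in the read and may overhang either read end, in which
#' case only its in-read part counts.  IUPAC codes in the primer match every
#' base they denote at zero cost; an N in the read matches nothing.  A hit
#' must satisfy `edits <= floor(max_error_rate * matched_len)` and cover at
#' least `min_overlap` bases on both the primer and the read side.  Ties
#' are broken by the leftmost read
#' start, then the longest matched primer stretch.
#'
#' @param sequence Nucleotide string to search.
#' @param primer IUPAC primer string.
#' @param max_error_rate,min_overlap See [primer_params()].
#' @return A list with `primer` (the query), `strand` (`"+"`), `read_start`,
#'   `read_end` (0-based half-open), `edits` and `matched_len`; or `NULL`
#'   when there is no qualifying hit.
#' @export
find_primer <- function(sequence, primer, max_error_rate = 0.20,
                        min_overlap = 15L) {
  primer <- toupper(primer)
  if (nchar(primer) < min_overlap) {
    stop("primer is shorter than min_overlap")
  }
  h <- cpp_find_primer(toupper(sequence), primer, max_error_rate,
                       as.integer(min_overlap))
  if (!isTRUE(h$found)) return(NULL)
  list(primer = primer, strand = "+",
       read_start = h$read_start, read_end = h$read_end,
       edits = h$edits, matched_len = h$matched_len)
}

# Best hit for any primer in `patterns` over the whole read batch.
# Returns a data.frame with one row per read (NA rows = no hit), using the
# same tie rules as find_primer plus "fewer edits wins across alternatives".
best_hit_batch <- function(seqs, patterns, params) {
  n <- length(seqs)
  best <- data.frame(found = logical(n), edits = NA_integer_,
                     read_start = NA_integer_, read_end = NA_integer_,
                     matched_len = NA_integer_, alt = NA_integer_)
  for (k in seq_along(patterns)) {
    m <- cpp_find_primer_batch(seqs, patterns[[k]], params$max_error_rate,
                               params$min_overlap)
    hit <- m[, "found"] == 1L
    better <- hit & (!best$found | m[, "edits"] < best$edits)
    if (any(better)) {
      best$found[better] <- TRUE
      best$edits[better] <- m[better, "edits"]
      best$read_start[better] <- m[better, "read_start"]
      best$read_end[better] <- m[better, "read_end"]
      best$matched_len[better] <- m[better, "matched_len"]
      best$alt[better] <- k
    }
  }
  best
}

#' Assign reads to barcode markers by primer content
#'
#' For every read and marker the forward primer (or cocktail) and the
#' reverse-complemented reverse primer are searched on both strands.  A read
#' is assigned to the marker with the most primer evidence (two-end evidence
#' preferred over one-end, which is accepted when the opposite end has been
#' eroded), ties broken by fewer total edits; a remaining tie between
#' markers leaves the read unassigned.
#'
#' @param reads A [read_set].
#' @param markers List of [marker_primer_set] objects.
#' @param params A [primer_params].
#' @return A data frame with one row per read: `read_id`, `marker`
#'   (`"unassigned"` when no primer is found), `orientation` (`"+"`, `"-"`
#'   or `NA`), `n_hits`, `total_edits`, and the 0-based half-open hit
#'   intervals `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (the
#'   5'-primer-side and 3'-primer-side hits in read coordinates).
#' @export
classify_reads <- function(reads, markers, params = primer_params()) {
  stopifnot(inherits(reads, "read_set"), length(markers) >= 1L)
  n <- length(reads)
  seqs <- reads$seq
  out <- data.frame(
    read_id = reads$id,
    marker = rep("unassigned", n),
    orientation = rep(NA_character_, n),
    n_hits = rep(0L, n),
    total_edits = rep(NA_integer_, n),
    fwd_start = rep(NA_integer_, n), fwd_end = rep(NA_integer_, n),
    rev_start = rep(NA_integer_, n), rev_end = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  best_ev <- rep(0L, n)
  best_ed <- rep(.Machine$integer.max, n)
  tied <- rep(FALSE, n)
  for (mp in markers) {
    fwd <- unlist(mp$forward)
    rev <- unlist(mp$reverse)
    for (ori in c("+", "-")) {
      # plus-strand read: forward primer 5' side, revcomp(reverse) 3' side;
      # minus-strand read: reverse primer 5' side, revcomp(forward) 3' side.
      p5 <- if (ori == "+") fwd else rev
      p3 <- if (ori == "+") revcomp(rev) else revcomp(fwd)
      h5 <- best_hit_batch(seqs, p5, params)
      h3 <- best_hit_batch(seqs, p3, params)
      ev <- as.integer(h5$found) + as.integer(h3$found)
      ed <- ifelse(h5$found, h5$edits, 0L) + ifelse(h3$found, h3$edits, 0L)
      better <- ev > best_ev | (ev == best_ev & ev > 0L & ed < best_ed)
      same <- ev == best_ev & ev > 0L & ed == best_ed & out$marker != mp$marker
      tied <- (tied | same) & !better
      idx <- which(better)
      if (length(idx)) {
        best_ev[idx] <- ev[idx]
        best_ed[idx] <- ed[idx]
        out$marker[idx] <- mp$marker
        out$orientation[idx] <- ori
        out$n_hits[idx] <- ev[idx]
        out$total_edits[idx] <- ed[idx]
        out$fwd_start[idx] <- ifelse(h5$found[idx], h5$read_start[idx], NA_integer_)
        out$fwd_end[idx] <- ifelse(h5$found[idx], h5$read_end[idx], NA_integer_)
        out$rev_start[idx] <- ifelse(h3$found[idx], h3$read_start[idx], NA_integer_)
        out$rev_end[idx] <- ifelse(h3$found[idx], h3$read_end[idx], NA_integer_)
      }
    }
  }
  amb <- which(tied)
  if (length(amb)) {
    out$marker[amb] <- "unassigned"
    out$orientation[amb] <- NA_character_
    out$n_hits[amb] <- 0L
    out$total_edits[amb] <- NA_integer_
    out$fwd_start[amb] <- out$fwd_end[amb] <- NA_integer_
    out$rev_start[amb] <- out$rev_end[amb] <- NA_integer_
  }
  out
}

#' Classify a single read
#'
#' @param read A single-read [read_set].
#' @inheritParams classify_reads
#' @return A one-row data frame, see [classify_reads()].
#' @export
classify_read <- function(read, markers, params = primer_params()) {
  classify_reads(read, markers, params)
}

#' Trim marker primers off classified reads
#'
#' Keeps the interval strictly between the inner boundaries of the two
#' primer hits recorded by [classify_reads()]; a read with a single-end hit
#' is trimmed on that end only.  Orientation is not normalized here (that
#' happens at the alignment stage).  Reads whose primer hits overlap
#' (degenerate amplicons) and reads with an empty insert are dropped and
#' counted.
#'
#' @param reads A [read_set].
#' @param hits The classification data frame from [classify_reads()] for
#'   these reads.
#' @return A list with `reads` (trimmed [read_set]) and `stats`
#'   (`input`, `kept`, `dropped_overlap`, `dropped_empty`).
#' @export
trim_primers <- function(reads, hits) {
  stopifnot(inherits(reads, "read_set"), nrow(hits) == length(reads))
  n <- length(reads)
  keep <- logical(n)
  seqs <- character(n)
  quals <- vector("list", n)
  dropped_overlap <- 0L
  dropped_empty <- 0L
  for (i in seq_len(n)) {
    len <- nchar(reads$seq[i])
    lo <- 1L
    hi <- len
    iv <- list()
    if (!is.na(hits$fwd_start[i])) {
      iv[[length(iv) + 1L]] <- c(hits$fwd_start[i], hits$fwd_end[i])
    }
    if (!is.na(hits$rev_start[i])) {
      iv[[length(iv) + 1L]] <- c(hits$rev_start[i], hits$rev_end[i])
    }
    if (length(iv) == 2L) {
      iv <- iv[order(vapply(iv, `[`, numeric(1), 1L))]
      if (iv[[1]][2] > iv[[2]][1]) {  # overlapping hits
        dropped_overlap <- dropped_overlap + 1L
        next
      }
      lo <- iv[[1]][2] + 1L
      hi <- iv[[2]][1]
    } else if (length(iv) == 1L) {
      mid <- (iv[[1]][1] + iv[[1]][2]) / 2
      if (mid <= len / 2) lo <- iv[[1]][2] + 1L else hi <- iv[[1]][1]
    }
    if (lo > hi) {
      dropped_empty <- dropped_empty + 1L
      next
    }
    keep[i] <- TRUE
    seqs[i] <- substr(reads$seq[i], lo, hi)
    quals[[i]] <- reads$qual[[i]][lo:hi]
  }
  out <- read_set(reads$id[keep], seqs[keep], quals[keep])
  list(reads = out,
       stats = list(input = n, kept = sum(keep),
                    dropped_overlap = dropped_overlap,
                    dropped_empty = dropped_empty))
}

#' Run-to-run carry-over fraction
#'
#' Classifies the reads of a sequencing run and reports which fraction of
#' the primer-classified reads belongs to a marker other than the one the
#' run targeted — the signature of residual library molecules on a reused
#' flow cell.  Because the intended denominator ("total reads") is ambiguous
#' for raw data, the fraction over all reads is reported alongside.
#'
#' @param reads A [read_set].
#' @param current_marker Marker name this run targeted.
#' @param other_markers List of [marker_primer_set] for the other markers.
#' @param current_primers A [marker_primer_set] for `current_marker`.
#' @param params A [primer_params].
#' @return A list with `fraction` (other-marker / classified; `NA` when no
#'   read classifies), `fraction_of_total`, and the counts `n_other`,
#'   `n_classified`, `n_total`.
#' @export
carryover_fraction <- function(reads, current_marker, other_markers,
                               current_primers, params = primer_params()) {
  markers <- c(list(current_primers), other_markers)
  cls <- classify_reads(reads, markers, params)
  classified <- cls$marker != "unassigned"
  n_other <- sum(classified & cls$marker != current_marker)
  n_classified <- sum(classified)
  list(
    fraction = if (n_classified == 0L) NA_real_ else n_other / n_classified,
    fraction_of_total = if (length(reads) == 0L) NA_real_ else n_other / length(reads),
    n_other = n_other, n_classified = n_classified, n_total = length(reads)
  )
}
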
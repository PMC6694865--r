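#' Subsample a cluster before alignment
#'
#' Clusters larger than `cap` reads are reduced to a uniform random subset
#' of exactly `cap` members; using more reads does not improve the consensus
#' and slows alignment.  Deterministic under a fixed seed.
#'
#' @param cluster One cluster from [greedy_cluster()].
#' @param cap Maximum number of reads passed on (default 100).
#' @param seed Integer seed, or `NULL` to use the caller's RNG stream.
#' @return Character vector of member read ids.
#' @export
subsample_cluster <- function(cluster, cap = 100L, seed = NULL) {
  stopifnot(cap >= 1L)
  ids <- cluster$member_ids
  if (length(ids) <= cap) return(ids)
  with_seed(seed, sample(ids, cap))
}

#' Orient reads against their cluster representative
#'
#' Each read is kept as-is or reverse-complemented, whichever gives the
#' higher identity to the representative, so that all cluster members share
#' one strand before alignment.
#'
#' @param reads A [read_set] (one cluster's members).
#' @param reference The representative sequence.
#' @return A list with `reads` (oriented [read_set]) and `flipped` (logical
#'   vector).
#' @export
orient_reads <- function(reads, reference) {
  stopifnot(inherits(reads, "read_set"))
  flipped <- logical(length(reads))
  seqs <- reads$seq
  quals <- reads$qual
  for (i in seq_along(seqs)) {
    rc <- revcomp(seqs[i])
    # Orientation by unit-cost edit distance (the same objective the
    # identity uses); exact distance ties fall back to the full identity.
    dfwd <- cpp_edit_distance(seqs[i], reference)
    dbwd <- cpp_edit_distance(rc, reference)
    flip <- dbwd < dfwd
    if (dbwd == dfwd) {
      flip <- cpp_identity_to_reps(rc, reference, 0, FALSE) >
        cpp_identity_to_reps(seqs[i], reference, 0, FALSE)
    }
    if (flip) {
      seqs[i] <- rc
      quals[[i]] <- rev(quals[[i]])
      flipped[i] <- TRUE
    }
  }
  list(reads = read_set(reads$id, seqs, quals), flipped = flipped)
}

#' Center-star multiple sequence alignment
#'
#' The center is the read with the maximal summed pairwise identity to a
#' sampled subset of the other reads.  Every read is aligned to the center
#' with a unit-cost global alignment, and the pairwise gaps are merged into
#' common columns ("once a gap, always a gap"); insertions falling between
#' the same pair of center positions are left-aligned within their block.
#' For the near-identical reads of one cluster this is an adequate stand-in
#' for heavier iterative aligners.
#'
#' @param reads An oriented [read_set] with at least 2 reads.
#' @param sample_pairs Number of partners sampled per read when scoring
#'   center candidates.
#' @param seed Integer seed for the partner sampling, or `NULL`.
#' @return An object of class `msa`: list with `rows` (gapped sequences of
#'   equal length), `row_ids`, `ncol`, `center_id`.
#' @export
build_msa <- function(reads, sample_pairs = 10L, seed = NULL) {
  stopifnot(inherits(reads, "read_set"))
  n <- length(reads)
  if (n < 2L) stop("an MSA needs at least 2 reads")
  center_idx <- with_seed(seed, {
    scores <- numeric(n)
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      part <- if (length(others) > sample_pairs) {
        sample(others, sample_pairs)
      } else {
        others
      }
      # identity estimated from the pairwise edit distance: cheap, and only
      # the argmax matters for the center choice
      li <- nchar(reads$seq[i])
      lp <- nchar(reads$seq[part])
      e <- vapply(part, function(p) cpp_edit_distance(reads$seq[i],
                                                      reads$seq[p]), numeric(1))
      scores[i] <- sum(100 * pmin(pmin(li, lp), (li + lp - e) / 2) / pmin(li, lp))
    }
    which.max(scores)
  })
  center <- reads$seq[center_idx]
  lc <- nchar(center)
  # Per read: bases matched to each center position ("-" for deletions) and
  # inserted strings between center positions (slot i = before position i+1).
  aligned <- matrix("-", nrow = n, ncol = lc)
  inserts <- matrix("", nrow = n, ncol = lc + 1L)
  for (i in seq_len(n)) {
    if (i == center_idx) {
      aligned[i, ] <- strsplit(center, "", fixed = TRUE)[[1]]
      next
    }
    al <- cpp_pair_align_strings(center, reads$seq[i])
    ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
    ra <- strsplit(al$b, "", fixed = TRUE)[[1]]
    cpos <- 0L
    buf <- character()
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        buf <- c(buf, ra[k])
      } else {
        if (length(buf)) {
          inserts[i, cpos + 1L] <- paste(buf, collapse = "")
          buf <- character()
        }
        cpos <- cpos + 1L
        aligned[i, cpos] <- ra[k]
      }
    }
    if (length(buf)) inserts[i, lc + 1L] <- paste(buf, collapse = "")
  }
  block_len <- apply(nchar(inserts), 2, max)
  rows <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (p in 0:lc) {
      if (block_len[p + 1L] > 0L) {
        ins <- inserts[i, p + 1L]
        pad <- strrep("-", block_len[p + 1L] - nchar(ins))
        parts <- c(parts, paste0(ins, pad))
      }
      if (p < lc) parts <- c(parts, aligned[i, p + 1L])
    }
    paste(parts, collapse = "")
  }, character(1))
  structure(list(rows = rows, row_ids = reads$id, ncol = nchar(rows[1]),
                 center_id = reads$id[center_idx]),
            class = "msa")
}

#' Majority-rule consensus from an alignment
#'
#' Per column, the frequencies of A, C, G, T and `-` are computed (N is
#' excluded from the tally).  The most frequent symbol wins; base-vs-gap
#' frequency ties favor the base and base-vs-base ties are broken
#' alphabetically.  A column is emitted only when the winner is a base with
#' frequency strictly above `threshold`; columns won by a gap, or whose top
#' frequency does not exceed the threshold, are dropped, so the consensus
#' length tracks the true template length.
#'
#' @param msa An `msa` from [build_msa()].
#' @param threshold Winning-frequency threshold (default 0.30, strict).
#' @param consensus_id Identifier for the resulting record.
#' @param marker Marker name carried on the record.
#' @return An object of class `consensus_record`: list with `consensus_id`,
#'   `sequence`, `n_reads_used`, `column_support`, `marker`.
#' @export
majority_consensus <- function(msa, threshold = 0.30,
                               consensus_id = "consensus", marker = NA_character_) {
  stopifnot(inherits(msa, "msa"))
  if (!length(msa$rows)) stop("empty alignment")
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  symbols <- c("A", "C", "G", "T", "-")
  counts <- vapply(symbols, function(s) colSums(mat == s),
                   numeric(ncol(mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  tot <- rowSums(counts)
  win <- max.col(counts, ties.method = "first")  # symbol order = tie order
  freq <- counts[cbind(seq_len(nrow(counts)), win)] / pmax(tot, 1)
  emit <- tot > 0 & win <= 4L & freq > threshold
  structure(list(
    consensus_id = consensus_id,
    sequence = paste(symbols[win[emit]], collapse = ""),
    n_reads_used = length(msa$rows),
    column_support = freq[emit],
    marker = marker
  ), class = "consensus_record")
}

#' Strip residual primer sequence from a consensus
#'
#' Terminal primer occurrences that survive consensus building (forward or
#' reverse, either strand) are located with the error-tolerant matcher in a
#' window at each consensus end and removed; interior hits are left alone.
#'
#' @param consensus A `consensus_record`.
#' @param markers List of [marker_primer_set] whose primers are searched.
#' @param params A [primer_params].
#' @return The trimmed `consensus_record`.
#' @export
strip_primer_residues <- function(consensus, markers,
                                  params = primer_params()) {
  stopifnot(inherits(consensus, "consensus_record"))
  seq <- consensus$sequence
  support <- consensus$column_support
  pats <- unique(unlist(lapply(markers, function(mp) {
    p <- c(unlist(mp$forward), unlist(mp$reverse))
    c(p, revcomp(p))
  })))
  repeat {
    n <- nchar(seq)
    if (n == 0L) break
    w <- min(n, max(nchar(pats)) + 20L)
    lo <- 1L
    hi <- n
    for (pat in pats) {
      h <- cpp_find_primer(substr(seq, 1L, w), pat, params$max_error_rate,
                           params$min_overlap)
      if (isTRUE(h$found)) lo <- max(lo, h$read_end + 1L)
      off <- n - w
      t <- cpp_find_primer(substr(seq, off + 1L, n), pat,
                           params$max_error_rate, params$min_overlap)
      if (isTRUE(t$found)) hi <- min(hi, off + t$read_start)
    }
    if (lo == 1L && hi == n) break
    if (lo > hi) { seq <- ""; support <- numeric(); break }
    seq <- substr(seq, lo, hi)
    support <- support[lo:hi]
  }
  consensus$sequence <- seq
  consensus$column_support <- support
  consensus
}

#' Per-cluster consensus calling
#'
#' Runs the full per-cluster consensus stage: minimum-size gate,
#' subsampling, orientation against the representative, center-star MSA,
#' majority consensus, and primer-residue stripping.
#'
#' @param reads The [read_set] the clusters refer to.
#' @param clusters A `cluster_set` from [greedy_cluster()].
#' @param markers List of [marker_primer_set] used for residue stripping
#'   (may be empty).
#' @param marker Marker name recorded on each consensus.
#' @param cap Subsampling cap (default 100).
#' @param threshold Majority threshold (default 0.30).
#' @param min_cluster_size Clusters below this size are skipped (default 5):
#'   column support from a handful of noisy reads is not meaningful.
#' @param params A [primer_params] for residue stripping.
#' @param seed Integer seed.
#' @return A list of `consensus_record` objects (class `consensus_set`).
#' @export
cluster_consensus <- function(reads, clusters, markers = list(),
                              marker = NA_character_, cap = 100L,
                              threshold = 0.30, min_cluster_size = 5L,
                              params = primer_params(), seed = 1L) {
  stopifnot(inherits(reads, "read_set"), inherits(clusters, "cluster_set"))
  idx <- stats::setNames(seq_along(reads$id), reads$id)
  out <- list()
  with_seed(seed, {
    for (cl in clusters) {
      if (cl$size < min_cluster_size) next
      ids <- subsample_cluster(cl, cap = cap, seed = NULL)
      sub <- reads[idx[ids]]
      rep_seq <- reads$seq[idx[[cl$representative_id]]]
      ori <- orient_reads(sub, rep_seq)
      cid <- sprintf("%s_cluster%03d", if (is.na(marker)) "consensus" else marker,
                     cl$cluster_id)
      if (length(sub) == 1L) {
        cons <- structure(list(consensus_id = cid, sequence = ori$reads$seq[1],
                               n_reads_used = 1L,
                               column_support = rep(1.0, nchar(ori$reads$seq[1])),
                               marker = marker),
                          class = "consensus_record")
      } else {
        msa <- build_msa(ori$reads, seed = NULL)
        cons <- majority_consensus(msa, threshold = threshold,
                                   consensus_id = cid, marker = marker)
      }
      if (length(markers)) {
        cons <- strip_primer_residues(cons, markers, params)
      }
      if (nchar(cons$sequence)) out[[length(out) + 1L]] <- cons
    }
  })
  structure(out, class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set with %d record(s)\n", length(x)))
  for (co in utils::head(x, 10L)) {
    cat(sprintf("  %s: %d nt from %d read(s), median support %.2f\n",
                co$consensus_id, nchar(co$sequence), co$n_reads_used,
                stats::median(co$column_support)))
  }
  invisible(x)
}
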
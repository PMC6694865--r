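#' Percent identity between two sequences
#'
#' Global alignment with unit mismatch and gap costs; among minimum-cost
#' alignments the one with the most matched identical positions is used.
#' Identity is `100 * matches / length(shorter sequence)` — the short-side
#' denominator used by greedy identity clustering tools.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGAACGT")  # 87.5
pairwise_identity <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("sequences must be non-empty")
  cm <- cpp_global_cost_matches(seq_a, seq_b)
  100 * cm[["matches"]] / min(nchar(seq_a), nchar(seq_b))
}

#' Greedy incremental clustering at an identity threshold
#'
#' Reads are processed longest first (ties in input order).  Each read joins
#' the existing cluster whose representative gives the highest identity at
#' or above `threshold` (ties: lowest cluster id); otherwise it founds a new
#' cluster with itself as representative.  Identity is evaluated on both
#' read strands and the better one counts: amplicon reads come in both
#' orientations, and the downstream orientation-adjustment step presumes
#' clusters hold both.  Joining the best cluster rather than the first
#' acceptable one makes the outcome independent of cluster creation order
#' and at least as cohesive.
#'
#' With `prescreen = TRUE`, representatives that provably cannot reach the
#' threshold are skipped using a bit-parallel edit-distance bound
#' (`matches <= (|a| + |b| - dist) / 2` on any minimum-cost alignment); the
#' clustering result is identical with the prescreen on or off.
#'
#' @param reads A [read_set].
#' @param threshold Percent identity threshold (default 80).
#' @param prescreen Skip provably sub-threshold representative comparisons.
#' @return A `cluster_set`: list of clusters, each with `cluster_id`,
#'   `representative_id`, `member_ids`, `identity_to_rep`, `size`.
#' @export
greedy_cluster <- function(reads, threshold = 80.0, prescreen = TRUE) {
  stopifnot(inherits(reads, "read_set"), length(reads) >= 1L)
  ord <- order(-nchar(reads$seq))  # stable: ties keep input order
  rep_seq <- character()
  rep_id <- character()
  members <- list()
  idents <- list()
  for (i in ord) {
    s <- reads$seq[i]
    joined <- FALSE
    if (length(rep_seq)) {
      best <- cpp_best_rep(s, revcomp(s), rep_seq, threshold, prescreen)
      k <- best[1]  # 0 when no representative reaches the threshold
      if (k > 0) {
        members[[k]] <- c(members[[k]], reads$id[i])
        idents[[k]] <- c(idents[[k]], best[2])
        joined <- TRUE
      }
    }
    if (!joined) {
      rep_seq <- c(rep_seq, s)
      rep_id <- c(rep_id, reads$id[i])
      members[[length(members) + 1L]] <- reads$id[i]
      idents[[length(idents) + 1L]] <- 100.0
    }
  }
  out <- lapply(seq_along(members), function(k) {
    list(cluster_id = k, representative_id = rep_id[k],
         member_ids = members[[k]], identity_to_rep = idents[[k]],
         size = length(members[[k]]))
  })
  structure(out, class = "cluster_set")
}

#' @export
`[.cluster_set` <- function(x, i) {
  structure(unclass(x)[i], class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set with %d cluster(s), %d read(s)\n",
              length(x), sum(vapply(x, `[[`, integer(1), "size"))))
  for (cl in utils::head(x, 10L)) {
    cat(sprintf("  cluster %d: %d read(s), representative %s\n",
                cl$cluster_id, cl$size, cl$representative_id))
  }
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

#' Cluster membership as a data frame
#'
#' @param clusters A `cluster_set` from [greedy_cluster()].
#' @return Data frame with columns `cluster_id`, `read_id`,
#'   `is_representative`, `identity_to_rep`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, read_id = cl$member_ids,
               is_representative = cl$member_ids == cl$representative_id,
               identity_to_rep = cl$identity_to_rep,
               stringsAsFactors = FALSE)
  }))
}
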
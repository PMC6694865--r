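#' Unit-cost global alignment error counts
#'
#' Aligns a query to a target globally, minimizing mismatches + gapped
#' positions with every penalty equal to 1, and reports the error counts of
#' the optimal alignment.  Among cost ties the alignment with the fewest
#' gaps is counted (the totals are tie-invariant; only gap placement is
#' not).  Insertions are query bases absent from the target, deletions are
#' target bases absent from the query.
#'
#' @param query,target Non-empty nucleotide strings.
#' @return A list of class `error_counts`: `mismatches`, `insertions`,
#'   `deletions`, `query_len`.
#' @export
#' @examples
#' unit_cost_align("ACGT", "AGGT")  # one substitution
unit_cost_align <- function(query, target) {
  query <- toupper(query); target <- toupper(target)
  if (!nchar(query) || !nchar(target)) stop("sequences must be non-empty")
  v <- cpp_unit_cost_counts(query, target)
  structure(list(mismatches = v[["mismatches"]],
                 insertions = v[["insertions"]],
                 deletions = v[["deletions"]],
                 query_len = nchar(query)),
            class = "error_counts")
}

#' Pooled error percentage
#'
#' `100 * (sum of mismatches + deletions + insertions) / (sum of read
#' lengths)` over a set of per-read error counts.  Pooling the counts makes
#' the result independent of how reads are batched.
#'
#' @param counts A single `error_counts` or a list of them.
#' @return The pooled error percentage.
#' @export
error_percentage <- function(counts) {
  if (inherits(counts, "error_counts")) counts <- list(counts)
  if (!length(counts)) stop("no error counts supplied")
  err <- sum(vapply(counts, function(x) {
    x$mismatches + x$insertions + x$deletions
  }, numeric(1)))
  len <- sum(vapply(counts, `[[`, numeric(1), "query_len"))
  if (len <= 0) stop("total query length must be positive")
  100 * err / len
}

#' Orient a query onto a target
#'
#' Reads and consensi are strand-arbitrary; this returns the query strand
#' (as-is or reverse-complemented) with the smaller unit edit distance to
#' the target, as a strand-insensitive aligner would pick it.
#'
#' @param query,target Nucleotide strings.
#' @return The better-fitting strand of `query`.
#' @export
best_strand <- function(query, target) {
  rc <- revcomp(query)
  if (cpp_edit_distance(rc, target) < cpp_edit_distance(query, target)) rc
  else query
}

#' Error statistics of reads against target sequences
#'
#' Aligns each read to its mapped target with [unit_cost_align()], on the
#' read strand that fits the target better (alignments of nanopore reads
#' are strand-insensitive), and reports per-target and pooled error
#' percentages.  Used both against consensus sequences (the observable in a
#' real run) and, in simulations, against the true template.
#'
#' @param reads A [read_set].
#' @param targets Named character vector of target sequences.
#' @param mapping Data frame with columns `read_id`, `target_id`.
#' @return A list with `per_target` (data frame `target_id`, `n_reads`,
#'   `error_pct`) and `pooled` (overall error percentage).
#' @export
error_stats <- function(reads, targets, mapping) {
  stopifnot(inherits(reads, "read_set"))
  idx <- stats::setNames(seq_along(reads$id), reads$id)
  mapping <- mapping[mapping$read_id %in% reads$id, , drop = FALSE]
  counts <- vector("list", nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    tgt <- targets[[mapping$target_id[i]]]
    counts[[i]] <- unit_cost_align(
      best_strand(reads$seq[idx[[mapping$read_id[i]]]], tgt), tgt)
  }
  per <- lapply(split(seq_len(nrow(mapping)), mapping$target_id), function(ii) {
    data.frame(target_id = mapping$target_id[ii[1]], n_reads = length(ii),
               error_pct = error_percentage(counts[ii]),
               stringsAsFactors = FALSE)
  })
  list(
    per_target = if (length(per)) do.call(rbind, c(per, make.row.names = FALSE))
                 else data.frame(target_id = character(), n_reads = integer(),
                                 error_pct = numeric()),
    pooled = if (length(counts)) error_percentage(counts) else NA_real_
  )
}
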
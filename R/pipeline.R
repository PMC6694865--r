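#' Pipeline configuration
#'
#' Houses every workflow parameter with its default: mean Phred >= 10,
#' length 500-800 nt, primer matching at 20% error rate with 15 nt minimum
#' overlap, greedy clustering at 80% identity with a minimum cluster size of
#' 5, subsampling cap of 100 reads per cluster, 30% majority consensus, and
#' taxonomic assignment at 98% identity / 90% query coverage with an exact
#' score-tie margin.
#'
#' @param min_mean_q,min_len,max_len Read filter thresholds.
#' @param max_error_rate,min_overlap Primer matching parameters.
#' @param cluster_threshold Percent identity for greedy clustering.
#' @param min_cluster_size Smallest cluster passed to consensus calling.
#' @param subsample_cap Reads per cluster passed to the MSA.
#' @param consensus_threshold Majority-consensus winning-frequency threshold.
#' @param min_identity,min_coverage,score_margin Taxonomy thresholds.
#' @param seed Global seed; stage seeds are derived from it by fixed
#'   offsets so stages are individually reproducible.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean_q = 10, min_len = 500L, max_len = 800L,
                            max_error_rate = 0.20, min_overlap = 15L,
                            cluster_threshold = 80.0, min_cluster_size = 5L,
                            subsample_cap = 100L, consensus_threshold = 0.30,
                            min_identity = 98.0, min_coverage = 90.0,
                            score_margin = 0, seed = 1L) {
  cfg <- list(min_mean_q = min_mean_q, min_len = as.integer(min_len),
              max_len = as.integer(max_len),
              max_error_rate = max_error_rate,
              min_overlap = as.integer(min_overlap),
              cluster_threshold = cluster_threshold,
              min_cluster_size = as.integer(min_cluster_size),
              subsample_cap = as.integer(subsample_cap),
              consensus_threshold = consensus_threshold,
              min_identity = min_identity, min_coverage = min_coverage,
              score_margin = score_margin, seed = as.integer(seed))
  stopifnot(cfg$min_len <= cfg$max_len, cfg$min_mean_q >= 0,
            cfg$max_error_rate >= 0, cfg$max_error_rate <= 1,
            cfg$cluster_threshold > 0, cfg$cluster_threshold <= 100,
            cfg$subsample_cap >= 1,
            cfg$consensus_threshold >= 0, cfg$consensus_threshold < 1,
            cfg$min_identity >= 0, cfg$min_identity <= 100,
            cfg$min_coverage >= 0, cfg$min_coverage <= 100)
  structure(cfg, class = "pipeline_config")
}

#' Run the full identification pipeline
#'
#' Executes, per marker: quality/length filtering, primer-based marker
#' classification, primer trimming, greedy clustering, per-cluster majority
#' consensus with primer-residue stripping, and taxonomic assignment against
#' the reference set; finally combines the markers into per-taxon
#' conclusions.  Fully deterministic under `config$seed`.
#'
#' @param reads Either a single [read_set] (one pooled run, demultiplexed by
#'   primer content) or a named list of [read_set] objects, one sequencing
#'   run per marker (the name is the marker the run targeted; carry-over
#'   from a previous run of the flow cell is then quantified).
#' @param refs A [reference_set] covering the markers.
#' @param primers Named list of [marker_primer_set] objects.
#' @param config A [pipeline_config].
#' @param absence_labels Optional data frame (`taxon`, `marker`, `label`)
#'   with experiment-derived absence codes such as "no amplicon".
#' @param output_dir Optional directory; when given, every intermediate is
#'   written there (filtered FASTQ, per-marker FASTQ, cluster and hit TSVs,
#'   consensus FASTA, final conclusions TSV, JSON report).
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(reads, refs, primers, config = pipeline_config(),
                         absence_labels = NULL, output_dir = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  if (inherits(reads, "read_set")) reads <- list(pooled = reads)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  fp <- filter_params(config$min_mean_q, config$min_len, config$max_len)
  pp <- primer_params(config$max_error_rate, config$min_overlap)
  marker_names <- vapply(primers, `[[`, character(1), "marker")
  stages <- list()
  trimmed <- stats::setNames(vector("list", length(marker_names)), marker_names)
  carry <- list()
  for (run in names(reads)) {
    flt <- filter_reads(reads[[run]], fp)
    cls <- classify_reads(flt$reads, unname(primers), pp)
    run_stage <- list(run = run, input = length(reads[[run]]),
                      filter = flt$stats,
                      classified = table(cls$marker))
    if (run %in% marker_names) {
      other <- cls$marker != "unassigned" & cls$marker != run
      n_cls <- sum(cls$marker != "unassigned")
      run_stage$carryover <- list(
        fraction = if (n_cls) sum(other) / n_cls else NA_real_,
        fraction_of_total = if (length(flt$reads)) sum(other) / length(flt$reads)
                            else NA_real_,
        n_other = sum(other), n_classified = n_cls
      )
      carry[[run]] <- run_stage$carryover
    }
    # In a single-marker run, reads carrying another marker's primers are
    # residual molecules from the previous run of the flow cell: they are
    # counted above and excluded from analysis.  In pooled mode every read
    # follows its classified marker.
    use_markers <- if (run %in% marker_names) run else marker_names
    for (mk in use_markers) {
      sel <- which(cls$marker == mk)
      if (!length(sel)) next
      tr <- trim_primers(flt$reads[sel], cls[sel, , drop = FALSE])
      run_stage[[paste0("trimmed_", mk)]] <- tr$stats
      trimmed[[mk]] <- if (is.null(trimmed[[mk]])) tr$reads
                       else c(trimmed[[mk]], tr$reads)
    }
    stages[[run]] <- run_stage
    if (!is.null(output_dir)) {
      write_fastq(flt$reads, file.path(output_dir,
                                       sprintf("%s_filtered.fastq", run)))
      utils::write.table(cls, file.path(output_dir,
                                        sprintf("%s_classification.tsv", run)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  per_marker_assign <- list()
  marker_stats <- list()
  all_consensus <- list()
  for (k in seq_along(marker_names)) {
    mk <- marker_names[k]
    rs <- trimmed[[mk]]
    if (is.null(rs) || length(rs) == 0L) {
      marker_stats[[mk]] <- list(reads = 0L, clusters = 0L, consensi = 0L)
      per_marker_assign[[mk]] <- list()
      next
    }
    if (!is.null(output_dir)) {
      write_fastq(rs, file.path(output_dir, sprintf("%s_trimmed.fastq", mk)))
    }
    clusters <- greedy_cluster(rs, threshold = config$cluster_threshold)
    consensi <- cluster_consensus(
      rs, clusters, markers = unname(primers), marker = mk,
      cap = config$subsample_cap, threshold = config$consensus_threshold,
      min_cluster_size = config$min_cluster_size, params = pp,
      seed = config$seed + 1000L * k
    )
    mrefs <- refs[refs$marker == mk, , drop = FALSE]
    class(mrefs) <- c("reference_set", "data.frame")
    assigns <- lapply(consensi, function(co) {
      assign_taxonomy(co, mrefs, min_identity = config$min_identity,
                      min_coverage = config$min_coverage,
                      score_margin = config$score_margin)
    })
    per_marker_assign[[mk]] <- assigns
    marker_stats[[mk]] <- list(reads = length(rs), clusters = length(clusters),
                               consensi = length(consensi))
    all_consensus[[mk]] <- consensi
    if (!is.null(output_dir)) {
      utils::write.table(cluster_table(clusters),
                         file.path(output_dir, sprintf("%s_clusters.tsv", mk)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(consensi)) {
        write_fasta(
          stats::setNames(
            vapply(consensi, `[[`, character(1), "sequence"),
            vapply(consensi, function(co) {
              sprintf("%s n_reads=%d", co$consensus_id, co$n_reads_used)
            }, character(1))
          ),
          file.path(output_dir, sprintf("%s_consensus.fasta", mk))
        )
        hits <- do.call(rbind, lapply(assigns, function(a) {
          if (nrow(a$hits)) a$hits[, c("consensus_id", "accession", "score",
                                       "identity", "coverage")]
          else NULL
        }))
        if (!is.null(hits)) {
          utils::write.table(hits,
                             file.path(output_dir, sprintf("%s_hits.tsv", mk)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  final <- combine_markers(per_marker_assign,
                           expected_markers = marker_names,
                           absence_labels = absence_labels)
  report <- structure(list(
    stages = stages, marker_stats = marker_stats,
    assignments = per_marker_assign, consensus = all_consensus,
    final = final, carryover = carry, config = unclass(config)
  ), class = "run_report")
  if (!is.null(output_dir)) {
    utils::write.table(final, file.path(output_dir, "final_conclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

# JSON-serializable view of a run report.
report_json <- function(report) {
  list(
    config = report$config,
    stages = lapply(report$stages, function(s) {
      s$classified <- as.list(s$classified)
      s
    }),
    marker_stats = report$marker_stats,
    assignments = lapply(report$assignments, function(as_) {
      lapply(as_, function(a) {
        list(consensus_id = a$consensus_id, rank = a$rank, taxon = a$taxon)
      })
    }),
    final = report$final
  )
}

#' Summarize a pipeline run as an identification table
#'
#' One row per detected lineage: per-marker call, final conclusion, flags —
#' the layout of a study's identification table.
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return The `final_conclusions` data frame.
#' @export
summary.run_report <- function(object, ...) {
  object$final
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (run in names(x$stages)) {
    s <- x$stages[[run]]
    cat(sprintf("  run %s: %d reads in, %d kept by filter\n",
                run, s$input, s$filter$kept))
  }
  for (mk in names(x$marker_stats)) {
    m <- x$marker_stats[[mk]]
    cat(sprintf("  marker %s: %d trimmed reads, %d clusters, %d consensi\n",
                mk, m$reads, m$clusters, m$consensi))
  }
  if (length(x$carryover)) {
    for (run in names(x$carryover)) {
      co <- x$carryover[[run]]
      if (!is.na(co$fraction)) {
        cat(sprintf("  run %s carry-over: %.1f%% of classified reads\n",
                    run, 100 * co$fraction))
      }
    }
  }
  cat("Final conclusions:\n")
  print.data.frame(x$final)
  invisible(x)
}
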
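#' Align a query against one reference barcode
#'
#' Smith-Waterman local alignment (match +1, mismatch -2, linear gap -2).
#' Both query strands are aligned and the better one kept, since cluster
#' representatives — and hence consensi — are in arbitrary orientation.
#' Identity is computed over the aligned columns and coverage over the
#' query.
#'
#' @param query Query nucleotide string (a consensus sequence).
#' @param subject Reference nucleotide string.
#' @return A list with `score`, `identity`, `coverage`, `strand`, and the
#'   0-based half-open intervals `q_start`, `q_end`, `s_start`, `s_end`
#'   (query coordinates are on the original, un-complemented query).
#' @export
align_to_reference <- function(query, subject) {
  query <- toupper(query); subject <- toupper(subject)
  if (!nchar(query) || !nchar(subject)) stop("sequences must be non-empty")
  score_one <- function(q) cpp_local_align(q, subject)
  fwd <- score_one(query)
  rev <- score_one(revcomp(query))
  strand <- "+"
  hit <- fwd
  if (rev$score > fwd$score) {
    hit <- rev
    strand <- "-"
    lq <- nchar(query)
    tmp <- hit
    hit$q_start <- lq - tmp$q_end
    hit$q_end <- lq - tmp$q_start
  }
  list(
    score = hit$score,
    identity = if (hit$columns > 0) 100 * hit$matches / hit$columns else 0,
    coverage = 100 * (hit$q_end - hit$q_start) / nchar(query),
    strand = strand,
    q_start = hit$q_start, q_end = hit$q_end,
    s_start = hit$s_start, s_end = hit$s_end
  )
}

#' Hit table of a consensus against a reference set
#'
#' @param consensus A `consensus_record` (or a bare named sequence string).
#' @param refs A [reference_set], usually restricted to one marker.
#' @return Data frame with one row per reference: accession, lineage,
#'   score, identity, coverage, strand and alignment intervals.
#' @export
reference_hits <- function(consensus, refs) {
  stopifnot(inherits(refs, "reference_set"))
  seq <- if (inherits(consensus, "consensus_record")) consensus$sequence else consensus
  cid <- if (inherits(consensus, "consensus_record")) consensus$consensus_id else "query"
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    h <- align_to_reference(seq, refs$sequence[i])
    data.frame(consensus_id = cid, accession = refs$accession[i],
               family = refs$family[i], genus = refs$genus[i],
               species = refs$species[i],
               score = h$score, identity = h$identity, coverage = h$coverage,
               strand = h$strand,
               q_start = h$q_start, q_end = h$q_end,
               s_start = h$s_start, s_end = h$s_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Taxonomic assignment of one consensus sequence
#'
#' Candidate hits are those with identity at or above `min_identity` and
#' query coverage at or above `min_coverage`.  Among candidates, hits whose
#' raw score is within `score_margin` of the best are retained, and the
#' assignment is the lowest common rank of their lineages: one species gives
#' a species-rank call; several species in one genus a genus call; several
#' genera in one family a family call; anything broader is unassigned.
#'
#' @param consensus A `consensus_record` or a nucleotide string.
#' @param refs A [reference_set] restricted to the consensus's marker.
#' @param min_identity Identity threshold in percent (default 98).
#' @param min_coverage Query-coverage threshold in percent (default 90).
#' @param score_margin Hits scoring at least `top score - score_margin` are
#'   retained (default 0: exact ties only).
#' @return An object of class `taxonomic_assignment`: list with
#'   `consensus_id`, `rank` (`"species"`, `"genus"`, `"family"` or
#'   `"unassigned"`), `taxon`, `family`, `genus`, `marker`, `hits` (the
#'   supporting hit rows).
#' @export
assign_taxonomy <- function(consensus, refs, min_identity = 98.0,
                            min_coverage = 90.0, score_margin = 0) {
  if (!nrow(refs)) stop("empty reference set")
  hits <- reference_hits(consensus, refs)
  marker <- if (inherits(consensus, "consensus_record")) consensus$marker else NA_character_
  cand <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
               drop = FALSE]
  mk <- function(rank, taxon, fam, gen, sup) {
    structure(list(consensus_id = hits$consensus_id[1], rank = rank,
                   taxon = taxon, family = fam, genus = gen,
                   marker = marker, hits = sup),
              class = "taxonomic_assignment")
  }
  if (!nrow(cand)) {
    return(mk("unassigned", "", NA_character_, NA_character_,
              cand))
  }
  top <- max(cand$score)
  sup <- cand[cand$score >= top - score_margin, , drop = FALSE]
  if (length(unique(sup$species)) == 1L) {
    return(mk("species", sup$species[1], sup$family[1], sup$genus[1], sup))
  }
  if (length(unique(sup$genus)) == 1L) {
    return(mk("genus", sup$genus[1], sup$family[1], sup$genus[1], sup))
  }
  if (length(unique(sup$family)) == 1L) {
    return(mk("family", sup$family[1], sup$family[1], NA_character_, sup))
  }
  mk("unassigned", "", NA_character_, NA_character_, sup)
}

#' Combine marker-level assignments into final conclusions
#'
#' Assignments from all markers are merged per lineage: a species-rank call
#' from either marker becomes the final identification provided every other
#' marker's call for that lineage is an ancestor (genus or family) or
#' absent.  Two species-rank calls naming different species in the same
#' genus raise the conflict flag and the final call retreats to the genus.
#' Genus- or family-rank calls with no species beneath them stand on their
#' own at that rank.  Markers with no call for a lineage are reported with
#' `absence_labels` (e.g. "no reads" vs "no amplicon", known from the
#' experiment) or `"no call"`.
#'
#' @param per_marker Named list (marker name -> list of
#'   `taxonomic_assignment` objects).
#' @param expected_markers Character vector of all markers in the study.
#' @param absence_labels Optional data frame with columns `taxon`, `marker`,
#'   `label` overriding the absence code for specific cells.
#' @return A data frame of class `final_conclusions`: one row per detected
#'   lineage with one column per marker, `final_rank`, `final_taxon` and
#'   `conflict`.
#' @export
combine_markers <- function(per_marker, expected_markers = names(per_marker),
                            absence_labels = NULL) {
  recs <- list()
  for (mk in names(per_marker)) {
    for (a in per_marker[[mk]]) {
      if (a$rank == "unassigned") next
      recs[[length(recs) + 1L]] <- data.frame(
        marker = mk, rank = a$rank, taxon = a$taxon,
        family = a$family,
        genus = if (is.na(a$genus)) NA_character_ else a$genus,
        species = if (a$rank == "species") a$taxon else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  empty <- data.frame(matrix(character(), nrow = 0,
                             ncol = length(expected_markers) + 3,
                             dimnames = list(NULL, c(expected_markers,
                                                     "final_rank", "final_taxon",
                                                     "conflict"))),
                      stringsAsFactors = FALSE)
  class(empty) <- c("final_conclusions", "data.frame")
  if (!length(recs)) return(empty)
  recs <- unique(do.call(rbind, recs))
  # A genus is in conflict when two markers both make species-rank calls in
  # it but agree on none of them: the markers then contradict each other for
  # what should be one organism.  Two congeners where only one marker covers
  # each (the dropout pattern) share no such contradiction.
  sp_recs <- recs[recs$rank == "species", , drop = FALSE]
  conflicted <- character()
  for (g in unique(sp_recs$genus)) {
    sets <- lapply(split(sp_recs$species[sp_recs$genus == g],
                         sp_recs$marker[sp_recs$genus == g]), unique)
    if (length(sets) >= 2L) {
      pairs <- utils::combn(length(sets), 2)
      for (p in seq_len(ncol(pairs))) {
        if (!length(intersect(sets[[pairs[1, p]]], sets[[pairs[2, p]]]))) {
          conflicted <- c(conflicted, g)
          break
        }
      }
    }
  }
  sp <- unique(sp_recs[!(sp_recs$genus %in% conflicted),
                       c("family", "genus", "species")])
  lineages <- sp
  if (length(conflicted)) {
    cf <- unique(sp_recs[sp_recs$genus %in% conflicted,
                         c("family", "genus")])
    lineages <- rbind(lineages,
                      data.frame(family = cf$family, genus = cf$genus,
                                 species = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  gn <- unique(recs[recs$rank == "genus", c("family", "genus")])
  if (nrow(gn)) {
    orphan <- !(gn$genus %in% lineages$genus)
    if (any(orphan)) {
      lineages <- rbind(lineages,
                        data.frame(family = gn$family[orphan],
                                   genus = gn$genus[orphan],
                                   species = NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  fm <- unique(recs[recs$rank == "family", "family", drop = FALSE])
  if (nrow(fm)) {
    orphan <- !(fm$family %in% lineages$family)
    if (any(orphan)) {
      lineages <- rbind(lineages,
                        data.frame(family = fm$family[orphan],
                                   genus = NA_character_,
                                   species = NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  rank_level <- c(family = 1L, genus = 2L, species = 3L)
  rows <- lapply(seq_len(nrow(lineages)), function(i) {
    lin <- lineages[i, ]
    conflict <- !is.na(lin$genus) && lin$genus %in% conflicted
    is_rel <- recs$family == lin$family &
      (recs$rank == "family" |
         (!is.na(lin$genus) & !is.na(recs$genus) & recs$genus == lin$genus &
            (recs$rank == "genus" | conflict |
               (!is.na(lin$species) & !is.na(recs$species) &
                  recs$species == lin$species))))
    sub <- recs[is_rel, , drop = FALSE]
    cells <- stats::setNames(rep(NA_character_, length(expected_markers)),
                             expected_markers)
    for (mk in expected_markers) {
      ms <- sub[sub$marker == mk, , drop = FALSE]
      if (!nrow(ms)) next
      lvl <- rank_level[ms$rank]
      best <- ms[lvl == max(lvl), , drop = FALSE]
      cells[mk] <- paste(unique(best$taxon), collapse = "/")
    }
    if (conflict) {
      final_rank <- "genus"; final_taxon <- lin$genus
    } else if (!is.na(lin$species)) {
      final_rank <- "species"; final_taxon <- lin$species
    } else if (!is.na(lin$genus)) {
      final_rank <- "genus"; final_taxon <- lin$genus
    } else {
      final_rank <- "family"; final_taxon <- lin$family
    }
    out <- as.data.frame(as.list(cells), stringsAsFactors = FALSE,
                         optional = TRUE)
    names(out) <- expected_markers
    out$final_rank <- final_rank
    out$final_taxon <- final_taxon
    out$conflict <- conflict
    out
  })
  out <- do.call(rbind, rows)
  # absence labels for markers with no call
  for (mk in expected_markers) {
    missing <- is.na(out[[mk]])
    out[[mk]][missing] <- "no call"
    if (!is.null(absence_labels)) {
      for (j in which(missing)) {
        lab <- absence_labels$label[absence_labels$marker == mk &
                                      absence_labels$taxon == out$final_taxon[j]]
        if (length(lab)) out[[mk]][j] <- lab[1]
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("final_conclusions", "data.frame")
  out
}
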
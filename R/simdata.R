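#' Nanopore-like read error profile
#'
#' Per-base probabilities of substitution, insertion and deletion applied
#' when simulating reads, plus the mean Phred score of the emitted quality
#' strings.  The default totals 13% (0.08 substitution, 0.025 insertion,
#' 0.025 deletion), the combined error level typical of the long-read
#' amplicon data this pipeline corrects; substitutions dominate in practice,
#' which is how the total is apportioned here.
#'
#' @param sub_rate,ins_rate,del_rate Per-base event probabilities in `[0,1]`;
#'   their sum must be below 1.
#' @param mean_q Mean Phred score of simulated quality strings.
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(sub_rate = 0.08, ins_rate = 0.025, del_rate = 0.025,
                          mean_q = 12) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 1, mean_q >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, mean_q = mean_q),
            class = "error_profile")
}

#' Species mixture profile
#'
#' Describes a multi-species template mixture: one weight fraction per
#' species plus the species/marker combinations that are expected to yield
#' nothing.  `marker_dropouts` models failed amplification (no reads at all
#' for that species and marker); `read_dropouts` models libraries whose reads
#' are produced but fall below the quality filter (reads are emitted with low
#' mean quality so the preprocessing stage removes them).
#'
#' @param species Character vector of species labels (each appears once).
#' @param weight Numeric weight fractions in `(0,1]` summing to 1.
#' @param marker_dropouts Data frame with columns `species`, `marker`.
#' @param read_dropouts Data frame with columns `species`, `marker`.
#' @return An object of class `mixture_profile`.
#' @export
mixture_profile <- function(species, weight,
                            marker_dropouts = NULL, read_dropouts = NULL) {
  species <- as.character(species)
  weight <- as.numeric(weight)
  stopifnot(length(species) == length(weight), all(weight > 0), all(weight <= 1))
  if (anyDuplicated(species)) stop("every species must appear once")
  if (abs(sum(weight) - 1) > 1e-9) stop("weight fractions must sum to 1")
  empty <- data.frame(species = character(), marker = character(),
                      stringsAsFactors = FALSE)
  structure(list(species = species, weight = weight,
                 marker_dropouts = marker_dropouts %||% empty,
                 read_dropouts = read_dropouts %||% empty),
            class = "mixture_profile")
}

#' Generate a synthetic barcode reference set
#'
#' Builds random barcode sequences with a controlled divergence structure:
#' one random root per family, genus roots mutated from the family root, and
#' species mutated from their genus root so that two species in the same
#' genus differ by approximately `inter_species_divergence` (substitutions
#' only).  Species in different families differ by much more.  One
#' independent barcode is drawn per marker.
#'
#' @param n_families Number of families (ignored when `lineages` is given).
#' @param species_per_genus Species per genus (ignored when `lineages` is given).
#' @param genera_per_family Genera per family (ignored when `lineages` is given).
#' @param barcode_length Barcode length in nt.
#' @param inter_species_divergence Target within-genus substitution fraction,
#'   in (0, 0.5).
#' @param markers Character vector of marker names.
#' @param seed Integer seed; the same seed reproduces the same set.
#' @param lineages Optional data frame with columns `family`, `genus`,
#'   `species` giving the exact taxa to generate instead of synthetic labels.
#' @return A [reference_set] covering all markers.
#' @export
generate_reference_set <- function(n_families = 2L, species_per_genus = 2L,
                                   genera_per_family = 1L,
                                   barcode_length = 600L,
                                   inter_species_divergence = 0.05,
                                   markers = c("cytb", "COI"),
                                   seed = 1L, lineages = NULL) {
  stopifnot(inter_species_divergence > 0, inter_species_divergence < 0.5,
            barcode_length >= 50)
  if (is.null(lineages)) {
    if (species_per_genus > 1 && inter_species_divergence <= 0) {
      stop("divergence 0 with more than one species per genus would give identical species")
    }
    lineages <- do.call(rbind, lapply(seq_len(n_families), function(f) {
      do.call(rbind, lapply(seq_len(genera_per_family), function(g) {
        data.frame(
          family = sprintf("Family%02d", f),
          genus = sprintf("Genus%02d_%02d", f, g),
          species = sprintf("Genus%02d_%02d species%02d", f, g,
                            seq_len(species_per_genus)),
          stringsAsFactors = FALSE
        )
      }))
    }))
  }
  with_seed(seed, {
    recs <- lapply(markers, function(mk) {
      fam_roots <- new.env(parent = emptyenv())
      gen_roots <- new.env(parent = emptyenv())
      seqs <- character(nrow(lineages))
      for (i in seq_len(nrow(lineages))) {
        fam <- lineages$family[i]
        gen <- lineages$genus[i]
        if (is.null(fam_roots[[fam]])) {
          fam_roots[[fam]] <- random_dna(barcode_length)
        }
        if (is.null(gen_roots[[gen]])) {
          gen_roots[[gen]] <- mutate_substitutions(
            fam_roots[[fam]], 2 * inter_species_divergence)
        }
        seqs[i] <- mutate_substitutions(
          gen_roots[[gen]], inter_species_divergence / 2)
      }
      reference_set(
        accession = sprintf("%s_REF%03d", mk, seq_len(nrow(lineages))),
        marker = mk, family = lineages$family, genus = lineages$genus,
        species = lineages$species, sequence = seqs
      )
    })
    out <- do.call(rbind, recs)
    class(out) <- c("reference_set", "data.frame")
    out
  })
}

#' Build an amplicon from a barcode and its primer pair
#'
#' The amplicon is forward primer + barcode + reverse complement of the
#' reverse primer, as produced by PCR.  Degenerate (IUPAC) primer positions
#' are resolved uniformly at random per call, from the caller's RNG stream.
#'
#' @param barcode Barcode nucleotide string.
#' @param primers A [marker_primer_set].
#' @return The amplicon nucleotide string.
#' @export
make_amplicon <- function(barcode, primers) {
  stopifnot(inherits(primers, "marker_primer_set"))
  fwd <- resolve_iupac(primers$forward[[1]])
  rev <- resolve_iupac(primers$reverse[[1]])
  paste0(fwd, toupper(barcode), revcomp(rev))
}

# Replace each IUPAC code by one of its bases, uniformly at random.
resolve_iupac <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  amb <- !(chars %in% DNA_BASES)
  if (any(amb)) {
    chars[amb] <- vapply(chars[amb], function(c) {
      set <- IUPAC_SETS[[c]]
      if (is.null(set)) stop(sprintf("not an IUPAC nucleotide code: '%s'", c))
      if (length(set) == 1L) set else sample(set, 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

# Apply the error model to one template; returns the read sequence.
corrupt_sequence <- function(template, profile) {
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  L <- length(chars)
  u <- stats::runif(L)
  del <- u < profile$del_rate
  sub <- !del & u < profile$del_rate + profile$sub_rate
  if (any(sub)) {
    chars[sub] <- vapply(chars[sub], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  ins <- stats::runif(L) < profile$ins_rate
  ins_base <- character(L)
  if (any(ins)) ins_base[ins] <- sample(DNA_BASES, sum(ins), replace = TRUE)
  emitted <- ifelse(del, "", chars)
  paste0(paste0(ins_base, emitted, collapse = ""))
}

#' Simulate noisy reads from one amplicon
#'
#' Walks the amplicon base by base: each position is deleted with
#' `del_rate`, substituted (to a uniformly chosen different base) with
#' `sub_rate`, and preceded by a uniform inserted base with `ins_rate`.
#' With probability `strand_flip_prob` the finished read is
#' reverse-complemented.  Qualities are integers drawn around the profile's
#' `mean_q`.  Deterministic under a fixed seed.
#'
#' @param amplicon Template nucleotide string.
#' @param n Number of reads.
#' @param profile An [error_profile].
#' @param strand_flip_prob Probability that a read is emitted on the minus
#'   strand.  The default 0.5 mirrors library molecules entering the pore in
#'   either orientation.
#' @param seed Integer seed, or `NULL` to use the caller's RNG stream.
#' @param id_prefix Prefix for generated read identifiers.
#' @return A [read_set] with `n` reads.
#' @export
simulate_reads <- function(amplicon, n, profile = error_profile(),
                           strand_flip_prob = 0.5, seed = NULL,
                           id_prefix = "sim") {
  stopifnot(n >= 0)
  with_seed(seed, {
    if (n == 0L) return(read_set())
    seqs <- character(n)
    quals <- vector("list", n)
    flips <- stats::runif(n) < strand_flip_prob
    for (i in seq_len(n)) {
      s <- corrupt_sequence(amplicon, profile)
      if (flips[i]) s <- revcomp(s)
      q <- as.integer(pmin(41L, pmax(1L, round(stats::rnorm(nchar(s),
                                                            profile$mean_q, 3)))))
      seqs[i] <- s
      quals[[i]] <- q
    }
    rs <- read_set(id = sprintf("%s_%05d", id_prefix, seq_len(n)),
                   seq = seqs, qual = quals)
    attr(rs, "strand") <- ifelse(flips, "-", "+")
    rs
  })
}

#' Simulate one sequencing run of a species mixture
#'
#' Reads are allocated to species by multinomial sampling proportional to the
#' mixture weight fractions, renormalized over the species that amplify for
#' `marker` (species listed in `marker_dropouts` contribute nothing).
#' Species listed in `read_dropouts` are simulated at mean Phred 6 so the
#' quality filter removes them downstream.  When `carryover` is given, the
#' stated fraction of the output is drawn from the supplied other-marker read
#' set, emulating residual molecules from the previous run of a reused flow
#' cell.
#'
#' @param mixture A [mixture_profile].
#' @param refs A [reference_set] holding a barcode for every amplifying
#'   mixture species at `marker`.
#' @param primers A [marker_primer_set] for `marker`.
#' @param marker Marker name for this run.
#' @param total_reads Total number of reads to emit.
#' @param profile An [error_profile].
#' @param strand_flip_prob Per-read minus-strand probability.
#' @param carryover Optional `list(reads = <read_set>, fraction = <number>)`.
#' @param seed Integer seed.
#' @return A [read_set] with a `truth` attribute: a data frame with columns
#'   `read_id`, `species`, `marker`, `source`.
#' @export
simulate_mixture_run <- function(mixture, refs, primers, marker, total_reads,
                                 profile = error_profile(),
                                 strand_flip_prob = 0.5,
                                 carryover = NULL, seed = 1L) {
  stopifnot(inherits(mixture, "mixture_profile"),
            inherits(refs, "reference_set"))
  md <- mixture$marker_dropouts
  rd <- mixture$read_dropouts
  dropped <- md$species[md$marker == marker]
  lowq <- rd$species[rd$marker == marker]
  active <- setdiff(mixture$species, dropped)
  missing_ref <- setdiff(active, refs$species[refs$marker == marker])
  if (length(missing_ref)) {
    stop(sprintf("species without a %s reference and not a declared dropout: %s",
                 marker, paste(missing_ref, collapse = ", ")))
  }
  with_seed(seed, {
    n_carry <- 0L
    if (!is.null(carryover) && carryover$fraction > 0) {
      n_carry <- as.integer(round(carryover$fraction * total_reads))
    }
    n_own <- total_reads - n_carry
    w <- mixture$weight[match(active, mixture$species)]
    counts <- if (length(active) && n_own > 0) {
      as.integer(stats::rmultinom(1, n_own, w / sum(w)))
    } else {
      integer(length(active))
    }
    parts <- list()
    truth <- list()
    for (k in seq_along(active)) {
      if (counts[k] == 0L) next
      sp <- active[k]
      ref_row <- which(refs$marker == marker & refs$species == sp)[1]
      amplicon <- make_amplicon(refs$sequence[ref_row], primers)
      prof <- profile
      if (sp %in% lowq) prof$mean_q <- 6
      slug <- gsub("[^A-Za-z0-9]+", "_", sp)
      rs <- simulate_reads(amplicon, counts[k], prof, strand_flip_prob,
                           seed = NULL,
                           id_prefix = sprintf("%s_%s", marker, slug))
      parts[[length(parts) + 1L]] <- rs
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = rs$id, species = sp, marker = marker,
        strand = attr(rs, "strand"), source = "mixture",
        stringsAsFactors = FALSE
      )
    }
    if (n_carry > 0L) {
      pool <- carryover$reads
      idx <- sample(length(pool), n_carry, replace = n_carry > length(pool))
      cr <- pool[idx]
      cr$id <- sprintf("carry_%05d_%s", seq_len(n_carry), cr$id)
      parts[[length(parts) + 1L]] <- cr
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = cr$id, species = NA_character_, marker = "carryover",
        strand = NA_character_, source = "carryover",
        stringsAsFactors = FALSE
      )
    }
    out <- if (length(parts)) do.call(c, parts) else read_set()
    tr <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(read_id = character(), species = character(),
                 marker = character(), strand = character(),
                 source = character(), stringsAsFactors = FALSE)
    }
    if (length(out)) {
      perm <- sample(length(out))
      out <- out[perm]
      tr <- tr[match(out$id, tr$read_id), , drop = FALSE]
      rownames(tr) <- NULL
    }
    attr(out, "truth") <- tr
    out
  })
}
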
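#' Demonstration primer sets for two mitochondrial markers
#'
#' A pair of [marker_primer_set] objects for the cytochrome b and COI
#' barcode markers, with a few IUPAC-degenerate positions like typical fish
#' barcoding primers.  They drive the simulator and the examples; real
#' analyses supply their own primers.
#'
#' @return Named list of two [marker_primer_set] objects.
#' @export
demo_primer_sets <- function() {
  list(
    cytb = marker_primer_set(
      "cytb",
      forward = "GTGACYTGAAAAACCACCGTTG",
      reverse = "CTCCGATCTYCGGATTACAAGAC"
    ),
    COI = marker_primer_set(
      "COI",
      forward = "TCGACYAATCAYAAAGATATCGGC",
      reverse = "ACTTCYGGGTGRCCAAAGAATC"
    )
  )
}

#' Demonstration fish mixtures
#'
#' Two experimental flatfish-dominated mixtures used throughout the examples
#' and tests.  Mixture "a" holds six species (one at 75% by weight, five at
#' 5%), with no COI amplicon for Scophthalmus rhombus and no usable cytb
#' reads for Limanda aspera.  Mixture "b" holds eleven species (17% plus ten
#' at 8%), with no COI amplicon for Scophthalmus maximus, no cytb amplicon
#' for Osmerus eperlanus, and no usable cytb reads for Limanda aspera.
#'
#' @param which `"a"` (six species) or `"b"` (eleven species).
#' @return A [mixture_profile] with a `lineages` attribute (data frame with
#'   columns `family`, `genus`, `species`).
#' @export
fish_mixture <- function(which = c("a", "b")) {
  which <- match.arg(which)
  if (which == "a") {
    lin <- data.frame(
      family = c("Pleuronectidae", "Pleuronectidae", "Pleuronectidae",
                 "Pleuronectidae", "Pleuronectidae", "Scophthalmidae"),
      genus = c("Pleuronectes", "Limanda", "Microstomus", "Limanda",
                "Platichthys", "Scophthalmus"),
      species = c("Pleuronectes platessa", "Limanda limanda",
                  "Microstomus kitt", "Limanda aspera",
                  "Platichthys flesus", "Scophthalmus rhombus"),
      stringsAsFactors = FALSE
    )
    mix <- mixture_profile(
      species = lin$species,
      weight = c(0.75, 0.05, 0.05, 0.05, 0.05, 0.05),
      marker_dropouts = data.frame(species = "Scophthalmus rhombus",
                                   marker = "COI", stringsAsFactors = FALSE),
      read_dropouts = data.frame(species = "Limanda aspera",
                                 marker = "cytb", stringsAsFactors = FALSE)
    )
  } else {
    lin <- data.frame(
      family = c("Pleuronectidae", "Pleuronectidae", "Pleuronectidae",
                 "Pleuronectidae", "Pleuronectidae", "Agonidae", "Cottidae",
                 "Pleuronectidae", "Zoarcidae", "Osmeridae", "Scophthalmidae"),
      genus = c("Microstomus", "Pleuronectes", "Limanda", "Limanda",
                "Platichthys", "Agonus", "Myoxocephalus", "Hippoglossoides",
                "Zoarces", "Osmerus", "Scophthalmus"),
      species = c("Microstomus kitt", "Pleuronectes platessa",
                  "Limanda limanda", "Limanda aspera", "Platichthys flesus",
                  "Agonus cataphractus", "Myoxocephalus scorpius",
                  "Hippoglossoides platessoides", "Zoarces viviparus",
                  "Osmerus eperlanus", "Scophthalmus maximus"),
      stringsAsFactors = FALSE
    )
    mix <- mixture_profile(
      species = lin$species,
      weight = c(0.17, rep(0.083, 10)),
      marker_dropouts = data.frame(
        species = c("Scophthalmus maximus", "Osmerus eperlanus"),
        marker = c("COI", "cytb"), stringsAsFactors = FALSE),
      read_dropouts = data.frame(species = "Limanda aspera",
                                 marker = "cytb", stringsAsFactors = FALSE)
    )
  }
  attr(mix, "lineages") <- lin
  mix
}

#' Demonstration reference set for the fish mixtures
#'
#' Builds a synthetic barcode reference set for [fish_mixture()] with a
#' controlled inter-species divergence, plus two deliberate database
#' pathologies for mixture "b" that real reference databases exhibit:
#'
#' * database incompleteness: the Agonus cataphractus cytb record is
#'   omitted, while two other Agonidae genera carry its cytb haplotype, so
#'   cytb consensi of this species resolve only to family rank;
#' * lack of genetic variability: a second Myoxocephalus species shares the
#'   M. scorpius COI haplotype, so COI consensi of M. scorpius resolve only
#'   to genus rank.
#'
#' @param which Mixture, `"a"` or `"b"`.
#' @param barcode_length Barcode length in nt.
#' @param divergence Within-genus substitution divergence (default 0.05).
#' @param seed Integer seed.
#' @return A [reference_set] for markers cytb and COI.
#' @export
demo_reference_set <- function(which = c("a", "b"), barcode_length = 600L,
                               divergence = 0.05, seed = 100L) {
  which <- match.arg(which)
  lin <- attr(fish_mixture(which), "lineages")
  refs <- generate_reference_set(barcode_length = barcode_length,
                                 inter_species_divergence = divergence,
                                 markers = c("cytb", "COI"),
                                 seed = seed, lineages = lin)
  if (which == "b") {
    ago <- refs$sequence[refs$marker == "cytb" &
                           refs$species == "Agonus cataphractus"]
    refs <- refs[!(refs$marker == "cytb" &
                     refs$species == "Agonus cataphractus"), ]
    twins <- reference_set(
      accession = c("cytb_AGO001", "cytb_AGO002"),
      marker = "cytb", family = "Agonidae",
      genus = c("Leptagonus", "Podothecus"),
      species = c("Leptagonus decagonus", "Podothecus veternus"),
      sequence = ago
    )
    myx <- refs$sequence[refs$marker == "COI" &
                           refs$species == "Myoxocephalus scorpius"]
    twin2 <- reference_set(
      accession = "COI_MYX001", marker = "COI", family = "Cottidae",
      genus = "Myoxocephalus", species = "Myoxocephalus quadricornis",
      sequence = myx
    )
    refs <- rbind(refs, twins, twin2)
    class(refs) <- c("reference_set", "data.frame")
    rownames(refs) <- NULL
  }
  refs
}

#' Simulate the two sequencing runs of a demonstration study
#'
#' One run per marker (markers are sequenced in separate runs of a reused
#' flow cell), at the default 13% total error profile.
#'
#' @param which Mixture, `"a"` or `"b"`.
#' @param reads_per_marker Total reads per marker run.
#' @param refs Optional [reference_set]; defaults to
#'   [demo_reference_set()] for `which`.
#' @param profile An [error_profile].
#' @param seed Integer seed.
#' @return A list with `reads` (named list of [read_set] per marker),
#'   `refs`, `mixture`, `primers`.
#' @export
simulate_demo_study <- function(which = c("a", "b"), reads_per_marker = 8000L,
                                refs = NULL, profile = error_profile(),
                                seed = 1L) {
  which <- match.arg(which)
  mix <- fish_mixture(which)
  primers <- demo_primer_sets()
  if (is.null(refs)) refs <- demo_reference_set(which)
  # The omitted A. cataphractus cytb reference must still template its
  # reads: simulate from a full reference set, assign from the pruned one.
  sim_refs <- if (which == "b") {
    full <- generate_reference_set(barcode_length = 600L,
                                   inter_species_divergence = 0.05,
                                   markers = c("cytb", "COI"), seed = 100L,
                                   lineages = attr(mix, "lineages"))
    full
  } else {
    refs
  }
  reads <- list()
  for (i in seq_along(primers)) {
    mk <- names(primers)[i]
    reads[[mk]] <- simulate_mixture_run(
      mix, sim_refs, primers[[mk]], mk, reads_per_marker,
      profile = profile, seed = seed + i
    )
  }
  list(reads = reads, refs = refs, mixture = mix, primers = primers)
}
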
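ref_fixture <- function() {
  set.seed(51)
  seqs <- c(a = random_dna_str(600))
  seqs["b"] <- mutate_str(seqs["a"], 0.05)   # congener of a, ~95% identity
  seqs["c"] <- random_dna_str(600)           # different family
  seqs["d"] <- mutate_str(seqs["c"], 0.05)   # congener of c
  reference_set(
    accession = sprintf("R%d", 1:4), marker = "cytb",
    family = c("FamA", "FamA", "FamB", "FamB"),
    genus = c("GenA", "GenA", "GenB", "GenB"),
    species = c("GenA alpha", "GenA beta", "GenB gamma", "GenB delta"),
    sequence = unname(seqs)
  )
}

test_that("local alignment reports score, identity and query-side coverage", {
  refs <- ref_fixture()
  q <- refs$sequence[1]
  h <- align_to_reference(q, refs$sequence[1])
  expect_equal(h$identity, 100)
  expect_equal(h$coverage, 100)
  expect_equal(h$score, 600)
  expect_equal(h$strand, "+")

  # 12 scattered substitutions over 600 nt -> identity 98.0 (588/600)
  qm <- q
  pos <- seq(25, by = 48, length.out = 12)
  for (p in pos) {
    substr(qm, p, p) <- setdiff(c("A", "C", "G", "T"), substr(qm, p, p))[1]
  }
  h2 <- align_to_reference(qm, refs$sequence[1])
  expect_equal(h2$identity, 98.0)

  # a query matching only half the reference still has 100% query coverage
  half <- substr(q, 1, 300)
  h3 <- align_to_reference(half, refs$sequence[1])
  expect_equal(h3$coverage, 100)
  expect_equal(h3$s_end - h3$s_start, 300)

  # minus-strand queries align equally well, with the strand recorded
  h4 <- align_to_reference(revcomp(q), refs$sequence[1])
  expect_equal(h4$score, 600)
  expect_equal(h4$strand, "-")
})

test_that("assignment resolves rank from threshold-passing, score-tied hits", {
  refs <- ref_fixture()
  # clean consensus of species alpha: species rank
  a <- assign_taxonomy(refs$sequence[1], refs)
  expect_equal(a$rank, "species")
  expect_equal(a$taxon, "GenA alpha")

  # best hit below 98% identity (15 substitutions over 600 nt): unassigned
  far <- refs$sequence[1]
  for (p in seq(20, by = 38, length.out = 15)) {
    substr(far, p, p) <- setdiff(c("A", "C", "G", "T"), substr(far, p, p))[1]
  }
  a2 <- assign_taxonomy(far, refs)
  expect_equal(a2$rank, "unassigned")
  expect_equal(a2$taxon, "")

  # two identical references under different species names tie exactly:
  # genus rank when they share the genus ...
  twins <- refs
  twins$sequence[2] <- twins$sequence[1]
  class(twins) <- c("reference_set", "data.frame")
  a3 <- assign_taxonomy(twins$sequence[1], twins)
  expect_equal(a3$rank, "genus")
  expect_equal(a3$taxon, "GenA")

  # ... family rank when they only share the family
  fam <- twins
  fam$genus[2] <- "GenA2"
  class(fam) <- c("reference_set", "data.frame")
  a4 <- assign_taxonomy(fam$sequence[1], fam)
  expect_equal(a4$rank, "family")
  expect_equal(a4$taxon, "FamA")

  expect_error(assign_taxonomy("ACGT", refs[0, ]), "empty reference")
})

test_that("raising thresholds never yields a more specific rank", {
  refs <- ref_fixture()
  twins <- refs
  twins$sequence[2] <- twins$sequence[1]
  class(twins) <- c("reference_set", "data.frame")
  rank_level <- c(unassigned = 0, family = 1, genus = 2, species = 3)
  set.seed(53)
  queries <- c(refs$sequence[1],
               mutate_str(refs$sequence[1], 0.01),
               mutate_str(refs$sequence[3], 0.015),
               twins$sequence[1])
  for (q in queries) {
    for (rf in list(refs, twins)) {
      base <- rank_level[[assign_taxonomy(q, rf, 98, 90)$rank]]
      for (ident in c(98.5, 99, 99.9)) {
        expect_lte(rank_level[[assign_taxonomy(q, rf, ident, 90)$rank]], base)
      }
      for (cov in c(95, 99, 100)) {
        expect_lte(rank_level[[assign_taxonomy(q, rf, 98, cov)$rank]], base)
      }
    }
  }
})

test_that("error-free consensi recover species rank with identity 100", {
  refs <- ref_fixture()
  for (i in seq_len(nrow(refs))) {
    a <- assign_taxonomy(refs$sequence[i], refs)
    expect_equal(a$rank, "species")
    expect_equal(a$taxon, refs$species[i])
    expect_equal(max(a$hits$identity), 100)
  }
})

test_that("marker combination merges lineages and flags real conflicts", {
  mk_assign <- function(rank, taxon, fam, gen, marker) {
    structure(list(consensus_id = "c", rank = rank, taxon = taxon,
                   family = fam, genus = gen, marker = marker,
                   hits = data.frame()),
              class = "taxonomic_assignment")
  }
  # family call on one marker + species call on the other -> species final
  fc <- combine_markers(list(
    cytb = list(mk_assign("family", "Agonidae", "Agonidae", NA, "cytb")),
    COI = list(mk_assign("species", "Agonus cataphractus", "Agonidae",
                         "Agonus", "COI"))
  ))
  expect_equal(nrow(fc), 1L)
  expect_equal(fc$final_taxon, "Agonus cataphractus")
  expect_equal(fc$final_rank, "species")
  expect_equal(fc$cytb, "Agonidae")
  expect_false(fc$conflict)

  # species on one marker, nothing on the other -> species final, absence coded
  fc2 <- combine_markers(list(
    cytb = list(mk_assign("species", "Scophthalmus maximus", "Scophthalmidae",
                          "Scophthalmus", "cytb")),
    COI = list()
  ), absence_labels = data.frame(taxon = "Scophthalmus maximus",
                                 marker = "COI", label = "no amplicon"))
  expect_equal(fc2$final_taxon, "Scophthalmus maximus")
  expect_equal(fc2$COI, "no amplicon")

  # different species, same genus, different markers, no agreement -> conflict
  fc3 <- combine_markers(list(
    cytb = list(mk_assign("species", "Limanda limanda", "Pleuronectidae",
                          "Limanda", "cytb")),
    COI = list(mk_assign("species", "Limanda aspera", "Pleuronectidae",
                         "Limanda", "COI"))
  ))
  expect_equal(nrow(fc3), 1L)
  expect_true(fc3$conflict)
  expect_equal(fc3$final_rank, "genus")
  expect_equal(fc3$final_taxon, "Limanda")

  # two congeners where the markers agree on one of them: no conflict
  fc4 <- combine_markers(list(
    cytb = list(mk_assign("species", "Limanda limanda", "Pleuronectidae",
                          "Limanda", "cytb")),
    COI = list(mk_assign("species", "Limanda limanda", "Pleuronectidae",
                         "Limanda", "COI"),
               mk_assign("species", "Limanda aspera", "Pleuronectidae",
                         "Limanda", "COI"))
  ))
  expect_equal(nrow(fc4), 2L)
  expect_false(any(fc4$conflict))
  expect_setequal(fc4$final_taxon, c("Limanda limanda", "Limanda aspera"))

  # genus-rank call with species beneath it merges; orphan genus stands alone
  fc5 <- combine_markers(list(
    cytb = list(mk_assign("species", "Myoxocephalus scorpius", "Cottidae",
                          "Myoxocephalus", "cytb")),
    COI = list(mk_assign("genus", "Myoxocephalus", "Cottidae",
                         "Myoxocephalus", "COI"))
  ))
  expect_equal(nrow(fc5), 1L)
  expect_equal(fc5$final_taxon, "Myoxocephalus scorpius")
  expect_equal(fc5$COI, "Myoxocephalus")

  # empty input
  fc6 <- combine_markers(list(cytb = list(), COI = list()),
                         expected_markers = c("cytb", "COI"))
  expect_equal(nrow(fc6), 0L)
})
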
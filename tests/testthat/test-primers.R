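test_that("primer hits respect the edit budget and minimum overlap", {
  set.seed(11)
  primer <- random_dna_str(20)
  txt <- paste0(random_dna_str(40), primer, random_dna_str(40))
  h <- find_primer(txt, primer)
  expect_equal(h$edits, 0)
  expect_equal(h$read_start, 40)
  expect_equal(h$read_end, 60)

  # floor(0.20 * 20) = 4: four scattered substitutions still hit ...
  mut <- function(p, k) {
    chars <- strsplit(p, "")[[1]]
    pos <- seq(2, by = 4, length.out = k)
    chars[pos] <- vapply(chars[pos],
                         function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(chars, collapse = "")
  }
  t4 <- paste0(strrep("T", 30), mut(primer, 4), strrep("T", 30))
  expect_equal(find_primer(t4, primer)$edits, 4)
  # ... five do not (no other chance match in a T-homopolymer context)
  t5 <- paste0(strrep("T", 30), mut(primer, 5), strrep("T", 30))
  h5 <- find_primer(t5, primer)
  expect_true(is.null(h5) || h5$edits <= 4)

  # an overhanging primer with only 14 nt inside the read is rejected
  expect_null(find_primer(substr(primer, 7, 20), primer, min_overlap = 15))
  # with 15 nt inside it qualifies
  expect_equal(find_primer(substr(primer, 6, 20), primer,
                           min_overlap = 15)$matched_len, 15)

  expect_error(find_primer("ACGT", "ACGTACGTACGT", min_overlap = 15),
               "shorter than min_overlap")
})

test_that("the primer matcher agrees with the brute-force semi-global oracle", {
  set.seed(21)
  params <- primer_params(max_error_rate = 0.25, min_overlap = 8L)
  n_agree <- 0L
  for (case in 1:120) {
    m <- sample(8:18, 1)
    n <- sample(12:60, 1)
    primer <- random_dna_str(m, alphabet = c("A", "C", "G", "T", "R", "Y"))
    txt <- if (runif(1) < 0.5) {
      random_dna_str(n)
    } else {
      # plant a mutated copy so hits are common
      core <- chartr("RY", "AT", primer)
      pre <- random_dna_str(sample(0:20, 1))
      paste0(pre, mutate_str(core, 0.15), random_dna_str(sample(0:20, 1)))
    }
    got <- find_primer(txt, primer, params$max_error_rate, params$min_overlap)
    want <- oracle_find_primer(txt, primer, params$max_error_rate,
                               params$min_overlap)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$edits, want$edits)
      expect_equal(got$read_start, want$read_start)
      expect_equal(got$read_end, want$read_end)
      expect_equal(got$matched_len, want$matched_len)
    }
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 120L)
})

test_that("IUPAC codes are free on the primer side only; read N never matches", {
  h <- find_primer("TTTTTTTTTTAGAGAGAGAGTTTTTTTTTT", "RGRGRGRGRG",
                   max_error_rate = 0, min_overlap = 10)
  expect_equal(h$edits, 0)
  # N in the read is a mismatch even against primer N
  hN <- find_primer("TTTTTTTTTTAGAGNGAGAGTTTTTTTTTT", "AGAGNGAGAG",
                    max_error_rate = 0.2, min_overlap = 10)
  expect_equal(hN$edits, 1)
})

test_that("error-free amplicon reads classify to their marker with full truth", {
  set.seed(31)
  primers <- demo_primer_sets()
  refs <- generate_reference_set(n_families = 2L, species_per_genus = 1L,
                                 markers = c("cytb", "COI"), seed = 12L)
  mix <- mixture_profile(unique(refs$species), c(0.5, 0.5))
  none <- error_profile(0, 0, 0)
  for (mk in c("cytb", "COI")) {
    run <- simulate_mixture_run(mix, refs, primers[[mk]], mk, 40L,
                                profile = none, seed = 3L)
    cls <- classify_reads(run, unname(primers))
    expect_true(all(cls$marker == mk))
    truth <- attr(run, "truth")
    expect_equal(cls$orientation,
                 truth$strand[match(cls$read_id, truth$read_id)])
    expect_true(all(cls$n_hits == 2L))
  }
  # reverse-complemented reads classify with minus orientation
  runm <- simulate_mixture_run(mix, refs, primers$COI, "COI", 10L,
                               profile = none, strand_flip_prob = 1,
                               seed = 4L)
  clsm <- classify_reads(runm, unname(primers))
  expect_true(all(clsm$marker == "COI"))
  expect_true(all(clsm$orientation == "-"))

  # random sequence carries no primers
  rnd <- read_set("x", random_dna_str(600), list(rep(12L, 600)))
  expect_equal(classify_reads(rnd, unname(primers))$marker, "unassigned")
})

test_that("primer trimming keeps the insert between the hits", {
  primers <- list(marker_primer_set("m", strrep("A", 15), strrep("G", 15)))
  insert <- strrep("C", 100)
  amp <- paste0(strrep("A", 15), insert, strrep("C", 15))  # revcomp(G*) = C*
  # use a distinctive insert so hits are unambiguous
  set.seed(5)
  insert <- random_dna_str(100)
  amp <- paste0(strrep("A", 15), insert, strrep("C", 15))
  rs <- read_set("r", amp, list(rep(12L, nchar(amp))))
  cls <- classify_reads(rs, primers)
  tr <- trim_primers(rs, cls)
  expect_equal(tr$reads$seq, insert)
  expect_equal(tr$stats$kept, 1L)

  # trimmed reads carry no exact primer substring at their termini
  expect_false(startsWith(tr$reads$seq, strrep("A", 15)))
  expect_false(endsWith(tr$reads$seq, strrep("C", 15)))

  # zero-length insert between adjacent hits is dropped and counted
  rs0 <- read_set("r0", paste0(strrep("A", 15), strrep("C", 15)),
                  list(rep(12L, 30)))
  cls0 <- classify_reads(rs0, primers)
  tr0 <- trim_primers(rs0, cls0)
  expect_equal(tr0$stats$kept + tr0$stats$dropped_overlap +
                 tr0$stats$dropped_empty, 1L)
  expect_equal(length(tr0$reads), tr0$stats$kept)

  # a single-end hit trims that end only
  one <- paste0(strrep("A", 15), insert)
  rs1 <- read_set("r1", one, list(rep(12L, nchar(one))))
  cls1 <- classify_reads(rs1, primers)
  if (!is.na(cls1$fwd_start[1]) && is.na(cls1$rev_start[1])) {
    tr1 <- trim_primers(rs1, cls1)
    expect_equal(tr1$reads$seq, insert)
  }
})

test_that("carry-over fraction recovers an injected contamination level", {
  set.seed(41)
  primers <- demo_primer_sets()
  refs <- generate_reference_set(n_families = 1L, species_per_genus = 1L,
                                 markers = c("cytb", "COI"), seed = 13L)
  mix <- mixture_profile(refs$species[1], 1)
  cytb_pool <- simulate_mixture_run(mix, refs, primers$cytb, "cytb", 400L,
                                    seed = 6L)
  run <- simulate_mixture_run(mix, refs, primers$COI, "COI", 1500L,
                              carryover = list(reads = cytb_pool,
                                               fraction = 0.14),
                              seed = 7L)
  est <- carryover_fraction(run, "COI", list(primers$cytb), primers$COI)
  expect_gt(est$fraction, 0.12)
  expect_lt(est$fraction, 0.16)
  expect_lte(est$n_other, est$n_classified)

  # boundary cases
  clean <- simulate_mixture_run(mix, refs, primers$COI, "COI", 200L, seed = 8L)
  expect_equal(carryover_fraction(clean, "COI", list(primers$cytb),
                                  primers$COI)$fraction, 0)
  all_other <- simulate_mixture_run(mix, refs, primers$cytb, "cytb", 200L,
                                    seed = 9L)
  expect_equal(carryover_fraction(all_other, "COI", list(primers$cytb),
                                  primers$COI)$fraction, 1)
  empty <- read_set()
  expect_true(is.na(carryover_fraction(empty, "COI", list(primers$cytb),
                                       primers$COI)$fraction))
})
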
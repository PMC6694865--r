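test_that("subsampling caps cluster size at 100 deterministically", {
  cl <- list(cluster_id = 1L, representative_id = "m001",
             member_ids = sprintf("m%03d", 1:250), size = 250L)
  ids <- subsample_cluster(cl, cap = 100L, seed = 9L)
  expect_equal(length(ids), 100L)
  expect_true(all(ids %in% cl$member_ids))
  expect_identical(ids, subsample_cluster(cl, cap = 100L, seed = 9L))

  small <- list(cluster_id = 2L, representative_id = "s1",
                member_ids = sprintf("s%d", 1:80), size = 80L)
  expect_identical(subsample_cluster(small, cap = 100L, seed = 1L),
                   small$member_ids)
})

test_that("orientation flips reads onto the representative strand", {
  set.seed(21)
  template <- random_dna_str(300)
  rs <- simulate_reads(template, 20, error_profile(), strand_flip_prob = 0.5,
                       seed = 22)
  ori <- orient_reads(rs, template)
  expect_equal(ori$flipped, attr(rs, "strand") == "-")
  for (s in ori$reads$seq) {
    expect_gte(pairwise_identity(s, template), 80)
  }
  # identical read stays, exact reverse complement flips
  two <- read_set(c("same", "flip"), c(template, revcomp(template)),
                  list(rep(12L, 300), rep(12L, 300)))
  o2 <- orient_reads(two, template)
  expect_equal(o2$flipped, c(FALSE, TRUE))
  expect_equal(o2$reads$seq, c(template, template))
})

test_that("the center-star MSA preserves its input rows", {
  set.seed(23)
  template <- random_dna_str(200)
  rs <- simulate_reads(template, 15, error_profile(), strand_flip_prob = 0,
                       seed = 24)
  msa <- build_msa(rs, seed = 1L)
  expect_equal(length(msa$rows), 15L)
  expect_equal(length(unique(nchar(msa$rows))), 1L)
  degapped <- gsub("-", "", msa$rows, fixed = TRUE)
  expect_equal(degapped, rs$seq)

  # two identical reads align without gap columns
  two <- read_set(c("a", "b"), c(template, template),
                  list(rep(12L, 200), rep(12L, 200)))
  m2 <- build_msa(two, seed = 1L)
  expect_equal(m2$ncol, 200L)
  expect_false(any(grepl("-", m2$rows, fixed = TRUE)))

  expect_error(build_msa(two[1], seed = 1L), "at least 2")
})

test_that("majority consensus applies the 30% rule with documented tie-breaks", {
  mkmsa <- function(rows) {
    structure(list(rows = rows, row_ids = seq_along(rows),
                   ncol = nchar(rows[1]), center_id = "1"), class = "msa")
  }
  # column {A:60%, C:40%} -> A with support 0.6
  co <- majority_consensus(mkmsa(c("A", "A", "A", "C", "C")))
  expect_equal(co$sequence, "A")
  expect_equal(co$column_support, 0.6)

  # four-way 25% tie: top frequency not above 30% -> column dropped
  co2 <- majority_consensus(mkmsa(c("A", "C", "G", "T")))
  expect_equal(co2$sequence, "")

  # {-:70%, A:30%}: gap wins -> dropped
  co3 <- majority_consensus(mkmsa(c(rep("-", 7), rep("A", 3))))
  expect_equal(co3$sequence, "")

  # base-vs-gap tie favors the base
  co4 <- majority_consensus(mkmsa(c("A", "A", "-", "-")))
  expect_equal(co4$sequence, "A")
  expect_equal(co4$column_support, 0.5)

  # base-vs-base ties break alphabetically
  co5 <- majority_consensus(mkmsa(c("T", "T", "G", "G", "A")))
  expect_equal(co5$sequence, "G")

  # N is excluded from the tally (support over non-N symbols)
  co6 <- majority_consensus(mkmsa(c("A", "A", "N", "N", "C")))
  expect_equal(co6$sequence, "A")
  expect_equal(co6$column_support, 2 / 3)

  # strict ">" at the threshold: exactly 30% does not qualify
  co7 <- majority_consensus(mkmsa(c("A", "A", "A", "C", "C", "C", "G", "G",
                                    "G", "T")), threshold = 0.30)
  expect_equal(co7$sequence, "")

  # threshold 0 with a single row returns the row unchanged
  co8 <- majority_consensus(mkmsa("ACGTT"), threshold = 0)
  expect_equal(co8$sequence, "ACGTT")
  expect_true(all(co8$column_support == 1))

  # emitted support always lies in (threshold, 1]
  expect_true(all(co$column_support > 0.3 & co$column_support <= 1))
})

test_that("primer residues are stripped from consensus termini only", {
  set.seed(25)
  primers <- demo_primer_sets()
  fwd <- "GTGACTTGAAAAACCACCGTTG"  # a resolved forward primer
  core <- random_dna_str(300)
  cons <- structure(list(consensus_id = "c1",
                         sequence = paste0(fwd, core),
                         n_reads_used = 10L,
                         column_support = rep(0.9, nchar(fwd) + 300),
                         marker = "cytb"),
                    class = "consensus_record")
  out <- strip_primer_residues(cons, unname(primers))
  expect_equal(out$sequence, core)
  expect_equal(length(out$column_support), nchar(out$sequence))

  # no residues: unchanged
  clean <- structure(list(consensus_id = "c2", sequence = core,
                          n_reads_used = 10L,
                          column_support = rep(0.9, 300), marker = "cytb"),
                     class = "consensus_record")
  expect_equal(strip_primer_residues(clean, unname(primers))$sequence, core)

  # partial 16-nt residue with 2 edits at the 3' end is found and removed
  res <- substr(fwd, 1, 16)
  substr(res, 4, 4) <- "T"; substr(res, 9, 9) <- "A"
  o <- oracle_find_primer(paste0(substr(core, 250, 300), res),
                          primers$cytb$forward[[1]], 0.2, 15L)
  expect_false(is.null(o))
  cons3 <- structure(list(consensus_id = "c3",
                          sequence = paste0(core, res),
                          n_reads_used = 10L,
                          column_support = rep(0.9, 300 + 16),
                          marker = "cytb"),
                     class = "consensus_record")
  out3 <- strip_primer_residues(cons3, unname(primers))
  expect_equal(out3$sequence, core)
})

test_that("consensus error falls with cluster size and beats the raw reads", {
  set.seed(26)
  primers <- demo_primer_sets()
  barcode <- random_dna_str(550)
  amp <- make_amplicon(barcode, primers$cytb)
  err_for_size <- function(n, seed) {
    rs <- simulate_reads(amp, n, error_profile(), seed = seed)
    cl <- greedy_cluster(rs, 80)
    big <- which.max(vapply(cl, `[[`, integer(1), "size"))
    cons <- cluster_consensus(rs, cl[big], markers = list(primers$cytb),
                              marker = "cytb", min_cluster_size = 2L,
                              seed = seed + 1)
    # compare against the primer-trimmed truth, strand-aware
    s <- best_strand(cons[[1]]$sequence, barcode)
    error_percentage(unit_cost_align(s, barcode))
  }
  sizes <- c(5, 20, 50, 100)
  errs <- sapply(seq_along(sizes), function(i) {
    mean(c(err_for_size(sizes[i], 300 + i), err_for_size(sizes[i], 400 + i)))
  })
  raw <- 13
  expect_lt(errs[which(sizes == 20)], raw)
  expect_lt(errs[which(sizes == 100)], 2)
  expect_lte(errs[length(errs)], errs[1])
})

test_that("cluster consensus respects the size gate and the subsample cap", {
  set.seed(27)
  amp <- random_dna_str(400)
  rs <- simulate_reads(amp, 30, error_profile(), seed = 28)
  cl <- greedy_cluster(rs, 80)
  cons <- cluster_consensus(rs, cl, marker = "m", min_cluster_size = 5L,
                            seed = 1L)
  for (co in cons) {
    expect_lte(co$n_reads_used, 100L)
    expect_true(all(co$column_support > 0.3))
  }
  # clusters below the gate produce nothing
  tiny <- noisy_reads(random_dna_str(150), 3, 0.02)
  cl2 <- greedy_cluster(tiny)
  expect_equal(length(cluster_consensus(tiny, cl2, marker = "m", seed = 1L)),
               0L)
})
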
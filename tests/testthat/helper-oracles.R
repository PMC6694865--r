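# Independent brute-force oracles, all plain-R dynamic programming.
# They deliberately share no code with the package internals.

oracle_base_match <- function(a, b) a == b && a %in% c("A", "C", "G", "T")

# Global unit-cost edit distance.
oracle_edit_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- c(i, rep(0L, lb))
    for (j in seq_len(lb)) {
      m <- if (oracle_base_match(A[i], B[j])) 0L else 1L
      cur[j + 1] <- min(prev[j] + m, prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[lb + 1]
}

# (cost, matches) of the minimum-cost global alignment, matches maximized
# among cost ties; identity = 100 * matches / shorter length.
oracle_cost_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  pc <- 0:lb; pm <- rep(0L, lb + 1)
  for (i in seq_len(la)) {
    cc <- c(i, rep(0L, lb)); cm <- rep(0L, lb + 1)
    for (j in seq_len(lb)) {
      mt <- oracle_base_match(A[i], B[j])
      c1 <- pc[j] + !mt; m1 <- pm[j] + mt
      c2 <- pc[j + 1] + 1L; m2 <- pm[j + 1]
      if (c2 < c1 || (c2 == c1 && m2 > m1)) { c1 <- c2; m1 <- m2 }
      c3 <- cc[j] + 1L; m3 <- cm[j]
      if (c3 < c1 || (c3 == c1 && m3 > m1)) { c1 <- c3; m1 <- m3 }
      cc[j + 1] <- c1; cm[j + 1] <- m1
    }
    pc <- cc; pm <- cm
  }
  c(cost = pc[lb + 1], matches = pm[lb + 1])
}

oracle_identity <- function(a, b) {
  100 * oracle_cost_matches(a, b)[["matches"]] / min(nchar(a), nchar(b))
}

# (mismatches, insertions, deletions) of the minimum-cost unit alignment,
# gaps minimized among cost ties.
oracle_unit_counts <- function(q, t) {
  Q <- strsplit(q, "")[[1]]; T <- strsplit(t, "")[[1]]
  lq <- length(Q); lt <- length(T)
  pc <- 0:lt; pg <- 0:lt
  for (i in seq_len(lq)) {
    cc <- c(i, rep(0L, lt)); cg <- c(i, rep(0L, lt))
    for (j in seq_len(lt)) {
      mt <- oracle_base_match(Q[i], T[j])
      c1 <- pc[j] + !mt; g1 <- pg[j]
      c2 <- pc[j + 1] + 1L; g2 <- pg[j + 1] + 1L
      if (c2 < c1 || (c2 == c1 && g2 < g1)) { c1 <- c2; g1 <- g2 }
      c3 <- cc[j] + 1L; g3 <- cg[j] + 1L
      if (c3 < c1 || (c3 == c1 && g3 < g1)) { c1 <- c3; g1 <- g3 }
      cc[j + 1] <- c1; cg[j + 1] <- g1
    }
    pc <- cc; pg <- cg
  }
  cost <- pc[lt + 1]; gaps <- pg[lt + 1]
  c(mismatches = cost - gaps,
    insertions = (gaps + (lq - lt)) %/% 2L,
    deletions = (gaps - (lq - lt)) %/% 2L)
}

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Semi-global primer search with read-end overhangs.  Enumerates every
# allowed primer start row `a` (a > 0 forces read start 0) with its own DP,
# then chooses among all end candidates by (edits, read_start, matched
# length desc, read_end).  Returns NULL or a list like find_primer's.
oracle_find_primer <- function(text, primer, max_error_rate = 0.2,
                               min_overlap = 15L) {
  P <- strsplit(primer, "")[[1]]; X <- strsplit(text, "")[[1]]
  m <- length(P); n <- length(X)
  pmatch_ <- function(pc, xc) {
    xc %in% c("A", "C", "G", "T") && xc %in% oracle_iupac[[pc]]
  }
  best <- NULL
  lex_less <- function(x, y) {
    for (d in seq_along(x)) {
      if (x[d] < y[d]) return(TRUE)
      if (x[d] > y[d]) return(FALSE)
    }
    FALSE
  }
  consider <- function(cost, s, e, a, b) {
    ml <- b - a
    if (ml < min_overlap) return()
    if (e - s < min_overlap) return()
    if (cost > floor(max_error_rate * ml)) return()
    # order: edits, leftmost start, longest match, largest end, leftmost window
    cand <- c(cost, s, -ml, -e, a, b)
    if (is.null(best) || lex_less(cand[1:5], best[1:5])) best <<- cand
  }
  for (a in 0:(m - 1)) {
    # DP over primer rows a..m (rows indexed r = i - a) and text cols 0..n;
    # cell = c(cost, start col), lexicographic.
    rows <- m - a
    INF <- .Machine$integer.max %/% 4L
    cost <- matrix(INF, rows + 1, n + 1)
    sc <- matrix(INF, rows + 1, n + 1)
    if (a == 0) {
      cost[1, ] <- 0L; sc[1, ] <- 0:n
    } else {
      cost[1, 1] <- 0L; sc[1, 1] <- 0L
      for (j in seq_len(n)) { cost[1, j + 1] <- j; sc[1, j + 1] <- 0L }
    }
    for (r in seq_len(rows)) {
      cost[r + 1, 1] <- cost[r, 1] + 1L; sc[r + 1, 1] <- sc[r, 1]
      for (j in seq_len(n)) {
        mt <- pmatch_(P[a + r], X[j])
        c1 <- cost[r, j] + !mt; s1 <- sc[r, j]
        c2 <- cost[r, j + 1] + 1L; s2 <- sc[r, j + 1]
        if (c2 < c1 || (c2 == c1 && s2 < s1)) { c1 <- c2; s1 <- s2 }
        c3 <- cost[r + 1, j] + 1L; s3 <- sc[r + 1, j]
        if (c3 < c1 || (c3 == c1 && s3 < s1)) { c1 <- c3; s1 <- s3 }
        cost[r + 1, j + 1] <- c1; sc[r + 1, j + 1] <- s1
      }
    }
    for (j in 0:n) consider(cost[rows + 1, j + 1], sc[rows + 1, j + 1], j, a, m)
    if (m - 1 >= 1) {
      for (b in seq_len(m - 1)) {   # 3' overhang: primer ends past text end
        if (b - a >= 1 && b > a) {
          r <- b - a
          consider(cost[r + 1, n + 1], sc[r + 1, n + 1], n, a, b)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(edits = best[1], read_start = best[2], read_end = -best[4],
       matched_len = -best[3], primer_start = best[5], primer_end = best[6])
}

# Greedy best-cluster clustering with strand-aware oracle identity.
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_greedy_cluster <- function(ids, seqs, threshold = 80) {
  ord <- order(-nchar(seqs))
  reps <- integer()
  assign <- integer(length(seqs))
  for (i in ord) {
    best_k <- 0L; best_id <- -1
    for (k in seq_along(reps)) {
      rp <- seqs[reps[k]]
      idn <- max(oracle_identity(seqs[i], rp),
                 oracle_identity(oracle_revcomp(seqs[i]), rp))
      if (idn >= threshold && idn > best_id) { best_id <- idn; best_k <- k }
    }
    if (best_k > 0L) {
      assign[i] <- best_k
    } else {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  list(assign = assign, rep_ids = ids[reps])
}

random_dna_str <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Point-substitute a plain ACGT string at the given per-base rate.
mutate_str <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- runif(length(chars)) < rate
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  paste(chars, collapse = "")
}

# A small read_set of noisy copies of one template (plus strand only).
noisy_reads <- function(template, n, rate = 0.05, prefix = "r") {
  seqs <- vapply(seq_len(n), function(i) {
    chars <- strsplit(template, "")[[1]]
    hit <- runif(length(chars)) < rate
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(chars, collapse = "")
  }, character(1))
  read_set(sprintf("%s%03d", prefix, seq_len(n)), seqs,
           lapply(nchar(seqs), function(L) rep(12L, L)))
}
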
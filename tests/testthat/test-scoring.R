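ions_df <- function(...) {
  # ions_df("b", 3, "y", 7): quick matching-ion table
  v <- list(...)
  data.frame(series = unlist(v[c(TRUE, FALSE)]),
             index = as.integer(unlist(v[c(FALSE, TRUE)])),
             stringsAsFactors = FALSE)
}

test_that("sequence coverage follows the j + k rule", {
  expect_equal(sequence_coverage(60, 60, 100), 100)
  expect_equal(sequence_coverage(40, 30, 100), 70)
  expect_equal(sequence_coverage(0, 0, 50), 0)
  expect_equal(sequence_coverage(100, 53, 153), 100)
  expect_error(sequence_coverage(1, 1, 0), "positive")
})

test_that("bond coverage counts cleavage sites, not ions", {
  n <- 10
  expect_equal(bond_coverage(ions_df("b", 3), n), 100 / 9)
  # b3 and y7 cut the same bond of a 10-mer: still one bond
  expect_equal(bond_coverage(ions_df("b", 3, "y", 7), n), 100 / 9)
  expect_equal(bond_coverage(ions_df("b", 3, "y", 6), n), 200 / 9)
  all_b <- data.frame(series = "b", index = 1:9)
  expect_equal(bond_coverage(all_b, n), 100)
  expect_equal(bond_coverage(ions_df("b", 3)[0, ], n), 0)
})

test_that("PMP collapses charge states and neutral losses", {
  m <- data.frame(series = c("b", "b", "y", "a"),
                  index = c(3L, 3L, 7L, 2L))
  # b3 twice (two charges) and one a-ion: 2 unique b/y of 40 theoretical
  expect_equal(pmp(m, 40), 5)
  expect_equal(pmp(m[0, ], 40), 0)
  expect_equal(pmp(data.frame(series = rep(c("b", "y"), each = 5),
                              index = rep(1:5, 2)), 10), 100)
  expect_error(pmp(m, 0), "> 0")
})

test_that("interpreted fractions count linked peaks and their abundance", {
  spec <- centroid_spectrum(c(100, 200, 300, 400), c(10, 10, 10, 70))
  fake_match <- function(idx) {
    structure(list(exp_idx = idx), class = "envelope_match")
  }
  f <- interpreted_fractions(list(fake_match(c(1L, 2L)), fake_match(3L)),
                             spec)
  expect_equal(unname(f), c(75, 30))
  all_linked <- interpreted_fractions(list(fake_match(1:4)), spec)
  expect_equal(unname(all_linked), c(100, 100))
  expect_equal(unname(interpreted_fractions(list(), spec)), c(0, 0))
})

test_that("PTM score counts site-discriminating charge-collapsed ions", {
  n <- 20
  # single candidate site: every ion containing it counts, charges collapse
  m <- data.frame(series = c("b", "b", "y", "b", "y", "y"),
                  index = c(5L, 5L, 18L, 5L, 18L, 2L))
  expect_equal(ptm_score(m, site = 4, candidate_sites = 4, n = n), 2)
  # two candidates: only ions separating them count
  # b5 contains site 4 and excludes site 10 -> discriminating
  # y18 contains both 4 and 10 -> not discriminating
  expect_equal(ptm_score(m, site = 4, candidate_sites = c(4, 10), n = n), 1)
  expect_equal(ptm_score(m[m$series == "y" & m$index == 2, ],
                         site = 4, candidate_sites = c(4, 10), n = n), 0)
})

test_that("decoys preserve composition and are reproducible", {
  d <- make_decoy("P1", "PEPTIDE", mode = "reverse")
  expect_equal(d$sequence, "EDITPEP")
  expect_equal(d$protein_id, "DECOY_P1")
  r1 <- make_decoy("P1", "GAVLKWHY", mode = "random", seed = 42)
  r2 <- make_decoy("P1", "GAVLKWHY", mode = "random", seed = 42)
  expect_equal(r1$sequence, r2$sequence)
  expect_equal(sort(strsplit(r1$sequence, "")[[1]]),
               sort(strsplit("GAVLKWHY", "")[[1]]))
})

test_that("the FDR cutoff is the loosest passing threshold", {
  f <- fdr_filter(c(10, 9, 8, 7), c(7, 6), alpha = 0.25)
  expect_equal(f$cutoff, 8)
  expect_equal(f$n_accepted, 3)
  # no decoys: everything is accepted
  f2 <- fdr_filter(c(5, 4, 3), numeric(0), alpha = 0.01)
  expect_equal(f2$n_accepted, 3)
  # decoys dominate: nothing is accepted
  f3 <- fdr_filter(c(1, 2, 3), c(9, 9, 9, 9), alpha = 0.01)
  expect_equal(f3$n_accepted, 0)
  expect_equal(f3$cutoff, Inf)
})

test_that("FDR control is calibrated on simulated score mixtures", {
  set.seed(2024)
  # pure null: targets and decoys from one distribution, alpha 1% ->
  # acceptance stays near zero
  null_frac <- replicate(200, {
    f <- fdr_filter(rnorm(100), rnorm(100), alpha = 0.01)
    f$n_accepted / 100
  })
  expect_lt(mean(null_frac), 0.05)
  # mixture: 60 shifted true targets + 40 null targets vs 40 null decoys;
  # empirical FDR among accepted stays at or below alpha within
  # binomial error
  alpha <- 0.25
  tot_false <- 0; tot_acc <- 0
  for (r in 1:200) {
    true_scores <- rnorm(60, mean = 3.5)
    false_scores <- rnorm(40)
    decoy_scores <- rnorm(40)
    f <- fdr_filter(c(true_scores, false_scores), decoy_scores, alpha)
    tot_false <- tot_false + sum(f$accept[61:100])
    tot_acc <- tot_acc + f$n_accepted
  }
  emp_fdr <- tot_false / tot_acc
  se <- sqrt(alpha * (1 - alpha) / tot_acc)
  expect_lte(emp_fdr, alpha + 3 * se)
})

test_that("PrSM grouping keeps the best-supported representative", {
  prsms <- data.frame(
    sequence = c("AAA", "AAA", "AAA", "AAA", "CCC"),
    ptm_string = c("no PTM", "no PTM", "no PTM", "K1ac", "no PTM"),
    n_matching = c(12, 9, 12, 5, 3),
    rank_score = c(12.1, 9.0, 12.1, 5.0, 3.0),
    scan_id = c("s2", "s1", "s1", "s3", "s4"),
    stringsAsFactors = FALSE)
  g <- group_proteoforms(prsms)
  expect_equal(nrow(g), 3)  # two proteoforms of AAA + CCC
  kept <- g[g$sequence == "AAA" & g$ptm_string == "no PTM", ]
  expect_equal(kept$n_matching, 12)
  expect_equal(kept$scan_id, "s1")  # tie broken toward the earlier scan
  expect_equal(nrow(group_proteoforms(prsms[0, ])), 0)
})

test_that("coverage metrics are monotone and charge-collapse invariant", {
  set.seed(5)
  n <- 30
  for (i in 1:20) {
    k <- sample(1:12, 1)
    ions <- data.frame(series = sample(c("b", "y"), k, replace = TRUE),
                       index = sample(n - 1, k, replace = TRUE))
    sub <- ions[seq_len(sample(k, 1)), , drop = FALSE]
    expect_lte(bond_coverage(sub, n), bond_coverage(ions, n))
    expect_lte(pmp(sub, 2 * (n - 1)), pmp(ions, 2 * (n - 1)))
    expect_true(bond_coverage(ions, n) >= 0 && bond_coverage(ions, n) <= 100)
    # duplicating every ion at a new charge changes nothing
    dup <- rbind(ions, ions)
    expect_equal(pmp(dup, 2 * (n - 1)), pmp(ions, 2 * (n - 1)))
    expect_equal(bond_coverage(dup, n), bond_coverage(ions, n))
    expect_equal(ptm_score(dup, site = 10, candidate_sites = c(10, 20), n = n),
                 ptm_score(ions, site = 10, candidate_sites = c(10, 20), n = n))
  }
})
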
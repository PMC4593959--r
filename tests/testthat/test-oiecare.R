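# Shared-peak abundance partitioning: worked-example values, algebraic
# oracle equivalence, and whole-spectrum resolution behaviour.

test_that("ideal abundance reproduces the worked-example cells", {
  expect_equal(round(ideal_abundance(23.01, 128926.921875, 63.64), 6),
               46615.469396)
  expect_equal(round(ideal_abundance(55.06, 120854.796875, 100.00), 6),
               66542.651159)
  expect_equal(round(ideal_abundance(100.00, 281777.0625, 67.65), 6),
               416521.895787)
  # an OIP that is its own reference keeps its abundance
  expect_equal(ideal_abundance(42.5, 1234.5, 42.5), 1234.5)
  expect_error(ideal_abundance(10, 100, 0), "> 0")
})

test_that("relative deviation matches the worked example and edge cases", {
  deas <- c(46615.469396, 416521.895787, 66542.651159)
  rd <- relative_deviation(480992.3125, deas)
  expect_equal(round(rd, 2), -0.09)
  expect_lt(abs(rd - (-0.0919)), 1e-3)
  expect_equal(relative_deviation(sum(deas), deas), 0)
  expect_equal(relative_deviation(200, c(50, 50)), 1.0)
  expect_error(relative_deviation(10, numeric(0)), "> 0")
})

test_that("partitioning reproduces the worked-example final abundances", {
  group <- list(
    exp_idx = 1L, exp_mz = 1142.617676, ea_oip = 480992.3125,
    claimants = data.frame(
      label = c("y10-1+", "y20-2+", "y72-7+"),
      theo_peak = 1:3,
      ta_i = c(23.01, 100.00, 55.06),
      ea_r = c(128926.921875, 281777.0625, 120854.796875),
      ta_r = c(63.64, 67.65, 100.00),
      degenerate = FALSE))
  res <- partition_oip(group)
  expect_equal(round(res$claimants$final, 6),
               c(42330.617979, 378235.583145, 60426.111376))
  expect_equal(round(res$claimants$dea, 6),
               c(46615.469396, 416521.895787, 66542.651159))
  expect_equal(round(sum(res$claimants$dea), 6), 529680.016342)
  # full-precision RD: multiplying by the 2-decimal printed value would
  # not reproduce the reported partition
  expect_false(isTRUE(all.equal(res$claimants$dea[1] * (1 - 0.09),
                                42330.617979, tolerance = 1e-6)))
  # single claimant: the whole observed abundance is assigned
  solo <- partition_oip(list(exp_idx = 1L, exp_mz = 100, ea_oip = 5e4,
                             claimants = group$claimants[2, ]))
  expect_equal(solo$claimants$final, 5e4)
  # degenerate references abort the group
  bad <- group; bad$claimants$degenerate <- TRUE
  expect_error(partition_oip(bad), "degenerate")
})

test_that("partitioning equals proportional allocation and conserves
           abundance on random groups", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    group <- list(exp_idx = 1L, exp_mz = 1000,
                  ea_oip = runif(1, 1e3, 1e7),
                  claimants = data.frame(
                    label = paste0("ion", seq_len(n)), theo_peak = seq_len(n),
                    ta_i = runif(n, 1, 100),
                    ea_r = runif(n, 1e3, 1e7),
                    ta_r = runif(n, 1, 100),
                    degenerate = FALSE))
    res <- partition_oip(group)
    # conservation: partitioned abundances sum to the observed abundance
    expect_equal(sum(res$claimants$final), group$ea_oip,
                 tolerance = 1e-9)
    # oracle: proportional allocation of the observed abundance
    oracle <- proportional_allocation(group$ea_oip,
                                      group$claimants$ta_i,
                                      group$claimants$ea_r,
                                      group$claimants$ta_r)
    expect_equal(res$claimants$final, oracle, tolerance = 1e-9)
  }
})

test_that("partitioning a 1000-claimant group is exact and immediate", {
  n <- 1000
  group <- list(exp_idx = 1L, exp_mz = 1000, ea_oip = 1e8,
                claimants = data.frame(
                  label = paste0("ion", 1:n), theo_peak = 1:n,
                  ta_i = runif(n, 1, 100), ea_r = runif(n, 1e3, 1e6),
                  ta_r = runif(n, 1, 100), degenerate = FALSE))
  t0 <- proc.time()[["elapsed"]]
  res <- partition_oip(group)
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
  expect_equal(sum(res$claimants$final), 1e8, tolerance = 1e-6)
})

test_that("whole-spectrum resolution flips overlapped ions to matching
           without changing the fished-ion set", {
  pf <- proteoform("MYG_HORSE", myoglobin_sequence())
  ions <- c("y10-1+", "y20-2+", "y72-7+")
  sim <- simulate_spectrum(pf, ions,
                           abundances = c(202588.8, 416521.9, 120854.8),
                           noise_cv = 0, ppm_jitter = 0, seed = 1)
  db <- generate_fragments(pf, series = "y", max_charge = 7, ipaco = 20)
  db <- db[db$label %in% ions, ]
  p <- search_params(20, 15, 50)
  matches <- fish_spectrum(db, sim$spectrum, p)
  before <- vapply(matches, `[[`, "", "verdict")
  expect_equal(unname(before[c("y10-1+", "y72-7+")]),
               c("non-matching", "non-matching"))
  res <- resolve_spectrum(matches, sim$spectrum, p)
  after <- vapply(res$matches, `[[`, "", "verdict")
  expect_equal(unname(after[ions]), rep("matching", 3))
  # fished-ion set unchanged, matching count never decreases
  expect_setequal(names(res$matches), names(matches))
  expect_gte(sum(after == "matching"), sum(before == "matching"))
  # partitioned shared-peak abundances equal the known true contributions
  g <- res$groups[[which(vapply(res$groups, function(g)
    nrow(g$claimants) == 3, TRUE))]]
  tr <- sim$truth$peaks
  truth <- tr$true_abundance[tr$exp_index == g$exp_idx]
  truth <- truth[match(g$claimants$label,
                       tr$ion[tr$exp_index == g$exp_idx])]
  expect_equal(g$claimants$final, truth, tolerance = 1e-9)
})

test_that("spectra without overlaps resolve to an identical match set", {
  pf <- proteoform("X", "GAVLKGAVLKWH")
  sim <- simulate_spectrum(pf, c("b3-1+", "y4-1+"), c(1e5, 2e5),
                           noise_cv = 0, ppm_jitter = 0, seed = 3)
  db <- generate_fragments(pf, series = c("b", "y"), max_charge = 1,
                           ipaco = 20)
  db <- db[db$label %in% c("b3-1+", "y4-1+"), ]
  p <- search_params(20, 15, 50)
  matches <- fish_spectrum(db, sim$spectrum, p)
  res <- resolve_spectrum(matches, sim$spectrum, p)
  expect_length(res$groups, 0)
  expect_equal(res$matches, matches)
})

test_that("the IPAD gate leaves deficit-only groups unpartitioned", {
  # two ions sharing a peak whose observed abundance is far below both
  # ions' ideal share: provisional IPADs are negative, the gate holds
  group_spec <- function(ea_shared) {
    mzs <- c(1000.000, 1000.002, 1001.003, 1200.000, 1200.998)
    centroid_spectrum(mzs, c(5e4, ea_shared, 4e4, 6e4, 4.2e4))
  }
  env1 <- structure(list(mz = c(1000.002, 1001.003), rel = c(100, 80),
                         charge = 1L, monoisotopic_mz = 1000.002,
                         base_index = 1L), class = "theo_envelope")
  env2 <- structure(list(mz = c(1000.0021, 1200.000), rel = c(60, 100),
                         charge = 1L, monoisotopic_mz = 1000.0021,
                         base_index = 2L), class = "theo_envelope")
  p <- search_params(20, 15, 50)
  spec <- group_spec(10)  # tiny shared abundance: both IPADs negative
  matches <- fish_spectrum(
    .ion_db(list(list(label = "b1-1+", series = "b", index = 1L,
                      nl = "none", charge = 1L, base_mz = 1000.002,
                      mono_mz = 1000.002, envelope = env1),
                 list(label = "y1-1+", series = "y", index = 1L,
                      nl = "none", charge = 1L, base_mz = 1200.000,
                      mono_mz = 1200.000, envelope = env2))), spec, p)
  res <- resolve_spectrum(matches, spec, p)
  expect_length(res$groups, 0)
  expect_length(res$skipped, 1)
  expect_equal(res$skipped[[1]]$reason, "IPAD gate")
  # with the gate disabled the same group is partitioned
  res2 <- resolve_spectrum(matches, spec, p, gate_nonneg = FALSE)
  expect_length(res2$groups, 1)
})

test_that("match-report resolution reproduces the packaged worked example", {
  rep <- worked_example_report()
  res <- resolve_match_report(rep)
  rr <- res$resolution
  expect_equal(rr$dea, c(46615.469396, 416521.895787, 66542.651159))
  expect_equal(rr$final, c(42330.617979, 378235.583145, 60426.111376))
  expect_equal(unique(rr$rd), -0.09)
  expect_equal(rr$ipad_before, c(214L, 15L, 343L))
  expect_equal(rr$ipad_after, c(-2L, -9L, -5L))
  # updated report: shared-peak rows carry the partitioned abundances
  upd <- res$report
  expect_equal(upd$exp_abund[upd$ion == "y10-1+" & upd$is_oip],
               42330.617979)
  expect_equal(upd$exp_rel[upd$ion == "y10-1+" & upd$is_oip], 20.89)
  expect_equal(upd$exp_rel[upd$ion == "y20-2+" & upd$is_oip], 90.81)
  expect_equal(upd$exp_rel[upd$ion == "y72-7+" & upd$is_oip], 50.00)
})
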
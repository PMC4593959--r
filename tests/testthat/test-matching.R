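# Worked-example values used below come from the packaged match-report
# fixture (a myoglobin HCD region where three y ions collide on one peak).

test_that("m/z and abundance deviations match the worked-example table", {
  expect_equal(round(ipmd(1141.607714, 1141.613770)), 5)
  expect_equal(round(ipmd(1142.894250, 1142.910522)), 14)
  expect_equal(ipmd(500, 500), 0)
  expect_equal(round(ipad(23.01, 20.89)), -2)
  expect_equal(round(ipad(55.06, 480992.3125 * 100 / 120854.796875)), 343)
  expect_equal(ipad(67.65, 67.65), 0)
})

test_that("an ion self-matches a spectrum built from its own envelope", {
  comp <- parse_formula("C50H80N10O20")
  env <- aggregate_envelope(comp, charge = 2, ipaco = 20)
  spec <- centroid_spectrum(env$mz, env$rel * 1e5, scan_id = "self")
  p <- search_params(20, 15, 50)
  m <- fish_ion(list(label = "b1-2+", envelope = env), spec, p)
  expect_s3_class(m, "envelope_match")
  expect_equal(m$ipmd, rep(0, length(env$mz)))
  expect_equal(m$ipad, rep(0, length(env$mz)))
  expect_equal(classify_match(m, p), "matching")
})

test_that("ions without an observed 100% peak are not fished", {
  comp <- parse_formula("C50H80N10O20")
  env <- aggregate_envelope(comp, charge = 2, ipaco = 20)
  keep <- seq_along(env$mz) != env$base_index
  spec <- centroid_spectrum(env$mz[keep], env$rel[keep] * 1e5)
  p <- search_params(20, 15, 50)
  expect_null(fish_ion(list(label = "x", envelope = env), spec, p))
  # degenerate spectra return NULL rather than erroring
  expect_null(fish_ion(list(label = "x", envelope = env),
                       centroid_spectrum(numeric(0), numeric(0)), p))
})

test_that("the reference peak is the top clean peak and its IPAD is 0", {
  comp <- parse_formula("C60H100N15O25")
  env <- aggregate_envelope(comp, charge = 1, ipaco = 10)
  spec <- centroid_spectrum(env$mz, env$rel * 2e4)
  p <- search_params(10, 15, 50)
  m <- fish_ion(list(label = "x", envelope = env), spec, p)
  expect_equal(m$reference_index, env$base_index)
  expect_equal(m$ipad[m$reference_index], 0)
  # base peak flagged as overlapping: reference falls back to the next
  # most abundant clean peak, still with IPAD exactly 0
  oip <- m$exp_idx[env$base_index]
  m2 <- fish_ion(list(label = "x", envelope = env), spec, p,
                 oip_peaks = oip)
  expect_false(m2$reference_index == env$base_index)
  expect_equal(m2$reference_index, order(-env$rel)[2])
  expect_equal(m2$ipad[m2$reference_index], 0)
  # every linked peak overlapping: degenerate fallback still selects one
  all_oip <- m$exp_idx[!is.na(m$exp_idx)]
  ref3 <- select_reference(m, oip_peaks = all_oip)
  expect_true(ref3 %in% which(!is.na(m$exp_idx)))
})

test_that("classification is monotone in the tolerances", {
  set.seed(11)
  comp <- parse_formula("C40H60N8O14")
  env <- aggregate_envelope(comp, charge = 1, ipaco = 20)
  for (i in 1:20) {
    jitter_ppm <- runif(length(env$mz), -25, 25)
    ab_scale <- exp(rnorm(length(env$mz), 0, 0.4))
    spec <- centroid_spectrum(env$mz * (1 + jitter_ppm * 1e-6),
                              env$rel * 1e4 * ab_scale)
    tols <- list(c(15, 25), c(15, 50), c(30, 50), c(30, 100), c(50, 500))
    verdicts <- vapply(tols, function(tl) {
      p <- search_params(20, tl[1], tl[2])
      m <- fish_ion(list(label = "x", envelope = env), spec, p)
      if (is.null(m)) "unfished" else classify_match(m, p)
    }, "")
    # once matching under some tolerance pair, every looser pair matches too
    state <- verdicts == "matching"
    expect_true(all(state == cummax(state)))
  }
})

test_that("overlap detection groups shared peaks by distinct ions", {
  pf <- proteoform("MYG_HORSE", myoglobin_sequence())
  sim <- simulate_spectrum(pf, c("y10-1+", "y20-2+", "y72-7+"),
                           abundances = c(2e5, 4e5, 1.2e5),
                           noise_cv = 0, ppm_jitter = 0, seed = 1)
  db <- generate_fragments(pf, series = "y", max_charge = 7, ipaco = 20)
  db <- db[db$label %in% c("y10-1+", "y20-2+", "y72-7+"), ]
  p <- search_params(20, 15, 50)
  matches <- fish_spectrum(db, sim$spectrum, p)
  groups <- find_oips(matches, sim$spectrum)
  # the triple collision near m/z 1142.61 must be among the groups
  labs <- lapply(groups, function(g) sort(g$claimants$label))
  expect_true(list(sort(c("y10-1+", "y20-2+", "y72-7+"))) %in% labs)
  for (g in groups) {
    expect_gte(nrow(g$claimants), 2)
    expect_equal(g$ea_oip, sim$spectrum$abundance[g$exp_idx])
  }
  # one claimant per peak: no groups
  solo <- simulate_spectrum(pf, "y5-1+", 1e5, noise_cv = 0,
                            ppm_jitter = 0, seed = 1)
  db5 <- generate_fragments(pf, series = "y", max_charge = 1, ipaco = 20)
  db5 <- db5[db5$label == "y5-1+", ]
  m5 <- fish_spectrum(db5, solo$spectrum, p)
  expect_length(find_oips(m5, solo$spectrum), 0)
})

test_that("the match report has the documented columns and rounding", {
  comp <- parse_formula("C30H50N6O10")
  env <- aggregate_envelope(comp, charge = 1, ipaco = 20)
  spec <- centroid_spectrum(env$mz, env$rel * 1e4)
  p <- search_params(20, 15, 50)
  matches <- fish_spectrum(
    .ion_db(list(list(label = "b1-1+", series = "b", index = 1L,
                      nl = "none", charge = 1L,
                      base_mz = env$mz[env$base_index],
                      mono_mz = env$monoisotopic_mz, envelope = env))),
    spec, p)
  rep <- match_report(matches)
  expect_equal(names(rep),
               c("ion", "theo_mz", "theo_rel", "exp_mz", "exp_abund",
                 "exp_rel", "ipmd", "ipad", "is_oip", "verdict"))
  expect_type(rep$ipmd, "integer")
  expect_type(rep$ipad, "integer")
})
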
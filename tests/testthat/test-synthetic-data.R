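test_that("simulated spectra hit the exact precursor at zero noise", {
  cfg <- sim_config(mz_noise_ppm = 0, n_noise_peaks = 0, seed = 1)
  set.seed(1)
  acetyl <- simulate_acylcarnitine_spectrum("C2H2O", cfg)
  expect_equal(round(acetyl$precursor_mz, 4), 204.1230)
  free <- simulate_acylcarnitine_spectrum("", cfg)
  expect_equal(round(free$precursor_mz, 4), 162.1125)
  # the three diagnostic ions are present
  for (ion in DIAGNOSTIC_IONS)
    expect_true(any(abs(acetyl$peaks[, "mz"] - ion) < 1e-6))
  # base peak normalised to 100
  expect_equal(max(acetyl$peaks[, "intensity"]), 100)
  # acylium-like fragment at delta + proton
  expect_true(any(abs(acetyl$peaks[, "mz"] -
                        (monoisotopic_mass("C2H2O") + 1.0072765)) < 1e-4))
  expect_error(simulate_acylcarnitine_spectrum(c(C = -1L), cfg), "negative")
})

test_that("the simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123)
  r1 <- simulate_repository(cfg)
  r2 <- simulate_repository(cfg)
  expect_identical(r1$truth, r2$truth)
  expect_identical(lapply(r1$spectra, `[[`, "peaks"),
                   lapply(r2$spectra, `[[`, "peaks"))
  t1 <- simulate_timecourse(6, "liver", c(0, 4, 8),
                            planted_groups = list(list(tissue = "liver",
                                                       size = 3)),
                            seed = 9)
  t2 <- simulate_timecourse(6, "liver", c(0, 4, 8),
                            planted_groups = list(list(tissue = "liver",
                                                       size = 3)),
                            seed = 9)
  expect_identical(t1$table$abundance, t2$table$abundance)
})

test_that("ground truth covers every spectrum once and respects the
           configured structure", {
  cfg <- sim_config(n_datasets = 5, acyl_set = default_acyl_set()[1:5],
                    datasets_per_delta = c(3, 3), decoy_fraction = 0,
                    seed = 4)
  sim <- simulate_repository(cfg)
  ids <- vapply(sim$spectra, function(s) s$spectrum_id, "")
  expect_setequal(sim$truth$spectrum_id, ids)
  expect_false(anyDuplicated(sim$truth$spectrum_id) > 0)
  expect_true(all(sim$truth$is_carnitine))
  # every planted delta supported by exactly 3 datasets
  per_delta <- tapply(sim$truth$dataset_id, sim$truth$delta_formula,
                      function(d) length(unique(d)))
  expect_true(all(per_delta == 3))
  expect_error(simulate_repository(sim_config(acyl_set = character(0))),
               "empty acyl set")
})

test_that("generated carnitines pass the default query; class-(b) decoys
           fail at 50% and pass at 5%; class-(a) decoys fail both", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_repository(cfg)
  truth <- sim$truth
  pass50 <- vapply(sim$spectra, function(s)
    evaluate_query(s, carnitine_query())$pass, logical(1))
  pass5 <- vapply(sim$spectra, function(s)
    evaluate_query(s, carnitine_query(threshold_85 = 5))$pass, logical(1))
  expect_true(all(pass50[truth$is_carnitine]))
  b <- !is.na(truth$decoy_class) & truth$decoy_class == "b"
  a <- !is.na(truth$decoy_class) & truth$decoy_class == "a"
  cc <- !is.na(truth$decoy_class) & truth$decoy_class == "c"
  expect_true(all(!pass50[b]))
  expect_true(all(pass5[b]))
  expect_true(all(!pass50[a] & !pass5[a]))
  expect_true(all(pass50[cc]))
})

test_that("the planted chance-pass rate yields an FDR estimate inside the
           binomial band around the planted truth", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_repository(cfg)
  truth <- sim$truth
  retained <- filter_spectra(sim$spectra)
  fdr <- estimate_fdr(retained,
                      setNames(truth$is_carnitine, truth$spectrum_id))
  # oracle count over ground truth
  ids <- vapply(retained, function(s) s$spectrum_id, "")
  oracle <- sum(!truth$is_carnitine[match(ids, truth$spectrum_id)]) /
    length(ids)
  expect_equal(fdr, oracle)
  n <- length(ids)
  half_width <- 1.96 * sqrt(0.02 * 0.98 / n)
  expect_lt(abs(fdr - 0.02), half_width + 1e-9)
})

test_that("zero-noise timecourse groups are perfectly synchronized and
           independent features rarely cross the r threshold", {
  sim <- simulate_timecourse(
    n_features = 5, tissues = "blood", timepoints = c(0, 4, 8, 12, 16),
    planted_groups = list(list(tissue = "blood", size = 3,
                               template = c(1, 4, 9, 4, 1))),
    noise_sd = 0, seed = 2)
  ab <- sim$table$abundance
  members <- sim$truth[[1]]$members
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(cor(ab[members[i], ], ab[members[j], ]), 1)
  expect_error(simulate_timecourse(5, "blood", c(0, 4),
                                   planted_groups = list()),
               "3 timepoints")

  # false-positive rate of r >= 0.95 among independent pairs is near the
  # null tail probability for n = 6 timepoints (about 0.2%)
  set.seed(13)
  n_pairs <- 1000
  hits <- sum(replicate(n_pairs,
                        cor(rnorm(6), rnorm(6)) >= 0.95))
  p_tail <- stats::pt(0.95 * 2 / sqrt(1 - 0.95^2), df = 4,
                      lower.tail = FALSE)
  expect_lt(hits / n_pairs, 5 * p_tail + 0.01)
})
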
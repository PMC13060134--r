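make_table <- function(rt = c(1.5, 0.1, 8.5, 5.0),
                       abundance = NULL) {
  features <- data.frame(feature_id = paste0("f", seq_along(rt)),
                         mz = 200 + seq_along(rt), rt = rt)
  samples <- data.frame(
    sample_id = c("S1", "S2", "B1"),
    tissue = c("liver", "liver", "blank"),
    timepoint = c(0, 4, 0), group = c("g", "g", "blank"),
    is_blank = c(FALSE, FALSE, TRUE))
  if (is.null(abundance))
    abundance <- matrix(100, nrow(features), 3)
  feature_table(features, abundance, samples)
}

test_that("blank and RT filters apply the stated arithmetic", {
  # rows: ratio-kept (130 vs 25), ratio-removed rt ok is f4; rt excluded f2/f3
  ab <- rbind(c(130, 60, 25),   # f1: 130 >= 5*25 -> kept
              c(500, 500, 1),   # f2: rt 0.1 -> removed
              c(500, 500, 1),   # f3: rt 8.5 -> removed
              c(100, 80, 25))   # f4: 100 < 125 -> removed
  ft <- make_table(abundance = ab)
  out <- blank_and_rt_filter(ft)
  expect_equal(out$features$feature_id, "f1")
  expect_false(any(out$samples$is_blank))  # blank columns dropped
  # absent from blanks: kept regardless of ratio
  ab2 <- rbind(c(10, 20, NA), c(10, 20, 0))
  ft2 <- make_table(rt = c(1, 2), abundance = ab2)
  out2 <- blank_and_rt_filter(ft2)
  expect_setequal(out2$features$feature_id, c("f1", "f2"))
  # idempotent and never increasing
  expect_equal(nrow(blank_and_rt_filter(
    make_table(rt = c(1, 2), abundance = ab2))$abundance), 2L)
  # no blanks: warning, blank rule skipped
  ft3 <- feature_table(
    data.frame(feature_id = "f1", mz = 200, rt = 1),
    matrix(5, 1, 1),
    data.frame(sample_id = "S1", tissue = "t", timepoint = 0,
               group = "g", is_blank = FALSE))
  expect_warning(blank_and_rt_filter(ft3), "blank")
})

test_that("relative abundance normalises to the within-tissue maximum", {
  features <- data.frame(feature_id = c("f1", "f2"), mz = c(1, 2),
                         rt = c(1, 1))
  samples <- data.frame(
    sample_id = c("L1", "L2", "L3", "K1", "K2"),
    tissue = c("liver", "liver", "liver", "kidney", "kidney"),
    timepoint = c(0, 4, 8, 0, 4), group = "g", is_blank = FALSE)
  ab <- rbind(c(2, 4, 8, 10, 5), c(3, 3, 3, NA, NA))
  ft <- feature_table(features, ab, samples)
  out <- relative_abundance(ft)
  expect_equal(unname(out$abundance["f1", 1:3]), c(0.25, 0.5, 1.0))
  expect_equal(unname(out$abundance["f1", 4:5]), c(1.0, 0.5))
  expect_equal(unname(out$abundance["f2", 1:3]), c(1, 1, 1))
  expect_true(all(is.na(out$abundance["f2", 4:5])))
  # per-tissue maxima all 1 after transform
  for (ti in unique(samples$tissue)) {
    m <- out$abundance[, samples$tissue == ti, drop = FALSE]
    mx <- apply(m, 1, function(x) if (all(is.na(x))) NA else max(x, na.rm = TRUE))
    expect_true(all(is.na(mx) | abs(mx - 1) < 1e-12))
  }
})

test_that("log2 fold changes against the control group", {
  features <- data.frame(feature_id = "f1", mz = 1, rt = 1)
  samples <- data.frame(
    sample_id = paste0("S", 1:6),
    tissue = "colon", timepoint = 0,
    group = rep(c("gf", "spf"), each = 3), is_blank = FALSE)
  ab <- matrix(c(2, 2, 2, 8, 8, 8), 1)
  ft <- feature_table(features, ab, samples)
  fc <- log2fc_by_group(ft, "gf", pseudocount = 0)
  expect_equal(fc["f1", "spf"], 2)
  expect_equal(fc["f1", "gf"], 0)
  # zero control median with pseudocount p stays finite
  ab0 <- matrix(c(0, 0, 0, 8, 8, 8), 1)
  ft0 <- feature_table(features, ab0, samples)
  fc0 <- log2fc_by_group(ft0, "gf", pseudocount = 1)
  expect_equal(fc0["f1", "spf"], log2(9))
  expect_error(log2fc_by_group(ft, "nope"), "not present")
})

test_that("synchronized groups: identical profiles group, r = 0.94 pair is
           excluded and r = 0.96 pair included", {
  tp <- c(0, 4, 8, 12, 16, 20)
  base <- c(1, 3, 7, 5, 2, 1)
  # construct a companion with exactly a target Pearson r to `base`
  with_r <- function(r, seed) {
    x <- scale(base)[, 1]
    set.seed(seed)  # distinct residual directions so the two companions
                    # correlate only through `base` (r1 * r2 < 0.95)
    z <- stats::residuals(stats::lm(rnorm(length(x)) ~ x))
    z <- z / sqrt(sum(z^2) / (length(z) - 1))
    r * x + sqrt(1 - r^2) * z + 10  # shift up to keep abundances positive
  }
  features <- data.frame(feature_id = c("a", "b", "c94", "c96"),
                         mz = 1:4, rt = 1)
  samples <- data.frame(sample_id = paste0("u", seq_along(tp)),
                        tissue = "urine", timepoint = tp,
                        group = "g", is_blank = FALSE)
  ab <- rbind(base, base, with_r(0.94, seed = 5), with_r(0.96, seed = 6))
  ft <- feature_table(features, ab, samples)
  groups <- synchronized_groups(ft, "urine")
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$members, c("a", "b", "c96"))
  expect_gte(groups[[1]]$pairwise_min_r, 0.95)
  # the r = 0.94 feature stays out
  expect_false("c94" %in% groups[[1]]$members)
  # fewer than 3 timepoints: empty with warning
  ft2 <- feature_table(features, ab[, 1:2],
                       samples[1:2, ])
  expect_warning(expect_length(synchronized_groups(ft2, "urine"), 0L),
                 "timepoints")
})

test_that("planted groups are recovered exactly at zero noise and the
           result is invariant to feature order", {
  sim <- simulate_timecourse(
    n_features = 12, tissues = "liver", timepoints = c(0, 4, 8, 12),
    planted_groups = list(list(tissue = "liver", size = 4),
                          list(tissue = "liver", size = 3)),
    noise_sd = 0, seed = 3)
  groups <- synchronized_groups(sim$table, "liver")
  planted <- lapply(sim$truth, `[[`, "members")
  got <- lapply(groups, `[[`, "members")
  for (p in planted)
    expect_true(any(vapply(got, function(g) all(p %in% g), logical(1))))
  # members of different planted groups stay apart unless their random
  # templates happen to correlate; at these seeds they do not
  expect_false(any(vapply(got, function(g)
    all(planted[[1]] %in% g) && all(planted[[2]] %in% g), logical(1))))
  # zero-noise pairwise r within a planted group is exactly 1
  expect_true(all(vapply(groups, function(g)
    g$pairwise_min_r >= 1 - 1e-12, logical(1))))
})
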
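test_that("rarefaction on degenerate and disjoint dataset maps", {
  one <- rarefaction_curve(list(D1 = c(1.01, 2.02, 3.03, 4.04, 5.05)),
                           n_permutations = 10, seed = 1)
  expect_equal(one$mean_unique, 5)
  expect_equal(one$ci_low, 5)
  expect_equal(one$ci_high, 5)

  disj <- rarefaction_curve(list(D1 = 1:2, D2 = 3:5, D3 = 6:9),
                            exhaustive = TRUE)
  expect_equal(disj$mean_unique[3], 9)  # endpoint invariant to ordering
  curves <- attr(disj, "curves")
  expect_equal(nrow(curves), 6L)
  expect_true(all(curves[, 3] == 9))
  expect_error(rarefaction_curve(list()), "no datasets")
})

test_that("exhaustive rarefaction means equal the hand-enumerated average
           over all 6 orderings of 3 overlapping datasets", {
  sets <- list(D1 = c("a", "b"), D2 = c("b", "c", "d"), D3 = c("a", "d"))
  # oracle: enumerate the 6 orderings explicitly
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  oracle <- sapply(1:3, function(step)
    mean(sapply(orders, function(o)
      length(unique(unlist(sets[o[seq_len(step)]]))))))
  got <- rarefaction_curve(sets, exhaustive = TRUE)
  expect_equal(got$mean_unique, oracle)
  expect_equal(attr(got, "n_permutations"), 6L)
  # monotone per permutation, not just in the mean
  curves <- attr(got, "curves")
  expect_true(all(apply(curves, 1, function(r) !is.unsorted(r))))
  # sampled mode is deterministic under a seed
  a <- rarefaction_curve(sets, n_permutations = 50, seed = 7)
  b <- rarefaction_curve(sets, n_permutations = 50, seed = 7)
  expect_identical(a$mean_unique, b$mean_unique)
})

test_that("presence matrix cells, row/column sums and intersections", {
  obs <- data.frame(delta_key = c(42.01, 56.03, 56.03, 42.01),
                    group = c("A", "A", "B", "A"))
  mat <- presence_matrix(obs)
  expect_equal(dim(mat), c(2L, 2L))
  expect_equal(mat["42.01", ], c(A = 1L, B = 0L))
  expect_equal(mat["56.03", ], c(A = 1L, B = 1L))
  ic <- intersection_counts(mat)
  expect_equal(ic$count[ic$pattern == "A"], 1L)   # exclusive to A
  expect_equal(ic$count[ic$pattern == "A&B"], 1L)
  expect_equal(nrow(presence_matrix(obs[0, ])), 0L)

  # random assignment: counts match brute-force set algebra
  set.seed(61)
  keys <- sprintf("%.2f", sample(seq(10, 500, by = 0.07), 40))
  groups <- c("G1", "G2", "G3")
  obs2 <- do.call(rbind, lapply(keys, function(k)
    data.frame(delta_key = k,
               group = sample(groups, sample(1:3, 1)))))
  mat2 <- presence_matrix(obs2)
  # row sums = number of groups each key occupies
  occ <- tapply(obs2$group, obs2$delta_key, function(g) length(unique(g)))
  expect_equal(unname(rowSums(mat2)), as.vector(occ[rownames(mat2)]))
  # column sums = per-group unique key counts
  per_group <- tapply(obs2$delta_key, obs2$group,
                      function(k) length(unique(k)))
  expect_equal(unname(colSums(mat2)), as.vector(per_group[colnames(mat2)]))
  # intersection counts partition the keys
  expect_equal(sum(intersection_counts(mat2)$count), nrow(mat2))
})

test_that("composition frequencies split CHO from heteroatom formulas", {
  sps <- list(
    toy_spectrum("a1", CARNITINE_MH + 42.0106,
                 c(60.0808, 85.0284, 144.1019), c(10, 100, 50),
                 dataset_id = "D1"),
    toy_spectrum("a2", CARNITINE_MH + 42.0106,
                 c(60.0808, 85.0284, 144.1019), c(10, 99, 50),
                 dataset_id = "D2"),
    toy_spectrum("b1", CARNITINE_MH + 69.0215,
                 c(60.0808, 85.0284, 144.1019), c(10, 100, 50),
                 dataset_id = "D1"),
    toy_spectrum("b2", CARNITINE_MH + 69.0215,
                 c(60.0808, 85.0284, 144.1019), c(10, 98, 50),
                 dataset_id = "D2"))
  lib <- build_library(cluster_spectra(sps), sps)
  lib <- annotate_library(lib, c(a1 = "C9H17NO4",   # acetyl -> CHO
                                 b1 = "C10H18N2O4")) # C3H3NO -> CHNO
  fr <- composition_frequencies(lib)
  expect_equal(fr$by_class$n_unique_deltas[fr$by_class$composition_class == "CHO"], 1L)
  expect_equal(fr$by_class$n_unique_deltas[fr$by_class$composition_class == "CHNO"], 1L)
  expect_equal(fr$cho_formulas$formula, "C2H2O")
  expect_equal(fr$hetero_formulas$formula, "C3H3NO")
})

test_that("metadata join buckets unmapped files and cross-tabulates", {
  matches <- data.frame(
    file_id = c("f1", "f1", "f2", "f9"),
    delta_key = c(42.01, 56.03, 42.01, 42.01))
  meta <- data.frame(file_id = c("f1", "f2"),
                     organism = c("human", "human"),
                     tissue = c("urine", "feces"))
  out <- metadata_join(matches, meta)
  urine <- out[out$tissue == "urine", ]
  expect_equal(urine$n_matches, 2L)
  expect_equal(urine$n_unique_deltas, 2L)
  expect_equal(out$n_matches[out$tissue == "feces"], 1L)
  expect_equal(out$organism[out$tissue == "unannotated"], "unannotated")
})
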
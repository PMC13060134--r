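#' Blank subtraction and retention-time filtering
#'
#' A feature is retained when (a) it is absent from the blanks, or its
#' maximum sample abundance is at least `blank_ratio` times its maximum
#' blank abundance, and (b) its retention time lies within
#' [`rt_min`, `rt_max`] minutes. Blank columns are dropped from the
#' output. With no blank samples in the table the blank rule is skipped
#' with a warning. Never increases the feature count; idempotent.
#'
#' @param table A [feature_table()].
#' @param blank_ratio Sample/blank abundance ratio required (default 5).
#' @param rt_min,rt_max Retention-time window in minutes (defaults 0.2
#'   and 8).
#' @return The filtered [feature_table()].
#' @export
blank_and_rt_filter <- function(table, blank_ratio = 5,
                                rt_min = 0.2, rt_max = 8) {
  stopifnot(inherits(table, "FeatureTable"))
  is_blank <- table$samples$is_blank
  ab <- table$abundance
  rt_ok <- !is.na(table$features$rt) &
    table$features$rt >= rt_min & table$features$rt <= rt_max
  if (!any(is_blank)) {
    warning("no blank samples: blank-subtraction rule skipped")
    blank_ok <- rep(TRUE, nrow(ab))
  } else {
    rowmax <- function(m) apply(m, 1, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    max_blank <- rowmax(ab[, is_blank, drop = FALSE])
    max_sample <- rowmax(ab[, !is_blank, drop = FALSE])
    absent_in_blanks <- is.na(max_blank)
    blank_ok <- absent_in_blanks |
      (!is.na(max_sample) & max_sample >= blank_ratio * max_blank)
    blank_ok[is.na(blank_ok)] <- FALSE
  }
  keep <- rt_ok & blank_ok
  feature_table(table$features[keep, , drop = FALSE],
                ab[keep, !is_blank, drop = FALSE],
                table$samples[!is_blank, , drop = FALSE])
}

#' Relative abundance within a grouping
#'
#' Divides each feature's abundances by its maximum observed value within
#' each group of samples (tissue by default), so every retained feature
#' peaks at 1 within each group. Features entirely missing within a group
#' (or with a within-group maximum of 0) are left missing there.
#'
#' @param table A [feature_table()].
#' @param within Name of the sample-metadata column defining the grouping
#'   (default `"tissue"`).
#' @return The normalised [feature_table()].
#' @export
relative_abundance <- function(table, within = "tissue") {
  stopifnot(inherits(table, "FeatureTable"),
            within %in% names(table$samples))
  ab <- table$abundance
  groups <- table$samples[[within]]
  for (g in unique(groups)) {
    cols <- groups == g
    m <- suppressWarnings(
      apply(ab[, cols, drop = FALSE], 1,
            function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)))
    scale <- ifelse(is.na(m) | m == 0, NA_real_, m)
    ab[, cols] <- sweep(ab[, cols, drop = FALSE], 1, scale, "/")
  }
  feature_table(table$features, ab, table$samples)
}

#' Per-group log2 fold changes against a control group
#'
#' Computes, per feature, the median abundance within each sample group
#' and `log2((median_group + pseudocount) / (median_control +
#' pseudocount))` relative to the control. The control column is zero by
#' construction. The default pseudocount is half the smallest nonzero
#' abundance in the table, protecting against zero medians.
#'
#' @param table A [feature_table()].
#' @param control_group Name of the control level of the `group` metadata
#'   column.
#' @param aggregate Summary function per group (default [stats::median]).
#' @param pseudocount Stabilising constant; default half the smallest
#'   nonzero abundance.
#' @return Numeric matrix, features x groups, of log2 fold changes.
#' @export
log2fc_by_group <- function(table, control_group,
                            aggregate = stats::median, pseudocount = NULL) {
  stopifnot(inherits(table, "FeatureTable"))
  groups <- table$samples$group
  if (!control_group %in% groups)
    stop("control group '", control_group, "' not present")
  if (is.null(pseudocount)) {
    nz <- table$abundance[!is.na(table$abundance) & table$abundance > 0]
    pseudocount <- if (length(nz)) min(nz) / 2 else 0.5
  }
  glev <- unique(groups)
  med <- vapply(glev, function(g) {
    apply(table$abundance[, groups == g, drop = FALSE], 1,
          function(x) if (all(is.na(x))) NA_real_ else
            aggregate(x[!is.na(x)]))
  }, numeric(nrow(table$abundance)))
  med <- matrix(med, nrow = nrow(table$abundance),
                dimnames = list(table$features$feature_id, glev))
  log2((med + pseudocount) / (med[, control_group] + pseudocount))
}

#' Detect synchronized time-course groups within a tissue
#'
#' Collapses replicates to per-timepoint means, computes pairwise Pearson
#' correlations between all features detected in the tissue, keeps pairs
#' sharing at least `min_shared_timepoints` non-missing timepoints with
#' r >= `r_min`, and reports the connected components (of size >= 2) of
#' the qualifying-pair graph as synchronized groups. Invariant to feature
#' ordering.
#'
#' @param table A [feature_table()].
#' @param tissue Tissue label selecting the sample columns.
#' @param min_shared_timepoints Minimum shared non-missing timepoints per
#'   pair (default 3).
#' @param r_min Minimum Pearson correlation (default 0.95).
#' @return List of groups, each a list with `tissue`, `members`
#'   (character vector of feature ids) and `pairwise_min_r`; empty (with a
#'   warning) when the tissue has fewer than 3 timepoints.
#' @export
synchronized_groups <- function(table, tissue, min_shared_timepoints = 3L,
                                r_min = 0.95) {
  stopifnot(inherits(table, "FeatureTable"))
  sel <- table$samples$tissue == tissue
  if (!any(sel)) stop("no samples for tissue '", tissue, "'")
  tps <- sort(unique(table$samples$timepoint[sel]))
  if (length(tps) < 3L) {
    warning("tissue '", tissue, "' has fewer than 3 timepoints")
    return(list())
  }
  # replicate-collapsed per-timepoint mean profiles
  prof <- vapply(tps, function(tp) {
    cols <- sel & table$samples$timepoint == tp
    rowMeans(table$abundance[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(table$abundance)))
  prof[is.nan(prof)] <- NA_real_
  ids <- table$features$feature_id
  n <- length(ids)
  pair_i <- integer(0); pair_j <- integer(0); pair_r <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- !is.na(prof[i, ]) & !is.na(prof[j, ])
    if (sum(shared) < min_shared_timepoints) next
    r <- suppressWarnings(stats::cor(prof[i, shared], prof[j, shared]))
    if (!is.na(r) && r >= r_min) {
      pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
      pair_r <- c(pair_r, r)
    }
  }
  if (length(pair_i) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[pair_i], to = ids[pair_j]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  groups <- list()
  for (cc in unique(comp[ids[unique(c(pair_i, pair_j))]])) {
    members <- sort(names(comp)[comp == cc])
    if (length(members) < 2L) next
    in_cc <- ids[pair_i] %in% members & ids[pair_j] %in% members
    groups[[length(groups) + 1L]] <- list(
      tissue = tissue, members = members,
      pairwise_min_r = min(pair_r[in_cc]))
  }
  groups
}
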
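#' Rarefaction curve of unique delta masses over datasets
#'
#' For each random permutation of dataset order, counts the cumulative
#' number of unique delta-mass keys as datasets are added one at a time;
#' reports the per-step mean and a 95% percentile band (2.5/97.5) across
#' permutations. `exhaustive = TRUE` enumerates all `N!` orderings instead
#' of sampling (only sensible for small N), making the per-step mean
#' exact.
#'
#' @param dataset_to_deltas Named list, `dataset id -> vector of delta
#'   keys` observed in that dataset.
#' @param n_permutations Number of random permutations (default 1000).
#' @param seed Optional integer seed fixing the permutation draw.
#' @param exhaustive Enumerate all orderings instead of sampling.
#' @return Object of class `"RarefactionResult"`: data.frame with columns
#'   `n_sampled`, `mean_unique`, `ci_low`, `ci_high`; the permutation
#'   count is in the `"n_permutations"` attribute and the per-permutation
#'   curves in `"curves"` (a permutations x N matrix).
#' @export
rarefaction_curve <- function(dataset_to_deltas, n_permutations = 1000L,
                              seed = NULL, exhaustive = FALSE) {
  n <- length(dataset_to_deltas)
  if (n == 0L) stop("no datasets supplied")
  sets <- lapply(dataset_to_deltas, unique)
  orderings <- if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to 8 datasets")
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    perms(seq_len(n))
  } else {
    if (!is.null(seed)) set.seed(seed)
    lapply(seq_len(n_permutations), function(...) sample.int(n))
  }
  curves <- vapply(orderings, function(ord) {
    seen <- character(0)
    vapply(ord, function(d) {
      seen <<- union(seen, as.character(sets[[d]]))
      length(seen)
    }, numeric(1))
  }, numeric(n))
  # one row per permutation, one column per accumulation step
  curves <- if (n == 1L) matrix(curves, ncol = 1L) else t(curves)
  out <- data.frame(
    n_sampled = seq_len(n),
    mean_unique = unname(colMeans(curves)),
    ci_low = unname(apply(curves, 2, stats::quantile, probs = 0.025)),
    ci_high = unname(apply(curves, 2, stats::quantile, probs = 0.975)))
  structure(out, class = c("RarefactionResult", "data.frame"),
            n_permutations = nrow(curves), curves = curves)
}

#' Presence/absence matrix of delta keys across groups
#'
#' Binary matrix with one row per delta key and one column per group
#' (repository, tissue, ...), suitable for UpSet-style summaries of shared
#' and group-specific modifications.
#'
#' @param observations data.frame with columns `delta_key` and `group`
#'   (one row per observation; duplicates collapse).
#' @return Integer 0/1 matrix, rownames = delta keys (formatted to two
#'   decimals when numeric), colnames = groups.
#' @export
presence_matrix <- function(observations) {
  stopifnot(all(c("delta_key", "group") %in% names(observations)))
  if (nrow(observations) == 0L)
    return(matrix(integer(0), nrow = 0, ncol = 0))
  key <- if (is.numeric(observations$delta_key))
    sprintf("%.2f", observations$delta_key) else
      as.character(observations$delta_key)
  tab <- table(key, as.character(observations$group))
  mat <- matrix(as.integer(tab > 0), nrow = nrow(tab),
                dimnames = dimnames(tab))
  names(dimnames(mat)) <- NULL
  mat
}

#' Intersection cardinalities of a presence matrix
#'
#' Counts delta keys by their exact group membership pattern (the bars of
#' an UpSet plot), optionally truncated to the `top_k` largest
#' intersections.
#'
#' @param mat A [presence_matrix()].
#' @param top_k Keep only the `top_k` largest intersections
#'   (default all).
#' @return data.frame with `pattern` (groups joined by `&`), `degree`, and
#'   `count`, sorted by count descending.
#' @export
intersection_counts <- function(mat, top_k = Inf) {
  if (nrow(mat) == 0L)
    return(data.frame(pattern = character(0), degree = integer(0),
                      count = integer(0)))
  pattern <- apply(mat, 1, function(r)
    paste(colnames(mat)[r > 0], collapse = "&"))
  tab <- sort(table(pattern), decreasing = TRUE)
  out <- data.frame(pattern = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), row.names = NULL)
  utils::head(out, top_k)
}

#' Composition-class and formula frequencies of a library
#'
#' Tallies unique delta keys per composition class (CHO, CHNO, CHOS, ...,
#' or "unassigned") and occurrence counts per delta formula, with the
#' CHO-only and heteroatom-containing formula tallies reported separately.
#'
#' @param library A [build_library()] result (possibly annotated).
#' @return A list with data.frames `by_class` (`composition_class`,
#'   `n_unique_deltas`), `cho_formulas` and `hetero_formulas` (`formula`,
#'   `n`).
#' @export
composition_frequencies <- function(library) {
  stopifnot(inherits(library, "CarnitineLibrary"))
  key <- sprintf("%.2f", library$delta_key)
  cls <- library$composition_class
  by_class <- stats::aggregate(
    list(n_unique_deltas = key),
    by = list(composition_class = cls),
    FUN = function(k) length(unique(k)))
  assigned <- !is.na(library$delta_formula) & nzchar(library$delta_formula)
  ftab <- function(sel) {
    if (!any(sel)) return(data.frame(formula = character(0), n = integer(0)))
    tab <- sort(table(library$delta_formula[sel]), decreasing = TRUE)
    data.frame(formula = names(tab), n = as.integer(tab), row.names = NULL)
  }
  list(by_class = by_class,
       cho_formulas = ftab(assigned & cls == "CHO"),
       hetero_formulas = ftab(assigned & cls != "CHO"))
}

#' Join match results with sample metadata
#'
#' Aggregates library-search matches per (organism, tissue): how many
#' spectra matched and how many unique delta keys they represent. Files
#' not covered by the metadata are bucketed as "unannotated".
#'
#' @param matches data.frame with columns `file_id` and `delta_key`.
#' @param file_metadata data.frame with columns `file_id`, `organism`,
#'   `tissue` (a partial mapping).
#' @return data.frame with `organism`, `tissue`, `n_matches`,
#'   `n_unique_deltas`.
#' @export
metadata_join <- function(matches, file_metadata) {
  stopifnot(all(c("file_id", "delta_key") %in% names(matches)),
            all(c("file_id", "organism", "tissue") %in% names(file_metadata)))
  i <- match(matches$file_id, file_metadata$file_id)
  organism <- ifelse(is.na(i), "unannotated", file_metadata$organism[i])
  tissue <- ifelse(is.na(i), "unannotated", file_metadata$tissue[i])
  key <- if (is.numeric(matches$delta_key))
    sprintf("%.2f", matches$delta_key) else as.character(matches$delta_key)
  agg <- stats::aggregate(
    list(n_matches = key, n_unique_deltas = key),
    by = list(organism = organism, tissue = tissue),
    FUN = length)
  uniq <- stats::aggregate(
    list(n_unique_deltas = key),
    by = list(organism = organism, tissue = tissue),
    FUN = function(k) length(unique(k)))
  agg$n_unique_deltas <- uniq$n_unique_deltas[
    match(paste(agg$organism, agg$tissue),
          paste(uniq$organism, uniq$tissue))]
  agg
}
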
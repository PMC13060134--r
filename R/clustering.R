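#' Clustering parameters
#'
#' The redundancy-reduction contract: spectra are grouped when their
#' precursors agree within `precursor_tol_ppm` and their cosine distance is
#' at most `eps`. Preprocessing removes peaks below `min_mz` and drops
#' spectra with fewer than `min_peaks` peaks. Clusters observed in fewer
#' than `min_files` distinct files are flagged (never silently dropped) so
#' the later >=2-dataset curation rule stays the single support gate.
#'
#' Note on `eps`: the clustering tool this contract mirrors describes eps
#' as a minimum cosine similarity of 0.1 while its internals treat eps as a
#' cosine *distance*; both readings are selectable via `eps_mode`, with
#' distance (the internal semantics) the default.
#'
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 20).
#' @param fragment_tol_da Fragment tolerance in Da (default 0.02).
#' @param eps Cosine threshold in [0, 1] (default 0.1).
#' @param eps_mode `"distance"` (cluster when 1 - score <= eps, default) or
#'   `"similarity"` (cluster when score >= eps).
#' @param min_peaks Minimum peaks per spectrum after m/z filtering
#'   (default 3).
#' @param min_mz Minimum fragment m/z retained (default 50).
#' @param min_files Minimum distinct files for an unflagged cluster
#'   (default 2).
#' @param intensity_power Intensity exponent for the cosine (default 0.5).
#' @return Object of class `"ClusterParams"`.
#' @export
cluster_params <- function(precursor_tol_ppm = 20, fragment_tol_da = 0.02,
                           eps = 0.1, eps_mode = c("distance", "similarity"),
                           min_peaks = 3L, min_mz = 50, min_files = 2L,
                           intensity_power = 0.5) {
  eps_mode <- match.arg(eps_mode)
  stopifnot(precursor_tol_ppm > 0, fragment_tol_da > 0,
            eps > 0, eps <= 1, min_peaks >= 1, min_mz > 0, min_files >= 1)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_da = fragment_tol_da, eps = eps,
                 eps_mode = eps_mode, min_peaks = as.integer(min_peaks),
                 min_mz = min_mz, min_files = as.integer(min_files),
                 intensity_power = intensity_power),
            class = "ClusterParams")
}

# strip peaks below min_mz; NULL if too few remain
.preprocess_spectrum <- function(sp, min_mz, min_peaks) {
  keep <- sp$peaks[, "mz"] >= min_mz
  if (sum(keep) < min_peaks) return(NULL)
  sp$peaks <- sp$peaks[keep, , drop = FALSE]
  sp
}

#' Cluster near-identical spectra
#'
#' Single-linkage clustering within precursor buckets: spectra are sorted
#' by precursor m/z and every pair within the ppm tolerance is tested;
#' pairs whose cosine passes the `eps` gate are merged with union-find.
#' Two spectra therefore share a cluster exactly when connected by a chain
#' of pairs each satisfying both gates. Deterministic given input order.
#'
#' @param spectra List of [spectrum()] objects.
#' @param params A [cluster_params()].
#' @return Object of class `"ClusterAssignment"`: list with
#'   `assignments` (data.frame `spectrum_id`, `cluster_id`),
#'   `representatives` (data.frame `cluster_id`, `representative_id`,
#'   `n_members`, `n_files`, `flagged`), and `dropped` (ids removed by
#'   preprocessing).
#' @export
cluster_spectra <- function(spectra, params = cluster_params()) {
  prepped <- lapply(spectra, .preprocess_spectrum,
                    min_mz = params$min_mz, min_peaks = params$min_peaks)
  dropped <- vapply(spectra[vapply(prepped, is.null, logical(1))],
                    function(s) s$spectrum_id, character(1))
  prepped <- prepped[!vapply(prepped, is.null, logical(1))]
  n <- length(prepped)
  if (n == 0L)
    return(structure(list(
      assignments = data.frame(spectrum_id = character(0),
                               cluster_id = character(0)),
      representatives = data.frame(cluster_id = character(0),
                                   representative_id = character(0),
                                   n_members = integer(0),
                                   n_files = integer(0),
                                   flagged = logical(0)),
      dropped = dropped), class = "ClusterAssignment"))

  prec <- vapply(prepped, function(s) s$precursor_mz, numeric(1))
  ord <- order(prec)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  sim_pass <- function(a, b) {
    s <- cosine_similarity(a, b, fragment_tol_da = params$fragment_tol_da,
                           intensity_power = params$intensity_power)$score
    if (params$eps_mode == "distance") (1 - s) <= params$eps
    else s >= params$eps
  }
  for (u in seq_len(n - 1L)) {
    i <- ord[u]
    v <- u + 1L
    while (v <= n) {
      j <- ord[v]
      # chain condition: pairwise tolerance on the mean precursor
      tol <- mean(c(prec[i], prec[j])) * params$precursor_tol_ppm * 1e-6
      if (prec[j] - prec[i] > tol) break
      if (sim_pass(prepped[[i]], prepped[[j]])) unite(i, j)
      v <- v + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- vapply(prepped, function(s) s$spectrum_id, character(1))
  cluster_of <- match(roots, sort(unique(roots)))
  cluster_ids <- sprintf("cluster_%04d", cluster_of)
  reps <- do.call(rbind, lapply(sort(unique(cluster_of)), function(cid) {
    members <- which(cluster_of == cid)
    rep_id <- select_representative(
      prepped[members], fragment_tol_da = params$fragment_tol_da,
      intensity_power = params$intensity_power)
    files <- unique(vapply(prepped[members], function(s) s$file_id,
                           character(1)))
    data.frame(cluster_id = sprintf("cluster_%04d", cid),
               representative_id = rep_id,
               n_members = length(members),
               n_files = length(files),
               flagged = length(files) < params$min_files,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    assignments = data.frame(spectrum_id = ids, cluster_id = cluster_ids,
                             stringsAsFactors = FALSE),
    representatives = reps,
    dropped = dropped), class = "ClusterAssignment")
}

#' Select the representative (medoid) of a cluster
#'
#' Returns the member maximising the summed cosine similarity to all other
#' members; ties are broken by highest total peak intensity, then by
#' lexicographic spectrum id. A singleton represents itself.
#'
#' @param members Non-empty list of [spectrum()] objects.
#' @param fragment_tol_da,intensity_power Cosine parameters.
#' @return The representative's `spectrum_id`.
#' @export
select_representative <- function(members, fragment_tol_da = 0.02,
                                  intensity_power = 0.5) {
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L) return(members[[1]]$spectrum_id)
  n <- length(members)
  simsum <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    s <- cosine_similarity(members[[i]], members[[j]],
                           fragment_tol_da = fragment_tol_da,
                           intensity_power = intensity_power)$score
    simsum[i] <- simsum[i] + s
    simsum[j] <- simsum[j] + s
  }
  total_int <- vapply(members, function(s) sum(s$peaks[, "intensity"]),
                      numeric(1))
  ids <- vapply(members, function(s) s$spectrum_id, character(1))
  best <- order(-simsum, -total_int, ids)[1]
  ids[best]
}
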
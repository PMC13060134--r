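#' Run the full mining pipeline: query, cluster, network, purge, curate
#'
#' Chains the stages of the repository-mining workflow on an in-memory
#' spectra collection: diagnostic-query filtering with DIA exclusion,
#' redundancy-reducing clustering, molecular networking with purging of
#' components carrying non-target annotations, and delta-mass library
#' curation with the multi-dataset support rule.
#'
#' @param spectra List of [spectrum()] objects.
#' @param annotations Optional named character vector
#'   `spectrum_id -> compound label` used by the network purge.
#' @param query A [diagnostic_query()] (default [carnitine_query()]).
#' @param params A [cluster_params()].
#' @param min_score,min_matched_peaks,top_k Networking gates (defaults
#'   0.7 / 4 / 10).
#' @param min_datasets Library support rule (default 2).
#' @param is_target Annotation predicate for the purge (default: label
#'   contains "carnitine", case-insensitive).
#' @return A list with `retained` (post-query spectra), `assignment`
#'   (clustering), `network` (pre-purge), `purged` (post-purge network)
#'   and `library` (a [build_library()] result restricted to surviving
#'   representatives).
#' @export
mine_repository <- function(spectra, annotations = NULL,
                            query = carnitine_query(),
                            params = cluster_params(),
                            min_score = 0.7, min_matched_peaks = 4L,
                            top_k = 10L, min_datasets = 2L,
                            is_target = function(label)
                              grepl("carnitine", label, ignore.case = TRUE)) {
  retained <- filter_spectra(spectra, query)
  assignment <- cluster_spectra(retained, params)
  reps_ids <- assignment$representatives$representative_id
  idx <- .index_spectra(retained)
  network <- build_network(idx[reps_ids], min_score = min_score,
                           min_matched_peaks = min_matched_peaks,
                           top_k = top_k,
                           fragment_tol_da = params$fragment_tol_da,
                           intensity_power = params$intensity_power)
  purged <- if (is.null(annotations)) network else
    purge_nontarget_components(network, annotations, is_target = is_target)
  surviving <- purged$nodes$spectrum_id
  keep_clusters <- assignment$representatives$cluster_id[
    assignment$representatives$representative_id %in% surviving]
  pruned <- assignment
  pruned$representatives <- assignment$representatives[
    assignment$representatives$cluster_id %in% keep_clusters, , drop = FALSE]
  pruned$assignments <- assignment$assignments[
    assignment$assignments$cluster_id %in% keep_clusters, , drop = FALSE]
  library <- build_library(pruned, retained, min_datasets = min_datasets)
  list(retained = retained, assignment = assignment, network = network,
       purged = purged, library = library)
}
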
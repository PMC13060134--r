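#' Build a molecular network over representative spectra
#'
#' Computes the modified cosine between all pairs of representatives and
#' keeps an edge when the score and matched-peak count pass their gates and
#' each endpoint ranks the other within its `top_k` qualifying neighbours
#' (the mutual-rank topology filter of classical molecular networking).
#' Connected components of the resulting graph are the subnetworks.
#'
#' @param representatives List of [spectrum()] objects.
#' @param min_score Minimum modified cosine score (default 0.7).
#' @param min_matched_peaks Minimum matched fragment peaks (default 6).
#' @param top_k Mutual-rank neighbourhood size (default 10).
#' @param fragment_tol_da Fragment tolerance in Da (default 0.02).
#' @param intensity_power Intensity exponent (default 0.5).
#' @return Object of class `"MolecularNetwork"`: list with `nodes`
#'   (data.frame `spectrum_id`, `precursor_mz`, `component`), `edges`
#'   (data.frame `id_a`, `id_b`, `score`, `n_matched`), `graph` (igraph),
#'   and `spectra` (the input list, named by id).
#' @export
build_network <- function(representatives, min_score = 0.7,
                          min_matched_peaks = 6L, top_k = 10L,
                          fragment_tol_da = 0.02, intensity_power = 0.5) {
  stopifnot(length(representatives) >= 1L)
  spectra <- .index_spectra(representatives)
  ids <- names(spectra)
  n <- length(ids)
  cand <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]],
                            fragment_tol_da = fragment_tol_da,
                            intensity_power = intensity_power)
      if (mc$score >= min_score && mc$n_matched >= min_matched_peaks)
        cand[[length(cand) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j],
          score = mc$score, n_matched = mc$n_matched,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(cand)) do.call(rbind, cand) else
    data.frame(id_a = character(0), id_b = character(0),
               score = numeric(0), n_matched = integer(0))
  if (nrow(edges) && is.finite(top_k)) {
    # rank of each neighbour within a node's qualifying edges, by score desc
    rank_ok <- function(node, other, score) {
      sel <- edges$id_a == node | edges$id_b == node
      nb_scores <- edges$score[sel]
      sum(nb_scores > score) < top_k
    }
    keep <- vapply(seq_len(nrow(edges)), function(k) {
      rank_ok(edges$id_a[k], edges$id_b[k], edges$score[k]) &&
        rank_ok(edges$id_b[k], edges$id_a[k], edges$score[k])
    }, logical(1))
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  nodes <- data.frame(
    spectrum_id = ids,
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    component = as.integer(comp[ids]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, graph = g, spectra = spectra),
            class = "MolecularNetwork")
}

#' @export
print.MolecularNetwork <- function(x, ...) {
  cat(sprintf("<MolecularNetwork> %d nodes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$component))))
  invisible(x)
}

#' Purge network components contaminated by non-target annotations
#'
#' Removes, in full, every connected component that contains at least one
#' node whose annotation exists and is not of the target class — the
#' guilt-by-association purge used to clean a candidate library of
#' co-clustering non-carnitine chemistry. Components whose nodes are all
#' unannotated (or all target-annotated) are retained. Idempotent.
#'
#' @param network A [build_network()] result.
#' @param annotations Named character vector `spectrum_id -> label`;
#'   partial (unannotated nodes allowed).
#' @param is_target Predicate on labels; the default accepts any label
#'   containing "carnitine" case-insensitively.
#' @return The purged `"MolecularNetwork"`, with a `"purge_log"` attribute
#'   (data.frame of purged components and their trigger annotations).
#' @export
purge_nontarget_components <- function(network, annotations,
                                       is_target = function(label)
                                         grepl("carnitine", label,
                                               ignore.case = TRUE)) {
  stopifnot(inherits(network, "MolecularNetwork"))
  nodes <- network$nodes
  ann <- annotations[names(annotations) %in% nodes$spectrum_id]
  failing <- names(ann)[!vapply(unname(ann), is_target, logical(1))]
  bad_components <- unique(nodes$component[nodes$spectrum_id %in% failing])
  keep_nodes <- nodes$spectrum_id[!nodes$component %in% bad_components]
  log <- data.frame(
    component = bad_components,
    trigger = vapply(bad_components, function(cc) {
      trig <- intersect(failing, nodes$spectrum_id[nodes$component == cc])
      paste(sprintf("%s=%s", trig, ann[trig]), collapse = "; ")
    }, character(1)))
  edges <- network$edges
  edges <- edges[edges$id_a %in% keep_nodes & edges$id_b %in% keep_nodes, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = keep_nodes))
  comp <- igraph::components(g)$membership
  out_nodes <- nodes[nodes$spectrum_id %in% keep_nodes, , drop = FALSE]
  out_nodes$component <- as.integer(comp[out_nodes$spectrum_id])
  out <- structure(list(nodes = out_nodes, edges = edges, graph = g,
                        spectra = network$spectra[keep_nodes]),
                   class = "MolecularNetwork")
  attr(out, "purge_log") <- log
  out
}
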
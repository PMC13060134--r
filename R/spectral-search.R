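#' Search a spectral library against query spectra
#'
#' Identity-level cosine search: candidate query/library pairs are limited
#' to precursors within `precursor_tol_da` (set `analog = TRUE` to open the
#' precursor window), the cosine is computed as in [cosine_similarity()],
#' and a match is reported when the score and matched-peak gates both pass.
#' All qualifying pairs are returned (not best-only), sorted by score
#' descending then by ids, so consumers can aggregate or take per-query
#' top hits.
#'
#' @param queries,library_spectra Lists of [spectrum()] objects; the
#'   library must be non-empty.
#' @param min_cosine Minimum cosine score (default 0.7).
#' @param min_matched Minimum matched fragment ions (default 4).
#' @param precursor_tol_da Precursor tolerance in Da (default 0.02).
#' @param fragment_tol_da Fragment tolerance in Da (default 0.02).
#' @param analog Open the precursor window (default `FALSE`).
#' @param intensity_power Intensity exponent (default 0.5).
#' @return data.frame of matches: `query_id`, `library_id`, `cosine`,
#'   `n_matched`.
#' @export
search_library <- function(queries, library_spectra, min_cosine = 0.7,
                           min_matched = 4L, precursor_tol_da = 0.02,
                           fragment_tol_da = 0.02, analog = FALSE,
                           intensity_power = 0.5) {
  stopifnot(length(library_spectra) >= 1L)
  lib <- .index_spectra(library_spectra)
  lib_prec <- vapply(lib, function(s) s$precursor_mz, numeric(1))
  rows <- list()
  for (q in queries) {
    cand <- if (analog) seq_along(lib) else
      which(abs(lib_prec - q$precursor_mz) <= precursor_tol_da)
    for (j in cand) {
      cs <- cosine_similarity(q, lib[[j]],
                              fragment_tol_da = fragment_tol_da,
                              intensity_power = intensity_power)
      if (cs$score >= min_cosine && cs$n_matched >= min_matched)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q$spectrum_id, library_id = names(lib)[j],
          cosine = cs$score, n_matched = cs$n_matched,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), library_id = character(0),
               cosine = numeric(0), n_matched = integer(0))
  out[order(-out$cosine, out$query_id, out$library_id), , drop = FALSE]
}

#' Secondary cosine re-scoring on unfiltered spectra
#'
#' Index-based searches operate on filtered, truncated peak lists; this
#' re-scores each reported match on the original, unfiltered spectra and
#' removes matches whose unfiltered cosine falls below `retain_min`. A
#' match whose raw spectra cannot be resolved is retained with a warning
#' (`strict = TRUE` errors instead).
#'
#' @param matches data.frame from [search_library()].
#' @param raw_queries,raw_library Lists of unfiltered [spectrum()]
#'   objects, resolvable by id.
#' @param retain_min Minimum unfiltered cosine to retain (default 0.7).
#' @param fragment_tol_da,intensity_power Cosine parameters.
#' @param strict Error on unresolvable raw spectra (default `FALSE`).
#' @return The filtered matches with an `unfiltered_cosine` column; counts
#'   of removed and unresolvable matches are attached as attributes.
#' @export
recompute_unfiltered_cosine <- function(matches, raw_queries, raw_library,
                                        retain_min = 0.7,
                                        fragment_tol_da = 0.02,
                                        intensity_power = 0.5,
                                        strict = FALSE) {
  qidx <- .index_spectra(raw_queries)
  lidx <- .index_spectra(raw_library)
  matches$unfiltered_cosine <- NA_real_
  unresolvable <- logical(nrow(matches))
  for (k in seq_len(nrow(matches))) {
    qid <- matches$query_id[k]; lid <- matches$library_id[k]
    if (!qid %in% names(qidx) || !lid %in% names(lidx)) {
      msg <- sprintf("raw spectrum unresolvable for match %s ~ %s", qid, lid)
      if (strict) stop(msg)
      warning(msg)
      unresolvable[k] <- TRUE
      next
    }
    matches$unfiltered_cosine[k] <- cosine_similarity(
      qidx[[qid]], lidx[[lid]], fragment_tol_da = fragment_tol_da,
      intensity_power = intensity_power)$score
  }
  keep <- unresolvable | matches$unfiltered_cosine >= retain_min
  out <- matches[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_unresolvable") <- sum(unresolvable)
  out
}
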
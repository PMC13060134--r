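#' Construct a diagnostic product-ion query
#'
#' An AND-list of product-ion conditions, each specifying a target
#' fragment m/z, a symmetric ppm tolerance (computed on the target), and a
#' minimum relative intensity as a percentage of the spectrum base peak —
#' the semantics of a MassQL `MS2PROD ... TOLERANCEPPM ... INTENSITYPERCENT`
#' clause.
#'
#' @param target_mz Numeric vector of target fragment m/z (Da).
#' @param tolerance_ppm Per-condition ppm tolerance (recycled).
#' @param min_intensity_percent Per-condition minimum relative intensity in
#'   (0, 100], percent of base peak (recycled).
#' @return Object of class `"DiagnosticQuery"`: a data.frame of conditions.
#' @seealso [carnitine_query()] for the default three-ion carnitine query.
#' @export
diagnostic_query <- function(target_mz, tolerance_ppm = 20,
                             min_intensity_percent = 1) {
  conds <- data.frame(target_mz = target_mz,
                      tolerance_ppm = tolerance_ppm,
                      min_intensity_percent = min_intensity_percent)
  if (any(conds$target_mz <= 0) || any(conds$tolerance_ppm <= 0) ||
      any(conds$min_intensity_percent <= 0) ||
      any(conds$min_intensity_percent > 100))
    stop("invalid query: need target_mz > 0, tolerance_ppm > 0, ",
         "0 < min_intensity_percent <= 100")
  structure(conds, class = c("DiagnosticQuery", "data.frame"))
}

#' The three-ion carnitine diagnostic query
#'
#' The default repository-mining query: product ions at m/z 60.0808 (>= 1%
#' of base peak), 85.0284 (>= 50%), and 144.1019 (>= 1%), each at 20 ppm.
#' The 85.0284 threshold is the sensitivity knob: 50% is the stringent
#' library-building setting, 10% accommodates QToF collections, and 5% is
#' the relaxed post-networking re-filter.
#'
#' @param threshold_85 Relative-intensity threshold (%) for the 85.0284
#'   condition; default 50.
#' @param tolerance_ppm ppm tolerance for all three conditions; default 20.
#' @return A [diagnostic_query()].
#' @export
carnitine_query <- function(threshold_85 = 50, tolerance_ppm = 20) {
  diagnostic_query(target_mz = c(60.0808, 85.0284, 144.1019),
                   tolerance_ppm = tolerance_ppm,
                   min_intensity_percent = c(1, threshold_85, 1))
}

#' Evaluate a diagnostic query against one spectrum
#'
#' A condition passes iff some peak lies within +/- tolerance_ppm of the
#' target m/z and its intensity is at least `min_intensity_percent` of the
#' spectrum's base peak; the query passes iff all conditions pass. When
#' several peaks fall in a window the most intense one is the condition's
#' witness. A spectrum with no peaks fails every condition (not an error).
#'
#' @param spectrum A [spectrum()].
#' @param query A [diagnostic_query()].
#' @return A list with logical `pass` and a per-condition `report`
#'   data.frame (`target_mz`, `passed`, `witness_mz`, `witness_intensity`,
#'   `witness_relative` as % of base peak; witness columns `NA` when no
#'   peak lies in the window).
#' @export
evaluate_query <- function(spectrum, query) {
  stopifnot(inherits(spectrum, "Spectrum"))
  if (!inherits(query, "DiagnosticQuery")) stop("invalid query object")
  base <- base_peak_intensity(spectrum)
  mz <- spectrum$peaks[, "mz"]
  int <- spectrum$peaks[, "intensity"]
  report <- do.call(rbind, lapply(seq_len(nrow(query)), function(k) {
    target <- query$target_mz[k]
    tol <- target * query$tolerance_ppm[k] * 1e-6
    inwin <- which(abs(mz - target) <= tol)
    if (length(inwin) == 0L || base == 0)
      return(data.frame(target_mz = target, passed = FALSE,
                        witness_mz = NA_real_, witness_intensity = NA_real_,
                        witness_relative = NA_real_))
    w <- inwin[which.max(int[inwin])]
    rel <- int[w] / base * 100
    data.frame(target_mz = target,
               passed = rel >= query$min_intensity_percent[k],
               witness_mz = mz[w], witness_intensity = int[w],
               witness_relative = rel)
  }))
  list(pass = all(report$passed), report = report)
}

#' Filter a spectrum collection by diagnostic query and acquisition mode
#'
#' Retains spectra that pass [evaluate_query()] and whose acquisition mode
#' is not excluded (by default DIA spectra are removed, mirroring the
#' exclusion of chimeric data-independent acquisition data from library
#' building). Input order is preserved; counts are attached as attributes.
#'
#' @param spectra List of [spectrum()] objects.
#' @param query A [diagnostic_query()]; default [carnitine_query()].
#' @param exclude_acquisition Character vector of acquisition labels to
#'   drop; default `"DIA"`. Use `character(0)` to keep everything.
#' @return The retained sublist, with attributes `n_input`,
#'   `n_failed_query`, `n_excluded_acquisition`.
#' @export
filter_spectra <- function(spectra, query = carnitine_query(),
                           exclude_acquisition = "DIA") {
  pass_q <- vapply(spectra, function(s) evaluate_query(s, query)$pass,
                   logical(1))
  acq <- vapply(spectra, function(s) s$acquisition, character(1))
  excl <- acq %in% exclude_acquisition
  keep <- pass_q & !excl
  out <- spectra[keep]
  attr(out, "n_input") <- length(spectra)
  attr(out, "n_failed_query") <- sum(!pass_q)
  attr(out, "n_excluded_acquisition") <- sum(pass_q & excl)
  out
}

#' Estimate the false discovery rate of a query against labeled spectra
#'
#' Given the retained spectra and a truth labeling, the FDR estimate is
#' the fraction of retained spectra whose label is not the target class —
#' the procedure used to validate the diagnostic query against an
#' annotated reference library.
#'
#' @param retained List of retained [spectrum()] objects.
#' @param labels Named logical vector, `spectrum_id -> is_target`.
#' @return FDR in [0, 1].
#' @export
estimate_fdr <- function(retained, labels) {
  if (length(retained) == 0L)
    stop("FDR undefined: no retained spectra")
  ids <- vapply(retained, function(s) s$spectrum_id, character(1))
  if (!all(ids %in% names(labels)))
    stop("unlabeled retained spectra: ",
         paste(utils::head(setdiff(ids, names(labels)), 5), collapse = ", "))
  mean(!labels[ids])
}
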
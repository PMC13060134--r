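#' Construct an MS/MS spectrum
#'
#' A `Spectrum` is one centroided MS/MS scan: precursor information, a peak
#' list, and provenance (which dataset/file/scan it came from and how it was
#' acquired). Peaks are stored sorted ascending by m/z.
#'
#' @param spectrum_id Opaque string identifier, unique within a collection.
#' @param precursor_mz Precursor ion m/z in Da (positive mode); must be > 0.
#' @param peaks Two-column numeric matrix (or data.frame) of `mz` and
#'   `intensity`; m/z must be > 0 and intensities >= 0. Rows are reordered
#'   ascending by m/z.
#' @param charge Integer charge state >= 1; defaults to 1 (positive-mode
#'   [M+H]+ scope).
#' @param dataset_id,file_id Provenance strings (repository dataset and raw
#'   file); default `"unknown"`.
#' @param scan Integer scan number; default `NA`.
#' @param acquisition One of `"DDA"`, `"DIA"`, `"unknown"`.
#' @param ion_mode One of `"positive"`, `"negative"`, `"unknown"`.
#'
#' @return An object of class `"Spectrum"`.
#' @examples
#' sp <- spectrum("s1", 204.1230,
#'                peaks = cbind(c(60.0808, 85.0284, 144.1019),
#'                              c(10, 100, 50)))
#' sp$precursor_mz
#' @export
spectrum <- function(spectrum_id, precursor_mz, peaks, charge = 1L,
                     dataset_id = "unknown", file_id = "unknown",
                     scan = NA_integer_,
                     acquisition = c("unknown", "DDA", "DIA"),
                     ion_mode = c("positive", "negative", "unknown")) {
  acquisition <- match.arg(acquisition)
  ion_mode <- match.arg(ion_mode)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L)
    stop("'peaks' must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0L) {
    if (any(!is.finite(peaks)))
      stop("non-finite peak values in spectrum '", spectrum_id, "'")
    if (any(peaks[, "mz"] <= 0))
      stop("all peak m/z must be > 0 in spectrum '", spectrum_id, "'")
    if (any(peaks[, "intensity"] < 0))
      stop("negative peak intensity in spectrum '", spectrum_id, "'")
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      !is.finite(precursor_mz) || precursor_mz <= 0)
    stop("'precursor_mz' must be a single positive number")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("'charge' must be an integer >= 1")
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      precursor_mz = as.numeric(precursor_mz),
      charge = charge,
      peaks = peaks,
      dataset_id = as.character(dataset_id),
      file_id = as.character(file_id),
      scan = as.integer(scan),
      acquisition = acquisition,
      ion_mode = ion_mode
    ),
    class = "Spectrum"
  )
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf(
    "<Spectrum %s> precursor m/z %.4f (%d+), %d peaks [%s | %s | scan %s, %s]\n",
    x$spectrum_id, x$precursor_mz, x$charge, nrow(x$peaks),
    x$dataset_id, x$file_id,
    ifelse(is.na(x$scan), "?", x$scan), x$acquisition))
  invisible(x)
}

#' Base-peak intensity of a spectrum
#'
#' @param x A `Spectrum`.
#' @return The maximum peak intensity, or 0 for an empty peak list.
#' @export
base_peak_intensity <- function(x) {
  stopifnot(inherits(x, "Spectrum"))
  if (nrow(x$peaks) == 0L) return(0)
  max(x$peaks[, "intensity"])
}

# internal: named list of spectra keyed by spectrum_id, erroring on duplicates
.index_spectra <- function(spectra) {
  ids <- vapply(spectra, function(s) s$spectrum_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(spectra, ids)
}
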
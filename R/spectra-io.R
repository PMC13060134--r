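#' Read MS/MS spectra from an MGF file
#'
#' Parses the Mascot Generic Format dialect used by repository exports:
#' `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE`, `TITLE` headers
#' and one `mz intensity` pair per line. Provenance keys (`DATASET`,
#' `FILENAME`, `SCANS`, `ACQUISITION`, `IONMODE`) are read when present and
#' defaulted otherwise; unparseable optional keys degrade to their defaults
#' rather than dropping the spectrum. The first `PEPMASS` token is the
#' precursor m/z; `CHARGE` strings such as `"1+"` parse to +1 and a missing
#' charge defaults to 1 (positive-mode scope).
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects in file order; an empty file gives
#'   an empty list.
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    body <- lines[seq(begins[b] + 1L, ends[b] - 1L)]
    body <- body[nzchar(body)]
    is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
    kv <- body[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getval <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pep <- getval("PEPMASS")
    if (is.na(pep))
      stop("MGF block ", b, ": missing PEPMASS")
    precursor <- suppressWarnings(as.numeric(strsplit(pep, "[ \t]+")[[1]][1]))
    if (is.na(precursor))
      stop("MGF block ", b, ": non-numeric PEPMASS '", pep, "'")
    charge <- 1L
    ch <- getval("CHARGE")
    if (!is.na(ch)) {
      chn <- suppressWarnings(as.integer(sub("\\+$", "", ch)))
      if (!is.na(chn) && chn >= 1L) charge <- chn
    }
    title <- getval("TITLE")
    if (is.na(title)) title <- sprintf("spectrum_%d", b)
    scan <- suppressWarnings(as.integer(getval("SCANS")))
    acq <- toupper(getval("ACQUISITION"))
    acq <- if (!is.na(acq) && acq %in% c("DDA", "DIA")) acq else "unknown"
    mode <- tolower(getval("IONMODE"))
    mode <- if (!is.na(mode) && mode %in% c("positive", "negative")) mode
            else "positive"
    ds <- getval("DATASET"); if (is.na(ds)) ds <- "unknown"
    fl <- getval("FILENAME"); if (is.na(fl)) fl <- "unknown"
    peak_lines <- body[!is_kv]
    if (length(peak_lines)) {
      parts <- strsplit(peak_lines, "[ \t]+")
      bad <- vapply(parts, function(p)
        length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2]))),
        logical(1))
      if (any(bad))
        stop("MGF block ", b, ": non-numeric peak line '",
             peak_lines[which(bad)[1]], "'")
      peaks <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
    } else {
      peaks <- matrix(numeric(0), ncol = 2)
    }
    spectra[[b]] <- spectrum(title, precursor, peaks, charge = charge,
                             dataset_id = ds, file_id = fl, scan = scan,
                             acquisition = acq, ion_mode = mode)
  }
  spectra
}

#' Write MS/MS spectra to an MGF file
#'
#' Inverse of [read_mgf()]: emits one `BEGIN IONS` block per spectrum, in
#' input order, with full provenance keys so that a round trip is lossless
#' for precursor m/z, charge, peaks and provenance.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "Spectrum"))
    header <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$charge),
      if (!is.na(sp$scan)) paste0("SCANS=", sp$scan),
      paste0("DATASET=", sp$dataset_id),
      paste0("FILENAME=", sp$file_id),
      paste0("ACQUISITION=", sp$acquisition),
      paste0("IONMODE=", sp$ion_mode)
    )
    writeLines(header, con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.6f", sp$peaks[, "mz"],
                         sp$peaks[, "intensity"]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read centroided MS/MS spectra from an mzML file
#'
#' Read-only mzML support through the `mzR` backend; only centroided MS2
#' scans are accepted — profile-mode spectra raise an error because the
#' pipeline consumes centroided peak lists.
#'
#' @param path Path to an mzML file.
#' @param dataset_id Dataset accession to stamp on the spectra.
#' @return A list of [spectrum()] objects (MS2 scans only).
#' @export
read_mzml <- function(path, dataset_id = "unknown") {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  ms2 <- which(hdr$msLevel == 2L)
  if (any(!hdr$centroided[ms2]))
    stop("profile-mode MS2 spectra found; only centroided data supported")
  lapply(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    spectrum(sprintf("%s:scan:%d", basename(path), hdr$acquisitionNum[i]),
             precursor_mz = hdr$precursorMZ[i],
             peaks = pk,
             charge = max(1L, hdr$precursorCharge[i], na.rm = TRUE),
             dataset_id = dataset_id, file_id = basename(path),
             scan = hdr$acquisitionNum[i])
  })
}

#' Construct a feature quantification table
#'
#' Couples a feature x sample abundance matrix with feature annotations
#' (m/z, retention time, optional label) and sample metadata (tissue,
#' timepoint, group, blank flag). Missing abundances are `NA`, distinct
#' from a detected zero.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt` and
#'   optionally `annotation`.
#' @param abundance Numeric matrix, rows = features (rownames =
#'   feature ids), columns = samples (colnames = sample ids); `NA` encodes
#'   missing.
#' @param samples data.frame with columns `sample_id`, `tissue`,
#'   `timepoint`, `group`, `is_blank`.
#' @return An object of class `"FeatureTable"`.
#' @export
feature_table <- function(features, abundance, samples) {
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  abundance <- as.matrix(abundance)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(features)),
            all(c("sample_id", "tissue", "timepoint", "group", "is_blank")
                %in% names(samples)))
  if (!"annotation" %in% names(features)) features$annotation <- NA_character_
  if (nrow(abundance) != nrow(features) ||
      ncol(abundance) != nrow(samples))
    stop("abundance matrix dimensions do not match feature/sample lists")
  rownames(abundance) <- features$feature_id
  colnames(abundance) <- samples$sample_id
  if (any(abundance < 0, na.rm = TRUE)) stop("negative abundances")
  if (any(features$rt < 0, na.rm = TRUE)) stop("negative retention times")
  all_missing <- rowSums(!is.na(abundance)) == 0L
  structure(list(features = features, abundance = abundance,
                 samples = samples, all_missing = all_missing),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("<FeatureTable> %d features x %d samples (%d blanks, %d all-missing features)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$samples$is_blank), sum(x$all_missing)))
  invisible(x)
}

#' Read a feature table and its sample metadata from delimited text
#'
#' The matrix file's first column holds feature ids; optional `mz`, `rt`
#' and `annotation` columns are consumed as feature attributes and every
#' remaining column is a sample. Empty cells are missing (`NA`); a literal
#' 0 is a detected zero. Every sample column must have a metadata row.
#'
#' @param matrix_path Path to the feature x sample matrix (TSV or CSV by
#'   extension).
#' @param metadata_path Path to sample metadata with columns `sample_id`,
#'   `tissue`, `timepoint`, `group`, `is_blank`.
#' @param sep Field separator; default inferred from the file extension.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(matrix_path, metadata_path, sep = NULL) {
  pick_sep <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  sep1 <- if (is.null(sep)) pick_sep(matrix_path) else sep
  sep2 <- if (is.null(sep)) pick_sep(metadata_path) else sep
  mat <- utils::read.table(matrix_path, header = TRUE, sep = sep1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  meta <- utils::read.table(metadata_path, header = TRUE, sep = sep2,
                            check.names = FALSE, stringsAsFactors = FALSE)
  feat_cols <- intersect(c("mz", "rt", "annotation"), names(mat)[-1])
  sample_cols <- setdiff(names(mat)[-1], feat_cols)
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta))
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  meta$is_blank <- as.logical(meta$is_blank)
  features <- data.frame(feature_id = as.character(mat[[1]]),
                         stringsAsFactors = FALSE)
  features$mz <- if ("mz" %in% feat_cols) as.numeric(mat$mz) else NA_real_
  features$rt <- if ("rt" %in% feat_cols) as.numeric(mat$rt) else NA_real_
  features$annotation <- if ("annotation" %in% feat_cols)
    as.character(mat$annotation) else NA_character_
  abundance <- as.matrix(mat[, sample_cols, drop = FALSE])
  storage.mode(abundance) <- "double"
  feature_table(features, abundance, meta)
}
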
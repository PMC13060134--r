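#' Build the delta-mass spectral library
#'
#' Converts a clustering result into curated library entries: one entry
#' per cluster representative, with the delta mass of its precursor
#' against the carnitine core and the union of dataset accessions over the
#' cluster's members. Canonical two-decimal delta keys supported by fewer
#' than `min_datasets` distinct datasets across the whole library are
#' removed (the >=2-independent-study support rule); support is tallied on
#' canonical keys across the whole retained set.
#'
#' @param assignment A `"ClusterAssignment"` from [cluster_spectra()], or a
#'   data.frame with columns `spectrum_id` and `cluster_id` plus a
#'   `representatives` mapping.
#' @param spectra The full list of [spectrum()] objects the assignment was
#'   computed from (provenance source).
#' @param min_datasets Minimum distinct supporting datasets per delta key
#'   (default 2).
#' @return Object of class `"CarnitineLibrary"`: data.frame with columns
#'   `cluster_id`, `representative_id`, `precursor_mz`, `delta_mass`,
#'   `delta_key`, `n_datasets`, `supporting_datasets` (list column),
#'   `delta_formula`, `car_name`, `composition_class`; the dropped keys are
#'   recorded in the `"dropped_keys"` attribute and the representative
#'   spectra in the `"spectra"` attribute.
#' @export
build_library <- function(assignment, spectra, min_datasets = 2L) {
  stopifnot(inherits(assignment, "ClusterAssignment"))
  idx <- .index_spectra(spectra)
  reps <- assignment$representatives
  asg <- assignment$assignments
  entries <- do.call(rbind, lapply(seq_len(nrow(reps)), function(k) {
    cid <- reps$cluster_id[k]
    rep_sp <- idx[[reps$representative_id[k]]]
    members <- asg$spectrum_id[asg$cluster_id == cid]
    dsets <- sort(unique(vapply(idx[members], function(s) s$dataset_id,
                                character(1))))
    dm <- compute_delta_mass(rep_sp$precursor_mz, rep_sp$charge)
    data.frame(cluster_id = cid,
               representative_id = rep_sp$spectrum_id,
               precursor_mz = rep_sp$precursor_mz,
               delta_mass = dm$delta,
               delta_key = dm$key,
               valid = dm$valid,
               supporting_datasets = I(list(dsets)),
               stringsAsFactors = FALSE)
  }))
  entries <- entries[entries$valid, , drop = FALSE]
  # dataset support per canonical key, pooled across entries sharing the key
  key_chr <- sprintf("%.2f", entries$delta_key)
  support <- tapply(entries$supporting_datasets, key_chr,
                    function(l) length(unique(unlist(l))))
  entries$n_datasets <- as.integer(support[key_chr])
  keep <- entries$n_datasets >= min_datasets
  dropped <- unique(key_chr[!keep])
  entries <- entries[keep, , drop = FALSE]
  entries$valid <- NULL
  entries$delta_formula <- NA_character_
  entries$car_name <- NA_character_
  entries$composition_class <- "unassigned"
  rownames(entries) <- NULL
  structure(entries,
            class = c("CarnitineLibrary", "data.frame"),
            dropped_keys = dropped,
            spectra = idx[entries$representative_id])
}

#' Annotate library entries with delta formulas and CAR names
#'
#' Joins externally predicted precursor formulas onto the library, derives
#' each delta formula by subtracting the carnitine core, and fills in the
#' CAR nomenclature and composition class where the arithmetic is
#' consistent. Entries without a prediction, or whose precursor cannot
#' contain the core, stay unassigned.
#'
#' @param library A [build_library()] result.
#' @param precursor_formulas Named character vector,
#'   `representative_id -> precursor formula string` (neutral molecule).
#' @return The library with `delta_formula`, `car_name` and
#'   `composition_class` filled where derivable.
#' @export
annotate_library <- function(library, precursor_formulas) {
  stopifnot(inherits(library, "CarnitineLibrary"))
  for (k in seq_len(nrow(library))) {
    id <- library$representative_id[k]
    if (!id %in% names(precursor_formulas)) next
    delta <- delta_formula_from_precursor(precursor_formulas[[id]])
    if (is.null(delta)) next
    library$delta_formula[k] <- format_formula(delta)
    library$car_name[k] <- assign_car_nomenclature(delta)
    library$composition_class[k] <- composition_class(delta)
  }
  library
}

#' Export library entries as an annotated MGF plus a TSV table
#'
#' @param library A [build_library()] result.
#' @param mgf_path,tsv_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_library <- function(library, mgf_path, tsv_path) {
  stopifnot(inherits(library, "CarnitineLibrary"))
  write_mgf(attr(library, "spectra"), mgf_path)
  tab <- as.data.frame(library)
  tab$supporting_datasets <- vapply(tab$supporting_datasets,
                                    paste, character(1), collapse = ";")
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
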
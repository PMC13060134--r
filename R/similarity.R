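# Greedy one-to-one peak matching shared by all three similarity scores.
#
# Candidate pairs are peak index pairs (i in a, j in b) whose m/z agree
# within fragment_tol_da at any of the allowed shifts (0 for plain cosine;
# 0 and the precursor difference for modified cosine). Pairs are consumed
# greedily by descending weight product, each peak used at most once; ties
# broken by (i, j) index for determinism.
.match_peaks <- function(mza, wa, mzb, wb, fragment_tol_da, shifts = 0) {
  cand_i <- integer(0); cand_j <- integer(0)
  for (s in shifts) {
    for (i in seq_along(mza)) {
      hit <- which(abs(mza[i] - (mzb + s)) <= fragment_tol_da)
      cand_i <- c(cand_i, rep.int(i, length(hit)))
      cand_j <- c(cand_j, hit)
    }
  }
  if (length(cand_i) == 0L)
    return(list(i = integer(0), j = integer(0)))
  dup <- duplicated(cand_i * (length(mzb) + 1L) + cand_j)
  cand_i <- cand_i[!dup]; cand_j <- cand_j[!dup]
  prod <- wa[cand_i] * wb[cand_j]
  ord <- order(-prod, cand_i, cand_j)
  used_a <- logical(length(mza)); used_b <- logical(length(mzb))
  keep_i <- integer(0); keep_j <- integer(0)
  for (k in ord) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      keep_i <- c(keep_i, i); keep_j <- c(keep_j, j)
    }
  }
  list(i = keep_i, j = keep_j)
}

.peak_weights <- function(sp, intensity_power) {
  sp$peaks[, "intensity"]^intensity_power
}

#' Cosine similarity between two spectra
#'
#' Fragment peaks are matched one-to-one within `fragment_tol_da`, greedily
#' by descending product of intensity weights, and the score is the
#' normalised dot product of matched weights
#' (weights = intensity^`intensity_power`, square-root by default, the
#' molecular-networking convention). Symmetric in its arguments.
#'
#' @param a,b [spectrum()] objects with at least one peak each.
#' @param fragment_tol_da Fragment m/z tolerance in Da (default 0.02).
#' @param intensity_power Exponent applied to intensities before matching
#'   and scoring (default 0.5).
#' @return A list with `score` in [0, 1] and `n_matched`.
#' @export
cosine_similarity <- function(a, b, fragment_tol_da = 0.02,
                              intensity_power = 0.5) {
  stopifnot(inherits(a, "Spectrum"), inherits(b, "Spectrum"))
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L)
    stop("cosine similarity of an empty spectrum is undefined")
  wa <- .peak_weights(a, intensity_power)
  wb <- .peak_weights(b, intensity_power)
  m <- .match_peaks(a$peaks[, "mz"], wa, b$peaks[, "mz"], wb, fragment_tol_da)
  score <- if (length(m$i) == 0L) 0 else
    sum(wa[m$i] * wb[m$j]) / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
  list(score = min(1, score), n_matched = length(m$i))
}

#' Modified cosine similarity (analog-aware)
#'
#' Like [cosine_similarity()], but peaks may also match after shifting by
#' the precursor mass difference, linking structural analogs whose
#' fragments carry the modification. Candidate matches arise at zero shift
#' or at shift `precursor(a) - precursor(b)`; assignment is greedy
#' one-to-one by descending weight product and normalisation is identical
#' to the plain cosine, so the modified score is never below the plain one.
#'
#' @inheritParams cosine_similarity
#' @return A list with `score` in [0, 1] and `n_matched`.
#' @export
modified_cosine <- function(a, b, fragment_tol_da = 0.02,
                            intensity_power = 0.5) {
  stopifnot(inherits(a, "Spectrum"), inherits(b, "Spectrum"))
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L)
    stop("modified cosine of an empty spectrum is undefined")
  wa <- .peak_weights(a, intensity_power)
  wb <- .peak_weights(b, intensity_power)
  shift <- a$precursor_mz - b$precursor_mz
  shifts <- if (abs(shift) <= fragment_tol_da) 0 else c(0, shift)
  m <- .match_peaks(a$peaks[, "mz"], wa, b$peaks[, "mz"], wb,
                    fragment_tol_da, shifts = shifts)
  score <- if (length(m$i) == 0L) 0 else
    sum(wa[m$i] * wb[m$j]) / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
  list(score = min(1, score), n_matched = length(m$i))
}

#' Reverse cosine similarity against a reference spectrum
#'
#' Matching proceeds as in [cosine_similarity()], but the normalisation
#' uses the full reference peak norm and only the matched subset of the
#' query's peaks, so extra query-only peaks (e.g. fragments of an unknown
#' conjugated moiety) do not penalise the score. Used to annotate
#' conjugates whose spectra contain a known reference sub-spectrum. By
#' construction `reverse >= cosine` on any pair.
#'
#' @param query,reference [spectrum()] objects; the reference must be
#'   non-empty.
#' @param fragment_tol_da Fragment m/z tolerance in Da.
#' @param min_score,min_matched Gates for the `pass` flag (defaults 0.7
#'   and 3, the conjugate-annotation thresholds).
#' @param intensity_power Intensity exponent as in [cosine_similarity()].
#' @return A list with `score`, `n_matched` and logical `pass`.
#' @export
reverse_cosine <- function(query, reference, fragment_tol_da = 0.02,
                           min_score = 0.7, min_matched = 3L,
                           intensity_power = 0.5) {
  stopifnot(inherits(query, "Spectrum"), inherits(reference, "Spectrum"))
  if (nrow(reference$peaks) == 0L)
    stop("reverse cosine against an empty reference is undefined")
  if (nrow(query$peaks) == 0L)
    stop("reverse cosine of an empty query is undefined")
  wq <- .peak_weights(query, intensity_power)
  wr <- .peak_weights(reference, intensity_power)
  m <- .match_peaks(query$peaks[, "mz"], wq, reference$peaks[, "mz"], wr,
                    fragment_tol_da)
  score <- if (length(m$i) == 0L) 0 else
    sum(wq[m$i] * wr[m$j]) /
      (sqrt(sum(wq[m$i]^2)) * sqrt(sum(wr^2)))
  score <- min(1, score)
  list(score = score, n_matched = length(m$i),
       pass = score >= min_score && length(m$i) >= min_matched)
}
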
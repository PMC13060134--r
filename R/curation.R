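#' Parse a molecular formula string
#'
#' Parses Hill-style formulas such as `"C9H17NO4"` into element counts.
#' Implicit counts of 1 are handled; unknown element symbols or malformed
#' tokens raise an error naming the offending position.
#'
#' @param text Formula string. `""` parses to an empty formula.
#' @return Named integer vector of element counts (class
#'   `"element_counts"` semantics: plain named integer vector).
#' @examples
#' parse_formula("C7H15NO3")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regmatches(substr(text, pos, n),
                    regexpr("^([A-Z][a-z]?)([0-9]*)", substr(text, pos, n)))
    if (length(m) == 0L || !nzchar(m))
      stop("malformed formula token at position ", pos, " in '", text, "'")
    sym <- sub("[0-9]*$", "", m)
    if (!sym %in% names(ELEMENT_MASSES))
      stop("unknown element '", sym, "' at position ", pos, " in '", text, "'")
    num <- sub("^[A-Za-z]+", "", m)
    cnt <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m)
  }
  counts
}

#' Format element counts back into a formula string
#'
#' Hill order (C, H, then alphabetical); zero counts are dropped.
#'
#' @param counts Named integer vector of element counts.
#' @return A formula string; `""` for an empty formula.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return("")
  rest <- sort(setdiff(names(counts), c("C", "H")))
  ord <- c(intersect(c("C", "H"), names(counts)), rest)
  paste0(vapply(ord, function(el) {
    if (counts[[el]] == 1L) el else paste0(el, counts[[el]])
  }, character(1)), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of standard monoisotopic atomic masses; `charge_protons` protons are
#' added (and the matching electrons subtracted) to give an ion m/z, divided
#' by the charge for multiply protonated species.
#'
#' @param counts Named integer vector of element counts (or a formula
#'   string, parsed with [parse_formula()]).
#' @param charge_protons Number of added protons; 0 (default) returns the
#'   neutral monoisotopic mass.
#' @return Mass (or m/z) in Da.
#' @examples
#' monoisotopic_mass("C7H15NO3")              # neutral carnitine
#' monoisotopic_mass("C7H15NO3", 1)           # [M+H]+ m/z
#' @export
monoisotopic_mass <- function(counts, charge_protons = 0L) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (any(counts < 0)) stop("negative element counts")
  bad <- setdiff(names(counts), names(ELEMENT_MASSES))
  if (length(bad)) stop("unknown elements: ", paste(bad, collapse = ", "))
  m <- if (length(counts)) sum(counts * ELEMENT_MASSES[names(counts)]) else 0
  z <- as.integer(charge_protons)
  if (z < 0L) stop("'charge_protons' must be >= 0")
  if (z == 0L) return(m)
  (m + z * PROTON_MASS) / z
}

#' Delta mass of an acylcarnitine precursor
#'
#' The delta mass is the difference between the precursor ion m/z and the
#' protonated carnitine core (C7H15NO3, [M+H]+ at m/z 162.1125); it
#' identifies the conjugated modification independent of structure. The
#' canonical library key is the delta rounded (half-to-even) to two
#' decimals.
#'
#' @param precursor_mz Precursor ion m/z in Da.
#' @param charge Charge state; only 1 is accepted (positive-mode [M+H]+
#'   scope — multiply charged carnitines are not modelled).
#' @return A list with `delta` (full precision Da), `key` (two-decimal
#'   canonical value), and `valid` (`FALSE` when the precursor lies more
#'   than 0.02 Da below the carnitine core, i.e. cannot be a conjugate).
#' @examples
#' compute_delta_mass(204.1230)  # acetylcarnitine -> key 42.01
#' @export
compute_delta_mass <- function(precursor_mz, charge = 1L) {
  if (as.integer(charge) != 1L)
    stop("only singly charged [M+H]+ precursors are supported")
  delta <- precursor_mz - CARNITINE_MH
  list(delta = delta, key = round(delta, 2), valid = delta >= -0.02)
}

#' Mass defect of a delta mass
#'
#' Difference between a delta mass and its nearest integer, mapped to the
#' half-open interval (-0.5, 0.5].
#'
#' @param delta Delta mass in Da (vectorised).
#' @return Mass defect in Da, in (-0.5, 0.5].
#' @examples
#' mass_defect(42.0106)   #  0.0106
#' mass_defect(15.995)    # -0.005
#' @export
mass_defect <- function(delta) {
  delta - ceiling(delta - 0.5)
}

#' Delta formula from a predicted precursor formula
#'
#' Subtracts the carnitine core (C7H15NO3) element-wise from a neutral
#' precursor formula. Precursors that cannot contain the core (any element
#' going negative) yield `NULL` with the deficient elements reported in the
#' `"reason"` attribute.
#'
#' @param precursor_formula Named integer vector or formula string of the
#'   neutral precursor molecule.
#' @return Named integer vector of the delta formula, or `NULL`.
#' @examples
#' delta_formula_from_precursor("C9H17NO4")  # C2H2O (acetyl)
#' @export
delta_formula_from_precursor <- function(precursor_formula) {
  if (is.character(precursor_formula))
    precursor_formula <- parse_formula(precursor_formula)
  els <- union(names(precursor_formula), names(CARNITINE_FORMULA))
  get <- function(v, el) if (el %in% names(v)) v[[el]] else 0L
  delta <- vapply(els, function(el)
    get(precursor_formula, el) - get(CARNITINE_FORMULA, el), integer(1))
  if (any(delta < 0)) {
    warning("precursor lacks carnitine core (deficit: ",
            paste(els[delta < 0], collapse = ", "), ")")
    return(NULL)
  }
  out <- delta[delta > 0]
  if (length(out) == 0L) integer(0) else out
}

#' CAR lipid nomenclature for a CHO delta formula
#'
#' Assigns the LIPID MAPS-style label `CAR Cx:y` / `CAR Cx:y;Oz` to a delta
#' formula containing only C, H and O: an x-carbon acyl chain with y
#' unsaturations and z extra oxygens beyond the ester oxygen. The chain
#' arithmetic treats the ester carbonyl as not a chain unsaturation, so the
#' acetyl delta C2H2O maps to `CAR C2:0`. Formulas with heteroatoms,
#' non-integer or negative unsaturation counts, fewer than two carbons, or
#' no oxygen are left unlabeled (`NA`).
#'
#' @param delta Named integer vector (or formula string) of the delta
#'   formula.
#' @return The CAR label string, or `NA_character_` when no label applies.
#' @examples
#' assign_car_nomenclature("C2H2O")     # "CAR C2:0"
#' assign_car_nomenclature("C18H32O2")  # "CAR C18:1;O"
#' @export
assign_car_nomenclature <- function(delta) {
  if (is.character(delta)) delta <- parse_formula(delta)
  delta <- delta[delta > 0]
  if (length(delta) == 0L) return(NA_character_)
  if (!all(names(delta) %in% c("C", "H", "O"))) return(NA_character_)
  get <- function(el) if (el %in% names(delta)) delta[[el]] else 0L
  x <- get("C"); h <- get("H"); o <- get("O")
  if (o < 1L || x < 2L) return(NA_character_)
  y <- x - h / 2 - 1
  if (y < 0 || y != round(y)) return(NA_character_)
  z <- o - 1L
  if (z == 0L) sprintf("CAR C%d:%d", x, as.integer(y))
  else if (z == 1L) sprintf("CAR C%d:%d;O", x, as.integer(y))
  else sprintf("CAR C%d:%d;O%d", x, as.integer(y), z)
}

#' Composition class of a delta formula
#'
#' The set of elements present, in Hill order — e.g. `"CHO"`, `"CHNO"`,
#' `"CHOS"`; `NULL` formulas give `"unassigned"`.
#'
#' @param delta Named integer vector of element counts, or `NULL`.
#' @return Class string.
#' @export
composition_class <- function(delta) {
  if (is.null(delta)) return("unassigned")
  delta <- delta[delta > 0]
  if (length(delta) == 0L) return("none")
  rest <- sort(setdiff(names(delta), c("C", "H")))
  paste0(c(intersect(c("C", "H"), names(delta)), rest), collapse = "")
}

#' Brute-force elemental decomposition of a delta mass
#'
#' Enumerates all delta compositions within the element bounds whose
#' implied precursor ([M+H]+ of carnitine + delta) lies within `tol_ppm`
#' of the implied precursor m/z of the target delta. A ring-and-double-bond
#' equivalent (RDBE) filter is applied to the full precursor formula. This
#' is the desk-scale stand-in for external formula-prediction tools and is
#' only intended for small bounds.
#'
#' @param delta Delta mass in Da (> 0).
#' @param tol_ppm Mass tolerance in ppm applied on the precursor m/z scale.
#' @param element_bounds Named list of `c(min, max)` count bounds per
#'   element; default CHNO bounds sized for acyl modifications.
#' @param rdbe_range Allowed RDBE range of the precursor formula.
#' @return data.frame of candidate delta formulas (`formula`, element
#'   counts, `mass`, `error_ppm`) sorted by absolute mass error; zero rows
#'   when nothing fits.
#' @export
decompose_delta <- function(delta, tol_ppm = 5,
                            element_bounds = list(C = c(0, 30), H = c(0, 60),
                                                  N = c(0, 2), O = c(0, 10)),
                            rdbe_range = c(0, 40)) {
  stopifnot(delta > 0, all(vapply(element_bounds, length, 0L) == 2L))
  target_precursor <- CARNITINE_MH + delta
  grid <- expand.grid(lapply(element_bounds, function(b)
    seq.int(b[1], b[2])), KEEP.OUT.ATTRS = FALSE)
  els <- names(element_bounds)
  mass <- as.numeric(as.matrix(grid) %*% ELEMENT_MASSES[els])
  err <- (CARNITINE_MH + mass - target_precursor) / target_precursor * 1e6
  keep <- abs(err) <= tol_ppm
  grid <- grid[keep, , drop = FALSE]
  mass <- mass[keep]; err <- err[keep]
  if (nrow(grid)) {
    # RDBE of the neutral precursor (delta + carnitine core)
    full <- function(el) {
      base <- if (el %in% names(CARNITINE_FORMULA)) CARNITINE_FORMULA[[el]] else 0L
      base + (if (el %in% els) grid[[el]] else 0L)
    }
    hal <- Reduce(`+`, lapply(intersect(c("F", "Cl", "Br", "I"), els),
                              function(el) grid[[el]]), 0L)
    rdbe <- full("C") - (full("H") + hal) / 2 + full("N") / 2 + 1
    keep <- rdbe >= rdbe_range[1] & rdbe <= rdbe_range[2]
    grid <- grid[keep, , drop = FALSE]
    mass <- mass[keep]; err <- err[keep]
  }
  ord <- order(abs(err))
  grid <- grid[ord, , drop = FALSE]
  out <- data.frame(
    formula = vapply(seq_len(nrow(grid)), function(i) {
      cnt <- as.integer(grid[i, ]); names(cnt) <- els
      format_formula(cnt)
    }, character(1)),
    grid, mass = mass[ord], error_ppm = err[ord],
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Acyl chain length category
#'
#' Classifies an acyl carbon count as short (C2-C6), medium (C7-C12),
#' long (C13-C21) or very long (C22-C30); anything else is
#' `"out_of_range"`.
#'
#' @param x Integer carbon count (vectorised).
#' @return Character vector of categories.
#' @export
chain_length_category <- function(x) {
  out <- rep("out_of_range", length(x))
  out[x >= 2 & x <= 6] <- "short"
  out[x >= 7 & x <= 12] <- "medium"
  out[x >= 13 & x <= 21] <- "long"
  out[x >= 22 & x <= 30] <- "very_long"
  out
}
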
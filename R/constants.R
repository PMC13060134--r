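#' Monoisotopic atomic masses
#'
#' Standard monoisotopic masses (Da) of the most abundant isotope of each
#' supported element, plus the electron mass used in ion m/z arithmetic.
#' The electron term matters at the fourth decimal against the diagnostic
#' product ions, so it is never dropped.
#'
#' @format Named numeric vector of element masses in Da.
#' @export
ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473
)

#' @rdname ELEMENT_MASSES
#' @export
ELECTRON_MASS <- 0.00054857990907

# proton = H atom minus its electron; used throughout for [M+H]+ arithmetic
PROTON_MASS <- ELEMENT_MASSES[["H"]] - ELECTRON_MASS

#' Carnitine core constants
#'
#' The free L-carnitine core is C7H15NO3. Every delta mass in the library
#' is the difference between an acylcarnitine precursor ion and the
#' protonated carnitine core, so this m/z anchors the whole pipeline.
#'
#' @format `CARNITINE_FORMULA` is a named integer vector of element counts;
#'   `CARNITINE_MH` is the [M+H]+ m/z of free carnitine in Da.
#' @export
CARNITINE_FORMULA <- c(C = 7L, H = 15L, N = 1L, O = 3L)

#' @rdname CARNITINE_FORMULA
#' @export
CARNITINE_MH <- sum(CARNITINE_FORMULA *
                      ELEMENT_MASSES[names(CARNITINE_FORMULA)]) + PROTON_MASS

# m/z of a fragment cation given element counts of the charged species
.fragment_mz <- function(counts) {
  sum(counts * ELEMENT_MASSES[names(counts)]) - ELECTRON_MASS
}

#' Diagnostic product ions of the carnitine core
#'
#' Positive-mode fragment cations characteristic of acylcarnitines:
#' trimethylamine-derived C3H10N+ (m/z 60.0808), the butenoyl cation
#' C4H5O2+ (m/z 85.0284), and dehydrated protonated carnitine C7H14NO2+
#' (m/z 144.1019).
#'
#' @format Named numeric vector of fragment m/z values in Da.
#' @export
DIAGNOSTIC_IONS <- c(
  tma             = .fragment_mz(c(C = 3, H = 10, N = 1)),
  butenoyl        = .fragment_mz(c(C = 4, H = 5, O = 2)),
  dehydrated_core = .fragment_mz(c(C = 7, H = 14, N = 1, O = 2))
)
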
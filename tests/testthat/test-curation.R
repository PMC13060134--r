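test_that("formula parsing and formatting", {
  expect_equal(parse_formula("C9H17NO4"),
               c(C = 9L, H = 17L, N = 1L, O = 4L))
  expect_equal(parse_formula("C7H15NO3"),
               c(C = 7L, H = 15L, N = 1L, O = 3L))
  expect_error(parse_formula("C9Hx"), "position")
  expect_error(parse_formula("C9Xy2"), "unknown element")
  expect_equal(parse_formula(""), integer(0))
  expect_equal(format_formula(c(O = 1L, C = 2L, H = 2L)), "C2H2O")
  expect_equal(format_formula(parse_formula("C6H8O6S")), "C6H8O6S")
})

test_that("monoisotopic masses match independently derived values", {
  # frozen from an independent mass calculator (pyteomics) at 4 dp
  expect_equal(monoisotopic_mass("C7H15NO3"), 161.1052, tolerance = 5e-5)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 5e-5)
  expect_equal(monoisotopic_mass("C7H15NO3", 1), 162.1125, tolerance = 5e-5)
  expect_equal(monoisotopic_mass("C9H17NO4", 1), 204.1230, tolerance = 5e-5)
  expect_equal(monoisotopic_mass(integer(0)), 0)
  expect_error(monoisotopic_mass(c(C = -1L)), "negative")
})

test_that("delta mass computation and canonical keys", {
  # acetylcarnitine [M+H]+ -> acetylation delta 42.01
  expect_equal(compute_delta_mass(204.1230)$key, 42.01)
  expect_equal(compute_delta_mass(CARNITINE_MH)$key, 0)
  # sulfation shifts a conjugate by 79.96 at two decimals
  d1 <- compute_delta_mass(400.2000 + monoisotopic_mass("SO3"))$delta
  d2 <- compute_delta_mass(400.2000)$delta
  expect_equal(round(d1 - d2, 2), 79.96)
  expect_false(compute_delta_mass(150.0)$valid)
  expect_error(compute_delta_mass(300, charge = 2), "singly charged")
})

test_that("mass defect is the signed distance to the nearest integer", {
  expect_equal(mass_defect(42.0106), 0.0106, tolerance = 1e-10)
  expect_equal(mass_defect(15.995), -0.005, tolerance = 1e-10)
  expect_equal(mass_defect(0), 0)
  # range and integer-shift invariance
  set.seed(51)
  d <- runif(200, -10, 300)
  md <- mass_defect(d)
  expect_true(all(md > -0.5 & md <= 0.5))
  expect_equal(mass_defect(d + 7), md, tolerance = 1e-9)
})

test_that("delta formulas derive from precursor formulas by core subtraction", {
  expect_equal(delta_formula_from_precursor("C9H17NO4"), c(C = 2L, H = 2L, O = 1L))
  expect_equal(delta_formula_from_precursor("C7H15NO3"), integer(0))
  expect_warning(out <- delta_formula_from_precursor("C6H12O6"), "N")
  expect_null(out)
})

test_that("CAR nomenclature worked examples and exclusions", {
  expect_equal(assign_car_nomenclature("C2H2O"), "CAR C2:0")
  expect_equal(assign_car_nomenclature("C18H32O2"), "CAR C18:1;O")
  expect_equal(assign_car_nomenclature("C4H6O3"), "CAR C4:0;O2")
  expect_true(is.na(assign_car_nomenclature("C3H5NO")))   # heteroatom
  expect_true(is.na(assign_car_nomenclature("C2H2")))     # no oxygen
  expect_true(is.na(assign_car_nomenclature("CH2O")))     # one carbon
  expect_true(is.na(assign_car_nomenclature("C4H7O")))    # half-integer y
})

test_that("nomenclature round trip over the full chain/unsaturation grid", {
  for (x in 2:30) for (y in 0:6) for (z in 0:3) {
    h <- 2 * x - 2 * y - 2
    if (h < 0) next
    delta <- c(C = x, H = h, O = z + 1L)
    delta <- delta[delta > 0]
    want <- if (z == 0) sprintf("CAR C%d:%d", x, y)
            else if (z == 1) sprintf("CAR C%d:%d;O", x, y)
            else sprintf("CAR C%d:%d;O%d", x, y, z)
    expect_identical(assign_car_nomenclature(delta), want)
  }
})

test_that("bounded decomposition recovers known deltas and matches a
           triple-loop enumeration", {
  hits <- decompose_delta(42.0106, tol_ppm = 5,
                          element_bounds = list(C = c(0, 5), H = c(0, 10),
                                                O = c(0, 3)))
  expect_equal(hits$formula[1], "C2H2O")
  expect_true("H2O" %in% decompose_delta(
    18.0106, tol_ppm = 5,
    element_bounds = list(C = c(0, 3), H = c(0, 6), O = c(0, 2)))$formula)
  # independent triple-loop oracle over the same small CHO bounds
  target <- 100.0524  # monoisotopic mass of C5H8O2
  bounds <- list(C = c(0, 6), H = c(0, 12), O = c(0, 3))
  oracle <- character(0)
  for (c_ in 0:6) for (h in 0:12) for (o in 0:3) {
    m <- c_ * ELEMENT_MASSES[["C"]] + h * ELEMENT_MASSES[["H"]] +
      o * ELEMENT_MASSES[["O"]]
    prec <- CARNITINE_MH + target
    if (abs((CARNITINE_MH + m - prec) / prec * 1e6) <= 10)
      oracle <- c(oracle, format_formula(c(C = c_, H = h, O = o)))
  }
  got <- decompose_delta(target, tol_ppm = 10, element_bounds = bounds)
  expect_setequal(got$formula, oracle)
  # zero tolerance with no exact composition: empty
  none <- decompose_delta(42.5, tol_ppm = 0.0001,
                          element_bounds = list(C = c(0, 3), H = c(0, 6),
                                                O = c(0, 2)))
  expect_equal(nrow(none), 0L)
})

test_that("chain length categories match the stated brackets", {
  expect_equal(chain_length_category(c(2, 6, 7, 12, 13, 21, 22, 30, 31, 1)),
               c("short", "short", "medium", "medium", "long", "long",
                 "very_long", "very_long", "out_of_range", "out_of_range"))
})

test_that("library building applies the multi-dataset support rule", {
  mk <- function(id, prec, ds, fl) {
    toy_spectrum(id, prec, c(60.0808, 85.0284, 144.1019, 101.0),
                 c(10, 100, 50, 20), dataset_id = ds, file_id = fl)
  }
  acetyl <- CARNITINE_MH + 42.0106
  rare <- CARNITINE_MH + 99.99
  sps <- list(mk("a1", acetyl, "D1", "f1"), mk("a2", acetyl, "D2", "f2"),
              mk("r1", rare, "D1", "f3"))
  asg <- cluster_spectra(sps)
  lib <- build_library(asg, sps, min_datasets = 2)
  expect_equal(nrow(lib), 1L)
  expect_equal(lib$delta_key, 42.01)
  expect_equal(lib$n_datasets, 2L)
  expect_setequal(lib$supporting_datasets[[1]], c("D1", "D2"))
  expect_equal(attr(lib, "dropped_keys"), "99.99")

  # annotation fills delta formula, CAR name and composition class
  ann <- setNames("C9H17NO4", lib$representative_id)
  lib2 <- annotate_library(lib, ann)
  expect_equal(lib2$delta_formula, "C2H2O")
  expect_equal(lib2$car_name, "CAR C2:0")
  expect_equal(lib2$composition_class, "CHO")
})

test_that("library round-trips through MGF + TSV export", {
  sps <- list(
    toy_spectrum("a1", CARNITINE_MH + 42.0106,
                 c(60.0808, 85.0284, 144.1019), c(10, 100, 50),
                 dataset_id = "D1", file_id = "f1"),
    toy_spectrum("a2", CARNITINE_MH + 42.0106,
                 c(60.0808, 85.0284, 144.1019), c(11, 99, 51),
                 dataset_id = "D2", file_id = "f2"))
  lib <- build_library(cluster_spectra(sps), sps)
  mgf <- withr::local_tempfile(fileext = ".mgf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, mgf, tsv)
  expect_length(read_mgf(mgf), 1L)
  tab <- read.delim(tsv)
  expect_equal(tab$delta_key, 42.01)
  expect_equal(tab$supporting_datasets, "D1;D2")
})
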
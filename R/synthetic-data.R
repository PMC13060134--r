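#' Default acyl delta-formula set for simulations
#'
#' Twenty CHO acyl modifications emulating the homologous series that
#' dominate real acylcarnitine collections: a saturated even/odd chain
#' series (C2-C10), monounsaturated members (C4-C12), hydroxylated members
#' (C4-C16), and two long-chain entries. All have distinct two-decimal
#' delta keys.
#'
#' @return Character vector of 20 delta formula strings.
#' @export
default_acyl_set <- function() {
  sat <- sprintf("C%dH%dO", 2:10, 2 * (2:10) - 2)          # Cn:0
  unsat <- sprintf("C%dH%dO", c(4, 6, 8, 10, 12), 2 * c(4, 6, 8, 10, 12) - 4)
  hydroxy <- sprintf("C%dH%dO2", c(4, 8, 12, 16), 2 * c(4, 8, 12, 16) - 2)
  c(sat, unsat, hydroxy, "C14H26O", "C18H32O2")
}

#' Simulation configuration for the synthetic repository
#'
#' Fixes the generative model for a toy multi-dataset spectra collection:
#' how many datasets exist, which acyl deltas are planted and in how many
#' datasets each appears, how many same-delta replicate spectra each
#' dataset contributes, the decoy load and its class composition, the
#' diagnostic-ion intensity ranges, and the m/z noise. A single seed fixes
#' all randomness end-to-end (R's default Mersenne-Twister RNG).
#'
#' @param n_datasets Number of simulated dataset accessions (default 6).
#' @param acyl_set Character vector of delta formulas to plant (default
#'   [default_acyl_set()]).
#' @param datasets_per_delta Integer range `c(min, max)`: each delta is
#'   planted in a uniformly drawn number of distinct datasets (default
#'   `c(2, 4)`).
#' @param spectra_per_occurrence Integer range: replicate spectra per
#'   (delta, dataset) occurrence (default `c(3, 5)`).
#' @param decoy_fraction Decoys as a fraction of the total collection
#'   (default 0.5).
#' @param chance_pass_rate Fraction of decoys constructed to pass the
#'   default query by chance — class (c) — so the planted FDR is known
#'   exactly (default 0.02). The remaining decoys split evenly between
#'   class (a), lacking at least one diagnostic ion, and class (b), all
#'   ions present but 85.0284 below the 50% threshold.
#' @param diagnostic_intensity_ranges Named list of `c(low, high)` percent
#'   ranges (relative to base peak 100) for the three diagnostic ions.
#' @param mz_noise_ppm Gaussian m/z jitter in ppm applied to every peak
#'   and precursor (default 5).
#' @param n_noise_peaks Low-intensity random peaks per spectrum
#'   (default 3).
#' @param intensity_jitter Multiplicative intensity jitter range applied
#'   to replicate spectra of the same planted delta (default
#'   `c(0.85, 1.15)`).
#' @param seed Integer seed (default 1).
#' @return Object of class `"SimConfig"`.
#' @export
sim_config <- function(n_datasets = 6L,
                       acyl_set = default_acyl_set(),
                       datasets_per_delta = c(2L, 4L),
                       spectra_per_occurrence = c(3L, 5L),
                       decoy_fraction = 0.5,
                       chance_pass_rate = 0.02,
                       diagnostic_intensity_ranges = list(
                         tma = c(8, 40),
                         butenoyl = c(60, 100),
                         dehydrated_core = c(15, 60)),
                       mz_noise_ppm = 5,
                       n_noise_peaks = 3L,
                       intensity_jitter = c(0.85, 1.15),
                       seed = 1L) {
  stopifnot(decoy_fraction >= 0, decoy_fraction < 1,
            chance_pass_rate >= 0, chance_pass_rate <= 1)
  structure(list(n_datasets = as.integer(n_datasets), acyl_set = acyl_set,
                 datasets_per_delta = datasets_per_delta,
                 spectra_per_occurrence = spectra_per_occurrence,
                 decoy_fraction = decoy_fraction,
                 chance_pass_rate = chance_pass_rate,
                 diagnostic_intensity_ranges = diagnostic_intensity_ranges,
                 mz_noise_ppm = mz_noise_ppm,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 intensity_jitter = intensity_jitter,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.jitter_mz <- function(mz, ppm) {
  if (ppm <= 0) return(mz)
  # truncated at 3 sigma: calibrated mass analyzers do not produce
  # unbounded errors, and the clamp keeps jittered diagnostic ions inside
  # the 20 ppm query window by construction
  z <- pmin(3, pmax(-3, stats::rnorm(length(mz))))
  mz * (1 + z * ppm * 1e-6)
}

# uniform draw from an inclusive integer range (avoids sample()'s scalar
# expansion when the range collapses to one value)
.sample_range <- function(range) {
  s <- seq.int(range[1], range[2])
  s[sample.int(length(s), 1L)]
}

# intensity pattern shared by all replicates of one planted delta
.draw_pattern <- function(config) {
  r <- config$diagnostic_intensity_ranges
  c(tma = stats::runif(1, r$tma[1], r$tma[2]),
    butenoyl = stats::runif(1, r$butenoyl[1], r$butenoyl[2]),
    dehydrated_core = stats::runif(1, r$dehydrated_core[1],
                                   r$dehydrated_core[2]),
    acylium = stats::runif(1, 20, 80))
}

#' Simulate one acylcarnitine MS/MS spectrum
#'
#' The precursor is the exact [M+H]+ of carnitine plus the delta formula,
#' with ppm noise; the peak list carries the three diagnostic ions at
#' intensities drawn from the configured ranges, an acylium-like fragment
#' at monoisotopic(delta) + proton (so analog pairs share shifted
#' fragments), and `n_noise_peaks` random low-intensity peaks. The base
#' peak is normalised to 100.
#'
#' @param delta_formula Delta formula string or named count vector; the
#'   empty formula gives free carnitine.
#' @param config A [sim_config()] (noise and intensity ranges).
#' @param spectrum_id,dataset_id,file_id,scan Provenance.
#' @param pattern Optional fixed diagnostic-intensity pattern (named as in
#'   the config ranges plus `acylium`); drawn fresh when `NULL`.
#' @return A [spectrum()].
#' @export
simulate_acylcarnitine_spectrum <- function(delta_formula,
                                            config = sim_config(),
                                            spectrum_id = "sim_1",
                                            dataset_id = "D1",
                                            file_id = "F1",
                                            scan = 1L,
                                            pattern = NULL) {
  if (is.character(delta_formula)) delta_formula <- parse_formula(delta_formula)
  if (any(delta_formula < 0)) stop("negative element counts in delta formula")
  delta_mass <- monoisotopic_mass(delta_formula)
  precursor <- CARNITINE_MH + delta_mass
  if (is.null(pattern)) pattern <- .draw_pattern(config)
  jit <- stats::runif(4, config$intensity_jitter[1], config$intensity_jitter[2])
  mzs <- unname(DIAGNOSTIC_IONS)
  ints <- unname(pattern[c("tma", "butenoyl", "dehydrated_core")]) * jit[1:3]
  if (delta_mass > 0) {
    mzs <- c(mzs, delta_mass + PROTON_MASS)
    ints <- c(ints, pattern[["acylium"]] * jit[4])
  }
  if (config$n_noise_peaks > 0) {
    mzs <- c(mzs, stats::runif(config$n_noise_peaks, 50,
                               max(precursor - 1, 60)))
    ints <- c(ints, stats::runif(config$n_noise_peaks, 1, 10))
  }
  mzs <- .jitter_mz(mzs, config$mz_noise_ppm)
  ints <- ints / max(ints) * 100
  spectrum(spectrum_id,
           precursor_mz = .jitter_mz(precursor, config$mz_noise_ppm),
           peaks = cbind(mzs, ints),
           dataset_id = dataset_id, file_id = file_id, scan = scan,
           acquisition = "DDA")
}

# decoy generators -----------------------------------------------------------

# class (a): lacks at least one diagnostic ion
.decoy_missing_ion <- function(config, id, dataset_id, file_id, scan) {
  precursor <- stats::runif(1, 150, 600)
  present <- sample(names(DIAGNOSTIC_IONS), sample(0:2, 1))
  mzs <- unname(DIAGNOSTIC_IONS[present])
  ints <- stats::runif(length(present), 20, 100)
  n_extra <- 4L
  mzs <- c(mzs, stats::runif(n_extra, 50, precursor))
  ints <- c(ints, stats::runif(n_extra, 5, 100))
  mzs <- .jitter_mz(mzs, config$mz_noise_ppm)
  spectrum(id, precursor, cbind(mzs, ints / max(ints) * 100),
           dataset_id = dataset_id, file_id = file_id, scan = scan,
           acquisition = "DDA")
}

# class (b): all three ions present but 85.0284 below the 50% threshold
.decoy_low_85 <- function(config, id, dataset_id, file_id, scan,
                          rel_85_range = c(8, 40)) {
  precursor <- stats::runif(1, 150, 600)
  mzs <- c(unname(DIAGNOSTIC_IONS), precursor - stats::runif(1, 10, 60))
  ints <- c(stats::runif(1, 5, 90),
            stats::runif(1, rel_85_range[1], rel_85_range[2]),
            stats::runif(1, 5, 90),
            100)  # non-diagnostic base peak pins the relative scale
  mzs <- .jitter_mz(mzs, config$mz_noise_ppm)
  spectrum(id, precursor, cbind(mzs, ints),
           dataset_id = dataset_id, file_id = file_id, scan = scan,
           acquisition = "DDA")
}

# class (c): satisfies the default query by construction ("chance pass")
.decoy_chance_pass <- function(config, id, dataset_id, file_id, scan) {
  precursor <- stats::runif(1, 150, 600)
  mzs <- c(unname(DIAGNOSTIC_IONS),
           stats::runif(2, 50, precursor))
  ints <- c(stats::runif(1, 10, 60), 100, stats::runif(1, 10, 60),
            stats::runif(2, 5, 40))
  mzs <- .jitter_mz(mzs, config$mz_noise_ppm)
  spectrum(id, precursor, cbind(mzs, ints),
           dataset_id = dataset_id, file_id = file_id, scan = scan,
           acquisition = "DDA")
}

#' Simulate a multi-dataset spectra repository with ground truth
#'
#' Plants each acyl delta in a drawn number of distinct datasets with
#' several replicate spectra per occurrence (sharing one intensity
#' pattern, so clustering can merge them), then adds decoys in three
#' classes: (a) lacking at least one diagnostic ion, (b) all ions present
#' but the 85.0284 ion below the 50% threshold, and (c) constructed
#' chance-passes of the query, at exactly the configured rate, so the
#' planted false discovery rate is known. Every spectrum is labeled in the
#' returned ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with `spectra` (list of [spectrum()]) and `truth`
#'   (data.frame `spectrum_id`, `is_carnitine`, `decoy_class`,
#'   `delta_formula`, `delta_mass`, `dataset_id`).
#' @export
simulate_repository <- function(config = sim_config()) {
  if (length(config$acyl_set) == 0L) stop("empty acyl set")
  set.seed(config$seed)
  spectra <- list()
  truth <- list()
  scan <- 0L
  add <- function(sp, is_car, decoy_class, dformula, dmass) {
    spectra[[length(spectra) + 1L]] <<- sp
    truth[[length(truth) + 1L]] <<- data.frame(
      spectrum_id = sp$spectrum_id, is_carnitine = is_car,
      decoy_class = decoy_class, delta_formula = dformula,
      delta_mass = dmass, dataset_id = sp$dataset_id,
      stringsAsFactors = FALSE)
  }
  for (f in config$acyl_set) {
    counts <- parse_formula(f)
    dmass <- monoisotopic_mass(counts)
    k <- min(.sample_range(config$datasets_per_delta), config$n_datasets)
    dsets <- sample(config$n_datasets, k)
    pattern <- .draw_pattern(config)
    for (d in dsets) {
      n_rep <- .sample_range(config$spectra_per_occurrence)
      for (r in seq_len(n_rep)) {
        scan <- scan + 1L
        sp <- simulate_acylcarnitine_spectrum(
          counts, config,
          spectrum_id = sprintf("car_%s_D%d_%d", f, d, r),
          dataset_id = sprintf("D%d", d),
          file_id = sprintf("D%d_F%d", d, r), scan = scan,
          pattern = pattern)
        add(sp, TRUE, NA_character_, f, dmass)
      }
    }
  }
  n_car <- length(spectra)
  n_decoy <- round(config$decoy_fraction / (1 - config$decoy_fraction) * n_car)
  n_chance <- round(config$chance_pass_rate * n_decoy)
  n_b <- floor((n_decoy - n_chance) / 2)
  n_a <- n_decoy - n_chance - n_b
  classes <- c(rep("a", n_a), rep("b", n_b), rep("c", n_chance))
  for (i in seq_along(classes)) {
    scan <- scan + 1L
    d <- sample(config$n_datasets, 1)
    id <- sprintf("decoy_%s_%d", classes[i], i)
    ds <- sprintf("D%d", d)
    fl <- sprintf("D%d_F%d", d, sample(5L, 1))
    sp <- switch(classes[i],
                 a = .decoy_missing_ion(config, id, ds, fl, scan),
                 b = .decoy_low_85(config, id, ds, fl, scan),
                 c = .decoy_chance_pass(config, id, ds, fl, scan))
    add(sp, FALSE, classes[i], NA_character_, NA_real_)
  }
  list(spectra = spectra, truth = do.call(rbind, truth))
}

#' Simulate a time-course feature table with planted synchronized groups
#'
#' Members of a planted group share one template curve over the timepoints
#' plus independent Gaussian noise; all other features follow independent
#' random curves. Abundances are non-negative. At `noise_sd = 0` the
#' within-group pairwise Pearson correlation is exactly 1.
#'
#' @param n_features Total number of features (>= sum of planted group
#'   sizes).
#' @param tissues Character vector of tissue labels.
#' @param timepoints Numeric vector of at least 3 timepoints.
#' @param planted_groups List of groups, each a list with `tissue`,
#'   `size`, and optionally `template` (numeric curve over the
#'   timepoints; drawn randomly when absent).
#' @param noise_sd Gaussian noise standard deviation on the relative scale
#'   (default 0.02).
#' @param n_replicates Replicate samples per (tissue, timepoint)
#'   (default 1).
#' @param seed Integer seed (default 1).
#' @return A list with `table` (a [feature_table()]) and `truth` (list of
#'   planted member-id vectors per group).
#' @export
simulate_timecourse <- function(n_features, tissues, timepoints,
                                planted_groups = list(), noise_sd = 0.02,
                                n_replicates = 1L, seed = 1L) {
  if (length(timepoints) < 3L)
    stop("at least 3 timepoints are required")
  set.seed(seed)
  tp <- sort(timepoints)
  n_tp <- length(tp)
  total_planted <- sum(vapply(planted_groups, function(g) g$size, numeric(1)))
  if (total_planted > n_features)
    stop("planted group sizes exceed n_features")
  samples <- do.call(rbind, lapply(tissues, function(ti)
    do.call(rbind, lapply(tp, function(t)
      data.frame(sample_id = sprintf("%s_t%g_r%d", ti, t,
                                     seq_len(n_replicates)),
                 tissue = ti, timepoint = t, group = "timecourse",
                 is_blank = FALSE, stringsAsFactors = FALSE)))))
  features <- data.frame(
    feature_id = sprintf("feat_%03d", seq_len(n_features)),
    mz = stats::runif(n_features, 150, 600),
    rt = stats::runif(n_features, 0.5, 7.5),
    annotation = NA_character_, stringsAsFactors = FALSE)
  ab <- matrix(NA_real_, n_features, nrow(samples),
               dimnames = list(features$feature_id, samples$sample_id))
  rand_curve <- function() {
    y <- abs(stats::rnorm(n_tp, mean = 5, sd = 2)) + 0.5
    y / max(y)
  }
  truth <- list()
  next_feat <- 1L
  for (g in planted_groups) {
    template <- if (!is.null(g$template)) {
      stopifnot(length(g$template) == n_tp)
      g$template / max(g$template)
    } else rand_curve()
    members <- features$feature_id[seq(next_feat, next_feat + g$size - 1L)]
    next_feat <- next_feat + g$size
    for (m in members) {
      for (k in seq_len(n_tp)) {
        cols <- samples$tissue == g$tissue & samples$timepoint == tp[k]
        ab[m, cols] <- pmax(0, template[k] +
                              stats::rnorm(sum(cols), sd = noise_sd)) * 1000
      }
    }
    truth[[length(truth) + 1L]] <- list(tissue = g$tissue, members = members)
  }
  # independent background features, present in every tissue
  background <- if (next_feat <= n_features)
    features$feature_id[seq(next_feat, n_features)] else character(0)
  for (m in background) {
    for (ti in tissues) {
      curve <- rand_curve()
      for (k in seq_len(n_tp)) {
        cols <- samples$tissue == ti & samples$timepoint == tp[k]
        ab[m, cols] <- pmax(0, curve[k] +
                              stats::rnorm(sum(cols), sd = noise_sd)) * 1000
      }
    }
  }
  list(table = feature_table(features, ab, samples), truth = truth)
}
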
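# Shared fixtures and independent brute-force oracles for the test suite.

# random centroided spectrum with peaks spread over a wide m/z range
random_spectrum <- function(id, n_peaks, precursor = runif(1, 150, 600),
                            mz_range = c(50, 500)) {
  spectrum(id, precursor,
           peaks = cbind(runif(n_peaks, mz_range[1], mz_range[2]),
                         runif(n_peaks, 1, 100)))
}

# all one-to-one matchings (as index-pair subsets) of a candidate pair list
enumerate_matchings <- function(cand) {
  if (nrow(cand) == 0L) return(list(integer(0)))
  res <- list()
  recurse <- function(k, chosen, used_a, used_b) {
    if (k > nrow(cand)) {
      res[[length(res) + 1L]] <<- chosen
      return(invisible())
    }
    recurse(k + 1L, chosen, used_a, used_b)  # skip pair k
    i <- cand$i[k]; j <- cand$j[k]
    if (!(i %in% used_a) && !(j %in% used_b))
      recurse(k + 1L, c(chosen, k), c(used_a, i), c(used_b, j))
  }
  recurse(1L, integer(0), integer(0), integer(0))
  res
}

candidate_pairs <- function(a, b, tol, shifts = 0) {
  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  out <- expand.grid(i = seq_along(mza), j = seq_along(mzb))
  ok <- vapply(seq_len(nrow(out)), function(k)
    any(abs(mza[out$i[k]] - (mzb[out$j[k]] + shifts)) <= tol), logical(1))
  out[ok, , drop = FALSE]
}

# exhaustive-optimum cosine-type score: maximise the weighted dot product
# over all one-to-one matchings, then normalise
brute_force_score <- function(a, b, tol = 0.02, power = 0.5,
                              shifts = 0, reverse = FALSE) {
  wa <- a$peaks[, "intensity"]^power
  wb <- b$peaks[, "intensity"]^power
  cand <- candidate_pairs(a, b, tol, shifts)
  best_num <- 0; best_match <- integer(0)
  for (m in enumerate_matchings(cand)) {
    num <- sum(wa[cand$i[m]] * wb[cand$j[m]])
    if (num > best_num) { best_num <- num; best_match <- m }
  }
  n_matched <- length(best_match)
  if (reverse) {
    if (n_matched == 0L) return(list(score = 0, n_matched = 0L))
    score <- best_num /
      (sqrt(sum(wa[cand$i[best_match]]^2)) * sqrt(sum(wb^2)))
  } else {
    score <- best_num / (sqrt(sum(wa^2)) * sqrt(sum(wb^2)))
  }
  list(score = min(1, score), n_matched = n_matched)
}

# independent predicate scan for the diagnostic query: plain loops, no
# shared code with evaluate_query
brute_force_query_pass <- function(sp, query) {
  if (nrow(sp$peaks) == 0L) return(FALSE)
  base <- max(sp$peaks[, "intensity"])
  for (k in seq_len(nrow(query))) {
    target <- query$target_mz[k]
    tol <- target * query$tolerance_ppm[k] / 1e6
    ok <- FALSE
    for (p in seq_len(nrow(sp$peaks))) {
      if (abs(sp$peaks[p, "mz"] - target) <= tol &&
          sp$peaks[p, "intensity"] / base * 100 >=
            query$min_intensity_percent[k]) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# simple deterministic toy spectrum builder
toy_spectrum <- function(id, precursor, mz, intensity, ...) {
  spectrum(id, precursor, cbind(mz, intensity), ...)
}

# standard decoy annotation map used by pipeline tests: labels half of the
# decoys with a non-carnitine compound name
decoy_annotations <- function(truth, fraction = 0.5, seed = 1000) {
  a <- character(0)
  dec <- truth$spectrum_id[!truth$is_carnitine]
  set.seed(seed)
  dec <- sample(dec, round(fraction * length(dec)))
  a[dec] <- "phosphatidylcholine 34:1"
  a
}
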
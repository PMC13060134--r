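---
title: "Mining acylcarnitine MS/MS spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining acylcarnitine MS/MS spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnlib)
```

## The problem

Acylcarnitines are esters (and in principle amides) of L-carnitine
(C7H15NO3) with fatty acids, amino-acid derivatives, microbial products
and xenobiotics. In positive-mode electrospray they ionize as intact
[M+H]+ cations — the quaternary ammonium gives them a permanent charge —
and they fragment to a small set of class-diagnostic product ions:

* m/z 60.0808 — the trimethylamine-derived cation C3H10N+,
* m/z 85.0284 — the butenoyl cation C4H5O2+,
* m/z 144.1019 — dehydrated protonated carnitine, C7H14NO2+.

Because these ions identify the carnitine *core* regardless of what is
attached to it, any MS/MS spectrum carrying all three is a candidate
acylcarnitine, and the **delta mass**

$$\Delta m \;=\; m/z_{\text{precursor}} \;-\; m/z_{[\mathrm{M+H}]^+}(\text{carnitine})
       \;=\; m/z_{\text{precursor}} - 162.1125$$

is the mass of the conjugated modification, independent of its structure.
`carnlib` implements the desk-scale version of a repository-mining
workflow built on this idea: filter spectra by a diagnostic-ion query,
collapse redundancy by clustering, clean the candidate set with molecular
networking, curate a delta-mass library, search it back against spectra
with cosine and reverse cosine, and compute the downstream statistics
(mass defect, rarefaction, presence matrices, time-course synchrony).

## The diagnostic query

A `diagnostic_query()` is an AND-list of conditions
(target m/z, ppm tolerance, minimum relative intensity). The default
carnitine query is

```
60.0808  within 20 ppm at >=  1 % of base peak
85.0284  within 20 ppm at >= 50 % of base peak
144.1019 within 20 ppm at >=  1 % of base peak
```

Three semantics choices are deliberate and worth knowing:

* the intensity reference is the spectrum **base peak** (its most intense
  peak), the usual INTENSITYPERCENT reading;
* the ppm window is symmetric and computed on the target m/z;
* when several peaks fall inside a window the most intense one is the
  condition's witness in the per-condition report.

The 85.0284 threshold is the sensitivity dial. 50 % is the stringent
library-building setting; acyl chains that fragment internally
redistribute intensity away from the core ions, so a relaxed 5 %
re-filter recovers most of those spectra, and 10 % is an appropriate
setting for QToF-type collections, where the ion tends to be weaker.
Whether the QToF relaxation should be keyed to instrument metadata or
chosen per dataset is left to the caller (`carnitine_query(threshold_85 =)`),
not auto-detected: acquisition metadata in repositories is too unreliable
to infer from, which is also why DIA exclusion (`filter_spectra()`)
trusts the acquisition label and never infers mode from peak density.

## Spectral similarity

All three scores share one matcher: candidate peak pairs agree within the
fragment tolerance (0.02 Da by default), assignment is greedy one-to-one
by descending product of weights, with weights
$w = I^{0.5}$ (square-root intensity, the molecular-networking
convention; the exponent is a parameter).

* `cosine_similarity()` — zero-shift matching, normalised by both full
  peak norms.
* `modified_cosine()` — candidates also arise at a shift equal to the
  precursor mass difference, linking analogs whose fragments carry the
  modification; same normalisation, so modified >= plain on any pair.
* `reverse_cosine()` — zero-shift matching, but normalised by the full
  *reference* norm and only the *matched subset* of query weights, so
  extra query peaks (fragments of an unknown conjugate) do not penalise
  the score. The matching is chosen exactly as in the plain cosine
  (maximise the weighted dot product) and the reverse normalisation is
  then applied; this convention is declared rather than inherited from
  any external implementation.

Greedy assignment can in principle be suboptimal; the test suite checks
it against exhaustive enumeration of all one-to-one matchings on random
small spectra (up to 6 peaks a side, 1,000 pairs), where it attains the
optimum throughout.

## Clustering and networking

`cluster_spectra()` reduces redundancy under the published contract:
precursor tolerance 20 ppm, fragment tolerance 0.02 Da, eps 0.1, at least
3 peaks per spectrum after removing fragments below m/z 50, and a
two-file support flag. The algorithm is a sorted precursor sweep with
union-find — single linkage within precursor buckets — not a
re-implementation of any hashed nearest-neighbour tool: the contract is
preserved, the internals are chosen to be exactly testable at desk scale.
Representatives are medoids (maximum summed cosine to the other members;
ties broken by total intensity, then lexicographic id).

One documented ambiguity: the clustering literature this contract mirrors
describes eps 0.1 as a "minimum cosine similarity score" while the
algorithm it names treats eps as a cosine *distance*. Both readings are
selectable (`eps_mode`); distance is the default. We do not guess the
original intent.

`build_network()` runs modified cosine over all representative pairs and
keeps edges passing score and matched-peak gates plus a mutual top-k
topology filter (defaults 0.7 / 6 / 10 — common classical-networking
settings, stated explicitly because the reference workflow's exact job
parameters are not printed; `mine_repository()` relaxes the matched-peak
gate to 4 because simulated spectra are sparse). The purge rule is
guilt-by-association: any connected component containing at least one
node annotated as something other than a carnitine is removed whole,
including its carnitine-annotated and unannotated members. The purge is
idempotent and logs its triggers.

## Curation

`build_library()` assigns each representative its delta mass and
canonicalises it by rounding **half-to-even to two decimals**; dataset
support is the union of accessions over cluster members, tallied on
canonical keys **across the whole retained set** (the alternative —
per-cluster tallies — would undercount split clusters), and keys
supported by fewer than two independent datasets are dropped. Electron
mass is kept in all ion arithmetic; it shifts the fourth decimal, which
matters against the printed diagnostic-ion masses.

CAR nomenclature (`assign_car_nomenclature()`): a CHO-only delta
CxHhOo maps to `CAR Cx:y;Oz` with chain length x, unsaturations
y = x − h/2 − 1 and extra oxygens z = o − 1. The arithmetic treats the
ester carbonyl as *not* a chain unsaturation, so acetyl (C2H2O) is
`CAR C2:0`; non-integer or negative y, fewer than two carbons, missing
oxygen, or any heteroatom yield no label — possible amide or unusual
chemistry is left unlabeled rather than mislabeled.

`decompose_delta()` is a bounded brute-force CHNO enumerator standing in
for external formula-prediction tools (which are out of scope): it
enumerates compositions within element bounds, filters on ppm agreement
of the implied precursor and on RDBE of the full precursor formula, and
sorts by absolute mass error. It is intended for small bounds only; the
defaults cover acyl-sized modifications.

## Repository statistics

`rarefaction_curve()` permutes dataset order (1,000 permutations by
default, or exhaustively for small N) and accumulates unique canonical
delta keys. The 95 % band is the 2.5/97.5 **percentile** interval across
permutations — the band's construction is not specified in the procedure
this mirrors, and percentiles are distribution-free. All delta identity
in the statistics layer uses the two-decimal canonical key.

## Downstream feature-table analysis

* `blank_and_rt_filter()`: keep a feature if its maximum sample abundance
  is at least 5x its maximum blank abundance (or it is absent from
  blanks) and its retention time is within [0.2, 8] min. The blank rule
  compares max against max; the source procedure's wording is ambiguous
  between per-sample and max-over-samples comparison, and max-vs-max is
  the implemented, flagged reading.
* `relative_abundance()`: per feature, divide by the within-tissue
  maximum.
* `log2fc_by_group()`: per-group medians against a control; the default
  pseudocount is half the smallest nonzero abundance (zero handling is
  otherwise unspecified).
* `synchronized_groups()`: replicates are collapsed to per-timepoint
  means first; pairs sharing >= 3 non-missing timepoints with Pearson
  r >= 0.95 form a graph whose connected components (size >= 2) are the
  synchronized groups. Components are the minimal-assumption reading of
  "synchronized groups"; no tighter clustering rule is implied by the
  procedure being mirrored.

## The synthetic repository

`simulate_repository()` generates the study conditions every stage is
tested under: by default 6 datasets, 20 planted CHO acyl deltas
(saturated C2–C10, monounsaturated C4–C12, hydroxylated C4–C16 and two
long-chain entries), each planted in 2–4 datasets with 3–5 replicate
spectra per occurrence (about 250 carnitine spectra), and an equal
number of decoys. Planted spectra carry the three diagnostic ions with
intensities drawn once per delta (replicates share the pattern up to
±15 % jitter), an acylium-like fragment at monoisotopic(delta) + proton
so analog pairs have shifted matches, three low-intensity noise peaks,
and 5 ppm Gaussian m/z jitter **truncated at 3 sigma** — calibrated mass
analyzers do not produce unbounded errors, and the truncation guarantees
the generator's contract that every planted spectrum with
above-threshold intensities satisfies the 20 ppm query.

Decoys come in three classes with known labels: (a) missing at least one
diagnostic ion, (b) all ions present but 85.0284 at 8–40 % of base so
they fail the 50 % query and pass at 5 % (the threshold-sensitivity
experiment), and (c) spectra constructed to pass the query, at a planted
2 % rate, so the query's false discovery rate against ground truth is
known exactly rather than emergent.

What the generator does **not** emulate: isotope envelopes, adducts
beyond [M+H]+, multiply charged species, chimeric DIA spectra, retention
time, and the long-tailed intensity and peak-count distributions of real
repository spectra. Passing tests therefore demonstrate correctness of
the pipeline's logic under controlled conditions, not performance on
real repository data.

Two measurement notes. First, recovery of planted deltas is scored by
matching library delta masses to planted values within the 20 ppm
precursor tolerance, not by exact canonical-key string: a planted delta
lying within ~2 mDa of a two-decimal rounding boundary (e.g. C10H18O,
Δm 154.1358) flips between adjacent keys under m/z noise, an artifact of
the canonicalisation itself rather than of the pipeline. Second, the
problem sizes — a ~500-spectrum repository, 6 datasets, 30-feature
time courses — are chosen so the whole suite exercises every stage in
well under a minute while keeping binomial bands on the planted 2 % FDR
meaningfully narrow.

## Known limitations

* The pipeline is all-pairs in clustering and networking
  (O(n²) similarity calls within precursor buckets); it is a desk-scale
  reference implementation, not an indexed repository-scale engine.
* `decompose_delta()` grows multiplicatively with the element bounds and
  is not suitable for heteroatom-rich searches.
* `read_mzml()` requires centroided data and rejects profile spectra.
* The purge rule inherits annotation quality: a wrong non-target label
  removes a whole component, which is the intended, conservative
  behaviour.
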
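---
title: "Key-event modeling of hepatotoxicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key-event modeling of hepatotoxicity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketox)
```

This vignette documents the model underlying `ketox`, the assumptions
it makes, the parameters that matter, and the design choices taken
where the methodology was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The model

### From curve fits to response surfaces

The input is a *curve-fit summary*: for each chemical × assay, one or
more parameter sets (top, slope, AC50) with a goodness-of-fit score
("curve error", lower is better) and a binary hit call. Within each
chemical × assay group the fit with the lowest curve error is kept.
No convention exists for ties, so one is fixed here: smaller AC50,
then input row order — chosen purely so the pipeline is reproducible
under permutation of input rows.

Each retained fit is evaluated as a monotone three-parameter Hill
curve with zero baseline,

$$ f(c) = \frac{\mathrm{top}}{1 + (\mathrm{AC}_{50}/c)^{\mathrm{slope}}}, $$

on a shared grid of concentrations log10-spaced from 1 pM to
100 mM (1e-6–1e5 µM, 11 decades, default 10 points per decade).
Gain–loss and biphasic fit types are not modeled. Chemicals with
absent or unparseable parameters get a flat (all-zero) curve rather
than an error: in HTS practice an absent fit means "no response", and
treating it as zero is the conservative choice that keeps false
positives down. Responses are normalized per assay by the assay-wide
maximum positive entry, so every surface lies in [0, 1], a
no-response row is exactly 0, and the most responsive cell is exactly
1. Negative raw responses (possible for loss-of-signal readouts) are
clipped to zero before normalization — the same conservative zeroing
philosophy; whether signed responses or magnitudes are more faithful
for "down" assays is unknowable from fit parameters alone, and
clipping is our documented choice.

Grid density: 10 points/decade resolves Hill transitions with slopes
up to ~8 to well under 1% quadrature error versus a 1000× finer grid;
the acceptance suite verifies 1e-6 agreement for the trapezoid on
the piecewise-linear interpolant.

### Assay selection

For each assay and each endpoint (hepatocellular, hepatobiliary), a
2×2 table of hit call × label is tested with Fisher's exact test
(two-sided, hypergeometric, conditional on margins). The
Benjamini–Hochberg step-up procedure is applied *within each endpoint
separately* at FDR 0.15, and the endpoint sets are united afterwards.
Two deliberate choices:

* **Direction filter.** "Associated" is taken to mean *positively*
  associated (odds ratio > 1). A two-sided test alone would also
  admit protective associations; for building toxicity-relevant KEs
  the positive direction is the meaningful one, so the filter is
  applied after BH selection.
* **Degenerate tables** (any zero margin — e.g., every chemical
  labeled toxic) carry no information: they are flagged, given p = 1
  and odds ratio 1, and can never be selected.

Chemicals lacking a given endpoint label are excluded from that
endpoint's tables only, not from the analysis.

### KE curves and scores

Assays sharing a biological target/mechanism (the KE assignment is an
*input*, mirroring expert curation) are composed into a KE curve per
chemical. The additive rule is implemented as the **arithmetic mean**
of member-assay normalized responses, with zeros substituted for
untested chemicals. Rationale: the methodology states that KE curves
themselves range 0 to 1, which a raw sum violates for any multi-assay
KE; the mean preserves the stated bound by construction. The
alternative reading (sum, then rescale the KE by its maximum curve
value) is available as `mode = "sum"` and also restores the bound.

The KE score is the **area under the KE curve against
log10-concentration**, normalized by the 11-decade width, so a
constant-1 curve scores exactly 1. Integration in the log domain
matches both the log-spaced grid and the way such curves are plotted
and reasoned about; a linear-domain integral would be dominated
entirely by the top decade. Scores are scaled within each KE by the
KE-wide maximum (all-zero KEs stay zero, without division errors), so
1 always marks the most active chemical in that KE.

Predictivity per KE is the ROC AUC of scaled scores against the
hepatotoxicity label, computed as the Mann–Whitney concordance
probability with half-credit for ties; it is undefined (an explicit
error) when only one class is present.

### Toxicokinetic overlay

Css — the 95th-percentile steady-state plasma concentration at
1 mg/kg/day, i.e. the slow-metabolizer, most-vulnerable-population
estimate — is consumed as data, never computed: physiologically based
toxicokinetic simulation is a separate discipline with dedicated
software. The "realized" activity of a chemical is the KE-curve area
restricted to concentrations ≤ Css (log domain, same 11-decade
normalization, linear interpolation to the exact cut). This
formalizes as an integral the shaded "in-vivo-reachable" region such
analyses usually present only graphically. A chemical whose realized fraction stays below 5% in every
KE where it is active is flagged toxicokinetically unrealizable;
chemicals with no activity at all are deliberately *not* flagged —
inert is not the same as TK-limited.

### Structure clustering

Fingerprints are 2048-bit Morgan (circular, radius 2,
ECFP4-equivalent) — the community default when a publication names
only "70% similarity" and "Butina". Parsing, canonicalization,
fingerprints and Lipinski descriptors are delegated to RDKit through
a bundled Python helper, because no R cheminformatics toolkit is
available in the supported environment; similarity, clustering and
enrichment logic are native R. "70% similarity" is read as Tanimoto
≥ 0.70 (inclusive). Butina clustering takes, at each round, the
unassigned molecule with the most unassigned neighbors as centroid
(ties: lexicographically smallest chemical id, which also makes the
output invariant to input order), assigns it and its unassigned
neighbors, and repeats; the suite checks equality against an
independent brute-force reference. A cluster is
hepatotoxicant-enriched when strictly more than 2/3 of its
liver-annotated members are hepatotoxicants; clusters with no
annotated member have an undefined fraction and are never enriched.
Cluster KE signatures are means of scaled scores with zeros included,
so inactivity shows as low values rather than missingness.

### Logistic models

Model 1 uses scaled KE scores; Model 2 adds log10(Css) — Css spans
roughly eight orders of magnitude, so the raw scale would swamp
standardization — and seven Lipinski-type descriptors (MW, logP,
H-bond donors/acceptors, rotatable bonds, rings, heavy atoms).
Class imbalance is handled by undersampling the majority class
**once, before validation** — a single balanced set trains both
models — not per fold. Validation is leave-one-out; the
held-out chemical's label is never visible to the fold that scores
it, which the suite proves by flipping a held-out label and observing
an unchanged probability. Threshold 0.5.

Whether the original analysis standardized features or regularized is
unstated. Here features are standardized internally and the
log-likelihood carries a weak L2 penalty (default 1e-4·n on
standardized coefficients, intercept unpenalized, configurable
including off). With ~p tens of features on ~100-scale n, plain
maximum likelihood diverges under separation; the weak ridge
guarantees a finite unique optimum while leaving well-conditioned
problems essentially untouched (the constant-feature and base-rate
identities in the test suite hold to 1e-6).

## The synthetic world

The generator emulates the *statistical* structure the pipeline
assumes, not chemistry: labels first (68% hepatotoxic; of those
80.75% hepatocellular, 60.5% hepatobiliary, 56.8% both — the
benchmark composition), then activity conditioned on labels.
Non-associated assays activate at a 5% baseline (HTS hit rates are
generally below 5%); truly associated assays (default 10% of the
panel, each tied to one or both endpoints) add +0.25 activation
probability for chemicals positive on the matching endpoint. Active
pairs get Hill parameters — top uniform in (0, 100], slope uniform in
[0.5, 4], AC50 log-uniform across the full 11 grid decades (the
stated sampling law; real HTS potencies concentrate in a narrower
band, which only makes recovery harder) — and three curve fits each,
the true parameters carrying the lowest curve error, mirroring the
three-fit structure of real summary files. Hit calls are coherent
with curves by construction: hit ⇔ non-flat best fit. Ten percent of
chemical × assay pairs are untested and emit no row, exercising the
zero-substitution path. log10(Css) ~ Normal(1, 1.5) — median 10 µM,
chosen once to span the sub-nM to tens-of-mM range that
toxicokinetic predictions actually print.

With `tk_modulation = TRUE`, a designated fraction (default 25%) of
provisionally toxic, active chemicals is assigned a Css 1–3 decades
*below* its activity onset (minimum AC50 among its active assays) and
relabeled nontoxic. This encodes the bioavailability contrast the
methodology illustrates with an antiestrogen pair — comparable KE
curves, opposite outcomes, explained by Css — and gives the Model 2
vs Model 1 comparison a designed signal: only the model that sees
bioavailability can classify the rescued chemicals correctly. With
modulation off, Css is pure noise and the models should tie (the
no-free-lunch criterion).

What a green test does **not** establish: the generator has no
structure–activity relationship (SMILES families are independent of
labels), no assay noise correlated across chemicals, no biphasic
curves, and no missing-label patterns correlated with testing status.
Green means the algorithms are correct and the designed signals are
recoverable, not that the pipeline's effect sizes transfer to real
screening data.

SMILES come from a built-in valid library (11 scaffold families ×
enumerated linker/terminal tails, 528 structures), so clustering has
real family structure to find and every structure parses.

## Numerical choices and degenerate inputs

* Hill evaluation is done in log space to avoid overflow at extreme
  slope × decade products.
* Trapezoid quadrature everywhere; the restricted (Css-cut) integral
  interpolates linearly to the exact cut point and is continuous at
  the grid boundary within 1e-9.
* All-zero assays, KEs, and label sets are handled as documented
  degenerate cases (zeros, p = 1, explicit errors) rather than NaNs.
* Fisher's two-sided p sums hypergeometric densities ≤ observed
  × (1 + 1e-7), the standard slack against floating-point equality.
* Undersampling and generation snapshot and restore the caller's RNG
  state; all randomness flows from explicit seeds, and the pipeline
  derives per-stage seeds by hashing the stage name with the master
  seed.

## Known limitations

* Only monotone zero-baseline Hill curves; real pipelines also fit
  gain–loss shapes.
* KE aggregation is unweighted; assays within a KE are treated as
  exchangeable evidence.
* The ridge penalty, while weak, does bias coefficients; set
  `lambda = 0` to reproduce unpenalized fits on well-separated data.
* The structure backend requires an external RDKit; without it the
  chem module errors with a clear message while the rest of the
  pipeline (minus clustering and Model 2 descriptors) still runs.
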
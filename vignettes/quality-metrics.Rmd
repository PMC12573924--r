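---
title: "Auditing crystallographic quality metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing crystallographic quality metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifaudit)
```

## The problem

A single-crystal structure determination ends with a handful of scalar
diagnostics: the agreement residuals R and wR between observed and
calculated structure-factor amplitudes, the goodness of fit *S* (ideal
value 1), the largest final least-squares parameter shift over its standard
uncertainty (Δ/σ)max (near zero at convergence), the extreme residual
electron densities Δρmax and Δρmin left unmodelled by the refinement, and
the maximum Bragg angle θmax which, with the wavelength λ, fixes the
real-space resolution d = λ/(2 sin θmax). When these are mined across an
archive of deposited CIFs, three practical problems dominate: values are
*missing*, values are *non-numeric* (bounded texts such as `<0.01`, or free
text), and a small tail of values is *physically impossible* (an R factor
above 1, a positive Δρmin, θmax beyond 90°). `cifaudit` implements the
audit pipeline — extraction, curation, classification, derived metrics,
alerts, cohort statistics — together with a synthetic corpus generator that
stands in for the licensed archive no package can redistribute.

## Curation model

Every raw value is first classified into exactly one of four states:
*numeric* (with an optional standard uncertainty parsed from the
parenthesized suffix, applied to the last digits: `0.71073(10)` means su
0.00010), *bounded* (leading `<` or `>`), *missing* (`?`, `.`, or tag
absent) or *malformed* (anything else, including trailing junk — values are
excluded rather than repaired). Numeric values are then filtered by open
validity intervals; the defaults are the ranges in
`default_validity_rules()`:

```{r}
default_validity_rules()
```

Two deliberate strictness choices: the intervals are open *including at
zero* (an exactly-zero R factor or shift is rejected as out-of-range;
boundary hits are vanishingly rare in practice and a deterministic rule
beats a special case), and bounded values are rejected as unreadable rather
than interpreted as censored observations. Per tag the accounting identity
`numeric + missing + non_numeric = total` holds, with completeness defined
as `numeric / total` and `accepted = numeric − out_of_range`.

## Category axes

Six axes are assigned per entry, each with provenance
(`derived_from_cif`, `sidecar`, or `default`):

* **chemistry** — organic iff the atom-site element set avoids the
  exclusion set (transition metals of groups 3–12 including Zn/Cd/Hg,
  lanthanides, actinides, and Al, Ga, In, Tl, Ge, Sn, Pb, Sb, Bi, Po).
  Group 12 is included because the database convention this mirrors treats
  Zn/Cd/Hg as metals; the set ships as a reviewable table
  (`organic_exclusion_elements()`).
* **disordered** — any non-hydrogen site with occupancy < 1 − ε
  (ε = 10⁻⁶, to separate genuine partial occupancy from formatting noise),
  a populated disorder group, or a SQUEEZE/MASK keyword in
  `_refine_special_details`.
* **radiation** — `_diffrn_radiation_probe` when present, else a wavelength
  cutoff of 0.1 Å for electron diffraction (relativistic electron
  wavelengths at 100–300 kV are 0.037–0.020 Å, an order of magnitude below
  any X-ray line in use; neutron sources cannot be separated from X-rays by
  wavelength, so they require the probe item), else X-ray by default.
* **pressure** — non-ambient iff `_diffrn_ambient_pressure` > 200 kPa.
  The archive convention gives no cutoff; twice atmospheric cleanly
  separates deliberate pressurization from ambient reporting noise and is
  configurable.
* **refinement_type** — sidecar label when supplied, else a keyword
  heuristic over special details (`multipole`, `hirshfeld atom`,
  `invariom`, `aspherical`). Best-effort, provenance-flagged.
* **polymeric** — cannot be derived without connectivity perception, which
  is out of scope; sidecar or default `FALSE`. Honest provenance beats a
  wrong heuristic.

## Alerts

Thresholds are strict in the "above"/"below" sense: a value exactly at a
boundary does not trigger. R and wR carry only a C level (above 0.1 and
0.25; no A/B boundaries exist for them, and none are invented). The
goodness of fit escalates through nested two-sided bands — C outside
(0.8, 2.0), B outside (0.6, 4.0), A outside (0.4, 6.0). The residual
density test uses DTEST = 0.1·Zmax with A above 2·DTEST and B/C above 10%
and 7.5% of Zmax, evaluated on max(Δρmax, |Δρmin|) — the two extremes
behave symmetrically in surveyed data, so one combined level per entry is
reported (per-side levels are available via `residual_density_alert()`
directly). The resolution test fires C below sin θ/λ = 0.6 Å⁻¹. Note the
common prose equivalence "0.6 Å⁻¹ ≈ 0.84 Å" does not invert exactly
(1/(2·0.6) = 0.8333 Å); the alert is keyed on the 0.6 Å⁻¹ form.

Two settings are configuration, not published fact, and are flagged as
such in `alert_thresholds()$non_paper_defaults`: the (Δ/σ)max C threshold
(default 0.2; surveys only state that 0.008 lies *below* the boundary) and
the alert level of the resolution test (C here). An optional
`"strict-goof"` profile moves the *S* bands inward one level — the
recalibration that survey data suggest but that no validation service has
adopted; it is never the default.

## The synthetic stated world

The generator emulates the statistical structure an archive-scale survey
reports, so that every pipeline stage is testable without redistributable
data. Its defaults *are* the stated world and are not tuned against test
outcomes:

* **R** ~ lognormal, meanlog = ln 0.046, sdlog² = 2 ln(0.054/0.046) (the
  closed-form consequence of anchoring both the median 0.046 and mean
  0.054), truncated to (0, 0.995).
* **wR = R × F**, F lognormal with median 0.118/0.046, sdlog 0.30,
  truncated per entry to (1 + 1.5·10⁻⁴/R, 0.999/R). The lower bound makes
  wR > R survive fixed-precision printing; the upper keeps wR inside
  (0, 1). Both truncations move the population median by < 0.1%.
* ***S*** = 0.8 + lognormal with median 1.045 and 90th percentile 1.143
  (sdlog from the p90/median ratio). The 0.8 offset places the support
  just below the observed 10th percentile (0.969) while keeping the
  closed-form median exact.
* **(Δ/σ)max** — with probability 0.3 a "converged" value uniform on
  (10⁻⁶, 10⁻⁴) (prints as 0.000), else exponential with rate solved so the
  overall median is exactly 0.001. The implied p90 (≈ 0.006) is slightly
  below the reported 0.008; the median is the calibration target.
* **Δρmax** ~ lognormal with Zmax-dependent median scale(Z) ∝ (Z/8)^0.7
  and sdlog 0.75; the base scale is solved numerically (`uniroot` on the
  mixture CDF over the element palette) so the *population mixture median*
  is exactly 0.596. **Δρmin = −Δρmax · B** with B ~ Beta(8, b); b is
  calibrated by numerical integration of the product-distribution CDF so
  the population median of |Δρmin| is exactly 0.481 (product medians do not
  compose in closed form for beta factors).
* **θmax/λ** — X-ray entries split 62/38 between Mo (λ 0.71073 Å, θmax
  truncated normal around 26°) and Cu (1.54184 Å, around 68°), reproducing
  the bimodal θmax / unimodal d ≈ 0.7–0.85 Å picture; neutron (1.30 Å,
  ~45°) and electron (0.0251 Å, ~0.8°) entries are rare.
* **Category mixture** — organic 0.450, disordered 0.312 (15% of which are
  flagged via SQUEEZE text instead of partial occupancy), polymeric 0.130,
  aspherical 0.0017, high-pressure 0.0043, neutron 6.8·10⁻⁴, electron
  3.8·10⁻⁴: the cohort fractions the emulated survey reports. Tests that
  need many rare-category entries build a custom spec rather than bending
  these defaults.
* **Contamination** — injections are quota-exact (counts, not Bernoulli
  rates) at seeded disjoint positions: per-item missing+malformed rates
  reproduce the reported completeness (95.7% for R, 94.4% for wR and *S*,
  94.2% for the shift — whose non-numeric share is dominated by `<`-bounded
  texts — 97.3% for the densities and θmax), and out-of-range counts scale
  the reported non-permitted tallies (279 R, 19 wR, 1781 shift, 508/566
  densities, 27 *S*, 66 θmax per ~1.09M files) to corpus size.

What the generator does **not** emulate: chemically meaningful geometry,
symmetry, reflection data, correlations beyond the (wR, R) and (Δρmax,
Zmax) couplings, era/instrument drift, and real archives' long tails of
creative formatting. A green test therefore establishes that the pipeline
is correct *on the stated world* — exact quota accounting, zero-error label
recovery, calibrated medians — not that archive-scale numbers are
reproduced.

## Numerical choices

* Quantiles: linear interpolation between closest order statistics
  (type 7), recorded in output metadata; variance uses n−1. Percentile
  ranks use mid-rank tie treatment. Whether the emulated survey used
  interpolated or nearest-rank quantiles is unstated; the convention is
  recorded, not asserted to match.
* Angles are degrees at every interface and radians internally.
* All truncated sampling is inverse-CDF (exact truncation, fully
  deterministic under `set.seed(seed, "Mersenne-Twister", "Inversion",
  "Rejection")`); regeneration is byte-identical.
* Degenerate-draw guards: shift and density magnitudes are floored at
  10⁻⁶ / 10⁻³ so no valid-population value prints as exactly 0 at the
  fixed CIF precision (which would parse as 0 and corrupt the exact
  out-of-range quotas). The probability mass involved is < 3·10⁻⁴.
* Threshold recovery tests locate boundaries by bisection to 10⁻⁹; the
  1% tolerance on the n = 20000 corpus medians is approximately two
  standard errors of the sample median for R — tight by construction, and
  verified for the fixed default seed.
* Multi-block files: every `data_` block is a separate logical entry
  (depositions are one structure per block); duplicate tags keep the first
  occurrence with a warning; multi-value wavelength loops (Kα₁/Kα₂) use the
  first-listed value.

## Known limitations

* The CIF reader targets the CIF 1.1 subset found in deposition archives;
  CIF 2.0 syntax (triple-quoted strings, lists) is out of scope.
* Statistical significance testing between categories is deliberately
  absent: the metric distributions are skewed and the category sizes differ
  by orders of magnitude, so only descriptive comparison is produced.
* Parameter/restraint/constraint counts are extracted but not analysed.
* The full validation-service test battery (~570 checks), level-G alerts,
  space-group-aware residual-density exceptions, and chemical-geometry
  validation are out of scope.
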
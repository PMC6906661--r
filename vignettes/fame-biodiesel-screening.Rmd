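---
title: "From FAME composition to biodiesel properties: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FAME composition to biodiesel properties: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famescreen)
```

## The problem

Screening candidate lipid feedstocks for biodiesel usually starts long
before any engine test: a GC-MS analysis of the transesterified lipids
yields a fatty acid methyl ester (FAME) composition table, and a small
set of empirical correlations turns that table into predicted fuel
properties that can be compared against the ASTM D6751 (US) and EN 14214
(European) biodiesel standards. `famescreen` implements that desk
pipeline end to end for composition tables expressed as *mass percent of
total lipid*, together with the culture-level screening arithmetic
(biomass × lipid fraction) used to rank isolates.

The package ships a complete worked dataset: the FAME profiles and
culture metrics of four freshwater microalgae isolates (two
*Micractinium conductrix*, one *Choricystis parasitica*, one
*Monoraphidium* sp.) whose published property table the pipeline
reproduces cell for cell. That reproduction doubles as the package's
strongest regression test.

## The model

Every quantity downstream hangs off the **average degree of
unsaturation**,

$$\mathrm{ADU} = \sum_i M_i \, Y_i,$$

where $M_i$ is the number of carbon–carbon double bonds of fatty acid
$i$ and $Y_i$ its mass fraction of total lipid. Five fuel properties are
then linear in ADU:

| property | correlation | units |
|---|---|---|
| kinematic viscosity (40 °C) | $\mathrm{Vis} = -0.6316\,\mathrm{ADU} + 5.2065$ | mm² s⁻¹ |
| specific gravity | $\mathrm{SG} = 0.0055\,\mathrm{ADU} + 0.8726$ | kg L⁻¹ |
| cetane number | $\mathrm{CN} = -6.6684\,\mathrm{ADU} + 62.876$ | — |
| iodine value | $\mathrm{IV} = 74.373\,\mathrm{ADU} + 12.71$ | g I₂/100 g |
| higher heating value | $\mathrm{HHV} = 1.7601\,\mathrm{ADU} + 38.534$ | MJ kg⁻¹ |

Two modelling commitments deserve emphasis because both are easy to get
silently wrong:

**$M$ is derived from the name, never hand-entered.** The double-bond
count enters through the parsed lipid shorthand (`C18:3n-3` → $M = 3$),
so a typo in a composition table surfaces as a parse error, not as a
wrong ADU. The parser accepts the dialect variants found in composition
tables (optional leading `C`, explicit `:0` for saturated acids, omega
written `n-3`, `(n-3)`, `ω3` or `w3`, stray whitespace) and always emits
one canonical form. Structurally impossible identities — more double
bonds than a chain can hold, an omega class on a saturated acid — are
rejected rather than guessed, and branched/hydroxy/trans species are out
of scope. Positional locants ("5,11,14,17-") live only in the systematic
ester names; the model needs only the count.

**$Y_i$ is the fraction of total lipid, not of the FAME fraction.**
Composition tables of this kind report percentages whose column total
(the "total rendemen", here 60–90%) is the FAME recovery from total
lipid. Renormalising to the FAME total may look like hygiene but changes
every ADU — for the packaged isolate G4-9 it would give ≈2.00 instead of
the published 1.67 — so profiles are never renormalised.

## Rounding: reproducing printed tables

Published property tables are computed from *printed* (rounded) ADU
values. The package makes that explicit as a rounding policy:

* `policy = "paper"`: ADU is rounded half-up to 2 decimals, each
  correlation is applied to the **rounded** ADU, and each property is
  rounded half-up to its printed precision (Vis 2, SG 3, CN 1, IV 2,
  HHV 1 decimals). This two-stage rounding is what reproduces the
  packaged isolates' table exactly: G4-9 has full-precision ADU 1.6671,
  and only $74.373 \times 1.67 + 12.71 = 136.91$ matches the printed
  iodine value; the unrounded ADU gives 136.70.
* `policy = "none"` (default): full precision throughout — the right
  choice whenever the numbers feed further computation.

Ties round half *up* (away from zero), which is the convention that
reproduces every one of the 24 table cells; base R's round-half-to-even
does not. A guard of 10⁻⁹ absorbs binary representation error at the
rounding boundary. The rule itself is an inference from the reproduced
table — the source never states one — which is why it is confined to an
explicit, named policy.

```{r}
profiles <- microalgae_profiles()
suppressWarnings(fuel_properties_table(profiles, policy = "paper"))
```

## Standards compliance

The default criterion set mirrors the limits the packaged study was
judged against: Vis 1.9–6.0 mm² s⁻¹, SG 0.85–0.90 kg L⁻¹ and CN ≥ 47
(ASTM D6751), IV ≤ 120 g I₂/100 g (EN 14214), plus working ranges
ADU 0.6–1.6 and HHV 38–41 MJ kg⁻¹ that neither standard defines and
which therefore carry the source tag `paper_stated`. Bounds are
inclusive, and when properties were produced under `policy = "paper"`
the comparison uses those rounded values — that is how such studies
judge compliance, and it keeps verdicts like "HHV 41.4 exceeds 41"
deterministic instead of hinging on float noise.

With these criteria, P2-15 passes all six checks; G4-3, G4-9 and P5-4
each violate ADU, IV and HHV. The source text describes G4-3/G4-9 as
weak *only* in iodine value, which its own printed numbers contradict
(HHV 41.4/41.5 > 41; G4-3's ADU 1.63 > 1.6); the package reports what
the numbers imply and leaves the prose inconsistency to documentation.
A criterion naming a property the input does not carry is a hard
configuration error, never a silent skip.

The ADU range 0.6–1.6 also serves as the correlations' calibration
range: an ADU outside it still returns values but raises a
`famescreen_extrapolation` warning, since linear correlations degrade
away from the compositions they were fitted on.

## Culture screening

Feedstock ranking needs the culture dimension as well:
`lipid_volumetric_yield()` computes dry biomass × lipid fraction
(g L⁻¹, 3 decimals), and `screening_summary()` joins metrics, FAME
recovery, ADU and the compliance verdict into one table that
`rank_isolates()` orders deterministically (descending key, ties broken
by sample id, missing values last with a notice — G4-9's biomass was
published only as a figure, so the fixture stores it as missing rather
than a digitised guess). Reported ± standard deviations are stored as
metadata and never enter computations. The source reports P5-4's lipid
yield as "4.52 g L⁻¹", which cannot be reconciled with its printed
biomass (1.30 g L⁻¹) and lipid content (66.72%); the package computes
0.867 g L⁻¹ and treats the printed figure as a typo.

## Synthetic profiles

`generate_profiles()` emulates the *statistical shape* of real GC-MS
FAME tables so every pipeline stage is testable without downloads:
sparse panels (default 13 of the 21 catalog acids, matching the 8–18
observed per isolate), positive weights from a normalised-gamma
(symmetric Dirichlet) composition whose `concentration` parameter tunes
evenness (default 1, giving the few-dominant-acids look of real
profiles), and totals drawn uniformly from a recovery range (default
60–90%, the span of the packaged isolates). Each profile records its
ground-truth ADU from the unrounded weights at generation time, which
gives an exact oracle for the pipeline: over seeded batches the two
agree to better than 10⁻⁹, and after serialising at two decimals the
discrepancy stays below the worst-case rounding bound.

What the generator does *not* emulate: measurement error, chromatographic
co-elution, correlations between acids, or any biology linking culture
conditions to composition. Passing tests on synthetic data therefore
demonstrate arithmetic and plumbing correctness, not robustness to real
instrument noise.

A seed is mandatory (`synthetic_spec(..., seed = )`), batches are
byte-identical under the same spec, and the caller's RNG stream is left
untouched. `make_profile_with_target_adu()` complements the random
generator with a closed-form two-component profile hitting any feasible
ADU exactly — handy for probing the correlations at chosen points:

```{r}
twin <- make_profile_with_target_adu(2.08, "C20:4n-3", recovery = 86.04)
suppressWarnings(compute_fuel_properties(twin, policy = "paper"))
```

## Numerical and design choices

* **Sum tolerance.** A profile's component sum may exceed 100 by at most
  0.5 percentage points (configurable): printed tables carry rounding
  error, but anything beyond that indicates a broken table.
* **Zeros vs blanks.** An empty cell or `-` means "not detected" and
  produces no component; an explicit 0 is dropped with a logged notice,
  so the two cases remain distinguishable in logs.
* **Validation as data.** `validate_profile()` returns findings as a
  tibble and never throws; the constructor escalates findings to errors
  unless asked not to. Both are pure.
* **Replaceable coefficient and criterion sets.** Correlations and
  standard limits live in plain TSV files and are ordinary function
  arguments, since both are published, citable sets that users may swap.
* **Degenerate inputs.** An empty profile has ADU 0 and returns the
  rounded correlation intercepts; a fully saturated profile likewise has
  ADU 0. Both are exercised in tests.
* **Problem sizes.** The test suite runs the full fixture pipeline, 200
  synthetic profiles for the oracle check, and a 30-profile round-trip
  bound — sizes chosen to exercise the statistics while keeping the
  suite comfortably interactive.

## Limitations

Property prediction is linear in ADU only; per-acid blending rules,
cold-filter plugging point, and oxidative stability are out of scope, as
are the wet-lab stages upstream of the composition table (peak
integration, raw GC-MS formats) and growth-curve modelling. The
correlations are published fits with their own calibration domain —
outside ADU 0.6–1.6 they are extrapolations and flagged as such.
Compliance covers the six tabulated parameters, not the full ASTM/EN
test suites (flash point, sulfur, glycerin, ...).
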
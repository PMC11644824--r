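---
title: "Methods: triterpenoid spectral-library construction, matching and DDA simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triterpenoid spectral-library construction, matching and DDA simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triterpenlib)
```

This vignette is the package's account of its science: the models and
conventions behind each module, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the design decisions taken where more than one
reasonable choice existed.

## Mass arithmetic

All masses are monoisotopic and summed from a packaged CODATA/NIST table
(`element_masses()`); carbon is exactly 12 by definition. Two positive-mode
adducts are supported, matching a positive-ionisation electrospray screen
of neutral triterpenoids:

* `[M+H]+` adds one **proton** (1.00727646 Da) — not a hydrogen atom;
* `[M+Na]+` adds sodium **minus one electron** (22.98922070 Da).

These conventions reproduce the catalogued reference values to the four
printed decimals; using atom masses instead would be ~0.5 mDa off, well
outside the 0.0002 Da agreement the test suite demands. The formula
parser accepts both plain (`C30H46O4`) and underscore-subscript
(`C_30_H_46_O_4_`) dialects because typeset compound tables commonly use
the latter; serialization is Hill-ordered so a parse–serialize round trip
is the identity.

ppm errors use the `(calc − meas)/calc × 1e6` convention, so a measured
value above the calculated one is negative. Catalogue tables print the
calculated m/z at 4 decimals and the error at 1 decimal; the package
reproduces tabulated errors by computing them from the *displayed*
(4-decimal) calculated value, which is the only convention under which
the printed errors are self-consistent. A minority of catalogued error
values cannot be reproduced from their printed calc/meas pairs at any
rounding convention (they were evidently computed from unprinted extra
decimals); these rows are excluded from numeric assertions rather than
"corrected". Display rounding is half-away-from-zero.

## The library model

A `library_record` holds compound metadata (name, formula, Log p,
retention time), a curated skeleton class, adduct entries and
CE-resolved MS2 spectra. Three choices deserve comment:

* **Skeleton class is input, not inference.** Classifying a triterpenoid
  skeleton requires the structure, which the library does not carry; the
  class column is curated metadata. The packaged catalogue census is
  18 oleanane / 13 ursane / 6 lupane / 1 friedelane / 4 limonoid /
  1 other across its 43 records; the source collection is described as
  44 standards (with 14 ursanes), so one row is missing from the printed
  catalogue — the fixture keeps the 43 printed rows and this note rather
  than inventing a 44th.
* **Adduct augmentation.** Screening routinely detects sodium adducts of
  standards whose catalogue row lists only `[M+H]+`. `build_library()`
  therefore adds *calculated* entries for both standard adducts to every
  record, marked `observed = FALSE` where no measured value exists; the
  matcher can then assign a sodiated feature to a record catalogued as
  protonated. Identity counting is unaffected because adduct variants
  resolve to the same record.
* **Cross-checks, not corrections.** The calculated m/z is recomputed
  from the formula for every row; a disagreement beyond 0.0005 Da is a
  warning plus a `calc_inconsistent` flag, and the printed value is kept.
  One catalogue row (Oleanoic acid `[M+H]+`) is internally inconsistent —
  its printed calculated value corresponds to C30H48O3 while the printed
  formula is C30H46O3 — and stays flagged.

The archive format is versioned JSON written at 17 significant digits,
which round-trips IEEE doubles exactly; the suite asserts bit-level
round-trip identity on randomly generated libraries. MSP (NIST text
dialect) and MGF are supported for interchange; both tolerate missing
optional fields on import but refuse truncated entries or peak counts
that contradict `Num Peaks`, because silent partial loads corrupt
libraries irrecoverably.

The packaged spectra fixture is **synthetic**: measured reference spectra
live in a proprietary vendor database and are not deposited, so the MSP
shipped here combines reported fragment m/z values with in-silico
neutral-loss ions, and its intensities are arbitrary. Two reported
fragments with strongly negative mass defects (m/z 220.93, 288.92)
cannot be triterpenoid fragments and are treated as background ions
present in the original vendor entries: they are stored verbatim (the
matcher must reproduce the reported screen) but excluded from annotation
assertions.

## Consensus spectra

The fixed-CE series (10/20/30/40 eV) of one compound is merged by
single-linkage clustering of pooled peaks at the fragment tolerance;
each cluster is represented by its intensity-weighted mean m/z and its
**maximum** intensity across energies. Max-merging (rather than
averaging) preserves diagnostic ions that dominate only at one energy —
fragment prevalence shifts strongly across a 10–40 eV series. Merging is
iterated to a fixed point, making the operation idempotent; for points
sorted on m/z one pass already equals the all-pairs transitive closure,
which the suite verifies against a union-find oracle. CE-ramp spectra
(25–62.5 eV) carry a ramp descriptor instead of a scalar and are treated
identically in matching, since one library serves both acquisition modes.

## Fragment annotation

`loss_series()` enumerates all multisets of up to `max_depth` neutral
losses (defaults: H2O 18.010565, CO 27.994915, HCOOH 46.005480, C5H8O2
100.052430 — always computed from formulas, never hard-coded),
deduplicated by total loss mass with ties resolved toward the
fewer-loss explanation (parsimony; the underlying chemistry is agnostic:
H2O + CO is exactly isobaric with HCOOH). Theoretical fragments below
the 50 Da scan floor are dropped silently because the instrument could
not have recorded them.

`annotate_spectrum()` matches each peak greedily to the nearest
theoretical ion. Its default tolerance (0.01 Da) is deliberately wider
than the 0.005 Da identification tolerance: reported fragment values of
measured spectra deviate from exact subtraction by up to ~0.011 Da, and
annotation is an explanatory layer, not an identification filter. Class
diagnostics catalogued only at nominal (integer) precision — m/z 191,
203, 205 — are matched at ±0.5 Da, i.e. at their own precision; the
exact-mass oleanane diagnostics (249.1856, 203.1807, 191.1803) use the
configured tolerance. The electron-mass convention behind those printed
RDA values is ambiguous at the ~0.0005 Da level, so they are matched at
tolerance rather than re-derived. Lupane diagnostics are flagged
non-RDA (the saturated ring system cannot undergo the retro-Diels–Alder
cleavage); friedelane and limonoid classes have no catalogued
diagnostics and return an empty table with a documented-gap attribute
rather than pretending coverage.

## Matching and identification levels

Candidates are generated by a binary range query on the sorted adduct
index and are provably identical to a brute-force scan (property-tested
on random queries). Scoring and levels:

* level 1 = precursor (0.005 Da) + RT (0.5 min window) + ≥ 1 matched
  fragment; level 2 = precursor + fragments; level 3 = precursor only;
* `score` = fraction of the record's consensus peaks explained by the
  query fragments, in [0, 1];
* ranking by level, then score, then |ppm error|, with the record name
  as a deterministic tie-break.

Defaults embody three judgement calls. The RT window of 0.5 min covers
the largest drift observed on the reference system (0.41 min) with
margin — the original window is unstated. The fragment tolerance reuses
the stated 0.005 Da mass window, the conservative reading of a method
that states one tolerance. `min_fragments = 1` because the reference
screen accepts single-fragment matches (one reported identification
rests on exactly one fragment); stricter defaults would contradict the
reported outcome. Reported drifts are unsigned and rounded to 2
decimals; signed drifts are kept internally.

Isobaric standards are common (four catalogue compounds share
C30H46O4), so a level-1 feature can tie between standards with close
retention times; the ranking resolves the tie deterministically, and
identity-level benchmarks in the suite accept any tied-at-top
co-isobar as correct.

## The DDA simulator

The generator emulates the acquisition conditions of the reference
method; its defaults are those conditions, not tuning knobs:

| parameter | default | origin |
|---|---|---|
| MS1 rate | 5 Hz | stated scan speed |
| MS2 rate | 12 Hz | stated spectra rate |
| intensity threshold | 1000 counts | stated trigger threshold |
| active exclusions | 3 | stated optimum |
| scan range | 50–1200 m/z | stated TOF range |
| CE modes | 10/20/30/40 eV fixed; 25–62.5 eV ramp | stated |
| top-N per cycle | floor(12/5) = 2 | implied by the two rates |

Where the method is silent, values are chosen once at what a
practitioner would call realistic for a UHPLC-QTOF metabolomics run and
documented here: Gaussian chromatographic peaks with σ = 0.05 min
(≈ 7 s base width on a 13-min gradient), m/z jitter σ = 0.001 Da
(≈ 2 ppm at m/z 500), RT drift σ = 0.1 min, log-normal apex intensities
(median 2·10⁴ counts, sdlog 0.3), 10 background decoy components per
run and Poisson(3) decoy fragments per MS2 spectrum. The
exclusion-release rule is unspecified in vendor terminology; the
implemented reading — excluded after `active_exclusion_count`
selections, released (counter reset) after one full cycle below the
threshold — is the simplest rule consistent with "active exclusions =
3", and is isolated behind `acquisition_settings()` so another reading
is a one-line change. CE-ramp spectra are simulated from the same
source spectrum as fixed-CE ones; the true energy dependence of
fragment intensities is *not* modelled.

Every simulated run is audited before it is returned: each MS2 event
must have an above-threshold trigger intensity, no precursor may exceed
the exclusion count within an epoch, and no emitted peak may leave the
scan range. Exports are byte-identical under a fixed seed.

What passing simulator-based tests shows — and what it does not: the
pipeline recovers planted compounds under calibrated noise and rejects
mass-shifted decoys, which validates the bookkeeping (scheduling,
exclusion, tolerances, scoring) end to end. It says nothing about real
matrix effects, co-eluting isomers with genuinely different fragment
intensities, in-source fragmentation, or detector saturation — none of
which the generator models.

## Problem sizes and numerical choices

The suite runs the full 43-record catalogue everywhere it matters
(exact-mass reproduction on all rows, 200 random-query index checks,
100 random-library archive round trips) and sizes stochastic
experiments to stay desk-scale: 10-seed DDA recovery on the full
library, 20-seed bounded-jitter recall on an 8-record subset, and
3-point jitter grids on 2 seeds — together a few minutes on one CPU.
Peak-list invariants use 1e-6 Da as the duplicate threshold (far below
any instrument resolution), single-linkage clustering tolerances are
user-set with 0.005 Da defaults, and all display rounding is
half-away-from-zero at the catalogue's own precision (4 decimals m/z,
1 decimal ppm, 2 decimals minutes).

## Known limitations

* No negative-ion mode, multiply charged species or isotope-pattern
  modelling; the screen is positive-mode, singly charged by design.
* Fragment annotation is rule-based (loss combinatorics + catalogued
  diagnostics); it does not attempt bond-level in-silico fragmentation
  or intensity prediction.
* The identity of co-eluting isobaric standards is not decidable from
  mass and RT alone; ties are reported deterministically rather than
  resolved.
* The packaged spectra are synthetic stand-ins (see above); conclusions
  about real spectral match quality require instrument data imported
  via MSP/MGF.
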
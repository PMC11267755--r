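---
title: "Annotating pyoverdine variants and profiling A-domain specificity codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating pyoverdine variants and profiling A-domain specificity codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdms)
```

## The molecule and its mass model

Pyoverdine (PVD) is assembled by four non-ribosomal peptide synthetases and
matured into a three-part molecule: a dihydroxyquinoline chromophore carrying
a succinate or succinamide side chain, an eight-residue peptide
(Ser-Arg-Ser-fOHOrn-Lys-fOHOrn-Thr-Thr in *P. aeruginosa* PAO1), and a
macrolactam that closes the C-terminal threonine onto the Lys5 side chain.
Two consequences drive all mass arithmetic in this package:

1. **No terminal water.** A linear peptide's monoisotopic mass is the sum of
   its residue masses plus one water. In mature PVD the N-terminus is
   consumed by the chromophore acylation and the C-terminus by the
   macrolactam, so the neutral mass is simply the chromophore-acyl block plus
   the residue-mass sum. The same bookkeeping makes the ring-containing
   y-ions waterless: `y4 = Lys + fOHOrn + Thr + Thr + proton = 489.267`,
   which is what the fragment spectra of native PVD show.
2. **The ring is uncleavable.** A single backbone cleavage cannot open the
   macrolactam, so no y-ion smaller than the ring (y1–y3) and no b-ion
   cutting inside it (b5–b7) exists. `fragment_table()` therefore emits
   exactly b1–b4 and y4–y7, and flags the ring-containing y-ions
   `low_ce_only` — experimentally they survive only gentle collision
   energies.

### The chromophore-acyl block

No table of chromophore masses is hard-coded; the block is a registry entry
like any residue. Its elemental formula was derived once from the mature-PVD
structure: the chromophore free acid is C13H13N3O4; as an in-chain unit (acid
condensed onto Ser1, i.e. minus one water) it is C13H11N3O3, and the succinyl
side chain adds C4H4O3, giving **C17H15N3O6 = 357.09609 Da** for the
succinate form. The succinamide form replaces an acid OH with NH2
(C17H16N4O5, −0.98402 Da). With the succinate block the native scaffold gives
[M+H]⁺ = 1334.597 and [M+2H]²⁺ = 667.802 — matching the reported MALDI and
ESI precursors of the main secreted species — so `pvd_scaffold()` defaults to
`side_chain_form = "succinate"`.

### Constants

| constant | value | role |
|---|---|---|
| proton | 1.00728 Da | charge adduct; fixed at 5 decimals for stable reproduction of printed values |
| isotope spacing | 1.00335 Da | isotopologue lookup in envelope sums |
| RDA loss | 303.13 Da (configurable) | retro-Diels-Alder companion offset |

The chromophore undergoes an in-source retro-Diels-Alder (RDA)
rearrangement, producing a companion ion at a fixed neutral loss below every
singly-charged precursor. The rearrangement's composition is not modeled;
the default 303.13 Da is the difference of the native precursor/companion
pair, and the package's tests check that the second reported pair
(a PVD–antibiotic conjugate) agrees with it within 0.07 Da. The loss is a
parameter of every function that predicts companions.

## Matching, inference, localization

**Tolerances.** MALDI reflectron spectra show cross-spectrum calibration
offsets up to ~0.3 Da; ESI values agree to ~5 mDa. Default matching
tolerances are therefore **0.3 Da (MALDI)** and **0.02 Da (ESI)**, chosen per
peak list mode and never "fixed" by recalibrating observed values.

**Matcher.** `match_peaks()` is a deterministic greedy nearest-mass
assigner: among all peak/candidate pairs within tolerance it repeatedly
commits the smallest-error pair, breaking ties toward the lower-m/z
candidate, then the lower-m/z peak. Each peak and candidate is used at most
once; an equidistant peak is assigned by the tie-break and flagged
ambiguous. In the regime these spectra occupy — candidate spacing large
relative to the tolerance, jitter a fraction of it — each peak can reach at
most a couple of candidates and greedy assignment coincides with the
exhaustive minimum-total-error assignment, which the test suite verifies
against a full enumeration oracle on small instances. On adversarial
layouts (several candidates crowded within one tolerance width) greedy
matching is not globally optimal; such spectra also defeat the annotation
logic itself and are out of scope.

**Substitution inference.** A precursor shift Δ is explained by every
alphabet block whose residue-mass difference to the reference lies within
tolerance of Δ. Isobaric blocks are returned together — Leu and Ile are a
single registry entry (`"Leu/Ile"`), since no mass measurement separates
them. Calls report the exact theoretical shift and its nominal integer
(the "−14 amu" idiom); candidates are never ranked by biological
plausibility. An unexplainable shift returns an empty call carrying the
three nearest misses as a diagnostic.

**Localization.** `localize_from_msms()` intersects the spans of all
shifted fragments, subtracts the span union of unshifted ones, and then
keeps only positions whose reference residue can chemically yield the shift
under the alphabet. The default tolerance here is the ESI value (0.02 Da):
at 0.3 Da the decoy Lys→Asn (−14.052 Da) becomes indistinguishable from
Thr→Ser (−14.016 Da) and position 5 would wrongly stay in the window. For
the observed pattern — y4 and y7 shifted by −14, b1–b4 unshifted — the
window is {7, 8}: both ring threonines, and deliberately not a single site,
because y4 covers both and no fragment separates them. A shifted fragment
nested inside an unshifted one is contradictory; the call is flagged
ambiguous and both candidate windows are reported rather than silently
guessing. When the spatial window survives but no position passes the
chemistry filter, the returned `window` is empty while `window_spatial`
preserves the set-arithmetic result.

**Confirmation policy.** `annotate_spectrum()` reports a variant as
`confirmed` only when a main precursor peak (z = 1 or 2) matches; an RDA
companion alone yields `companion_only` — companions are derived species and
corroborate but never establish a variant.

## Titration quantification

The titration procedure sums, for each of two species, the intensities of
the full isotopic envelope of the main signal **plus** the envelope of its
RDA companion, then takes the ratio. Defaults: **K = 4** isotopologues past
the mono peak (a visually complete envelope near m/z 1300) at **0.3 Da**
per-isotopologue tolerance; missing isotopologues contribute zero, and a
species with no peak at the mono position is flagged absent (an absent
denominator is an error, not a zero).

`fit_response()` regresses measured intensity ratios on known concentration
ratios by ordinary least squares **with intercept** (whether the original
calibration was forced through the origin is not stated; both behaviours are
exposed via `through_origin`, and the ordinary coefficient of determination
is reported in either case). The slope is the MS response factor;
`estimate_ratio()` inverts the line. Beer–Lambert quantification
(`pvd_concentration()`) uses ε₄₀₀ = 19,000 (mol/L)⁻¹cm⁻¹ and a 1 cm path by
default.

## What the generators emulate — and what they do not

`gen_peaklist()` produces centroided stick spectra: per species and charge,
an isotopic envelope whose relative intensities follow Poisson weights with
mean λ·M/1000 (**λ = 0.65** per 1000 Da, a carbon-count proxy), scaled so
the envelope total equals the species abundance; an RDA companion envelope
at a configurable fraction (0.3 in the test fixtures); Gaussian m/z jitter;
and mean-one multiplicative lognormal intensity noise. The pipeline only
*sums* envelopes — it never fits their shape — so fidelity beyond "several
isotopologues of plausible relative intensity" is intentionally not
pursued. Not emulated: MALDI baseline and chemical noise, detector
saturation, adducts (Na⁺/K⁺), ferri-PVD species, isotopic fine structure,
profile-mode peak shapes. Passing round-trip tests therefore demonstrates
the correctness of the arithmetic and the decision rules, not robustness to
raw-spectrum artifacts; real data must arrive centroided.

`gen_sequence_set()` emulates a labeled specificity-code table: 8 code
columns plus an Asp anchor column. Planted cells draw the planted residue at
the stated per-category frequency and otherwise from the background
*excluding* it, keeping empirical frequencies unbiased; the background is
uniform over the 20 proteinogenic residues; anchor-Asp fractions default to
38/39 (T) and 1196/1507 (NT), the proportions the anchor filter leaves in
the real data set. It does not emulate phylogenetic correlation between
sequences — every sequence is independent, so conservation estimates
concentrate at the binomial rate, faster than correlated real sequence sets
would.

`gen_titration()` derives one peak list per known ratio with species-A
abundance = ratio × response factor × species-B abundance; per-point seeds
are derived deterministically from the master seed. The study conditions
frozen into the tests: 5 ratios **c(0.05, 0.1, 0.25, 0.5, 1)** (bracketing
the minor variant fraction), 5 % intensity CV, response factor 0.8, RDA
fraction 0.3.

## Specificity-code profiling choices

* **Gaps dilute.** Gap characters are counted as their own symbol *in the
  denominator*: a position gapped in half the category can never reach 90 %
  conservation. This is the conservative choice where the procedure is
  otherwise silent.
* **Strict thresholds.** A key residue requires f(T) > 0.90 **and**
  f(NT) < 0.05, both strict; a residue at exactly 90 % is not called.
* **Column mapping is configuration.** `code_positions()` takes the eight
  code columns and the anchor column as 1-based alignment indices; the
  mapping to PvdD residue numbering depends entirely on the user's
  alignment and is not hard-coded. The packaged defaults used by the
  generator (columns 1–8, anchor 9) are a synthetic layout, not the real
  alignment's.
* The upstream multiple alignment is consumed, never computed; if two
  aligners disagree, reconciliation is the user's responsibility.

## Numerical and degenerate-input conventions

* Fragment m/z are computed in double precision and written to files at 3
  decimals; matching always uses tolerances, never rounding.
* `enumerate_variants()` includes the identity variant, collapses duplicate
  substitution maps, and groups variants whose neutral masses agree within
  1 µDa as one isobaric mass group.
* Empty inputs degrade gracefully: an empty peak list annotates to an empty
  report, an empty candidate list leaves all peaks unmatched, an empty
  position set enumerates only the identity.
* Registry validation enforces unique ids, positive masses, formula/mass
  agreement within 1e-4 Da, and nominal = rounded monoisotopic mass.
* All simulation randomness flows from explicit seeds through
  `withr::with_seed()`; no function touches global RNG state implicitly.

## Problem sizes used by the test suite

The suite runs in well under a minute on one CPU: property loops use 10–25
replicates; planted-key recovery uses 50 seeded sets of 200 T + 1000 NT
sequences (large enough that a 95 %-conserved key exceeds the 90 % threshold
with ~99.9 % probability while an 80 % decoy practically never does);
mixing-ratio recovery uses 60 seeded titrations. These sizes were chosen as
the smallest at which the binomial/CLT concentration the invariants rely on
is comfortably inside the asserted bounds.

## Known limitations

* Monoisotopic arithmetic only; no average-mass mode, no isotope-resolved
  fine structure, no adducts beyond protons, no iron-bound species.
* Only b/y series, no internal fragments, no intensity prediction; collision
  energy appears only as the `low_ce_only` flag.
* The RDA loss is an empirical constant, not a derived composition.
* The greedy matcher's optimality guarantee is restricted to well-separated
  candidate sets (see above).
* MGF support covers the plain BEGIN/END IONS dialect with PEPMASS, CHARGE
  and TITLE headers — sufficient for peak-list exchange, not a general MGF
  implementation.
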
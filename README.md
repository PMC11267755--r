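# pvdms

Identification and quantification of **pyoverdine (PVD) sequence variants**
from MALDI/ESI mass spectra, and differential-conservation analysis of
**adenylation-domain specificity codes**.

Pyoverdine, the fluorescent siderophore of *Pseudomonas aeruginosa*, is a
non-ribosomal peptide: a dihydroxyquinoline chromophore acylated with a
succinate/succinamide side chain, an 8-residue peptide
(Ser-Arg-Ser-fOHOrn-Lys-fOHOrn-Thr-Thr in PAO1), and a C-terminal macrolactam
closing the last four residues onto the Lys5 side chain. When the adenylation
(A-) domain that selects the terminal threonines is engineered — or is
naturally promiscuous — the strain secretes PVD variants carrying other amino
acids (Ser, Val, Leu/Ile, or the clickable 4-azido-L-homoalanine). These
variants are recognized in mass spectra by small precursor mass shifts and
localized by shifted b/y fragment ions. `pvdms` implements that entire
desk-side workflow as composable, pipe-friendly functions.

## What it computes

**Mass model.** With monoisotopic residue masses `m_i` (amino acid − H₂O) and
the chromophore-acyl block mass `m_chr`, the neutral peptide mass is

```
M = m_chr + Σ m_i          (no terminal-water term)
```

because the macrolactam closure and the N-terminal acylation consume both
termini. Ions are proton adducts, `m/z = (M + z·1.00728)/z`. The chromophore
also produces an in-source retro-Diels-Alder (RDA) companion ion at a fixed
303.13 Da loss below each singly-charged precursor.

**Fragments.** The macrocycle is uncleavable by a single backbone bond break,
so only y-ions containing the whole ring (`y4`–`y7`) and b-ions outside it
(`b1`–`b4`) exist:

```
y_n = Σ (last n residue masses) + z·1.00728     (n ≥ ring size)
b_n = m_chr + Σ (first n residue masses) + z·1.00728   (n < ring start)
```

**Variant inference.** A precursor shift Δ is explained by every residue
substitution whose monoisotopic mass difference matches Δ within tolerance;
MS/MS localization intersects the spans of shifted fragments and subtracts
the spans of unshifted ones.

**Quantification.** The titration procedure sums each species' full isotopic
envelope plus its RDA companion, fits measured vs. known ratios by OLS
(slope = MS response factor), and inverts the line to estimate mixing
ratios. Photometric PVD quantification uses Beer–Lambert with
ε₄₀₀ = 19,000 (mol/L)⁻¹cm⁻¹.

**Specificity codes.** Given an aligned, category-labeled A-domain set
(threonine-specific T vs non-threonine NT), sequences without the conserved
Asp anchor are removed, per-position residue frequencies are computed for the
eight code positions, and a residue is called a *key residue* when it is
conserved > 90 % in T and represented < 5 % in NT (strict inequalities).

## Worked example

Annotate the three peaks of a wild-type MALDI spectrum (native PVD, its RDA
companion, and the unexpected lighter species):

```r
library(pvdms)

obs <- peaklist(c(1031.66, 1320.78, 1334.79), c(28, 35, 100),
                mode = "MALDI", label = "PaM1 supernatant")
annotate_spectrum(obs, pvd_scaffold(), positions = c(7, 8),
                  alphabet = c("Thr", "Ser", "Val", "Leu/Ile", "azHA"))
#> # A tibble: 2 × 8
#>   label neutral_mass mass_group status    n_main_matched n_rda_matched best_error
#> 1 7Ser         1320.          3 confirmed              1             0      0.199
#> 2 native       1334.          6 confirmed              1             1      0.193
```

The native species is confirmed by its precursor *and* corroborated by the
RDA companion; the lighter species matches a Ser-for-Thr variant (`7Ser` and
`8Ser` are isobaric — same `mass_group` — and MS cannot tell them apart from
the precursor alone). The −14 amu shift itself identifies serine:

```r
infer_substitution(1320.78 - 1334.79, "Thr")
#>   reference candidate observed_shift theoretical_shift nominal_shift   error
#> 1 Thr       Ser               -14.0             -14.0            -14 0.00565
```

and the fragment predictions anchor the localization — the computed
`y4` = 489.267 and `y7` = 890.469 sit on the observed C-terminal fragments,
while `b1`–`b4` are unshifted, placing the substitution in the ring
threonines (positions 7–8):

```r
y_ion(pvd_scaffold(), 4)$mz   # 489.2667
y_ion(pvd_scaffold(), 7)$mz   # 890.4690
```

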
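---
title: "Mass-window typing of wheat HMW glutenin subunits: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-window typing of wheat HMW glutenin subunits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutencaller)
```

## The measurement and its model

High-molecular-weight glutenin subunits (HMW-GS) are 67–101 kDa wheat
seed storage proteins encoded at *Glu-A1*, *Glu-B1* and *Glu-D1*. Each
locus carries a tightly linked x-type/y-type gene pair, of which most
cultivars express three to five subunits (the *Glu-A1* y gene is always
silent, and some x genes are too). Linear-mode MALDI-TOF-MS of a glutenin
extract shows one peak per expressed subunit; this package turns those
peaks into an allele composition such as `2*, 7+8, 5+10`.

The model behind the caller is deliberately minimal and matches how the
measurement behaves:

- **Masses are average, not monoisotopic.** At 80 kDa the isotopic
  envelope is unresolved in linear TOF mode; all sequence-derived masses
  are average residue-mass sums plus one water (18.0153 Da), the
  convention of the standard sequence-mass calculators
  (`average_mass()`).
- **Ions are treated as singly charged**, `[M+H]+ ≈ M` at this mass
  scale; no charge deconvolution is attempted.
- **Alkylation is hypothesis-dependent.** Extraction alkylates cysteines
  with 4-vinylpyridine, adding 105.14 Da per residue. The cysteine count
  is a property of the *candidate allele* (7 for y-type, 4 for x-type,
  with 1Dx5 = 5 and 1Bx20 = 2), so correction happens inside the
  matching loop: `strip_vp(m, n_cys) = floor(m − 105.14 · n_cys)`.
  Truncation to integer Da — rather than rounding — is the convention
  the embedded corrected-mass table follows; it reproduces every
  printed corrected value that is internally consistent (e.g. 1Bx20:
  84,014 − 210.28 = 83,803.72 → 83,803, which rounding would miss).
- **Replicate mass error is multiplicative.** Reproducibility across
  acquisitions is reported as a relative SD (RSD, 0.011–0.096 % in the
  reference data), so the simulator draws
  `observed = true · (1 + N(0, σ_rel))` rather than adding a constant
  Da-scale error.

## The reference library

`load_glu1_library()` ships 23 allele variant records covering 22
distinct subunit names. 1Bx7 is deliberately split into three records
sharing one legacy name:

- **group 1** (~82,400 Da corrected), the classical protein;
- **group 2** (~83,000 Da), carrying an 18 bp coding insertion worth six
  residues (~600 Da);
- **1Bx7OE**, mass-identical to group 2 but with a gene duplication that
  drives overexpression — detectable only by PCR, not by mass.

Each record carries the reference masses observed in 24 standard
cultivars, a gene-predicted mature-protein mass where a public sequence
exists (absent for 1By8* and 1Dx4), and the cysteine count. Matching
windows are the per-allele range of the standard-cultivar corrected
masses padded by the tolerance on both sides (`allele_window()`).

Two cells of the published mass tables are internally inconsistent with
each other (the Soissons 1By8 and Nanbu-Komugi 1Dy12 pairs differ by 4
and 20 Da between the raw and corrected tables; no correction rule can
reconcile them). The fixtures transcribe both tables verbatim and the
test suite pins the mismatch set to exactly those two pairs. Similarly,
the predicted mass of 1Dx2.2 is printed inconsistently in the source;
the library uses 100,886 Da, the value that reproduces the printed
difference column.

## The caller

`call_genotype()` performs an exhaustive search over one haplotype per
locus — 3 *Glu-A1* × 14 *Glu-B1* (after expanding the 1Bx7 variants) ×
4 *Glu-D1* options. For each combination, members are matched greedily
(in locus order, x before y) to the nearest unassigned peak whose
corrected mass lies in the member's window; the combination score is

```
sum(|corrected − reference mean|)  +  P · #unmatched members  +  Q · #unassigned peaks
```

with `P = 10000` and `Q = 1000`, chosen so that any complete low-error
assignment beats any incomplete one and explaining a peak is always
preferred to ignoring it. Both are arguments of `call_genotype()`. The
search space is tiny (≤ 168 combinations), so optimality is verified in
the tests by independent re-enumeration.

This structure is what resolves most look-alike subunits:

- the *Glu-B1* x slot is obligatory, so a lone x-type peak near 86.4 kDa
  is forced to 1Bx6 rather than 1Ax2* (which would leave *Glu-B1*
  without an x member);
- 1Bx13 vs 1Bx7 group 2, or 1By15/1By18/1By20 vs 1By8, are pinned by
  their tightly linked partners (1By16, 1Bx14, 1Bx17, 1Bx20), because
  only the correct haplotype explains both peaks without penalty.

### Ambiguity handling

Pairs whose reference means differ by less than the tolerance cannot be
separated by mass, whatever the windows say about a single peak. After
ranking, the caller therefore collects every combination that explains
the *same peaks with the same penalties* while swapping alleles less
than 300 Da apart in reference mean — an equivalence class within which
the residual score differences (a few tens of Da against a 300 Da
resolution) are noise. Within the class the reported call is the
canonical member (fewest label characters, then byte order: `8` before
`8*`, `7` before `7OE`), the class's minimum score is reported, and the
other members appear as `ambiguous_alternatives` with advisory flags.
Orthogonal evidence then resolves the class instead of the mass:

- `rphplc_calls` (subunits confirmed by RP-HPLC retention) select the
  consistent member — this is how `7+8` vs `7+8*` is decided;
- `bx7_duplication_pcr` gates the 1Bx7 records *before* the search:
  positive excludes plain group 2, negative excludes 1Bx7OE, unknown
  keeps both and the call reports `group2_or_OE`.

The group-1/group-2 boundary is a corrected mass of 82,700 Da, the
midpoint of the two class centroids (82,400 and 83,000 Da); observed
corrected masses leave a dead zone of ~500 Da around it (≤ 82,493 vs
≥ 82,981 in the reference data), so any boundary inside the zone is
equivalent on real data. The 1Ax2*/1Bx6 pair additionally carries an
advisory flag whenever the matched peak sits in both windows, because
the haplotype constraint, not mass, made that call.

## Peak detection and calibration

The reference workflow exports peak lists from vendor software, so
`detect_peaks()` exists mainly to make the package self-contained for
raw two-column profiles; its algorithm is intentionally simple and fully
parameterised: moving-average smoothing (default 25 Da window), noise as
the MAD (scaled to SD) of the baseline-subtracted trace, local maxima
above `min_snr = 3`, intensity-weighted centroid over the half-height
region (reported masses are centroids, not apexes — the source does not
state which it used), and a 300 Da minimum-spacing filter keeping the
higher peak. Calibration is one-point multiplicative against an external
bovine serum albumin standard (66,463 Da), with scale factors outside
[0.95, 1.05] rejected; a two-point linear model is available for users
with two standards.

## The simulator

`simulate_peaklist()` draws one peak per expressed subunit at the
allele's *simulation mass* plus the alkylation shift, with multiplicative
Gaussian error (default σ_rel = 5 × 10⁻⁴, i.e. 0.05 %, inside the
observed replicate-RSD range). The simulation mass is the gene-predicted
mature mass, which keeps simulation independent of the measured
reference windows — with four exceptions, where the measured mean is
used instead:

- 1By8* and 1Dx4 have no public gene sequence;
- 1Bx17 and 1Dx2.2 have predicted masses that deviate from every
  measurement by more than the 300 Da tolerance (+646 and −496 Da; the
  latter reflecting degraded accuracy at the upper edge of the
  60,000–110,000 Da acquisition window). Simulating those two from the
  predicted mass would build spectra the method itself classifies as
  unmatchable, which is not what an instrument produces.

1Bx7 group 2 is simulated at 83,122 Da, the predicted mass of the
duplication-allele gene, because group 2 genes have been sequenced
identical to it; the group-1 gene value (82,527 Da) would place the
simulated protein in the wrong mass class.

`simulate_profile()` renders the same peaks as Gaussians (default
σ = 150 Da, a width chosen to look like linear-mode TOF at 80 kDa and
never used in any acceptance arithmetic) over a constant baseline with
additive noise. The intensity model (log-normal) is arbitrary: the
source data carry no usable intensity information, so intensities are
excluded from all calling decisions and checks. `simulate_cohort()`
draws genotypes from the embedded cohort's empirical composition
frequencies by default and derives per-sample seeds from one master
seed, so a manifest is byte-reproducible.

What passing simulator round-trips does and does not show: recovery of
100 % at zero noise and ≥ 95 % at 0.05 % relative SD (ambiguity classes
counted as recovered when the truth is among the flagged alternatives)
demonstrates the caller's logic under the model's own assumptions. Real
spectra add baseline drift, adduct satellites, matrix effects and
intensity-dependent mass shifts that the simulator does not emulate, so
these figures bound the algorithmic, not the instrumental, error.

## Numerical conventions and degenerate inputs

- Corrected masses: floored to integer Da; display means: rounded
  half-up; error percentages: half-away-from-zero to 2 decimals;
  replicate RSD: sample SD (n−1) over mean, 3 decimals.
- Ties in peak matching resolve to the lower mass; ties in combination
  ranking resolve to fewer unassigned peaks, then byte-order
  composition.
- An empty or out-of-range peak list yields an `uncallable` result with
  diagnostics, never an error; unexplained peaks are flagged, not
  fatal, since they may be novel alleles.
- Replicate sets that disagree on composition are returned as a
  discordance report and excluded from aggregation.

## Problem sizes used in the shipped checks

The test suite calls all 62 embedded cultivar tables (24 standards + 38
cohort), verifies search optimality by full enumeration on each,
round-trips the 30 distinct fixture compositions at zero noise, and runs
200 simulated samples at 0.05 % relative SD plus 100 random sequences
against an independent residue-sum mass oracle — sizes at which every
check is exact or high-powered while the whole suite stays fast.

## Known limitations

- The caller assigns at most one allele per peak and cannot detect
  co-eluting subunits hidden under one peak.
- No quality scoring (Glu-1 scores), no low-molecular-weight glutenins
  or gliadins, and no de novo allele discovery beyond flagging
  unassigned peaks.
- Calibration behaviour at the extreme upper edge of the acquisition
  range (1Dx2.2, ~100.8 kDa measured) is not modelled; the library
  simply carries the measured values.
- Vendor binary formats are out of scope; input is delimited text.
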
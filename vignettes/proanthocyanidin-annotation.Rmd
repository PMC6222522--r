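---
title: "Annotating proanthocyanidin oligomers by exact mass, Kendrick analysis and diagnostic MS/MS fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating proanthocyanidin oligomers by exact mass, Kendrick analysis and diagnostic MS/MS fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdkit)
```

## The problem

Proanthocyanidins (condensed tannins) are polymers of flavan-3-ol
monomers joined by interflavan bonds. In grapes and wine four monomers
dominate: (epi)catechin (`Cat`, C15H14O6), (epi)gallocatechin (`GalCat`,
C15H14O7, a trihydroxylated B-ring) and their 3-*O*-gallate esters
(`Cat:Gal`, C22H18O10; `GalCat:Gal`, C22H18O11). Because every chain
position can hold any monomer, the number of possible compounds explodes
exponentially with the degree of polymerization (DP), and no authentic
standards exist for the vast majority. pcdkit implements an annotation
strategy for this situation: enumerate every *composition* a priori,
match high-resolution LC-MS features to the resulting exact-mass
database, visualise the assignments on a composition-revealing Kendrick
mass scale, and corroborate individual assignments with rule-generated
diagnostic MS/MS fragments.

## The compound database

`pcd_database()` enumerates subunit multisets, not sequences. Sequence
isomers (and epimers) share a molecular formula and an exact mass, so
MS1 cannot distinguish them; collapsing them keeps the database at

$$|\mathrm{db}| \;=\; \sum_{n=\mathrm{dp_{min}}}^{\mathrm{dp_{max}}} \binom{n+s-1}{s-1}$$

entries for $s$ subunit types — 996 for the default four subunits and DP
2–10. `sequence_isomer_count()` gives the $s^{\mathrm{dp}}$ sequence
count for reasoning about how many chromatographic isomer peaks a single
formula may legitimately produce.

Each composition's formula is the sum of its monomer formulas minus one
H2 per interflavan bond (B-type single linkage; a chain of dp units has
dp − 1 bonds). Doubly linked A-type polymers, anthocyanin adducts and
non-grape subunits are out of scope. Distinct compositions can share a
formula: a formula is determined by the triple (dp, number of gallate
esters, number of extra B-ring oxygens), and for ambiguous formulas
`formula_candidates()` orders candidates by a fixed canonical rule
(maximal `GalCat:Gal` count, then maximal `Cat` count, then name). The
rule is arbitrary but total and deterministic, and it reproduces the
representative compositions conventionally reported for such formulas.

## Mass arithmetic

All masses are monoisotopic, computed from C = 12 exactly,
H = 1.00782503207 and O = 15.9949146196 Da. Negative-mode ions are
`[M − zH]^z−` with z ∈ {1, 2} — m/z = (M − z·1.00727646688)/z — or the
formate adduct `[M + HCOO]−` at z = 1. Whether measured masses include
an electron-mass correction cannot be decided from ppm errors of a few
ppm either way; the proton-removal convention above reproduces every
reference fragment m/z at 4 decimals and is used throughout. The
unsigned relative error |theoretical − experimental|/theoretical × 10^6
is the reported ppm convention; a signed variant is available for
diagnosing calibration drift.

## Kendrick analysis with a C15H12O6 repeat unit

The classical Kendrick transform rescales masses so a chosen repeat unit
has integer nominal mass. Here the repeat unit is the catechin extension
unit C15H12O6 (catechin less H2, 288.063388 Da):

$$\mathrm{Kendrick\ mass} = \mathrm{IUPAC\ mass} \times \frac{288}{m(\mathrm{C_{15}H_{12}O_6})},\qquad
\mathrm{KMD} = \mathrm{KNM} - \mathrm{Kendrick\ mass}$$

where KNM, the Kendrick nominal mass, is the Kendrick mass rounded to
the nearest integer. Adding extension units leaves the KMD exactly
unchanged, so homologous series collapse onto horizontal lines of a
KMD-vs-KNM plot: every pure-catechin polymer sits at KMD −0.0152, one
extra B-ring oxygen shifts (KNM, KMD) by (16, +0.0086) and one gallate
ester by (152, +0.0225). Reading a compound's (KNM, KMD) off the plot
therefore reveals its subunit composition directly.

Numerical choices:

* The divisor is the full-precision mass of C15H12O6, which keeps the
  homologous-series invariance exact to machine precision; the printed
  4-decimal constant 288.0634 gives identical 4-decimal results and can
  be requested via `base_mass = 288.0634`.
* KNM rounds half away from zero. No database entry falls within 0.2 of
  a half-integer (asserted in the tests), so the tie rule is inert but
  fixed.
* Kendrick quantities are computed from the *neutral* monoisotopic
  mass, never from ion m/z: the catechin trimer sits at KNM 866, not at
  its [M − H]− m/z of 865. (Texts that quote a "dimer at KNM 577" are
  implicitly using the deprotonated m/z; the neutral convention is used
  consistently here.)

## Feature matching

`match_features()` re-implements the targeted extraction stage of a
vendor feature finder as an open, testable rule. Features (deisotoped,
negative mode) are filtered to abundance ≥ 750 counts (the boundary is
kept: "smaller than 750" is excluded) and charge 1–2. Each feature is
interpreted under every allowed adduct consistent with its charge, the
neutral mass is reconstructed, and the database entry with the smallest
unsigned ppm error within a ±20 ppm window (inclusive) wins; ties prefer
deprotonation, then lower DP. A brute-force scan over all entries ×
adducts is kept in the test suite as the oracle the indexed
implementation must agree with.

Matches sharing a formula are clustered on retention time by single
linkage to form isomer peaks. The clustering tolerance defaults to
0.02 min: amide-HILIC separations of these compounds resolve isomers as
little as 0.04 min apart, and replicate-to-replicate retention jitter on
modern UHPLC systems is of the order of a second, so 0.02 min merges
replicate detections without fusing genuinely resolved isomers. (A
looser, superficially safer 0.10 min would merge reported isomer pairs.)

### Limits of formula-level matching

A four-subunit combinatorial database grows mass-degenerate at high DP:
two gallate esters (2 × 152.0110 Da) differ from one extension unit plus
one oxygen (288.0634 + 15.9949 Da) by only 36.4 mDa, and further
combinations come closer still. Below DP 5 the 20 ppm window is
unambiguous; by DP 6–10 many formulas have neighbours within 9–20 ppm,
so *any* exact-mass-only matcher — this one, or the vendor tool it
mirrors — can assign a high-DP, poorly mass-calibrated feature to an
adjacent formula. The test suite pins one concrete instance: a
pentameric formula reported with a 15.8 ppm error is nearer (8.6 ppm) to
a tetra-meric digallate, and the matcher assigns the latter. Resolving
such cases needs isotope-pattern scoring or MS/MS, which is exactly why
the fragment module exists; isotope scoring itself is out of scope
(inputs are assumed deisotoped).

## Diagnostic MS/MS fragments

Three C-ring/interflavan cleavage families generate the diagnostic ions
of flavan-3-ol oligomers, and `generate_fragments()` applies them
compositionally:

* **QM** (quinone methide fission) splits an interflavan bond. For every
  proper sub-multiset S of the composition a terminal-side ion
  `[poly(S) − H]−` and an extension-side ion 2 Da lighter are generated.
  The monomer-level ions are the role diagnostics: catechin terminal
  289.0718 vs extension 287.0561; gallocatechin terminal 305.0667;
  catechin gallate terminal 441.0827. Presence/absence of these ions
  localises subunits: a spectrum with no peak near 305.0667 contains no
  gallocatechin extension unit, and `annotate_spectrum()`'s summary
  reports exactly this per-subunit, per-role evidence.
* **HRF** (heterocyclic ring fission) releases phloroglucinol (C6H6O3,
  126.0317 Da) from a unit with an intact A-ring, at most once per
  remaining unit (structure I; dehydrated, structure II).
* **RDA** (retro-Diels-Alder) loses the B-ring-containing fragment:
  C8H8O3 for catechol B-rings, C8H8O4 for pyrogallol, at most once and
  only when a unit of the matching type is present (structure IV;
  dehydrated, structure V).

Water loss is always available and gallate loss (C7H4O4, 152.0110 Da —
note: 46 mDa below the RDA catechol loss) requires a remaining gallate
ester (structure VI). Losses chain up to `max_losses` deep, applied to
the precursor and to every QM fragment, and the union is deduplicated
keeping the shortest pathway. The default depth is 3 because the
characteristic dehydrated products of galloylated precursors (structures
II and V) are three losses deep (HRF/RDA + gallate + water); depth 2
would silently drop them. Fragments are generated singly charged even
for doubly charged precursors, matching how product-ion spectra of
multiply charged proanthocyanidins read out. Because fragment sets are
generated over compositions (multisets), they are the union over all
sequence isomers — consistent with arguing from presence/absence of
ions rather than from a known sequence.

Annotation tolerance defaults to 20 ppm. Product-ion mass accuracy is
visibly poorer than MS1 in reference spectra (several printed fragments
sit 4–8 ppm from theory, some further), so a tighter default would
reject genuine diagnostic ions; strictness is configurable.

## The synthetic data generator

`simulate_features()` exists so every pipeline stage is testable without
instrument data. It emulates deisotoped negative-mode feature tables:

* **Planting.** By default the 21 published wine proanthocyanidin
  compositions (DP 2–7, at most one gallate) are planted — the compound
  universe the pipeline targets. `compounds = "sample"` draws entries
  from the whole database instead; note that such draws include high-DP
  formulas whose neighbours sit within a few ppm, where wrong-formula
  assignments are a property of the chemistry, not a test failure.
* **Mass error.** Observed m/z is true m/z × (1 + ε), ε ~ N(0, σ) with
  σ = 5 ppm by default — a realistic externally calibrated Q-TOF
  accuracy and a quarter of the matching window. The mean unsigned
  matched error then converges to the folded-normal mean 0.798 σ,
  which the tests verify at n > 1000 features.
* **Retention model.** RT = 5.1 min + 2.2 (DP − 2) + 0.9 × (extra
  oxygens) + 0.25 × (gallates) + N(0, 0.05) min. The signs encode the
  qualitative HILIC elution trends (later with DP, hydroxylation, and —
  more weakly — galloylation); the coefficients are a test harness
  placed near observed mean retention times, not a retention-prediction
  claim.
* **Abundances** are log-normal (meanlog log 5×10^4, sdlog 1) times a
  per-sample multiplier (defaults 1 and 3, emulating two contrasted
  samples); triplicate injections; polymers of DP ≥ 4 appear as
  [M − 2H]2− with probability 0.5.
* **Noise features** are uniform in m/z over the acquisition range but
  rejection-sampled to lie ≥ 30 ppm from every database ion under every
  allowed adduct/charge interpretation, so the false-positive rate of
  matching is well defined (a matched noise feature is always a bug,
  never bad luck).

What the generator does *not* emulate: chromatographic peak shapes,
isotope envelopes, ion suppression, cross-run retention drift, and
real abundance correlation structure. Passing tests on synthetic data
therefore demonstrate the correctness of the arithmetic and the
decision rules, not field performance on raw instrument output.

`published_compounds()` ships the published identification table (21
formulas, 89 retention-time entries) and `fixture_features()` replays it
as exact-mass features, which the tests push through
filter → match → group end-to-end, recovering 21 formula groups and 89
isomer peaks and reproducing every printed mean ppm error at one
decimal. The printed heptamer formula contains a typesetting artifact
(a misplaced digit separator); the fixture stores the arithmetically
consistent C105H86O42, which also reproduces the row's printed ppm
error.

## Problem sizes

The shipped tests run the full 996-entry database everywhere it
matters, replay all 89 fixture entries, and use simulations of 126
features (study scale: 21 compounds × 3 replicates × 2 samples) for the
recovery operating point and ~1000 features for the error-distribution
convergence checks; brute-force oracles (ordered-tuple enumeration,
full-scan matching) run on reduced ranges (DP ≤ 6, DP ≤ 4) where the
quadratic cost stays trivial. The whole suite completes in well under a
minute.

## Known limitations

* Formula-level assignment only; isomeric compositions sharing a
  formula are reported as a candidate list with a canonical
  representative, never resolved.
* No isotope-pattern scoring; deisotoped input is assumed.
* No A-type linkages, no subunits beyond the four grape monomers.
* The fragment engine predicts which diagnostic ions can occur, not
  their intensities, and does not attempt de novo sequencing.
* High-DP exact-mass matching is intrinsically ambiguous (see above);
  treat DP ≥ 6 assignments as formula hypotheses pending MS/MS
  corroboration.
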
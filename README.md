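# pcdkit

Annotation toolkit for **proanthocyanidin (condensed tannin) oligomers**
in negative-mode high-resolution LC-MS data, for analytical chemists
profiling wine, grape, cocoa or berry polyphenols.

Proanthocyanidins are polymers of flavan-3-ol monomers — in grapes,
(epi)catechin (`Cat`, C15H14O6), (epi)gallocatechin (`GalCat`, C15H14O7)
and their 3-*O*-gallate esters (`Cat:Gal`, `GalCat:Gal`). Authentic
standards barely exist above the dimer, so annotation works from theory:

1. **Combinatorial exact-mass database** — every subunit *multiset* of
   degree of polymerization (DP) 2–10, with formulas derived as the sum
   of monomer formulas minus one H2 per B-type interflavan bond:
   996 compositions, 501 distinct formulas.
2. **ppm-tolerance matching** — deisotoped features are filtered
   (abundance ≥ 750 counts, charge 1–2), interpreted as `[M − zH]^z−` or
   `[M + HCOO]−` ions, and assigned the database formula minimising the
   unsigned mass error within ±20 ppm; isomer peaks are resolved by
   retention-time clustering within each formula.
3. **Modified Kendrick mass defect analysis** — masses rescaled so the
   catechin extension unit C15H12O6 has integer mass 288:

   Kendrick mass = IUPAC mass × 288 / 288.0634,  KMD = KNM − Kendrick mass

   with KNM the nearest integer. Homologous series share a KMD (pure
   catechin polymers: −0.0152); one extra B-ring oxygen shifts
   (KNM, KMD) by (16, +0.0086), one gallate ester by (152, +0.0225), so
   a compound's plot position reveals its subunit composition.
4. **Rule-based MS/MS fragments** — quinone methide cleavage (terminal
   vs extension monomer ions), heterocyclic ring fission (phloroglucinol
   loss), retro-Diels-Alder losses, plus water/gallate chains, generated
   per composition and matched to observed spectra with per-subunit
   presence/absence diagnostics.

A synthetic feature/spectrum generator with ground truth makes every
stage testable without instrument data.

## Worked example

```r
library(pcdkit)

db <- pcd_database()        # DP 2-10 over the four grape subunits
glance(db)
#>   n_compositions n_formulas dp_min dp_max mass_min mass_max
#> 1            996        501      2     10     578.    4563.

# Kendrick coordinates of the catechin trimer and two substituted forms
kendrick_transform(formula_mass(c("C45H38O18", "C45H38O19", "C52H42O22")))
#>   iupac_mass kendrick_mass   knm     kmd
#> 1       866.          866.   866 -0.0152   # Cat-Cat-Cat
#> 2       882.          882.   882 -0.0066   # +O  (one GalCat)
#> 3      1018.         1018.  1018  0.0073   # +gallate ester
```

The KMD steps (+0.0086 per oxygen, +0.0225 per gallate) let you read
composition straight off a KMD-vs-KNM scatter (`plot_kendrick()`).

Replaying the packaged table of 89 published wine identifications as
exact-mass features through the full filter → match → group pipeline:

```r
cfg     <- match_config()                       # ±20 ppm, 750 counts
feats   <- filter_features(fixture_features(), cfg)
matches <- match_features(feats, db, cfg)
groups  <- group_matches(matches, cfg)
glance(groups)
#>   n_formulas n_isomer_peaks mean_ppm_error
#> 1         21             89           7.74

report_table(groups)[1:4, c("rt_list","formula","polymer","mean_ppm_error")]
#>   rt_list                formula     polymer       mean_ppm_error
#>   4.68, 4.72, 5.31, 5.63 C30H26O12   Cat-Cat       4.0
#>   6.01, 6.38, 7.05       C30H26O13   Cat-GalCat    11.0
#>   8.03                   C30H26O14   GalCat-GalCat 9.6
#>   5.78, 6.09, 6.59       C37H30O16   Cat-Cat:Gal   7.4
```

21 formula groups and 89 chromatographically resolved isomer peaks, with
each group's mean mass error in ppm against its theoretical mass.

Annotating a tandem spectrum of the catechin–catechin-gallate dimer:

```r
ann <- annotate_spectrum(
  data.frame(mz = c(729.1488, 577.1350, 451.1044, 289.0717, 287.0559),
             intensity = c(20, 100, 40, 60, 45)),
  "Cat-Cat:Gal")
tidy(ann)[, c("observed_mz", "fragment_formula", "ppm_error", "structure", "role")]
#>   observed_mz fragment_formula ppm_error structure role
#> 1        729. C37H30O16            3.69  precursor none
#> 2        577. C30H26O12            0.260 VI        none      # - gallate
#> 3        451. C24H20O9             2.09  I         none      # HRF - gallate
#> 4        289. C15H14O6             0.213 III       terminal  # QM, catechin
#> 5        287. C15H12O6             0.737 III       extension # QM, catechin
```

`ann$summary` additionally reports that no gallocatechin terminal or
extension ion (m/z 305.0667) was observed — the absence diagnostic that
confirms this dimer contains no gallocatechin unit.

A command-line wrapper (`inst/scripts/pcdkit`) exposes the same workflow
as subcommands: `build`, `match`, `kendrick`, `bubble`, `fragment`,
`annotate`, `simulate`, `fixture`. See `?pcd_cli`.

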
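# quadfoot

Quantitative analysis of how G-quadruplex (G4) ligands remodel a pre-mRNA
and shift alternative 5' splice-site choice — the Bcl-X problem: two
G4-forming tracts (Q2, Q5) sit next to the two alternative 5' splice sites
of exon 2 (X_S, pro-apoptotic short isoform; X_L, anti-apoptotic long
isoform), and G4-stabilizing small molecules can tip splicing between them.

The package implements the four computational readouts such a study needs,
plus a synthetic-data generator with known ground truth so every stage is
testable without instrument data:

* **Gel-lane quantification** (`detectBands`, `assignPositions`,
  `buildBandTable`) — 1-D densitometry band detection, Gaussian area
  fitting, and nucleotide assignment via ladder anchors; the role
  SAFA/OptiQuant play for phosphor images.
* **Cleavage-index statistic** (`computeIndex`, `fitNull`,
  `callSignificant`, `regionSummary`) — the per-nucleotide index

  `I(p) = [V1_lig(p)/V1_ctl(p)] / [T2_lig(p)/T2_ctl(p)]`

  from duplex-specific (RNase V1) and single-strand-specific (RNase T2)
  footprinting lanes; log10 indices are fit with an empirical Gaussian null
  (plain mean/SD over all analyzed positions) and positions beyond 2 SD are
  flagged with sign (+ = more structure with ligand).
* **Splicing isoform quantification** (`gCount`, `correctAndFraction`,
  `doseResponse`, `relativeChange`) — [alpha-32P]GTP body-labeled gel bands
  are molar amount x guanosine count, so intensities are divided by per-
  species G counts before computing the X_S fraction, spliced fraction,
  dose-response tables and ligand-induced relative site-usage changes.
* **G4 candidate scanning** (`scanG4`, `overlapAnnotate`) — four or more
  G-tracts (>= 3 G) with 1-7-nt loops within a 45-nt register, merged per
  locus and annotated with region overlap and signed splice-site distance.
* **Fluorescence binding classification** (`peakEmission`,
  `compareToFree`, `boundFraction`) — emission-peak enhancement and shift
  versus the free ligand under a one-site mass-action model; binder =
  fold >= 3 and |shift| >= 20 nm.
* **Pipeline** (`runPipeline`, `readRunConfig`) — one seeded,
  deterministic simulate → quantify → index → summarize run with manifest,
  TSV outputs and a text report. A thin CLI wrapper lives at
  `inst/scripts/quadfoot.R`.

## Worked example

```r
library(quadfoot)

out <- runPipeline(list(seed = 1, scenario = "paper_mimic_Q2Q5"),
                   outDir = "run1")
out$regionSummary
#>           region n_positions n_flagged n_positive n_negative    density
#> 1        P1_stem           0         0          0          0         NA
#> 2             Q2          25        15         15          0 0.60000000
#> 3        L3_loop          41         0          0          0 0.00000000
#> 4             Q5          25        19          8         11 0.76000000
#> 5 threeSS_region           1         0          0          0 0.00000000
#> 6    unannotated         408         1          0          1 0.00245098
```

Every flagged Q2 position is positive (the ligand stabilizes the Q2 G4),
Q5 shows both signs (restructuring), and the flag density is far higher in
the two G4 regions than anywhere else; the single unannotated flag is the
expected false-positive background of a 2-SD rule.

```r
out$splice[, c("ligand", "concentration", "fraction_xs")]
#>    ligand concentration fraction_xs
#> 1 control             0   0.1497032
#> 2  ligand            40   0.7987296
```

After guanine correction, the X_S share of mRNA rises from ~15% to ~80%
at the 40 uM dose (the planted truth is 15% and 80%; deviations are the
simulated 2% gel noise).

```r
out$binding[, c("sample_id", "fold_vs_free", "shift_nm", "call")]
#>     sample_id fold_vs_free  shift_nm       call
#> 1 full_length        15.00 +64.9        binder
#> 2         X_S        12.00 +64.8        binder
#> 3         X_L         9.00 +64.8        binder
#> 4      intron         1.00  +0.0    non-binder
#> 5     threeSS         1.00  +0.0    non-binder
```

Only the G4-containing domains bind: 15-fold peak enhancement and a
~65-nm red shift (493 → ~558 nm) for the full-length RNA, nothing for the
intron and 3'SS domains.

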
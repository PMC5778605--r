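---
title: "Methods: footprinting indices, guanine-corrected splicing and binding spectra"
author: "quadfoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprinting indices, guanine-corrected splicing and binding spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfoot)
```

# The scientific problem

Guanine-rich tracts in pre-mRNA can fold into four-stranded G-quadruplexes
(G4s). In Bcl-X pre-mRNA two such tracts (conventionally called Q2 and Q5)
sit next to the two alternative 5' splice sites of exon 2: the X_S site,
whose use yields the pro-apoptotic short isoform, and the X_L site, which
yields the anti-apoptotic long isoform. Small-molecule G4 stabilizers can
shift the equilibrium between competing secondary structures and the G4,
and thereby shift splice-site choice. Demonstrating this requires four
quantitative readouts, which this package implements end to end:

1. **Where does the ligand remodel the RNA?** Enzymatic footprinting with a
   duplex-specific ribonuclease (V1) and a single-strand-specific one (T2),
   each with and without ligand, quantified per nucleotide and summarized by
   a cleavage index with an empirical null.
2. **Does splice-site choice shift?** Radiolabeled in vitro splicing gels,
   where band intensity confounds molar amount with guanosine content and
   must be corrected before computing isoform fractions.
3. **Where could G4s form?** A motif scanner for four G-tracts in close
   proximity.
4. **Does the ligand bind the RNA, and where?** Fluorescence emission
   spectra of the ligand alone and with RNA domains, classified by peak
   enhancement and shift.

Because the original gels and spectra are in-house data, the package ships
a synthetic-data generator that emulates each instrument readout with known
ground truth; all statistical validation is against that truth.

# The cleavage index and its empirical null

For each analyzed nucleotide $p$ the index is

$$ I(p) \;=\; \frac{V1_\mathrm{lig}(p)\,/\,V1_\mathrm{ctl}(p)}
                   {T2_\mathrm{lig}(p)\,/\,T2_\mathrm{ctl}(p)}. $$

The T2 ratio in the denominator cancels lane-loading differences and local
accessibility, so $I(p) > 1$ indicates increased duplex/stacked character
upon ligand binding and $I(p) < 1$ the reverse. Logarithms of $I$ are fit
with a plain mean and sample standard deviation over **all** analyzed
positions — deliberately including true changes, exactly as practitioners
fit such nulls — and positions with $|\log I - \hat\mu| > k\hat\sigma$
(default $k = 2$, strict inequality) are flagged with the sign of the
deviation.

Numerical conventions:

* **Log base.** Base 10, recorded in the output metadata. Flags are
  base-invariant because $z$-scores are scale-free.
* **Zeros.** Default pseudocount $\varepsilon = 0$ with exclusion (and
  counting) of any position carrying a zero or missing intensity; a
  configurable $\varepsilon > 0$ keeps them instead. Exclusion is chosen
  because a zero in a ratio statistic is an artifact of detection limits,
  not evidence.
* **Contamination of the null.** Fitting the null on all positions makes
  the SD grow with the fraction of truly changed positions, which costs
  power but never validity of the "unchanged" calls. The optional robust
  null (median / 1.4826 MAD, `fitNull(robust = TRUE)`) is provided but off
  by default, to match standard practice for this statistic.
* **Ties at exactly $k\sigma$** are not flagged (strict inequality); with
  continuous data ties have measure zero, but the convention is fixed.
* **One ligand concentration per run.** The index is defined for a single
  ligand concentration against its control; dose series are independent
  runs.

Two properties are load-bearing and tested: multiplying any single lane by
$c > 0$ shifts all log indices by a constant and changes no $z$ and no
flag; and swapping ligand and control lanes maps $I \to 1/I$, negating all
$z$-scores and exchanging flag signs.

# Gel-lane quantification

The band-quantification layer plays the role SAFA/OptiQuant played for the
original phosphor images, on a 1-D lane densitometry trace. Bands are local
maxima above a prominence threshold (a fraction of the maximum density,
default 5%); each is fit by least squares over the window between its
flanking local minima with a single Gaussian plus a free constant offset.
The offset absorbs residual baseline and the tails of neighbouring bands,
which at gel-like separations (three or more band widths) keeps area errors
well under the 5% round-trip tolerance the tests enforce. The reported area
is the analytic integral $A\sigma\sqrt{2\pi}$, so truncation by the window
does not bias it. An optional rolling-minimum baseline (morphological
opening) handles constant or slowly varying backgrounds.

Nucleotide assignment interpolates piecewise-linearly between anchor pairs
(nucleotide, migration center) — the sequencing-ladder registration step —
assigning each band the nucleotide with the nearest predicted center,
enforcing monotone assignments, and resolving collisions in favour of the
larger-area band. Positions not quantified in all four lanes are dropped
and counted; they are never imputed as zeros, which would detonate the
ratio statistic.

# Guanine-corrected splicing quantification

Body-labeling with [alpha-32P]GTP makes band intensity proportional to
molar amount times guanosine count, so raw intensities overweight G-rich
species. `gCount()` counts G residues in the species body; the cap G
contributed by the GpppG dinucleotide is **not** counted, because the cap
is added from unlabeled GpppG rather than labeled GTP. Dividing intensity
by G count gives molar-scale amounts, from which the package reports the
X_S fraction of mRNA, the spliced fraction, tidy dose-response tables
(replicates aggregated as mean and sample SD), and the ligand-induced
relative change in the usage of each site. Usage is a molar site fraction;
the denominator defaults to total RNA (pre-mRNA plus both mRNAs) when the
pre-mRNA band is available, else total mRNA — the choice is exposed because
gel figures in this field are ambiguous about it.

# G4 candidate scanning

A candidate is at least four maximal runs of $\geq 3$ G separated by loops
of 1-7 nt within a 45-nt register, the standard quadruplex-pattern
convention. Tracts are *maximal* G-runs, so loops may contain isolated Gs
shorter than a tract but never a full tract. Overlapping registers are
merged into one candidate per locus reporting the full tract decomposition;
a merged candidate can exceed the single-register span limit when registers
chain, so the span constraint applies per register. RNA is scanned on the
given strand only. The scanner is validated against an exhaustive
substring-enumeration oracle on randomized G-enriched sequences.

# Two-state binding spectra

Binding is one-site mass action: the complex concentration solves
$x^2 - (R + L + K_d)x + RL = 0$ with the physical root, and the bound
fraction of ligand is $x/L$. A spectrum is the bound-fraction-weighted sum
of two emission Gaussians (free species centred at 493 nm, bound at
558 nm, both sd 25 nm by default, excitation 321 nm). Peak readout uses an
optional moving average plus quadratic interpolation around the grid
argmax; a sample is called a binder when its peak is at least 3-fold
enhanced **and** shifted by at least 20 nm versus the free-ligand
spectrum. Those thresholds are package choices — the underlying experiments
report a qualitative contrast (strong enhancement plus a 65-nm shift for
binding domains, essentially none for non-binding ones), not a cutoff — and
both are configurable.

A modelling note on the preset panel: with 1 uM RNA, 20 uM ligand and
$K_d = 1$ uM, only ~4.7% of the ligand is bound, so reproducing a 15-fold
peak enhancement requires the bound species to emit ~300-fold more strongly
than free — which is exactly the physics of turn-on fluorophores. The
preset calibrates the bound amplitude (by root-finding on the noiseless
composite maximum) so the full-length sample shows exactly 15-fold
enhancement; the apparent peak shift is then ~64.9 nm rather than 65.0,
because the free-peak tail pulls the composite maximum slightly
bluewards. The quadruplex-disrupted mutant domain presets keep a residual
1.5-fold signal, below the binder threshold.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions everywhere else.

* **Transcript.** A 681-nt layout with two planted G4 blocks (Q2 at
  141-165, Q5 at 441-465) adjacent to two splice sites (X_S at 180, X_L at
  480), plus stem/loop decoy regions. Flanks are G4-free by construction
  (no G-run of 3 is ever emitted outside planted regions), so scanner hits
  identify planted regions exactly. The real Bcl-X sequence is not
  reproduced — only the geometry matters to every downstream statistic.
* **Footprinting.** Latent per-position reactivities are lognormal
  (sd 0.5 natural log) per enzyme; planted effects multiply the ligand
  condition within a region (the ligand-mimicking scenario uses V1
  fold 2.5 across Q2, and 2.5 over the 5' half / 0.4 over the 3' half of
  Q5, giving the all-positive-Q2 / mixed-Q5 signature). Observed intensity
  is lane scale x reactivity x lognormal noise with mean 1 and CV
  `noiseCV` (default 0.1). The noise is multiplicative because gel
  intensities are strictly positive with lane-level multiplicative
  artifacts; under it the null log index is exactly Gaussian with SD
  $2\sqrt{\ln(1+cv^2)}/\ln 10$ (0.0866 at CV 0.1), so the 2-SD rule flags
  $2(1-\Phi(2)) \approx 4.55\%$ of null positions — the calibration the
  acceptance tests check. The number of analyzed positions (primer
  coverage) is a free parameter; the pipeline default covers positions
  101-600.
* **Lane traces.** One Gaussian per nucleotide, spacing shrinking
  geometrically (factor 0.998 per band from 10 a.u.) and width growing
  linearly (from 1 by 0.01 per band), emulating gel compression and
  diffusion. Defaults keep bands ~7-10 widths apart, comfortably inside
  the quantifier's tested regime.
* **Splicing gels.** Intensity = molar x G-count x lognormal noise. The
  scenario presets conserve total RNA at 1 molar unit (suppressed splicing
  returns molecules to the pre-mRNA pool): the wild-type-mimicking preset
  moves the X_S share of mRNA from 15% to 80% at the 40 uM dose; the Q2.2
  mutant preset removes the X_S response but keeps X_L down-regulation;
  the Q5.2 mutant largely removes the X_L response.
* **What the simulator does not emulate:** primer-extension chemistry and
  its sequence biases, 2-D gel geometry, RNase sequence preferences beyond
  the duplex/single-strand dichotomy, band-shape asymmetry, and correlated
  (smile/streak) noise. Passing tests therefore certify the statistics and
  their calibration under a clean multiplicative-noise model, not
  robustness to every gel pathology.

# Problem sizes and determinism

All simulations are desk-scale and single-process. The acceptance checks
use 5,000-position null footprints across 20 replicate simulations for the
calibration check, a 20-position planted effect in a 300-position
footprint across 20 replicates for recovery (pre-validated analytically:
power ~0.89, outside false-positive rate ~0.4% against the 0.70 / 1%
thresholds), 100 random tables up to 10^4 positions for oracle
equivalence, 1,000 randomized invariance trials, and 1,000 random 200-nt
sequences for scanner-oracle agreement. Every random draw flows from an
explicit integer seed; stage seeds are derived arithmetically from the run
seed, and identical (config, seed) reproduce byte-identical outputs, which
the pipeline tests verify literally.

# Known limitations

* The empirical null loses power as the truly-changed fraction grows
  (inflated SD); with ~10% of positions changed, per-position detection at
  fold 2.5 and noise CV 0.1 is ~60-90% depending on coverage. The robust
  null mitigates this but departs from standard practice, so it is opt-in.
* The band fitter assumes approximately Gaussian, well-separated bands;
  heavily overlapped doublets (< 2 widths apart) are resolved only as well
  as the valley between them allows.
* No multiple-testing correction beyond the 2-SD rule, by design: the
  statistic is reported exactly as the field uses it.
* Binder classification from a single-point spectrum cannot estimate
  $K_d$; titration fitting is an extension hook, not implemented.
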
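#' Named simulation scenarios
#'
#' Scenario presets bundle the planted footprinting effects, splicing-gel
#' truth and fluorescence panel for a run:
#' \describe{
#'   \item{`null`}{no planted changes anywhere; used for null calibration.}
#'   \item{`paper_mimic_Q2Q5`}{ligand stabilizes the Q2 G4 (all-positive
#'     cleavage-index changes) and restructures Q5 (mixed positive and
#'     negative changes); X_S usage of total mRNA rises from 15% to 80% at
#'     the high ligand dose; the X_S and X_L domains bind the ligand, the
#'     intron and 3'SS domains do not.}
#'   \item{`mutant_Q2.2`}{the Q2 quadruplex is disrupted (GG->UU-style
#'     compensating mutant): no Q2 footprint effect, X_S up-regulation lost
#'     while X_L down-regulation persists; the X_S domain loses most of its
#'     binding signal.}
#'   \item{`mutant_Q5.2`}{the Q5 quadruplex is disrupted: no Q5 footprint
#'     effect, X_L down-regulation largely lost; the X_L domain loses most
#'     of its binding signal.}
#' }
#'
#' @return character vector of scenario names.
#' @export
scenarioNames <- function() {
  c("null", "paper_mimic_Q2Q5", "mutant_Q2.2", "mutant_Q5.2", "custom")
}

#' Planted footprinting effect plan for a scenario
#'
#' The wild-type-mimicking plan increases duplex-specific (V1) cleavage
#' 2.5-fold across all of Q2 (all positive index changes), and splits Q5
#' into a stabilized 5' half (V1 x2.5, positive) and a destabilized 3' half
#' (V1 x0.4, negative), reproducing the mixed-sign signature of ligand-driven
#' restructuring. Mutant scenarios drop the effect in the disrupted region.
#'
#' @param scenario one of [scenarioNames()].
#' @param transcript an [AnnotatedTranscript-class] with `Q2`/`Q5` regions.
#' @param fold magnitude of the planted V1 fold change (default 2.5).
#' @return effect data.frame for [simulateFootprint()] (NULL for `null`).
#' @export
scenarioEffects <- function(scenario, transcript, fold = 2.5) {
  scenario <- match.arg(scenario, scenarioNames())
  if (scenario %in% c("null", "custom")) return(NULL)
  rg <- transcript@regions
  stopifnot(all(c("Q2", "Q5") %in% names(rg)))
  i2 <- match("Q2", names(rg)); i5 <- match("Q5", names(rg))
  q2 <- c(IRanges::start(rg)[i2], IRanges::end(rg)[i2])
  q5 <- c(IRanges::start(rg)[i5], IRanges::end(rg)[i5])
  mid <- q5[1L] + (q5[2L] - q5[1L]) %/% 2L
  q2Eff <- data.frame(region = NA_character_, start = q2[1L], end = q2[2L],
                      enzyme = "V1", fold = fold,
                      stringsAsFactors = FALSE)
  q5Eff <- data.frame(region = NA_character_,
                      start = c(q5[1L], mid + 1L), end = c(mid, q5[2L]),
                      enzyme = "V1", fold = c(fold, 1 / fold),
                      stringsAsFactors = FALSE)
  switch(scenario,
         paper_mimic_Q2Q5 = rbind(q2Eff, q5Eff),
         `mutant_Q2.2` = q5Eff,
         `mutant_Q5.2` = q2Eff)
}

#' True molar composition of the splicing gel for a scenario
#'
#' Returns the per-condition true molar amounts (arbitrary molar units) and
#' species G counts. In the wild-type-mimicking scenario the X_S share of
#' total mRNA is 15% without ligand and 80% at the 40 uM dose. In
#' `mutant_Q2.2` the ligand no longer up-regulates X_S but still
#' down-regulates X_L; in `mutant_Q5.2` X_L down-regulation is largely lost
#' and X_S stimulation is blunted.
#'
#' @param scenario one of [scenarioNames()] (`custom` not supported here).
#' @return list with `conditions` (named list of molar vectors per
#'   condition), `gCounts`, and `concentrations` (uM per condition).
#' @export
spliceGelPreset <- function(scenario = "paper_mimic_Q2Q5") {
  scenario <- match.arg(scenario, setdiff(scenarioNames(), "custom"))
  gCounts <- c(pre_mRNA = 170L, mRNA_XL = 140L, mRNA_XS = 120L)
  # total RNA is conserved at 1 molar unit: unspliced molecules stay in the
  # pre-mRNA pool, so suppressing one mRNA raises pre-mRNA, not the other
  mRNA <- 0.45
  mk <- function(xl, xs) c(pre_mRNA = 1 - xl - xs, mRNA_XL = xl,
                           mRNA_XS = xs)
  control <- mk(mRNA * 0.85, mRNA * 0.15)
  xl0 <- unname(control["mRNA_XL"]); xs0 <- unname(control["mRNA_XS"])
  conds <- switch(scenario,
    null = list(control = control, ligand_40uM = control),
    paper_mimic_Q2Q5 = list(control = control,
      ligand_40uM = mk(mRNA * 0.20, mRNA * 0.80)),
    # Q2 G4 gone: X_S output unchanged, X_L still down-regulated
    `mutant_Q2.2` = list(control = control,
      ligand_40uM = mk(xl0 * 0.35, xs0)),
    # Q5 G4 gone: X_L nearly unchanged, X_S stimulation blunted
    `mutant_Q5.2` = list(control = control,
      ligand_40uM = mk(xl0 * 0.9, xs0 * 2)))
  list(conditions = conds, gCounts = gCounts,
       concentrations = c(control = 0, ligand_40uM = 40))
}

#' Fluorescence domain panel preset
#'
#' Builds the free-ligand spectrum and the per-domain sample spectra of the
#' binding panel: the two G4-containing domains (`X_S`, containing Q2, and
#' `X_L`, containing Q5) bind with kd 1 uM and strong bound-state emission;
#' the `intron` and `threeSS` domains do not bind; the quadruplex-disrupted
#' mutant domains (`Q2.2_XS`, `Q5.2_XL`) retain only a sub-threshold
#' residual signal. Bound-state amplitudes are calibrated so the noiseless
#' full-length sample shows exactly `fullLengthFold` peak enhancement at the
#' mass-action bound fraction for 1 uM RNA + 20 uM ligand.
#'
#' @param scenario one of [scenarioNames()]; mutants reduce the
#'   corresponding domain to the residual signal.
#' @param noiseSD additive spectral noise sd (a.u.).
#' @param seed integer seed.
#' @param fullLengthFold target fold enhancement of the full-length sample
#'   (default 15).
#' @param includeMutants also emit the mutant-domain spectra.
#' @return list with `free` (an [EmissionSpectrum-class]), `samples`
#'   (named list of spectra: `full_length`, `X_S`, `X_L`, `intron`,
#'   `threeSS`, ...), and `truths`.
#' @export
fluorPanelPreset <- function(scenario = "paper_mimic_Q2Q5", noiseSD = 0,
                             seed = 1, fullLengthFold = 15,
                             includeMutants = FALSE) {
  scenario <- match.arg(scenario, setdiff(scenarioNames(), "custom"))
  kdBind <- 1; kdNone <- 1e6
  rna <- 1; lig <- 20
  f <- boundFraction(kdBind, rna, lig)
  calA <- function(fold) calibrateBoundIntensity(fold, f)
  grid <- seq(400, 700, by = 1)
  domains <- list(
    full_length = list(kd = kdBind, A = calA(fullLengthFold)),
    X_S = list(kd = kdBind, A = calA(12)),
    X_L = list(kd = kdBind, A = calA(9)),
    intron = list(kd = kdNone, A = 1),
    threeSS = list(kd = kdNone, A = 1))
  if (scenario == "mutant_Q2.2") domains$X_S$A <- calA(1.5)
  if (scenario == "mutant_Q5.2") domains$X_L$A <- calA(1.5)
  if (includeMutants) {
    domains$Q2.2_XS <- list(kd = kdBind, A = calA(1.5))
    domains$Q5.2_XL <- list(kd = kdBind, A = calA(1.5))
  }
  freeTruth <- SpectrumTruth(kd = kdNone, rnaConc = 0, ligandConc = lig)
  free <- simulateSpectrum(freeTruth, grid, noiseSD,
                           seed = deriveSeed(seed, 901L),
                           sampleId = "free_ligand")
  truths <- lapply(domains, function(d)
    SpectrumTruth(kd = d$kd, rnaConc = rna, ligandConc = lig,
                  boundPeak = c(558, d$A)))
  samples <- lapply(seq_along(truths), function(i)
    simulateSpectrum(truths[[i]], grid, noiseSD,
                     seed = deriveSeed(seed, 901L + i),
                     sampleId = names(domains)[i]))
  names(samples) <- names(domains)
  list(free = free, samples = samples, truths = truths)
}
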
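test_that("gCount counts guanosines and rejects invalid sequences", {
  expect_identical(gCount("GGAUG"), 3L)
  expect_identical(gCount(Biostrings::RNAString("GGGGG")), 5L)
  expect_identical(gCount("AAUU"), 0L)
  expect_error(gCount("ACGX"), "characters")
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "U"), 1000, TRUE), collapse = "")
  expect_identical(gCount(s),
                   sum(strsplit(s, "")[[1]] == "G"))
})

test_that("guanine correction recovers molar fractions from labeled intensities", {
  tbl <- data.frame(species = c("mRNA_XS", "mRNA_XL"),
                    intensity = c(30, 140), g_count = c(60L, 140L))
  res <- correctAndFraction(tbl)
  expect_equal(res$molar_xs, 0.5)
  expect_equal(res$molar_xl, 1.0)
  expect_equal(res$fraction_xs, 1 / 3)
  expect_true(is.na(res$spliced_fraction))
  # a species with zero g count would be invisible on the gel
  tbl$g_count[1] <- 0L
  expect_error(correctAndFraction(tbl), "g_count")
  # both mRNAs zero -> fraction reported missing, not 0/0
  res0 <- correctAndFraction(data.frame(
    species = c("mRNA_XS", "mRNA_XL"), intensity = c(0, 0),
    g_count = c(60L, 140L)))
  expect_true(is.na(res0$fraction_xs))
})

test_that("equimolar species show the g-ratio bias uncorrected and 0.5 corrected", {
  gel <- simulateSpliceGel(c(mRNA_XS = 1, mRNA_XL = 1),
                           c(mRNA_XS = 120L, mRNA_XL = 60L),
                           noiseCV = 0, seed = 1)
  corrected <- correctAndFraction(gel)
  expect_equal(corrected$fraction_xs, 0.5)
  uncorrected <- correctAndFraction(gel, gCorrection = FALSE)
  expect_equal(uncorrected$fraction_xs, 2 / 3)
})

test_that("preset X_S fractions of 15% and 80% are recovered exactly at noise 0", {
  preset <- spliceGelPreset("paper_mimic_Q2Q5")
  out <- vapply(names(preset$conditions), function(cond) {
    gel <- simulateSpliceGel(preset$conditions[[cond]], preset$gCounts,
                             noiseCV = 0, seed = 1)
    correctAndFraction(gel)$fraction_xs
  }, numeric(1))
  expect_equal(unname(out), c(0.15, 0.80), tolerance = 1e-12)
})

test_that("noisy gels recover the planted fraction on average across seeds", {
  preset <- spliceGelPreset("paper_mimic_Q2Q5")
  fr <- vapply(1:100, function(s) {
    gel <- simulateSpliceGel(preset$conditions$control, preset$gCounts,
                             noiseCV = 0.1, seed = s)
    correctAndFraction(gel)$fraction_xs
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.15), 2 * se + 1e-3)
})

test_that("dose-response tables aggregate replicates with mean and sample SD", {
  mk <- function(f, conc) data.frame(
    ligand = if (conc > 0) "drug" else "control", concentration = conc,
    fraction_xs = f, spliced_fraction = 0.5, molar_pre = 1,
    molar_xl = 1 - f, molar_xs = f, stringsAsFactors = FALSE)
  tbl <- doseResponse(list(mk(0.1, 10), mk(0.15, 10), mk(0.2, 10),
                           mk(0.12, 0)))
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$concentration, c(0, 10))  # zero condition first
  expect_equal(tbl$fraction_xs[2], 0.15)
  expect_equal(tbl$fraction_xs_sd[2], 0.05)
  expect_equal(tbl$n_replicates, c(1L, 3L))
  one <- doseResponse(list(mk(0.3, 5)))
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$fraction_xs_sd))
})

test_that("relative change is the ratio of molar site usage, 1 when nothing changes", {
  ctl <- correctAndFraction(data.frame(
    species = c("pre_mRNA", "mRNA_XL", "mRNA_XS"),
    intensity = c(55, 30, 15), g_count = c(100L, 100L, 100L)))
  expect_equal(relativeChange(ctl, ctl, "XS"), 1.0)
  expect_equal(relativeChange(ctl, ctl, "XL"), 1.0)
  # forced arithmetic: usage 0.45 vs 0.15 of total -> 3.0
  lig <- correctAndFraction(data.frame(
    species = c("pre_mRNA", "mRNA_XL", "mRNA_XS"),
    intensity = c(25, 30, 45), g_count = c(100L, 100L, 100L)))
  expect_equal(relativeChange(lig, ctl, "XS", denominator = "total"), 3.0)
  zero <- correctAndFraction(data.frame(
    species = c("mRNA_XL", "mRNA_XS"), intensity = c(10, 0),
    g_count = c(100L, 100L)))
  expect_true(is.na(relativeChange(ctl, zero, "XS")))
})

test_that("quadruplex-disrupted mutant presets lose only the adjacent site's response", {
  run <- function(scenario) {
    preset <- spliceGelPreset(scenario)
    res <- lapply(names(preset$conditions), function(cond)
      correctAndFraction(
        simulateSpliceGel(preset$conditions[[cond]], preset$gCounts,
                          noiseCV = 0, seed = 1)))
    list(xs = relativeChange(res[[2]], res[[1]], "XS"),
         xl = relativeChange(res[[2]], res[[1]], "XL"))
  }
  q22 <- run("mutant_Q2.2")
  expect_equal(q22$xs, 1, tolerance = 0.1)   # X_S response removed
  expect_lt(q22$xl, 0.8)                     # X_L still down-regulated
  wt <- run("paper_mimic_Q2Q5")
  expect_gt(wt$xs, 2)
  expect_lt(wt$xl, 0.5)
  q52 <- run("mutant_Q5.2")
  expect_gt(q52$xl, 0.8)                     # X_L down-regulation lost
})

test_that("fractions are invariant to a common lane scale", {
  tbl <- data.frame(species = c("pre_mRNA", "mRNA_XL", "mRNA_XS"),
                    intensity = c(50, 30, 20),
                    g_count = c(170L, 140L, 120L))
  a <- correctAndFraction(tbl)
  tbl$intensity <- tbl$intensity * 123.4
  b <- correctAndFraction(tbl)
  expect_equal(b$fraction_xs, a$fraction_xs, tolerance = 1e-12)
  expect_equal(b$spliced_fraction, a$spliced_fraction, tolerance = 1e-12)
})
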
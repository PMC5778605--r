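test_that("peak location is recovered with sub-grid precision", {
  grid <- seq(400, 700, 1)
  sp <- new("EmissionSpectrum", sampleId = "s", excitation = 321,
            wavelength = grid,
            intensity = 4 * exp(-(grid - 558.4)^2 / (2 * 25^2)))
  pk <- peakEmission(sp)
  expect_equal(pk$peak_nm, 558.4, tolerance = 0.1)
  expect_equal(pk$peak_intensity, 4, tolerance = 1e-3)
  flat <- new("EmissionSpectrum", sampleId = "f", excitation = 321,
              wavelength = grid, intensity = rep(2, length(grid)))
  expect_true(is.na(peakEmission(flat)$peak_nm))
})

test_that("noisy peak localization error is close to a dense-grid argmax oracle", {
  grid <- seq(400, 700, 1)
  dense <- seq(400, 700, 0.01)
  truthCenter <- 558
  errPkg <- errOracle <- numeric(50)
  set.seed(33)
  for (i in 1:50) {
    noise <- rnorm(length(grid), 0, 0.05)
    y <- 5 * exp(-(grid - truthCenter)^2 / (2 * 25^2)) + noise
    sp <- new("EmissionSpectrum", sampleId = "s", excitation = 321,
              wavelength = grid, intensity = pmax(0, y))
    errPkg[i] <- peakEmission(sp, smoothWindow = 7L)$peak_nm - truthCenter
    yd <- approx(grid, pmax(0, y), xout = dense)$y
    errOracle[i] <- dense[which.max(yd)] - truthCenter
  }
  rmse <- function(e) sqrt(mean(e^2))
  # quadratic-interpolated peak should do at least comparably to the
  # raw dense-grid argmax of the same noisy data
  expect_lt(rmse(errPkg), rmse(errOracle) * 1.2)
})

test_that("identical spectra give fold 1, shift 0 and a non-binder call", {
  grid <- seq(400, 700, 1)
  sp <- new("EmissionSpectrum", sampleId = "a", excitation = 321,
            wavelength = grid,
            intensity = exp(-(grid - 493)^2 / (2 * 25^2)))
  out <- compareToFree(sp, sp)
  expect_equal(out$fold_vs_free, 1)
  expect_equal(out$shift_nm, 0)
  expect_equal(out$call, "non-binder")
})

test_that("binder thresholds are strict on both fold and shift", {
  grid <- seq(400, 700, 1)
  mk <- function(center, amp) new("EmissionSpectrum", sampleId = "x",
    excitation = 321, wavelength = grid,
    intensity = amp * exp(-(grid - center)^2 / (2 * 25^2)))
  free <- mk(493, 1)
  expect_equal(compareToFree(mk(558, 2.9), free)$call, "non-binder")
  expect_equal(compareToFree(mk(493 + 19, 10), free)$call, "non-binder")
  expect_equal(compareToFree(mk(493 + 20, 3), free)$call, "binder")
})

test_that("fold and shift are invariant to a common intensity scale", {
  panel <- fluorPanelPreset("paper_mimic_Q2Q5")
  a <- compareToFree(panel$samples$X_S, panel$free)
  scale <- function(sp, c) { sp@intensity <- sp@intensity * c; sp }
  b <- compareToFree(scale(panel$samples$X_S, 41),
                     scale(panel$free, 41))
  expect_equal(b$fold_vs_free, a$fold_vs_free, tolerance = 1e-9)
  expect_equal(b$shift_nm, a$shift_nm, tolerance = 1e-9)
})

test_that("bound fraction solves the one-site quadratic and is monotone", {
  # closed form vs independent bisection on the mass-action equation
  for (kd in c(0.01, 0.3, 1, 10, 300)) {
    for (R in c(0.2, 1, 5)) {
      for (L in c(0.5, 20)) {
        expect_equal(boundFraction(kd, R, L),
                     oracleBoundFraction(kd, R, L), tolerance = 1e-9)
      }
    }
  }
  expect_equal(boundFraction(1e12, 1, 20), 0, tolerance = 1e-9)
  expect_equal(boundFraction(1, 0, 20), 0)
  expect_equal(boundFraction(1, 1, 0), 0)
  # monotone decreasing in kd, increasing in RNA
  kds <- c(0.1, 1, 10, 100)
  f1 <- vapply(kds, boundFraction, numeric(1), rnaTotal = 1,
               ligandTotal = 20)
  expect_true(all(diff(f1) < 0))
  rnas <- c(0.1, 1, 5, 20)
  f2 <- vapply(rnas, function(R) boundFraction(1, R, 20), numeric(1))
  expect_true(all(diff(f2) > 0))
  expect_error(boundFraction(0, 1, 1), "kd")
})

test_that("the noiseless binding preset reproduces the printed enhancement and shift", {
  panel <- fluorPanelPreset("paper_mimic_Q2Q5", noiseSD = 0)
  fl <- compareToFree(panel$samples$full_length, panel$free)
  expect_equal(fl$fold_vs_free, 15, tolerance = 0.01)
  expect_equal(fl$shift_nm, 65, tolerance = 1)
  expect_equal(fl$call, "binder")
})

test_that("only the G4-containing domains are called binders in the panel", {
  panel <- fluorPanelPreset("paper_mimic_Q2Q5", includeMutants = TRUE)
  domains <- c("X_S", "X_L", "intron", "threeSS")
  calls <- vapply(domains, function(d)
    compareToFree(panel$samples[[d]], panel$free)$call, character(1))
  expect_identical(unname(calls[c("X_S", "X_L")]), rep("binder", 2))
  expect_identical(unname(calls[c("intron", "threeSS")]),
                   rep("non-binder", 2))
  # quadruplex-disrupted mutant domains keep only a sub-threshold signal
  for (m in c("Q2.2_XS", "Q5.2_XL"))
    expect_equal(compareToFree(panel$samples[[m]], panel$free)$call,
                 "non-binder")
})
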
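# Isotope-distribution validation: identity, discrimination, invariances.

selfSpectrum <- function(hyp, scale = 1e5, prune = 1e-3) {
  pat <- nativeTDP:::.hypothesisPattern(hyp, prune)
  data.frame(mz = pat$mz, intensity = pat$abund * scale)
}

test_that("a self-generated noiseless pattern scores exactly 1", {
  hyp <- list(composition = "C120H190N30O40S2", charge = 2)
  f <- fitIsotopes(selfSpectrum(hyp), hyp)
  expect_equal(f$fitScore, 1.0, tolerance = 1e-9)
  expect_true(f$detected)
})

test_that("a +1 Da wrong hypothesis always scores lower, noise-free", {
  set.seed(41)
  for (i in 1:20) {
    mass <- runif(1, 2000, 16000)
    z <- sample(1:3, 1)
    hyp <- list(mass = mass, charge = z)
    spec <- selfSpectrum(hyp)
    right <- fitIsotopes(spec, hyp)
    wrong <- fitIsotopes(spec, list(mass = mass, charge = z, massShift = 1.0))
    expect_lt(wrong$fitScore, right$fitScore)
  }
})

test_that("5% intensity noise keeps the score above 0.9 in >= 95% of cases", {
  set.seed(43)
  hyp <- list(mass = 8000, charge = 1)
  base <- selfSpectrum(hyp)
  ok <- replicate(200, {
    noisy <- base
    noisy$intensity <- noisy$intensity * exp(rnorm(nrow(base), 0, 0.05))
    fitIsotopes(noisy, hyp)$fitScore > 0.9
  })
  expect_gte(mean(ok), 0.95)
})

test_that("score is scale-invariant and degrades with noise amplitude", {
  hyp <- list(composition = "C200H320N55O60S1", charge = 2)
  base <- selfSpectrum(hyp)
  f1 <- fitIsotopes(base, hyp)
  scaled <- base; scaled$intensity <- scaled$intensity * 1234.5
  f2 <- fitIsotopes(scaled, hyp)
  expect_equal(f1$fitScore, f2$fitScore, tolerance = 1e-9)
  set.seed(47)
  meanScore <- vapply(c(0, 0.02, 0.05, 0.10), function(s) {
    mean(replicate(40, {
      noisy <- base
      noisy$intensity <- noisy$intensity * exp(rnorm(nrow(base), 0, s))
      fitIsotopes(noisy, hyp)$fitScore
    }))
  }, 0)
  expect_true(all(diff(meanScore) < 0))
})

test_that("an ion absent at the base isotopologue is flagged not detected", {
  hyp <- list(mass = 5000, charge = 1)
  empty <- data.frame(mz = 100, intensity = 1)
  f <- fitIsotopes(empty, hyp)
  expect_false(f$detected)
  expect_equal(f$fitScore, 0)
})

test_that("hypothesis comparison ranks and flags ties", {
  # holo-generated data prefer the holo hypothesis over apo
  apo <- list(mass = 12000, charge = 2)
  holo <- list(mass = 12000, charge = 2, metals = c(Cu = 1))
  spec <- selfSpectrum(holo)
  r <- compareHypotheses(spec, list(apo = apo, holo = holo))
  expect_identical(r$hypothesis[1], "holo")
  # identical hypotheses tie
  r2 <- compareHypotheses(spec, list(a = holo, b = holo))
  expect_true(all(r2$tied))
  # acetyl vs trimethyl (0.0364 Da) at coarse tolerance: indistinguishable
  ac <- list(mass = 8000, charge = 1, massShift = 42.01057)
  tm <- list(mass = 8000, charge = 1, massShift = 42.04695)
  spec3 <- selfSpectrum(ac)
  r3 <- compareHypotheses(spec3, list(acetyl = ac, trimethyl = tm),
                          mzTol = 0.3, tieTol = 0.02)
  expect_true(all(r3$tied))
})
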
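# Exact mass chemistry: compositions, modification deltas, metal adducts,
# isotope distributions, averagine.

test_that("composition masses match standard isotope arithmetic", {
  # 2 x 1.0078250319 + 15.9949146221
  expect_equal(compositionMass("H2O")[["mono"]], 18.0105647, tolerance = 1e-6)
  expect_equal(compositionMass(character(0))[["mono"]], 0)
  expect_equal(compositionMass("C2H3NO")[["mono"]], 57.02146, tolerance = 1e-5)
  expect_error(compositionMass(c(Xx = 1)), "Xx")
  expect_error(parseFormula("C2H!O"), "malformed")
})

test_that("composition arithmetic is element-wise and never negative", {
  a <- parseFormula("C2H3NO")
  b <- parseFormula("H2O")
  expect_equal(addComposition(a, b)[["H"]], 5)
  expect_error(subtractComposition(b, parseFormula("N2")), "negative")
  # additivity of masses
  set.seed(42)
  for (i in 1:20) {
    x <- elementalComposition(c(C = sample(0:30, 1), H = sample(1:50, 1),
                                N = sample(0:10, 1), O = sample(0:10, 1),
                                S = sample(0:3, 1)))
    y <- elementalComposition(c(C = sample(1:30, 1), H = sample(0:50, 1)))
    expect_equal(compositionMass(addComposition(x, y))[["mono"]],
                 compositionMass(x)[["mono"]] + compositionMass(y)[["mono"]],
                 tolerance = 1e-6)
  }
})

test_that("built-in modification registry carries the standard deltas", {
  expected <- c(acetyl = 42.01057, methyl = 14.01565, dimethyl = 28.03130,
                trimethyl = 42.04695, phospho = 79.96633,
                deamidation = 0.98402, nitrosyl = 28.99017,
                `met-loss` = -131.04049, disulfide = -2.01565)
  for (nm in names(expected))
    expect_equal(modDelta(nm)@monoMass, expected[[nm]], tolerance = 1e-5)
  # additivity and difference arithmetic
  expect_equal(2 * modDelta("acetyl")@monoMass, 84.02113, tolerance = 1e-5)
  expect_equal(modDelta("dimethyl")@monoMass - modDelta("methyl")@monoMass,
               14.01565, tolerance = 1e-5)
  expect_error(modDelta("frobnicate"), "acetyl")  # error lists known names
})

test_that("every registered composition-backed delta is self-consistent", {
  for (nm in knownMods()) {
    d <- modDelta(nm)
    if (!length(d@gain) && !length(d@loss)) next
    mono <- compositionMass(d@gain)[["mono"]] - compositionMass(d@loss)[["mono"]]
    expect_lt(abs(mono - d@monoMass), 1e-4)
  }
})

test_that("registry is extensible at run time and from config", {
  registerMod("test-succinyl", gain = "C4H4O3", targets = "K")
  expect_equal(modDelta("test-succinyl")@monoMass, 100.01604,
               tolerance = 1e-5)
  cfg <- tempfile(fileext = ".yaml")
  writeLines(paste0(
    "- name: test-glygly\n  gain: C4H6N2O2\n  targets: [K]\n",
    "- name: test-custom\n  mono_mass: 123.4\n"), cfg)
  loadModConfig(cfg)
  expect_equal(modDelta("test-glygly")@monoMass, 114.04293, tolerance = 1e-5)
  expect_equal(modDelta("test-custom")@monoMass, 123.4)
})

test_that("metal adduct deltas follow proton-displacement bookkeeping", {
  expect_equal(metalAdductDelta("Cu", 2), 60.91395, tolerance = 1e-5)
  expect_equal(metalAdductDelta("Zn", 2), 61.91349, tolerance = 1e-5)
  expect_equal(metalAdductDelta("Cu", 0), 62.92960, tolerance = 1e-5)
  expect_equal(metalAdductDelta("Cu"), metalAdductDelta("Cu", 2))  # default 2
  expect_error(metalAdductDelta("Pb"), "unsupported")
})

test_that("isotope distributions are normalized, binned and correct", {
  d <- isotopeDistribution("H2O", prune = 0)
  expect_gt(d$abund[which.min(abs(d$mass - 18.011))], 0.99)
  expect_equal(sum(d$abund), 1, tolerance = 1e-9)
  expect_true(all(diff(d$mass) > 0))
  # binomial term ratio for C100: one 13C vs all 12C
  d2 <- isotopeDistribution("C100", prune = 0)
  expect_equal(d2$abund[2] / d2$abund[1], 100 * 0.0107 / 0.9893,
               tolerance = 1e-3)
  expect_error(isotopeDistribution(character(0)), "empty")
  expect_error(isotopeDistribution("H2O", prune = 1), "prune")
})

test_that("distribution of a sum equals convolution of distributions", {
  combos <- list(c("C10H20", "N5O3"), c("C3H5NOS", "C6H12N2O"),
                 c("H2O", "C2H3NO"))
  for (cb in combos) {
    joint <- isotopeDistribution(
      addComposition(parseFormula(cb[1]), parseFormula(cb[2])), prune = 0)
    a <- isotopeDistribution(cb[1], prune = 0)
    b <- isotopeDistribution(cb[2], prune = 0)
    # convolve a and b by outer sum/product, re-bin at nominal masses
    mass <- as.numeric(outer(a$mass, b$mass, `+`))
    ab <- as.numeric(outer(a$abund, b$abund, `*`))
    key <- round(mass)
    conv <- rowsum(ab, key)
    idx <- match(round(joint$mass), as.numeric(rownames(conv)))
    expect_lt(max(abs(joint$abund - conv[idx])), 1e-9)
  }
})

test_that("averagine composition scales to the target mass", {
  u <- averagineComposition(111.1254)
  expect_equal(unname(u[["C"]]), 5)
  expect_lt(abs(compositionMass(u)[["mono"]] - 111.1254), 0.6)
  m <- averagineComposition(11112.54)
  expect_lt(abs(compositionMass(m)[["mono"]] - 11112.54), 0.5)
  big <- averagineComposition(37000, type = "avg")
  expect_lt(abs(compositionMass(big)[["avg"]] - 37000), 1)
})
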
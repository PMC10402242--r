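# Proteoform/complexoform data model, mass arithmetic and text notation.

test_that("proteoform mass = residues + water + deltas", {
  expect_equal(proteoformMass(Proteoform("GG"))[["mono"]], 132.05349,
               tolerance = 1e-5)
  pAc <- Proteoform("GG", ntermMod = "acetyl")
  expect_equal(proteoformMass(pAc)[["mono"]], 174.06406, tolerance = 1e-5)
  # any sequence with one disulfide loses 2 H
  pSS <- Proteoform("ACKGCG", disulfides = c(2, 5))
  expect_equal(proteoformMass(pSS)[["mono"]],
               proteoformMass(Proteoform("ACKGCG"))[["mono"]] - 2.01565,
               tolerance = 1e-5)
  expect_error(Proteoform("GXG"), "non-canonical")
})

test_that("proteoform validity enforces site compatibility and structure", {
  expect_error(Proteoform("GGG", siteMods = data.frame(position = 9,
                                                       name = "acetyl")),
               "outside")
  expect_error(Proteoform("GKG", siteMods = data.frame(position = 1,
                                                       name = "acetyl")),
               "not allowed")
  expect_error(Proteoform("GKG", disulfides = c(1, 2)), "cysteine")
  expect_silent(Proteoform("GKG", siteMods = data.frame(
    position = NA_integer_, name = "acetyl", localized = FALSE)))
})

test_that("unlocalized modifications count toward mass regardless of site", {
  pu <- Proteoform("GKG", siteMods = data.frame(position = NA_integer_,
                                                name = "acetyl",
                                                localized = FALSE))
  pl <- Proteoform("GKG", siteMods = data.frame(position = 2, name = "acetyl"))
  expect_equal(proteoformMass(pu), proteoformMass(pl))
})

test_that("complexoform mass is additive and permutation-invariant", {
  a <- Proteoform("GGGG"); b <- Proteoform("AKGA")
  m <- function(cf) complexoformMass(cf)[["mono"]]
  expect_equal(m(Complexoform(list(a, a))),
               2 * proteoformMass(a)[["mono"]], tolerance = 1e-9)
  expect_equal(m(Complexoform(list(a, b, a))), m(Complexoform(list(b, a, a))))
  # dimer + Cu + Zn at default displacement
  expect_equal(m(Complexoform(list(a, a), metals = c(Cu = 1L, Zn = 1L))),
               2 * proteoformMass(a)[["mono"]] + 122.82744, tolerance = 1e-4)
  expect_error(Complexoform(list()), "at least one")
})

test_that("mass is strictly monotonic under positive-mass modification", {
  set.seed(7)
  for (i in 1:25) {
    p <- randomProteoform()
    chars <- strsplit(baseSequence(p), "")[[1]]
    kpos <- setdiff(which(chars == "K"), siteMods(p)$position)
    if (!length(kpos)) next
    p2 <- Proteoform(baseSequence(p), ntermMod = p@ntermMod,
                     siteMods = rbind(siteMods(p),
                                      data.frame(position = kpos[1],
                                                 name = "acetyl",
                                                 localized = TRUE)))
    expect_gt(proteoformMass(p2)[["mono"]], proteoformMass(p)[["mono"]])
  }
})

test_that("methyl vs dimethyl candidates are mass-distinguishable", {
  cs <- strsplit(strrep("SAVKGELTIDQR", 6), "")[[1]]
  cs[c(55, 63)] <- "K"
  base <- paste(cs, collapse = "")
  mk <- function(m55) Proteoform(base, siteMods = data.frame(
    position = c(4L, 55L, 63L), name = c("acetyl", m55, "acetyl")))
  d <- proteoformMass(mk("dimethyl"))[["mono"]] -
    proteoformMass(mk("methyl"))[["mono"]]
  expect_equal(d, 14.01565, tolerance = 1e-5)
  expect_gt(abs(d), 1e-3)  # well above matching tolerance at these masses
})

test_that("notation round-trips through parse/serialize", {
  p <- parseProteoform("{acetyl}-AK[acetyl]G")
  expect_equal(proteoformMass(p)[["mono"]],
               proteoformMass(Proteoform("AKG"))[["mono"]] + 2 * 42.010565,
               tolerance = 1e-5)
  expect_equal(siteMods(p)$position, 2L)
  expect_identical(serializeProteoform(p), "{acetyl}-AK[acetyl]G")
  expect_identical(baseSequence(parseProteoform("GG")), "GG")
  set.seed(11)
  for (i in 1:100) {
    q <- randomProteoform()
    s <- serializeProteoform(q)
    q2 <- parseProteoform(s)
    expect_identical(serializeProteoform(q2), s)
    expect_equal(proteoformMass(q2), proteoformMass(q))
  }
  expect_error(parseProteoform("AK[ox"), "character")
  expect_error(parseProteoform("A!G"), "character 2")
})

test_that("canonical coordinate mapping follows truncation records", {
  p <- Proteoform("AKG", truncation = c(2L, 4L))
  expect_equal(canonicalPosition(p, 1:3), 2:4)
  # a site called C80 on a Met-cleaved form is C81 canonically
  q <- Proteoform("AKG", ntermMod = "met-loss")
  expect_equal(canonicalPosition(q, 80L), 81L)
})

test_that("FASTA reading returns named sequences", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">sp1 test protein", "GGKA", "VVT", ">sp2", "MKLV"), f)
  s <- readFasta(f)
  expect_identical(s[["sp1"]], "GGKAVVT")
  expect_identical(s[["sp2"]], "MKLV")
})

test_that("stoichiometry records summarize subunits, mods and metals", {
  a <- Proteoform("GKGG", proteinId = "A",
                  siteMods = data.frame(position = 2, name = "acetyl"))
  b <- Proteoform("AKGA", proteinId = "B", ntermMod = "acetyl")
  st <- stoichiometryRecord(Complexoform(list(a, a, b),
                                         metals = c(Zn = 1L)))
  expect_equal(st$proteins[["A"]], 2L)
  expect_equal(st$proteins[["B"]], 1L)
  expect_equal(st$mods[["acetyl"]], 3L)
  expect_equal(st$metals[["Zn"]], 1L)
})
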
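# HCD b/y ladders, fragment matching, coverage maps, P-score,
# PTM localization and metal-site inference.

test_that("b/y ladders obey complementarity and modification shifts", {
  l <- generateByLadder(Proteoform("GG"))
  expect_equal(l$neutral_mass[l$series == "b" & l$index == 1], 57.02146,
               tolerance = 1e-5)
  expect_equal(l$neutral_mass[l$series == "y" & l$index == 1], 75.03203,
               tolerance = 1e-5)
  # acetyl at residue 2: b1 unshifted, b2.. shifted, y complementary
  p <- Proteoform("AKGAV", siteMods = data.frame(position = 2,
                                                 name = "acetyl"))
  l0 <- generateByLadder(Proteoform("AKGAV"))
  l1 <- generateByLadder(p)
  b0 <- l0$neutral_mass[l0$series == "b"]; b1 <- l1$neutral_mass[l1$series == "b"]
  expect_equal(b1[1], b0[1])
  expect_equal(b1[2:4], b0[2:4] + 42.010565, tolerance = 1e-6)
})

test_that("complementarity b_i + y_(n-i) = M holds over random proteoforms", {
  set.seed(5)
  for (i in 1:100) {
    p <- randomProteoform()
    M <- proteoformMass(p)[["mono"]]
    l <- generateByLadder(p)
    b <- l[l$series == "b", ]
    y <- l[l$series == "y", ]
    n <- nchar(baseSequence(p))
    for (k in seq_len(nrow(b))) {
      yk <- y$neutral_mass[y$index == n - b$index[k]]
      expect_equal(b$neutral_mass[k] + yk, M, tolerance = 1e-6)
    }
  }
})

test_that("intact disulfides suppress intra-loop cleavage and shift spanning fragments", {
  cs <- strsplit(strrep("GAVTKLESDIQF", 14), "")[[1]]
  cs[57] <- "C"; cs[111] <- "C"
  p <- Proteoform(paste(cs, collapse = ""), disulfides = c(57, 111))
  l <- generateByLadder(p)
  b <- l[l$series == "b", ]
  expect_false(any(b$index %in% 57:110))
  # a fragment spanning the whole loop carries the -2.01565 delta
  pr <- Proteoform(paste(cs, collapse = ""))
  lr <- generateByLadder(pr)
  b144 <- b$neutral_mass[b$index == 144]
  b144r <- lr$neutral_mass[lr$series == "b" & lr$index == 144]
  expect_equal(b144, b144r - 2.01565, tolerance = 1e-5)
  # reduced mode ignores disulfides
  lred <- generateByLadder(p, disulfideMode = "reduced")
  expect_true(any(lred$index[lred$series == "b"] %in% 57:110))
})

test_that("fragment matching is one-to-one, nearest-first, apo-preferred", {
  p <- Proteoform("AKGAVTLESK")
  l <- generateByLadder(p)
  m <- matchFragments(l, l$neutral_mass)
  expect_equal(nrow(m), nrow(l))
  expect_true(all(abs(m$ppm_error) < 1e-9))
  # decoys at > 50 ppm stay unmatched
  dec <- l$neutral_mass * (1 + 60e-6)
  m2 <- matchFragments(l, c(l$neutral_mass, dec), tolPpm = 10)
  expect_equal(nrow(m2), nrow(l))
  # two theoreticals within tolerance of one observed: smaller |ppm| wins
  theo <- data.frame(series = "b", index = 1:2, start = 1L, end = 1:2,
                     metals = "", neutral_mass = c(1000.000, 1000.005))
  m3 <- matchFragments(theo, 1000.001, tolPpm = 10)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$neutral_mass, 1000.000)
  # apo preferred over holo on an exact tie
  theo2 <- data.frame(series = "b", index = c(5, 9), start = 1L,
                      end = c(5, 9), metals = c("Cu", ""),
                      neutral_mass = c(1500, 1500))
  m4 <- matchFragments(theo2, 1500)
  expect_identical(m4$metals, "")
})

test_that("holo ladders enumerate metal submultisets up to the cap", {
  p <- Proteoform("AKGAVTLESK")
  l <- generateByLadder(p, metals = c(Cu = 1, Zn = 1))
  expect_setequal(unique(l$metals), c("", "Cu", "Zn", "Cu,Zn"))
  l2 <- generateByLadder(p, metals = c(Cu = 1, Zn = 1), maxHoloMetals = 1)
  expect_setequal(unique(l2$metals), c("", "Cu", "Zn"))
})

test_that("coverage counts cleavable bonds with fragment evidence", {
  p <- Proteoform("AKGAVTLESK")
  l <- generateByLadder(p)
  full <- coverageAndMap(p, matchFragments(l, l$neutral_mass))
  expect_equal(full$coverage, 1.0)
  bhalf <- l[l$series == "b" & l$index <= 4, ]
  half <- coverageAndMap(p, matchFragments(l, bhalf$neutral_mass))
  expect_equal(half$coverage, 4 / 9, tolerance = 1e-9)
  expect_match(half$map, "A K G A V")
  # disulfide-excluded bonds are omitted from the denominator by default
  pss <- Proteoform("ACKGACVTLK", disulfides = c(2, 6))
  lss <- generateByLadder(pss)
  css <- coverageAndMap(pss, matchFragments(lss, lss$neutral_mass))
  expect_equal(css$coverage, 1.0)
  cin <- coverageAndMap(pss, matchFragments(lss, lss$neutral_mass),
                        countDisulfideBonds = TRUE)
  expect_lt(cin$coverage, 1.0)
})

test_that("planted PTMs are localized by bracketing fragments", {
  set.seed(13)
  sites_ok <- 0; total <- 0
  for (i in 1:100) {
    seqstr <- randomSequence(30)
    chars <- strsplit(seqstr, "")[[1]]
    kpos <- which(chars == "K")
    if (!length(kpos)) next
    s <- kpos[sample(length(kpos), 1)]
    truthP <- Proteoform(seqstr, siteMods = data.frame(position = s,
                                                       name = "acetyl"))
    obs <- generateByLadder(truthP)$neutral_mass
    cand <- Proteoform(seqstr, siteMods = data.frame(
      position = NA_integer_, name = "acetyl", localized = FALSE))
    res <- localizeMods(cand, obs)
    total <- total + 1
    if (res[[1]]$status == "localized" && identical(res[[1]]$sites, s))
      sites_ok <- sites_ok + 1
    # soundness: never a *wrong* exclusive localization, and an ambiguity
    # set (accidental isobaric fragment within the ppm window) must still
    # contain the planted site
    if (res[[1]]$status == "localized")
      expect_identical(res[[1]]$sites, s)
    else
      expect_true(s %in% res[[1]]$sites)
  }
  expect_gt(total, 50)
  expect_gte(sites_ok / total, 0.9)  # exact localization in the vast majority
})

test_that("shift without bracketing fragments stays identified-not-localized", {
  p <- Proteoform("AKGAVKTLES", siteMods = data.frame(
    position = NA_integer_, name = "acetyl", localized = FALSE))
  # only unshifted small fragments observed: no bracketing pair
  base <- generateByLadder(Proteoform("AKGAVKTLES"))
  obs <- base$neutral_mass[base$series == "b" & base$index == 1]
  res <- localizeMods(p, obs)
  expect_identical(res[[1]]$status, "identified-not-localized")
  # two candidate sites both bracketed-consistent: ambiguity, no choice
  truthP <- Proteoform("AKGAVKTLES", siteMods = data.frame(position = 2,
                                                           name = "acetyl"))
  obs2 <- generateByLadder(truthP)$neutral_mass
  # drop fragments distinguishing K2 from K6: keep b1 and b6..; y., delta on all
  keep <- c(generateByLadder(truthP)$neutral_mass[1],
            obs2[c(6:9, 15:18)])
  res2 <- localizeMods(p, keep)
  expect_true(res2[[1]]$status %in% c("ambiguous", "identified-not-localized"))
})

test_that("characterization levels follow the decision table", {
  expect_identical(characterizationLevel(1e-9, 2, 2), "1")
  expect_identical(characterizationLevel(1e-9, 1, 0), "2A")
  expect_identical(characterizationLevel(1e-9, 1, 1, candidateAmbiguity = TRUE),
                   "2B")
  expect_identical(characterizationLevel(1e-9, modCountUncertain = TRUE), "3")
  expect_identical(characterizationLevel(0.5), "4")
  expect_identical(characterizationLevel(NA), "5")
})

test_that("metal intervals contain planted coordinating sets", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(60:120, 1)
    seqstr <- randomSequence(n)
    sites <- sort(sample(seq(10, n - 10), sample(2:4, 1)))
    p <- Proteoform(seqstr)
    lad <- generateByLadder(p, metals = c(Zn = 1))
    spans <- lad$start <= min(sites) & lad$end >= max(sites)
    obs <- c(lad$neutral_mass[spans & lad$metals == "Zn"],
             lad$neutral_mass[!spans & lad$metals == ""])
    m <- matchFragments(lad, obs)
    got <- metalLocalization(m, n)
    expect_identical(got$Zn$status, "localized")
    expect_lte(got$Zn$interval[1], min(sites))
    expect_gte(got$Zn$interval[2], max(sites))
  }
  # no holo ions -> unlocalized; contradictory evidence -> inconsistent
  p <- Proteoform(randomSequence(40))
  lad <- generateByLadder(p, metals = c(Cu = 1))
  apoOnly <- matchFragments(lad, lad$neutral_mass[lad$metals == ""])
  expect_length(metalLocalization(apoOnly, 40), 0)
  contra <- lad[(lad$series == "b" & lad$metals == "Cu" & lad$index == 10) |
                  (lad$series == "b" & lad$metals == "" & lad$index == 20), ]
  m <- matchFragments(lad, contra$neutral_mass)
  got <- metalLocalization(m, 40)
  expect_identical(got$Cu$status, "inconsistent")
})
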
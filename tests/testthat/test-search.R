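# Search-space expansion and intact-mass complexoform enumeration.

test_that("expansion counts modification multisets at mass level", {
  # one mod allowed 0-1x: two mass-distinct proteoforms
  sp <- expandSearchSpace(list(proteins = list(list(
    id = "P", sequence = "GKGKG",
    mods = list(list(name = "acetyl", max = 1))))))
  expect_length(sp$proteoforms, 2)
  # acetyl <= 2 and methyl <= 1: 3 x 2 = 6
  sp2 <- expandSearchSpace(list(proteins = list(list(
    id = "P", sequence = "KKKKGG",
    mods = list(list(name = "acetyl", max = 2),
                list(name = "methyl", max = 1))))))
  expect_length(sp2$proteoforms, 6)
  # deterministic, duplicate-free, stable ordering
  sp3 <- expandSearchSpace(list(proteins = list(list(
    id = "P", sequence = "KKKKGG",
    mods = list(list(name = "acetyl", max = 2),
                list(name = "methyl", max = 1))))))
  expect_identical(vapply(sp2$proteoforms, serializeProteoform, ""),
                   vapply(sp3$proteoforms, serializeProteoform, ""))
  # cap overflow names the protein
  expect_error(
    expandSearchSpace(list(proteins = list(list(
      id = "BIGP", sequence = "KKKKGG",
      mods = list(list(name = "acetyl", max = 3),
                  list(name = "methyl", max = 3))))), cap = 3),
    "BIGP")
})

test_that("met-loss and truncations expand sequence variants", {
  sp <- expandSearchSpace(list(proteins = list(list(
    id = "P", sequence = "MKGAVT", met_loss = TRUE,
    truncations = list(c(3, 6))))))
  seqs <- vapply(sp$proteoforms, baseSequence, "")
  expect_setequal(seqs, c("MKGAVT", "KGAVT", "GAVT"))
})

test_that("candidate enumeration finds the unique matching stoichiometry", {
  sp <- expandSearchSpace(list(
    proteins = list(list(id = "A", sequence = "GGGG"),
                    list(id = "B", sequence = "GGGA")),
    stoichiometry = list(min = 3, max = 3)))
  mA <- proteoformMass(Proteoform("GGGG"))[["mono"]]
  mB <- proteoformMass(Proteoform("GGGA"))[["mono"]]
  r <- enumerateCandidates(sp, 2 * mA + mB, tol = 0.01)
  expect_equal(nrow(r), 1)
  expect_equal(r$error_da, 0, tolerance = 1e-9)
  expect_equal(r$n_subunits, 3)
  st <- stoichiometryRecord(r$complexoform[[1]])
  expect_equal(st$proteins[["A"]], 2L)
  expect_equal(st$proteins[["B"]], 1L)
  # far-off mass: empty result, not an error
  expect_equal(nrow(enumerateCandidates(sp, 1234.5, tol = 0.5)), 0)
})

test_that("metal multisets participate in matching", {
  sp <- expandSearchSpace(list(
    proteins = list(list(id = "S", sequence = "GGGGGGGG")),
    metals = list(Cu = 1, Zn = 1),
    stoichiometry = list(min = 2, max = 2)))
  m <- proteoformMass(Proteoform("GGGGGGGG"))[["mono"]]
  r <- enumerateCandidates(sp, 2 * m + 122.827, tol = 0.01)
  expect_equal(nrow(r), 1)
  cf <- r$complexoform[[1]]
  expect_equal(length(subunits(cf)), 2)
  expect_equal(metals(cf), c(Cu = 1L, Zn = 1L))
})

test_that("enumeration agrees exactly with the brute-force oracle", {
  set.seed(23)
  for (rep in 1:20) {
    sp <- randomSearchSpace()
    # probe masses: some planted sums, some random
    planted <- sum(sample(sp$mono, min(2, length(sp$mono))))
    for (obs in c(planted, runif(1, min(sp$mono), 3 * max(sp$mono)))) {
      got <- enumerateCandidates(sp, obs, tol = 1.0)
      keys <- sort(vapply(seq_len(nrow(got)), function(i)
        candidateKey(got[i, ]), ""))
      expect_identical(keys, bruteForceSearch(sp, obs, 1.0))
    }
  }
})

test_that("match set grows monotonically with tolerance", {
  set.seed(31)
  sp <- randomSearchSpace()
  obs <- sum(sample(sp$mono, 2))
  r1 <- enumerateCandidates(sp, obs, tol = 0.5)
  r2 <- enumerateCandidates(sp, obs, tol = 2.0)
  k1 <- vapply(seq_len(nrow(r1)), function(i) candidateKey(r1[i, ]), "")
  k2 <- vapply(seq_len(nrow(r2)), function(i) candidateKey(r2[i, ]), "")
  expect_true(all(k1 %in% k2))
})

test_that("ranked output is invariant to subunit input order", {
  mk <- function(order_) expandSearchSpace(list(
    proteins = order_,
    stoichiometry = list(min = 2, max = 3)))
  pA <- list(id = "A", sequence = "GKGAVT",
             mods = list(list(name = "acetyl", max = 1)))
  pB <- list(id = "B", sequence = "AKGAVT")
  spaceAB <- mk(list(pA, pB)); spaceBA <- mk(list(pB, pA))
  obs <- proteoformMass(Proteoform("GKGAVT"))[["mono"]] +
    proteoformMass(Proteoform("AKGAVT"))[["mono"]]
  rAB <- enumerateCandidates(spaceAB, obs, tol = 1)
  rBA <- enumerateCandidates(spaceBA, obs, tol = 1)
  expect_identical(rAB$label, rBA$label)
  expect_equal(rAB$rank, rBA$rank)
})

test_that("near-isobaric candidates share a rank as an ambiguity set", {
  sp <- expandSearchSpace(list(proteins = list(list(
    id = "P", sequence = "KKKKGG",
    mods = list(list(name = "acetyl", max = 1),
                list(name = "trimethyl", max = 1))))))
  obs <- proteoformMass(Proteoform("KKKKGG"))[["mono"]] + 42.01057
  r <- enumerateCandidates(sp, obs, tol = 1)
  stopifnot(nrow(r) >= 2)
  # acetyl and trimethyl (0.0364 Da apart) tie at rank 1
  top <- r[r$rank == 1, ]
  expect_equal(nrow(top), 2)
  expect_true(any(grepl("acetyl", top$label)) &&
                any(grepl("trimethyl", top$label)))
})

test_that("evidence tiers reflect available support", {
  expect_identical(classifyTier(TRUE, TRUE), "mass_and_fragments")
  expect_identical(classifyTier(TRUE, FALSE), "mass_only")
  expect_identical(classifyTier(FALSE), "observed_mass_only")
})
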
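# Synthetic-data generator: determinism, conservation laws, envelope
# placement and truth annotation.

test_that("same seed gives byte-identical output", {
  a <- makeFixtureSuite(seed = 5)
  b <- makeFixtureSuite(seed = 5)
  for (nm in names(a)) {
    expect_identical(a[[nm]]$run$truth, b[[nm]]$run$truth)
    for (i in seq_along(a[[nm]]$run$spectra))
      expect_identical(peaks(a[[nm]]$run$spectra[[i]]),
                       peaks(b[[nm]]$run$spectra[[i]]))
  }
  c <- makeFixtureSuite(seed = 6)
  expect_false(identical(a$tpi_like$run$truth, c$tpi_like$run$truth))
})

test_that("dissociation conserves mass and charge exactly", {
  fx <- makeFixtureSuite(seed = 9, mzNoiseSigma = 0, intensityNoiseSigma = 0,
                         decoyRate = 0, fragmentDetectability = 1)
  for (nm in c("tpi_like", "sod1_like", "mif_like")) {
    tr <- fx[[nm]]$run$truth
    ms1 <- tr[tr$kind == "complex", ]
    for (ms2id in unique(tr$spectrum_id[tr$kind %in% c("monomer", "remnant")])) {
      prod <- tr[tr$spectrum_id == ms2id, ]
      sp2 <- Filter(function(s) spectrumId(s) == ms2id,
                    fx[[nm]]$run$spectra)[[1]]
      zPre <- sp2@precursorCharge
      lab <- prod$species[1]
      M <- ms1$neutral_mass[ms1$species == lab][1]
      expect_equal(sum(prod$neutral_mass), M, tolerance = 1e-9)
      expect_equal(sum(prod$charge), zPre)
    }
  }
})

test_that("a 12+ trimer ejects a 6+ monomer under the default +2 bonus", {
  # proportional share 12/3 = 4, bonus +2
  expect_equal(nativeTDP:::.ejectCharge(12, 12330, 37000, 2), 6L)
  # an 11+ dimer gives 6+ under symmetric partition (bonus 0)
  expect_equal(nativeTDP:::.ejectCharge(11, 15860, 31600, 0), 6L)
  # clamped below the precursor charge
  expect_lte(nativeTDP:::.ejectCharge(5, 9000, 10000, 3), 4L)
})

test_that("MS1 envelopes land at the expected native m/z", {
  fx <- makeFixtureSuite(seed = 9, mzNoiseSigma = 0)
  ms1 <- fx$mif_like$run$spectra[[1]]
  tr <- fx$mif_like$run$truth
  t12 <- tr[tr$kind == "complex" & tr$charge == 12, ]
  expect_true(all(t12$mz > 3080 & t12$mz < 3100))
  # tpi dimer charge states cover the 3318-3539 window
  tp <- fx$tpi_like$run$truth
  tpc <- tp[tp$kind == "complex", ]
  expect_equal(sort(unique(tpc$charge)), c(15, 16))
  expect_true(all(tpc$mz > 3317 & tpc$mz < 3540))
})

test_that("every non-decoy peak carries a truth annotation", {
  fx <- makeFixtureSuite(seed = 9)
  for (nm in names(fx)) {
    run <- fx[[nm]]$run
    for (s in run$spectra) {
      tr <- run$truth[run$truth$spectrum_id == spectrumId(s), ]
      expect_equal(nrow(tr), length(s@mz))
      expect_equal(tr$mz, s@mz)
      nd <- tr[tr$kind != "decoy", ]
      expect_true(all(!is.na(nd$species)))
    }
  }
})

test_that("metals follow the retention rule in MS2 truth", {
  fx <- makeFixtureSuite(seed = 9)
  tr <- fx$sod1_like$run$truth
  mono <- tr[tr$kind == "monomer", ]
  expect_identical(mono$metals, "Cu,Zn")
  rem <- tr[tr$kind == "remnant", ]
  expect_identical(rem$metals, "")
  # remnant retention moves them to the complementary product
  fx2 <- makeFixtureSuite(seed = 9, metalRetention = "remnant")
  tr2 <- fx2$sod1_like$run$truth
  expect_identical(tr2$metals[tr2$kind == "monomer"], "")
  expect_identical(tr2$metals[tr2$kind == "remnant"], "Cu,Zn")
})

test_that("fixture files are written as plain text when requested", {
  d <- tempfile()
  fx <- makeFixtureSuite(outDir = d, seed = 5)
  expect_true(file.exists(file.path(d, "tpi_like.peaks.txt")))
  expect_true(file.exists(file.path(d, "sod1_like.truth.tsv")))
  expect_true(file.exists(file.path(d, "nutf2_like.space.yaml")))
  rt <- readPeaklist(file.path(d, "tpi_like.peaks.txt"))
  expect_equal(length(rt), length(fx$tpi_like$run$spectra))
  sp <- expandSearchSpace(file.path(d, "nutf2_like.space.yaml"))
  expect_gt(length(sp$proteoforms), 1)
})
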
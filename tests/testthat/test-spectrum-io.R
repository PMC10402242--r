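# Peak-list format round trips, mzML reading and the MS^n provenance chain.

makeChain <- function() {
  list(
    Spectrum("a", 1, mz = c(3318.1, 3539.2), intensity = c(100, 80),
             faimsCV = -40),
    Spectrum("b", 2, mz = 2645.5, intensity = 50, precursorId = "a",
             isoCenter = 3318.1, isoWidth = 10, precursorCharge = 16L,
             activation = "HCD"),
    Spectrum("b2", 2, mz = 2000.25, intensity = 20, precursorId = "a",
             isoCenter = 3539.2, isoWidth = 10, precursorCharge = 15L,
             activation = "HCD"),
    Spectrum("c", 3, mz = c(500.125, 600.5, 700.75), intensity = c(1, 2, 3),
             precursorId = "b", isoCenter = 2645.5, isoWidth = 4,
             precursorCharge = 6L, activation = "HCD"))
}

test_that("spectrum validity enforces ordering and provenance", {
  expect_error(Spectrum("x", 1, mz = c(2, 1), intensity = c(1, 1)), "sorted")
  expect_error(Spectrum("x", 1, mz = -1, intensity = 1), "> 0")
  expect_error(Spectrum("x", 2, mz = 1, intensity = 1), "precursor")
})

test_that("peak-list text format round-trips losslessly", {
  f <- tempfile(fileext = ".txt")
  sp <- makeChain()
  writePeaklist(sp, f)
  rt <- readPeaklist(f)
  expect_length(rt, 4)
  for (i in seq_along(sp)) {
    expect_identical(spectrumId(rt[[i]]), spectrumId(sp[[i]]))
    expect_equal(msLevel(rt[[i]]), msLevel(sp[[i]]))
    expect_equal(peaks(rt[[i]]), peaks(sp[[i]]), tolerance = 1e-6)
    expect_identical(precursorId(rt[[i]]), precursorId(sp[[i]]))
    expect_equal(rt[[i]]@precursorCharge, sp[[i]]@precursorCharge)
    expect_equal(rt[[i]]@faimsCV, sp[[i]]@faimsCV)
  }
  # empty file -> empty list
  f0 <- tempfile(); writeLines("# empty", f0)
  expect_length(readPeaklist(f0), 0)
  # malformed input errors carry line numbers
  fb <- tempfile()
  writeLines(c("BEGIN SPECTRUM id=x", "ms_level=1", "5.0 1.0", "2.0 1.0",
               "END SPECTRUM"), fb)
  expect_error(readPeaklist(fb), "line 5.*sorted")
  fb2 <- tempfile()
  writeLines(c("BEGIN SPECTRUM id=x", "5.0 -3.0", "END SPECTRUM"), fb2)
  expect_error(readPeaklist(fb2), "line 2")
})

test_that("round trip is identity on simulated runs", {
  fx <- makeFixtureSuite(seed = 3)
  f <- tempfile(fileext = ".txt")
  sp <- fx$mif_like$run$spectra
  writePeaklist(sp, f)
  rt <- readPeaklist(f)
  expect_length(rt, length(sp))
  for (i in seq_along(sp))
    expect_equal(rt[[i]]@mz, sp[[i]]@mz, tolerance = 1e-6)
})

test_that("hierarchy linking builds MS1->MS2->MS3 trees and flags problems", {
  h <- linkHierarchy(makeChain())
  expect_identical(h$roots, "a")
  expect_setequal(h$children[["a"]], c("b", "b2"))
  expect_identical(h$children[["b"]], "c")
  expect_length(h$orphans, 0)
  # MS1-only input -> singleton roots
  h1 <- linkHierarchy(list(Spectrum("x", 1, 100, 1), Spectrum("y", 1, 200, 1)))
  expect_setequal(h1$roots, c("x", "y"))
  expect_length(h1$children, 0)
  # dangling precursor
  expect_error(linkHierarchy(list(
    Spectrum("m", 2, 1, 1, precursorId = "ghost"))), "ghost")
})

test_that("mzML round trip preserves levels, linkage and FAIMS CV", {
  f <- tempfile(fileext = ".mzML")
  writeMzML(makeChain(), f)
  m <- readMzML(f)
  expect_length(m, 4)
  expect_equal(vapply(m, msLevel, 0L), c(1L, 2L, 2L, 3L))
  expect_equal(m[[1]]@faimsCV, -40)
  expect_equal(m[[2]]@precursorCharge, 16L)
  expect_equal(m[[4]]@mz, c(500.125, 600.5, 700.75), tolerance = 1e-9)
  # MS3 chain resolves back to the MS1 root
  h <- linkHierarchy(m)
  expect_identical(h$roots, spectrumId(m[[1]]))
  expect_length(h$orphans, 0)
  # absent precursor charge stays unknown
  sp <- makeChain()
  sp[[2]]@precursorCharge <- NA_integer_
  writeMzML(sp, f)
  m2 <- readMzML(f)
  expect_true(is.na(m2[[2]]@precursorCharge))
})
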
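## Ground-truthed synthetic native MS1/MS2/MS3 data: charge envelopes of
## intact assemblies, HCD subunit ejection with asymmetric charge partition,
## metal retention, MS3 b/y ladders, decoys and noise -- every emitted
## non-decoy peak carries a truth annotation.

#' Define a simulation
#'
#' @param species List of species entries, each a list with `complexoform`
#'   (a [Complexoform-class]), `abundance` (> 0), `charges` (MS1 charge
#'   states), and optionally `metalSites` (named list: metal -> coordinating
#'   residue positions on the ejected subunit, driving holo fragment
#'   emission) and `chargeBonus` / `metalRetention` overrides.
#' @param ejectChargeBonus Asymmetry bonus added to the ejected monomer's
#'   proportional charge share before rounding up (default +2, the native-MS
#'   asymmetric-partition behavior; clamped to `1..z-1`).
#' @param metalRetention `"monomer"` (default) or `"remnant"`: which MS2
#'   product keeps the bound metals.
#' @param fragmentDetectability Probability that each theoretical MS3
#'   fragment is emitted (default 0.8).
#' @param mzNoiseSigma Gaussian m/z noise SD in Th (default 0.001,
#'   high-resolution-Orbitrap-like centroid precision; applied uniformly in
#'   m/z, without m/z-dependent scaling).
#' @param intensityNoiseSigma Multiplicative log-normal intensity noise SD
#'   (default 0.05).
#' @param decoyRate Expected number of uniform decoy peaks added per MS3
#'   spectrum (default 5).
#' @param seed Random seed; fully determines the output.
#' @return A `SimulationSpec` (classed list).
#' @export
simulationSpec <- function(species, ejectChargeBonus = 2L,
                           metalRetention = c("monomer", "remnant"),
                           fragmentDetectability = 0.8,
                           mzNoiseSigma = 0.001,
                           intensityNoiseSigma = 0.05,
                           decoyRate = 5, seed = 1L) {
  metalRetention <- match.arg(metalRetention)
  stopifnot(length(species) >= 1)
  for (s in species) {
    stopifnot(is(s$complexoform, "Complexoform"),
              is.numeric(s$abundance), s$abundance > 0,
              all(s$charges >= 1))
  }
  structure(list(species = species, ejectChargeBonus = ejectChargeBonus,
                 metalRetention = metalRetention,
                 fragmentDetectability = fragmentDetectability,
                 mzNoiseSigma = mzNoiseSigma,
                 intensityNoiseSigma = intensityNoiseSigma,
                 decoyRate = decoyRate, seed = as.integer(seed)),
            class = "SimulationSpec")
}

## charge taken by the ejected monomer: ceil(z * m/M + bonus), clamped
.ejectCharge <- function(zComplex, mMono, mComplex, bonus) {
  z <- ceiling(zComplex * mMono / mComplex + bonus)
  max(1L, min(as.integer(z), as.integer(zComplex) - 1L))
}

#' Simulate a native MS1/MS2/MS3 run
#'
#' Emits one MS1 spectrum holding every species' charge envelope at
#' `mzFor(mass, z)`; per species and distinct subunit, an MS2 spectrum from
#' HCD of the most intense MS1 charge state containing the ejected monomer
#' and the complementary remnant (mass and charge conserved exactly before
#' noise; metals follow the retention rule); and per MS2, an MS3 spectrum of
#' the isolated monomer charge state holding its b/y ladder (holo forms
#' emitted for fragments spanning all coordinating residues of a metal),
#' thinned by the detectability probability, rendered singly protonated,
#' plus uniform decoy peaks. All spectra are linked by precursor metadata.
#'
#' @param spec A `SimulationSpec` from [simulationSpec()].
#' @return A list with `spectra` (list of [Spectrum-class]) and `truth`
#'   (data.frame: `spectrum_id`, `mz`, `kind`
#'   (complex/monomer/remnant/fragment/decoy), `species`, `subunit`,
#'   `series`, `index`, `metals`, `neutral_mass`, `charge`).
#' @export
simulateRun <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  spectra <- list()
  truth <- list()
  noiseMz <- function(mz) mz + stats::rnorm(length(mz), 0, spec$mzNoiseSigma)
  noiseInt <- function(i) i * exp(stats::rnorm(length(i), 0,
                                               spec$intensityNoiseSigma))
  addTruth <- function(...) truth[[length(truth) + 1L]] <<- data.frame(...)

  ## ---- MS1 ----
  ms1_mz <- numeric(0); ms1_int <- numeric(0); ms1_ann <- list()
  for (si in seq_along(spec$species)) {
    sp <- spec$species[[si]]
    cf <- sp$complexoform
    M <- complexoformMass(cf)[["mono"]]
    lab <- if (!is.na(cf@label)) cf@label else paste0("species", si)
    zs <- sort(as.integer(sp$charges))
    ## bell-shaped envelope over the charge set
    w <- stats::dnorm(seq_along(zs), mean = (length(zs) + 1) / 2, sd = 1)
    w <- w / max(w)
    for (k in seq_along(zs)) {
      ms1_mz <- c(ms1_mz, mzFor(M, zs[k]))
      ms1_int <- c(ms1_int, sp$abundance * w[k])
      ms1_ann[[length(ms1_ann) + 1L]] <- data.frame(
        kind = "complex", species = lab, subunit = NA_character_,
        series = NA_character_, index = NA_integer_, metals = "",
        neutral_mass = M, charge = zs[k])
    }
  }
  ms1_mz <- noiseMz(ms1_mz); ms1_int <- noiseInt(ms1_int)
  o <- order(ms1_mz)
  spectra$ms1 <- Spectrum("ms1", 1L, mz = ms1_mz[o], intensity = ms1_int[o])
  ann <- do.call(rbind, ms1_ann)[o, , drop = FALSE]
  addTruth(spectrum_id = "ms1", mz = ms1_mz[o], ann)

  ## ---- MS2 / MS3 per species and distinct subunit ----
  for (si in seq_along(spec$species)) {
    sp <- spec$species[[si]]
    cf <- sp$complexoform
    M <- complexoformMass(cf)[["mono"]]
    lab <- if (!is.na(cf@label)) cf@label else paste0("species", si)
    zsel <- sort(as.integer(sp$charges))[ceiling(length(sp$charges) / 2)]
    bonus <- sp$chargeBonus %||% spec$ejectChargeBonus
    retention <- sp$metalRetention %||% spec$metalRetention
    keys <- vapply(cf@subunits, serializeProteoform, "")

    ## single-subunit species: HCD at MS2 fragments the monomer directly
    if (length(cf@subunits) == 1L) {
      su <- cf@subunits[[1]]
      ms2id <- sprintf("ms2_%d_1", si)
      fragSpec <- .fragmentSpectrum(su, cf@metals, sp, spec)
      mz2n <- noiseMz(fragSpec$mz); int2n <- noiseInt(fragSpec$int)
      o2 <- order(mz2n)
      spectra[[ms2id]] <- Spectrum(
        ms2id, 2L, mz = mz2n[o2], intensity = int2n[o2],
        precursorId = "ms1",
        isoCenter = mzFor(complexoformMass(cf)[["mono"]], zsel),
        isoWidth = 10, precursorCharge = zsel, activation = "HCD")
      addTruth(spectrum_id = ms2id, mz = mz2n[o2],
               kind = fragSpec$kind[o2], species = lab, subunit = keys[1],
               series = fragSpec$series[o2], index = fragSpec$index[o2],
               metals = fragSpec$metals[o2],
               neutral_mass = fragSpec$neutral_mass[o2],
               charge = fragSpec$charge[o2])
      next
    }

    for (ui in which(!duplicated(keys))) {
      su <- cf@subunits[[ui]]
      m0 <- proteoformMass(su)[["mono"]]
      metalsOnMono <- if (retention == "monomer") cf@metals else
        stats::setNames(integer(0), character(0))
      mMono <- m0 + .metalSetMass(metalsOnMono)
      mRem <- M - mMono
      zMono <- .ejectCharge(zsel, mMono, M, bonus)
      zRem <- as.integer(zsel) - zMono
      ms2id <- sprintf("ms2_%d_%d", si, ui)
      mz2 <- c(mzFor(mMono, zMono), mzFor(mRem, zRem))
      int2 <- c(100, 60)
      mz2n <- noiseMz(mz2); int2n <- noiseInt(int2)
      o2 <- order(mz2n)
      spectra[[ms2id]] <- Spectrum(
        ms2id, 2L, mz = mz2n[o2], intensity = int2n[o2],
        precursorId = "ms1", isoCenter = mzFor(M, zsel), isoWidth = 10,
        precursorCharge = zsel, activation = "HCD")
      metalsOnRem <- cf@metals
      for (met in names(metalsOnMono))
        metalsOnRem[met] <- metalsOnRem[met] - metalsOnMono[met]
      metalsOnRem <- metalsOnRem[metalsOnRem > 0]
      addTruth(spectrum_id = ms2id, mz = mz2n[o2],
               kind = c("monomer", "remnant")[o2], species = lab,
               subunit = keys[ui], series = NA_character_, index = NA_integer_,
               metals = c(.metalLabel(metalsOnMono),
                          .metalLabel(metalsOnRem))[o2],
               neutral_mass = c(mMono, mRem)[o2],
               charge = c(zMono, zRem)[o2])

      ## ---- MS3 on the ejected monomer ----
      ms3id <- sprintf("ms3_%d_%d", si, ui)
      fragSpec <- .fragmentSpectrum(su, metalsOnMono, sp, spec)
      mz3n <- noiseMz(fragSpec$mz); int3n <- noiseInt(fragSpec$int)
      o3 <- order(mz3n)
      spectra[[ms3id]] <- Spectrum(
        ms3id, 3L, mz = mz3n[o3], intensity = int3n[o3],
        precursorId = ms2id, isoCenter = mzFor(mMono, zMono), isoWidth = 4,
        precursorCharge = zMono, activation = "HCD")
      addTruth(spectrum_id = ms3id, mz = mz3n[o3],
               kind = fragSpec$kind[o3], species = lab, subunit = keys[ui],
               series = fragSpec$series[o3], index = fragSpec$index[o3],
               metals = fragSpec$metals[o3],
               neutral_mass = fragSpec$neutral_mass[o3],
               charge = fragSpec$charge[o3])
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(spectra = unname(spectra), truth = truth)
}

## b/y ladder peaks (singly protonated) with holo forms for fragments
## spanning all coordinating residues of a retained metal, thinned by the
## detectability probability, plus uniform decoys
.fragmentSpectrum <- function(su, metalsOnFrag, sp, spec) {
  frag <- generateByLadder(su)
  if (length(metalsOnFrag) && !is.null(sp$metalSites)) {
    for (met in names(sp$metalSites)) {
      if (!met %in% names(metalsOnFrag)) next
      sites <- sp$metalSites[[met]]
      spans <- frag$start <= min(sites) & frag$end >= max(sites)
      frag$neutral_mass[spans] <- frag$neutral_mass[spans] +
        metalAdductDelta(met) * metalsOnFrag[[met]]
      frag$metals[spans] <- ifelse(nzchar(frag$metals[spans]),
                                   paste(frag$metals[spans], met, sep = ","),
                                   met)
    }
  }
  keep <- stats::runif(nrow(frag)) <= spec$fragmentDetectability
  frag <- frag[keep, , drop = FALSE]
  nDecoy <- stats::rpois(1, spec$decoyRate)
  mzr <- if (nrow(frag)) range(frag$neutral_mass + .PROTON) else c(200, 2000)
  dec_mz <- stats::runif(nDecoy, mzr[1], mzr[2])
  list(mz = c(frag$neutral_mass + .PROTON, dec_mz),
       int = c(stats::runif(nrow(frag), 30, 100),
               stats::runif(nDecoy, 5, 25)),
       kind = c(rep("fragment", nrow(frag)), rep("decoy", nDecoy)),
       series = c(frag$series, rep(NA_character_, nDecoy)),
       index = c(frag$index, rep(NA_integer_, nDecoy)),
       metals = c(frag$metals, rep("", nDecoy)),
       neutral_mass = c(frag$neutral_mass, rep(NA_real_, nDecoy)),
       charge = c(rep(1L, nrow(frag)), rep(NA_integer_, nDecoy)))
}
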
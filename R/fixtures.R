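## The standard synthetic fixture suite: four ground-truthed datasets
## emulating archetypal native top-down experiments. All sequences are
## SYNTHETIC stand-ins built from repeating motifs with site residues placed
## where the scenario needs them and short tuning tails; they are not the
## real proteins, only mass/topology look-alikes.

.motif <- function(pat, n) {
  x <- strsplit(strrep(pat, ceiling(n / nchar(pat))), "")[[1]]
  paste(x[seq_len(n)], collapse = "")
}

.placeResidues <- function(seqstr, at) {
  cs <- strsplit(seqstr, "")[[1]]
  for (i in seq_along(at)) cs[as.integer(names(at)[i])] <- at[[i]]
  paste(cs, collapse = "")
}

## ~26.5 kDa subunit whose deamidated homodimer hits 53,070.895 Da mono
## (two charge states, 15+/16+): Asn sites at 15 and 71, five C-terminal-
## region Lys->Gln swaps plus an S/G/A tail tune the mass.
.tpiLikeSequence <- function() {
  core <- .placeResidues(.motif("AKVLSEGTDFIR", 160), c("15" = "N", "71" = "N"))
  cs <- strsplit(core, "")[[1]]
  kpos <- rev(which(cs == "K"))[1:5]
  cs[kpos] <- "Q"
  paste0(paste(cs, collapse = ""), strrep("S", 7), strrep("G", 47),
         strrep("A", 80))
}

## ~12.3 kDa subunit (trimers land in the 12+ ~3080-3100 Th window):
## Lys77 acetylation site, Cys80 nitrosylation site.
.mifLikeSequence <- function() {
  core <- .placeResidues(.motif("AGVKSELTIDPR", 90), c("77" = "K", "80" = "C"))
  paste0(core, strrep("S", 18), strrep("G", 22))
}

## ~15.7 kDa metalloprotein subunit: His sites for Cu (46, 48, 63, 120) and
## Zn (63, 71, 80, D83), disulfide C57-C111, N-terminally acetylated.
.sod1LikeSequence <- function() {
  core <- .placeResidues(.motif("GAVTKLESDIQF", 140),
                         c("46" = "H", "48" = "H", "63" = "H", "120" = "H",
                           "71" = "H", "80" = "H", "83" = "D",
                           "57" = "C", "111" = "C"))
  paste0(core, strrep("S", 1), strrep("G", 1), strrep("A", 7))
}

## ~14.3 kDa subunit, Met-cleaved processed form with Lys sites 4, 55, 63
## (acetyl / methyl / dimethyl / trimethyl combinatorics).
.nutf2LikeSequence <- function() {
  core <- .placeResidues(.motif("SAVKGELTIDQR", 100),
                         c("4" = "K", "55" = "K", "63" = "K"))
  paste0(core, strrep("S", 15), strrep("G", 33), strrep("A", 4))
}

#' The standard ground-truthed fixture suite
#'
#' Builds four simulated native MS^n datasets covering the archetypal
#' scenarios of the engine, each with a [simulationSpec()], the simulated
#' run, a matching search-space definition and the planted truth:
#'
#' * `tpi_like` -- a 53,070.9 Da homodimer observed at 15+/16+, one subunit
#'   carrying two deamidations (N15, N71) to be localized from MS3.
#' * `mif_like` -- ~37 kDa trimers built from three subunit proteoforms
#'   (unmodified, K77-acetylated, C80-nitrosylated) in different
#'   arrangements, 12+/13+.
#' * `sod1_like` -- a homodimeric metalloprotein + Cu + Zn with an intact
#'   C57-C111 disulfide and planted coordinating residues; HCD ejects a 6+
#'   monomer from the 11+ complex with the metals retained.
#' * `nutf2_like` -- Met-cleaved subunits with K4/K55/K63
#'   acetyl/methyl/dimethyl combinatorics, a dimer plus a trimethyl-vs-
#'   acetyl near-isobaric monomer case.
#'
#' All sequences are synthetic stand-ins (see the source); the masses,
#' charge states, stoichiometries and modification topologies -- not the
#' sequences -- are the emulated features.
#'
#' @param outDir Optional directory: when given, each fixture's spectra are
#'   written as peak-list text (`<name>.peaks.txt`), the truth as TSV and
#'   the search space as YAML.
#' @param seed Seed for the simulations (one per fixture, derived).
#' @param ... Overrides passed to every [simulationSpec()] call (e.g.
#'   `mzNoiseSigma = 0` for noise-free fixtures).
#' @return Named list of fixtures, each with `name`, `spec`, `run`
#'   (spectra + truth), `space` (search-space list) and `planted` (labels of
#'   the planted complexoforms).
#' @export
makeFixtureSuite <- function(outDir = NULL, seed = 1L, ...) {
  out <- list()

  ## ---- tpi_like ----
  tseq <- .tpiLikeSequence()
  tA <- Proteoform(tseq, proteinId = "TPIL",
                   siteMods = data.frame(position = c(15L, 71L),
                                         name = "deamidation"))
  tB <- Proteoform(tseq, proteinId = "TPIL")
  tpiCf <- Complexoform(list(tA, tB), label = "tpi_like_dimer")
  out$tpi_like <- list(
    name = "tpi_like",
    spec = simulationSpec(list(list(complexoform = tpiCf, abundance = 100,
                                    charges = c(15L, 16L))),
                          seed = seed, ...),
    space = list(proteins = list(list(
                   id = "TPIL", sequence = tseq,
                   mods = list(list(name = "deamidation", max = 2),
                               list(name = "phospho", max = 1)))),
                 stoichiometry = list(min = 2, max = 2)),
    planted = "tpi_like_dimer")

  ## ---- mif_like ----
  mseq <- .mifLikeSequence()
  m0 <- Proteoform(mseq, proteinId = "MIFL")
  mAc <- Proteoform(mseq, proteinId = "MIFL",
                    siteMods = data.frame(position = 77L, name = "acetyl"))
  mNo <- Proteoform(mseq, proteinId = "MIFL",
                    siteMods = data.frame(position = 80L, name = "nitrosyl"))
  out$mif_like <- list(
    name = "mif_like",
    spec = simulationSpec(list(
      list(complexoform = Complexoform(list(m0, m0, mNo),
                                       label = "mif_like_trimer_nitrosyl"),
           abundance = 100, charges = c(12L, 13L)),
      list(complexoform = Complexoform(list(m0, mAc, mAc),
                                       label = "mif_like_trimer_diacetyl"),
           abundance = 70, charges = c(12L, 13L))),
      seed = seed + 1L, ...),
    space = list(proteins = list(list(
                   id = "MIFL", sequence = mseq,
                   mods = list(list(name = "acetyl", max = 1),
                               list(name = "nitrosyl", max = 1)))),
                 stoichiometry = list(min = 3, max = 3)),
    planted = c("mif_like_trimer_nitrosyl", "mif_like_trimer_diacetyl"))

  ## ---- sod1_like ----
  sseq <- .sod1LikeSequence()
  sSu <- Proteoform(sseq, proteinId = "SODL", ntermMod = "acetyl",
                    disulfides = c(57L, 111L))
  sodCf <- Complexoform(list(sSu, sSu), metals = c(Cu = 1L, Zn = 1L),
                        label = "sod1_like_dimer")
  out$sod1_like <- list(
    name = "sod1_like",
    spec = simulationSpec(list(list(
      complexoform = sodCf, abundance = 100, charges = c(10L, 11L),
      chargeBonus = 0L,
      metalSites = list(Cu = c(46L, 48L, 63L, 120L),
                        Zn = c(63L, 71L, 80L, 83L)))),
      seed = seed + 2L, ...),
    space = list(proteins = list(list(
                   id = "SODL", sequence = sseq,
                   nterm_mods = list("acetyl"),
                   disulfides = list(c(57L, 111L)),
                   mods = list(list(name = "methyl", max = 1)))),
                 metals = list(Cu = 1, Zn = 1),
                 stoichiometry = list(min = 2, max = 2)),
    planted = "sod1_like_dimer")

  ## ---- nutf2_like ----
  nseq <- .nutf2LikeSequence()
  nA <- Proteoform(nseq, proteinId = "NUTL", truncation = c(2L, nchar(nseq) + 1L),
                   siteMods = data.frame(position = 4L, name = "acetyl"))
  nAB <- Proteoform(nseq, proteinId = "NUTL", truncation = c(2L, nchar(nseq) + 1L),
                    siteMods = data.frame(position = c(4L, 55L),
                                          name = c("acetyl", "methyl")))
  nTm <- Proteoform(nseq, proteinId = "NUTL", truncation = c(2L, nchar(nseq) + 1L),
                    siteMods = data.frame(position = 63L, name = "trimethyl"))
  out$nutf2_like <- list(
    name = "nutf2_like",
    spec = simulationSpec(list(
      list(complexoform = Complexoform(list(nA, nAB),
                                       label = "nutf2_like_dimer"),
           abundance = 100, charges = c(11L, 12L)),
      list(complexoform = Complexoform(list(nTm),
                                       label = "nutf2_like_monomer_tm"),
           abundance = 50, charges = c(7L, 8L))),
      seed = seed + 3L, ...),
    space = list(proteins = list(list(
                   id = "NUTL", sequence = paste0("M", nseq), met_loss = TRUE,
                   mods = list(list(name = "acetyl", max = 1),
                               list(name = "methyl", max = 1),
                               list(name = "dimethyl", max = 1),
                               list(name = "trimethyl", max = 1)))),
                 stoichiometry = list(min = 1, max = 2)),
    planted = c("nutf2_like_dimer", "nutf2_like_monomer_tm"))

  for (nm in names(out)) out[[nm]]$run <- simulateRun(out[[nm]]$spec)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (nm in names(out)) {
      writePeaklist(out[[nm]]$run$spectra,
                    file.path(outDir, paste0(nm, ".peaks.txt")))
      utils::write.table(out[[nm]]$run$truth,
                         file.path(outDir, paste0(nm, ".truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      yaml::write_yaml(out[[nm]]$space,
                       file.path(outDir, paste0(nm, ".space.yaml")))
    }
  }
  out
}
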
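## Pipeline orchestration: spectra -> hierarchy -> MS1 deconvolution ->
## complexoform candidates -> MS2 subunit-ejection bookkeeping -> MS3
## proteoform characterization -> metal localization -> result bundle.

#' Build and validate a pipeline run configuration
#'
#' @param input Spectra: a list of [Spectrum-class] objects, or a path to a
#'   peak-list text file (see [readPeaklist()]) or mzML file.
#' @param space Search space: an [expandSearchSpace()] result, a config list
#'   or a YAML path.
#' @param complexTolDa Intact-mass tolerance at the complex level in Da
#'   (default 1).
#' @param fragmentTolPpm MS3 fragment tolerance in ppm (default 10).
#' @param alpha P-score significance level (default 1e-4).
#' @param validateIsotopes Run isotope-distribution validation on matched
#'   fragments (slower; default `FALSE`).
#' @param massType `"mono"` or `"avg"` theoretical masses for matching.
#' @param ambigTol Near-isobaric ambiguity grouping tolerance (Da).
#' @param fragmentCharge Assumed charge of rendered fragment peaks when
#'   decharging MS3 spectra (default 1; set `NA` if peaks are already
#'   neutral masses).
#' @param seed Seed for any stochastic step (none in the core path; kept for
#'   reproducibility of optional extras).
#' @return A validated `RunConfig` (classed list).
#' @export
runConfig <- function(input, space, complexTolDa = 1.0, fragmentTolPpm = 10,
                      alpha = 1e-4, validateIsotopes = FALSE,
                      massType = c("mono", "avg"), ambigTol = 0.05,
                      fragmentCharge = 1L, seed = 1L) {
  massType <- match.arg(massType)
  if (!is.numeric(complexTolDa) || complexTolDa <= 0)
    stop("complexTolDa must be > 0", call. = FALSE)
  if (!is.numeric(fragmentTolPpm) || fragmentTolPpm <= 0)
    stop("fragmentTolPpm must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(input = input, space = space, complexTolDa = complexTolDa,
                 fragmentTolPpm = fragmentTolPpm, alpha = alpha,
                 validateIsotopes = validateIsotopes, massType = massType,
                 ambigTol = ambigTol, fragmentCharge = fragmentCharge,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

.loadSpectra <- function(input) {
  if (is.character(input)) {
    if (grepl("\\.mzml$", input, ignore.case = TRUE)) return(readMzML(input))
    return(readPeaklist(input))
  }
  input
}

.loadSpace <- function(space) {
  if (inherits(space, "SearchSpace")) return(space)
  expandSearchSpace(space)
}

#' Run the identification pipeline
#'
#' Walks every MS1 spectrum: deconvolves charge series to native neutral
#' masses, enumerates complexoform candidates within the intact-mass
#' tolerance, verifies subunit-ejection mass bookkeeping on MS2 children
#' (precursor mass = monomer + remnant within tolerance), characterizes
#' fragment spectra (MS3, or MS2 for species fragmented directly) against
#' matching subunit proteoforms -- fragment matching, Poisson P-score,
#' backbone coverage, PTM localization, metal binding-site intervals,
#' characterization level -- and assembles a ranked identification table.
#' Stage failures are logged and skipped; the pipeline continues.
#'
#' @param config A `RunConfig` from [runConfig()].
#' @return A result bundle: list with `identifications` (data.frame),
#'   `characterizations` (list), `bookkeeping` (data.frame),
#'   `observedOnly` (data.frame of unexplained recurring masses), `log`
#'   (character) and `config`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  logs <- character(0)
  logf <- function(stage, id, msg)
    logs <<- c(logs, sprintf("[%s] %s: %s", stage, id, msg))

  spectra <- .loadSpectra(config$input)
  if (!length(spectra))
    return(.emptyBundle(config))
  hier <- linkHierarchy(spectra)
  space <- .loadSpace(config$space)

  idrows <- list(); chars <- list(); book <- list(); obsOnly <- list()

  for (rootId in hier$roots) {
    root <- hier$spectra[[rootId]]
    dec <- deconvolveSeries(root, tolDa = config$complexTolDa)
    ms2kids <- hier$children[[rootId]]
    ## assign each MS2 child to the nearest deconvolved series whose charge
    ## set contains the precursor charge and whose m/z falls in the window
    ms2series <- rep(NA_integer_, length(ms2kids))
    for (k in seq_along(ms2kids)) {
      s2 <- hier$spectra[[ms2kids[k]]]
      z2 <- s2@precursorCharge
      if (is.na(z2)) next
      dist <- vapply(dec$series, function(ser) {
        if (!z2 %in% ser$charges) return(Inf)
        abs(mzFor(ser$neutralMass, z2) - s2@isoCenter)
      }, 0)
      if (length(dist) && min(dist) <= max(s2@isoWidth / 2, 2, na.rm = TRUE))
        ms2series[k] <- which.min(dist)
    }
    for (siIdx in seq_along(dec$series)) {
      ser <- dec$series[[siIdx]]
      cand <- enumerateCandidates(space, ser$neutralMass,
                                  tol = config$complexTolDa,
                                  massType = config$massType,
                                  ambigTol = config$ambigTol)
      if (!nrow(cand)) {
        obsOnly[[length(obsOnly) + 1L]] <- data.frame(
          ms1_id = rootId, obs_mass = ser$neutralMass,
          intensity = sum(ser$intensity),
          charges = paste(ser$charges, collapse = ","),
          tier = classifyTier(FALSE))
        logf("search", rootId,
             sprintf("no candidate within %.2f Da of %.3f",
                     config$complexTolDa, ser$neutralMass))
        next
      }
      ## MS2 children isolating this series
      serMs2 <- ms2kids[!is.na(ms2series) & ms2series == siIdx]
      fragSig <- FALSE
      for (k2 in serMs2) {
        s2 <- hier$spectra[[k2]]
        ms3kids <- hier$children[[k2]] %||% character(0)
        if (length(ms3kids)) {
          for (k3 in ms3kids) {
            s3 <- hier$spectra[[k3]]
            z3 <- s3@precursorCharge
            if (is.na(z3)) { logf("ms3", k3, "unknown precursor charge"); next }
            mMono <- z3 * (s3@isoCenter - .PROTON)
            mRem <- ser$neutralMass - mMono
            zRem <- s2@precursorCharge - z3
            remOk <- FALSE
            if (zRem >= 1) {
              remOk <- any(abs(s2@mz - mzFor(max(mRem, 1e-6), zRem)) * zRem <=
                             config$complexTolDa)
            }
            book[[length(book) + 1L]] <- data.frame(
              ms2_id = k2, ms3_id = k3, precursor_mass = ser$neutralMass,
              monomer_mass = mMono, remnant_mass = mRem,
              bookkeeping_ok = remOk)
            res <- .characterizeFragmentSpectrum(
              s3, mMono, space, config, logf)
            if (!is.null(res)) {
              res$ms1_id <- rootId; res$series_idx <- siIdx
              chars[[length(chars) + 1L]] <- res
              if (res$p_score <= config$alpha) fragSig <- TRUE
            }
          }
        } else {
          ## no MS3: the MS2 spectrum is the fragment spectrum of a
          ## directly-fragmented (monomeric) species
          res <- .characterizeFragmentSpectrum(
            s2, ser$neutralMass, space, config, logf)
          if (!is.null(res)) {
            res$ms1_id <- rootId; res$series_idx <- siIdx
            chars[[length(chars) + 1L]] <- res
            if (res$p_score <= config$alpha) fragSig <- TRUE
          }
        }
      }
      cand$tier <- classifyTier(TRUE, fragSig)
      cand$ms1_id <- rootId
      cand$series_idx <- siIdx
      cand$intensity <- sum(ser$intensity)
      cand$charges <- paste(ser$charges, collapse = ",")
      idrows[[length(idrows) + 1L]] <-
        cand[, setdiff(names(cand), "complexoform")]
    }
  }

  bundle <- list(
    identifications = if (length(idrows)) do.call(rbind, idrows) else
      .emptyIdTable(),
    characterizations = chars,
    bookkeeping = if (length(book)) do.call(rbind, book) else
      data.frame(ms2_id = character(0), ms3_id = character(0),
                 precursor_mass = numeric(0), monomer_mass = numeric(0),
                 remnant_mass = numeric(0), bookkeeping_ok = logical(0)),
    observedOnly = if (length(obsOnly)) do.call(rbind, obsOnly) else
      data.frame(ms1_id = character(0), obs_mass = numeric(0),
                 intensity = numeric(0), charges = character(0),
                 tier = character(0)),
    log = logs, config = config)
  class(bundle) <- "ResultBundle"
  bundle
}

.emptyIdTable <- function() {
  data.frame(label = character(0), theo_mass = numeric(0),
             obs_mass = numeric(0), error_da = numeric(0),
             n_subunits = integer(0), n_mods = integer(0),
             metals = integer(0), tier = character(0),
             ambiguity_set = integer(0), rank = integer(0),
             ms1_id = character(0), series_idx = integer(0),
             intensity = numeric(0), charges = character(0))
}

.emptyBundle <- function(config) {
  structure(list(identifications = .emptyIdTable(),
                 characterizations = list(),
                 bookkeeping = data.frame(),
                 observedOnly = data.frame(), log = character(0),
                 config = config),
            class = "ResultBundle")
}

#' @export
print.ResultBundle <- function(x, ...) {
  cat(sprintf(
    "ResultBundle: %d candidate row(s), %d characterization(s), %d log line(s)\n",
    nrow(x$identifications), length(x$characterizations), length(x$log)))
  invisible(x)
}

## Characterize one fragment spectrum against the subunit proteoforms of the
## search space matching the precursor monomer mass (allowing retained metal
## submultisets). Returns the best-scoring characterization or NULL.
.characterizeFragmentSpectrum <- function(s, monomerMass, space, config,
                                          logf) {
  obs <- s@mz - config$fragmentCharge * .PROTON
  obs <- obs[obs > 0]
  if (!length(obs)) return(NULL)
  mm <- .metalMultisets(space$metals)
  cands <- list()
  for (i in seq_along(space$proteoforms)) {
    for (j in seq_len(nrow(mm$counts))) {
      theo <- space[[config$massType]][i] + mm$mono[j]
      if (abs(theo - monomerMass) <= config$complexTolDa) {
        mets <- mm$counts[j, , drop = TRUE]
        mets <- mets[mets > 0]
        cands[[length(cands) + 1L]] <- list(
          idx = i, metals = stats::setNames(as.integer(mets), names(mets)),
          err = theo - monomerMass)
      }
    }
  }
  if (!length(cands)) {
    logf("characterize", s@id,
         sprintf("no subunit candidate for monomer mass %.3f", monomerMass))
    return(NULL)
  }
  ## keep the near-isobaric leading set (within ambigTol of the best)
  errs <- vapply(cands, function(cc) abs(cc$err), 0)
  lead <- which(errs <= min(errs) + config$ambigTol)
  best <- NULL
  for (ci in lead[seq_len(min(length(lead), 5L))]) {
    cc <- cands[[ci]]
    p <- space$proteoforms[[cc$idx]]
    ladder <- generateByLadder(p, metals = if (length(cc$metals)) cc$metals)
    matches <- matchFragments(ladder, obs, tolPpm = config$fragmentTolPpm)
    psc <- pScore(nrow(matches), length(obs), ladder$neutral_mass,
                  tolPpm = config$fragmentTolPpm,
                  massWindow = range(c(obs, ladder$neutral_mass)))
    if (is.null(best) || psc < best$p_score)
      best <- list(spectrum_id = s@id, proteoform = p,
                   proteoform_text = serializeProteoform(p),
                   protein = proteinId(p), metals = cc$metals,
                   monomer_mass = monomerMass, mass_error_da = cc$err,
                   matches = matches, p_score = psc)
  }
  p <- best$proteoform
  cov <- coverageAndMap(p, best$matches)
  loc <- localizeMods(p, obs, tolPpm = config$fragmentTolPpm)
  metloc <- metalLocalization(best$matches, nchar(p@sequence))
  nIdent <- nrow(p@siteMods) + (!is.na(p@ntermMod)) + (!is.na(p@ctermMod))
  nLocalized <- sum(!is.na(p@siteMods$position)) +
    (!is.na(p@ntermMod)) + (!is.na(p@ctermMod)) +
    sum(vapply(loc, function(l) l$status == "localized", TRUE))
  level <- characterizationLevel(
    best$p_score, nModsIdentified = nIdent, nModsLocalized = nLocalized,
    candidateAmbiguity = length(lead) > 1, alpha = config$alpha)
  iso <- NULL
  if (isTRUE(config$validateIsotopes) && nrow(best$matches)) {
    ## validate the largest matched fragment against its averagine envelope
    k <- which.max(best$matches$neutral_mass)
    iso <- fitIsotopes(
      peaks(s),
      list(mass = best$matches$neutral_mass[k],
           charge = config$fragmentCharge),
      mzTol = 0.05)
  }
  c(best[c("spectrum_id", "proteoform_text", "protein", "metals",
           "monomer_mass", "mass_error_da", "p_score", "matches")],
    list(coverage = cov$coverage, map = cov$map, localization = loc,
         metal_intervals = metloc, level = level,
         n_candidates = length(lead), isotope_fit = iso))
}

#' Differential comparison of two result bundles
#'
#' Presence/absence and intensity ratios per complexoform label between two
#' runs (e.g. two cell states). A label present in only one run gets an
#' infinite/zero ratio and `status` `"only_a"`/`"only_b"`.
#'
#' @param bundleA,bundleB Result bundles from [runPipeline()].
#' @param rankMax Consider candidates up to this rank (default 1).
#' @return data.frame `label`, `intensity_a`, `intensity_b`, `ratio`,
#'   `status`.
#' @export
differentialTable <- function(bundleA, bundleB, rankMax = 1L) {
  pick <- function(b) {
    tab <- b$identifications
    tab <- tab[tab$rank <= rankMax, , drop = FALSE]
    stats::aggregate(intensity ~ label, data = tab, FUN = sum)
  }
  a <- pick(bundleA); b <- pick(bundleB)
  labs <- union(a$label, b$label)
  ia <- stats::setNames(a$intensity, a$label)[labs]
  ib <- stats::setNames(b$intensity, b$label)[labs]
  ia[is.na(ia)] <- 0; ib[is.na(ib)] <- 0
  data.frame(label = labs, intensity_a = as.numeric(ia),
             intensity_b = as.numeric(ib),
             ratio = as.numeric(ia) / as.numeric(ib),
             status = ifelse(ia > 0 & ib > 0, "both",
                             ifelse(ia > 0, "only_a", "only_b")))
}
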
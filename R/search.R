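## Intact-mass complexoform search: enumerate subunit multisets + metal
## multisets whose theoretical mass falls within +/- tol of an observed
## native neutral mass.

#' Enumerate complexoform candidates matching an observed mass
#'
#' Searches all multisets of candidate proteoforms (within the stoichiometry
#' bounds) combined with all allowed metal submultisets, keeping combinations
#' whose complexoform mass lies within `tol` of `obsMass`. Enumeration is a
#' depth-first walk over proteoforms sorted by mass with partial-sum bounds
#' pruning; correctness is defined against exhaustive enumeration (see the
#' package tests). Results are ranked by absolute mass error; ties break by
#' fewer total modifications, then fewer metals, then lexical label.
#'
#' @param space A `SearchSpace` from [expandSearchSpace()].
#' @param obsMass Observed neutral mass in Da.
#' @param tol Mass tolerance in Da (default 1, applied at the complex level).
#' @param massType Match against `"mono"`isotopic (default) or `"avg"` masses.
#' @param ambigTol Near-isobaric grouping tolerance in Da (default 0.05):
#'   candidates whose theoretical masses lie within it (e.g. trimethyl vs
#'   acetyl, 0.0364 Da apart) are reported as one ambiguity set sharing a
#'   rank, since intact-mass data cannot order them reliably.
#' @return A `data.frame` with one row per candidate: `label`, `theo_mass`,
#'   `obs_mass`, `error_da`, `n_subunits`, `n_mods`, `metals`, `tier`
#'   (initialized to `"mass_only"`; see [classifyTier()]), `rank` (shared
#'   within an ambiguity set) and `ambiguity_set` (set id), plus a list
#'   column `complexoform` holding the [Complexoform-class] objects.
#' @export
#' @examples
#' sp <- expandSearchSpace(list(
#'   proteins = list(list(id = "A", sequence = "GGGG")),
#'   stoichiometry = list(min = 2, max = 2)))
#' enumerateCandidates(sp, 2 * proteoformMass(Proteoform("GGGG"))[["mono"]])
enumerateCandidates <- function(space, obsMass, tol = 1.0,
                                massType = c("mono", "avg"),
                                ambigTol = 0.05) {
  massType <- match.arg(massType)
  stopifnot(inherits(space, "SearchSpace"), obsMass > 0, tol > 0)
  masses <- space[[massType]]
  n <- length(masses)
  mm <- .metalMultisets(space$metals)
  mdelta <- if (massType == "mono") mm$mono else mm$avg
  smin <- space$stoich$min; smax <- space$stoich$max
  pp <- space$stoich$perProtein
  minMetal <- if (length(mdelta)) min(mdelta) else 0

  hits <- list()
  visited <- 0L
  ## DFS over non-decreasing proteoform indices (multisets)
  recurse <- function(start, chosen, total) {
    visited <<- visited + 1L
    if (visited > space$cap)
      stop("candidate enumeration exceeds cap (",
           format(space$cap, scientific = FALSE), ")", call. = FALSE)
    k <- length(chosen)
    if (k >= smin && k >= 1) {
      for (j in seq_along(mdelta)) {
        theo <- total + mdelta[j]
        if (abs(theo - obsMass) <= tol && .perProteinOk(chosen, space, pp)) {
          hits[[length(hits) + 1L]] <<- list(idx = chosen, metal = j,
                                             theo = theo)
        }
      }
    }
    if (k == smax) return(invisible())
    need <- max(smin - k - 1L, 0L)
    for (i in seq(start, length.out = max(0L, n - start + 1L))) {
      ## lower bound on the final complex mass if proteoform i is taken next
      ## and the multiset is completed with the cheapest legal choices
      ## (masses are globally sorted, indices non-decreasing)
      if (total + masses[i] * (1 + need) + minMetal > obsMass + tol) break
      recurse(i, c(chosen, i), total + masses[i])
    }
    invisible()
  }
  ## sort proteoform indices globally by mass for effective pruning
  o <- order(masses)
  masses_o <- masses[o]
  space_o <- space
  space_o$mono <- space$mono[o]; space_o$avg <- space$avg[o]
  space_o$protein <- space$protein[o]
  space_o$proteoforms <- space$proteoforms[o]
  masses <- masses_o
  space <- space_o

  if (n) recurse(1L, integer(0), 0)

  if (!length(hits)) return(.emptyMatchTable(obsMass))
  rows <- lapply(hits, function(h) {
    subs <- space$proteoforms[h$idx]
    mets <- mm$counts[h$metal, , drop = TRUE]
    mets <- mets[mets > 0]
    cf <- Complexoform(subs,
                       metals = stats::setNames(as.integer(mets), names(mets)))
    lab <- paste(sort(vapply(subs, function(s)
      paste0(proteinId(s), ":", serializeProteoform(s)), "")), collapse = " + ")
    if (length(cf@metals))
      lab <- paste0(lab, " + ",
                    paste0(names(cf@metals), "x", cf@metals, collapse = " + "))
    cf@label <- lab
    data.frame(label = lab, theo_mass = h$theo, obs_mass = obsMass,
               error_da = h$theo - obsMass, n_subunits = length(subs),
               n_mods = .totalMods(cf), metals = sum(cf@metals),
               tier = "mass_only", complexoform = I(list(cf)))
  })
  out <- do.call(rbind, rows)
  ## collapse subunit-permutation duplicates (same label = same multiset)
  out <- out[!duplicated(out$label), , drop = FALSE]
  o <- order(abs(out$error_da), out$n_mods, out$metals, out$label)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  ## near-isobaric ambiguity sets share a rank
  grp <- integer(nrow(out))
  grpMass <- numeric(0)
  for (i in seq_len(nrow(out))) {
    hit <- which(abs(grpMass - out$theo_mass[i]) <= ambigTol)
    if (length(hit)) grp[i] <- hit[1]
    else { grpMass <- c(grpMass, out$theo_mass[i]); grp[i] <- length(grpMass) }
  }
  out$ambiguity_set <- grp
  out$rank <- match(grp, unique(grp))
  out
}

.emptyMatchTable <- function(obsMass) {
  data.frame(label = character(0), theo_mass = numeric(0),
             obs_mass = numeric(0), error_da = numeric(0),
             n_subunits = integer(0), n_mods = integer(0),
             metals = integer(0), tier = character(0),
             ambiguity_set = integer(0), rank = integer(0),
             complexoform = I(list()))
}

.perProteinOk <- function(idx, space, pp) {
  if (is.null(pp)) return(TRUE)
  cnt <- table(space$protein[idx])
  for (nm in names(pp)) {
    k <- if (nm %in% names(cnt)) cnt[[nm]] else 0L
    if (k < pp[[nm]][1] || k > pp[[nm]][2]) return(FALSE)
  }
  TRUE
}

#' Evidence tier of a complexoform match
#'
#' `"mass_and_fragments"` when MS3 fragment evidence significantly supports
#' at least one subunit; `"mass_only"` when a theoretical candidate exists
#' but no fragment support; `"observed_mass_only"` for recurring observed
#' masses with no candidate in the search space (reported, not discarded).
#'
#' @param hasCandidate Does a theoretical candidate within tolerance exist?
#' @param fragmentSignificant Does MS3 evidence link at least one subunit
#'   (P-score at or below the significance level)?
#' @return One of `"mass_and_fragments"`, `"mass_only"`,
#'   `"observed_mass_only"`.
#' @export
classifyTier <- function(hasCandidate, fragmentSignificant = FALSE) {
  if (!hasCandidate) return("observed_mass_only")
  if (isTRUE(fragmentSignificant)) "mass_and_fragments" else "mass_only"
}
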
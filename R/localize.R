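## PTM localization by bracketing fragments, characterization levels and
## holo/apo metal binding-site inference.

#' Localize unplaced modifications by bracketing fragment evidence
#'
#' For each modification carried as unlocalized on the proteoform, every
#' candidate site `s` is tested against the observed fragment masses: the
#' site is supported when the evidence brackets it, i.e. some matched
#' fragment whose span includes `s` carries the mass shift while a matched
#' fragment whose span ends at the adjacent cleavage and excludes `s` does
#' not. Concretely, left-boundary evidence is an unshifted `b_(s-1)` or a
#' shifted `y_(n-s+1)`, right-boundary evidence a shifted `b_s` or an
#' unshifted `y_(n-s)`; a terminus substitutes for the missing boundary.
#' Exactly one supported site localizes the modification; several supported
#' sites are reported as an ambiguity set (no arbitrary choice); none leaves
#' it identified-not-localized.
#'
#' Modifications are assessed one at a time against the ladder of the
#' proteoform's localized modifications; simultaneous localization of
#' several interacting unplaced modifications is out of scope.
#'
#' @param p [Proteoform-class] carrying unlocalized site modifications.
#' @param observedMasses Neutral monoisotopic fragment masses (Da).
#' @param candidateSites Named list: modification name -> integer candidate
#'   positions. Defaults to every target-compatible residue.
#' @param tolPpm Fragment tolerance (ppm).
#' @return A list per unlocalized modification: `name`, `status`
#'   (`"localized"`, `"ambiguous"` or `"identified-not-localized"`) and
#'   `sites` (supported positions).
#' @export
localizeMods <- function(p, observedMasses, candidateSites = NULL,
                         tolPpm = 10) {
  stopifnot(is(p, "Proteoform"))
  unloc <- p@siteMods[is.na(p@siteMods$position), , drop = FALSE]
  if (!nrow(unloc)) return(list())
  chars <- strsplit(p@sequence, "")[[1]]
  n <- length(chars)
  base <- p
  base@siteMods <- p@siteMods[!is.na(p@siteMods$position), , drop = FALSE]
  ladder <- generateByLadder(base)
  bmass <- stats::setNames(
    ladder$neutral_mass[ladder$series == "b"],
    ladder$index[ladder$series == "b"])
  ymass <- stats::setNames(
    ladder$neutral_mass[ladder$series == "y"],
    ladder$index[ladder$series == "y"])
  seen <- function(m) {
    if (is.na(m)) return(FALSE)
    any(abs(observedMasses - m) / m * 1e6 <= tolPpm)
  }
  bAt <- function(i) if (as.character(i) %in% names(bmass))
    bmass[[as.character(i)]] else NA_real_
  yAt <- function(j) if (as.character(j) %in% names(ymass))
    ymass[[as.character(j)]] else NA_real_

  out <- list()
  ## identical unplaced modifications are assessed together: k copies with
  ## exactly k supported sites localize one copy per site
  for (nm in unique(unloc$name)) {
    k <- sum(unloc$name == nm)
    d <- modDelta(nm)
    cand <- candidateSites[[nm]]
    if (is.null(cand)) {
      tg <- d@targets
      cand <- if ("*" %in% tg) seq_len(n) else which(chars %in% tg)
    }
    supported <- integer(0)
    for (s in cand) {
      left <- s == 1 ||
        seen(bAt(s - 1L)) || seen(yAt(n - s + 1L) + d@monoMass)
      right <- s == n ||
        seen(bAt(s) + d@monoMass) || seen(yAt(n - s))
      if (left && right) supported <- c(supported, s)
    }
    for (copy in seq_len(k)) {
      if (length(supported) == k)
        out[[length(out) + 1L]] <- list(name = nm, status = "localized",
                                        sites = supported[copy])
      else if (length(supported) > k)
        out[[length(out) + 1L]] <- list(name = nm, status = "ambiguous",
                                        sites = supported)
      else if (copy <= length(supported))
        out[[length(out) + 1L]] <- list(name = nm, status = "localized",
                                        sites = supported[copy])
      else
        out[[length(out) + 1L]] <- list(name = nm,
                                        status = "identified-not-localized",
                                        sites = integer(0))
    }
  }
  out
}

#' Characterization confidence level
#'
#' The five-level (plus 2A/2B) graded taxonomy for proteoform
#' identifications: level 1 -- significant fragment evidence with all
#' modifications localized; 2A -- significant evidence but at least one
#' modification identified only by mass shift; 2B -- significant evidence
#' with a near-isobaric candidate ambiguity; 3 -- sequence identified but
#' the number of modifications uncertain; 4 -- protein identified,
#' proteoform not; 5 -- mass-only observation.
#'
#' @param pScore Fragment-evidence P-score (`NA` = no fragment evidence).
#' @param nModsIdentified,nModsLocalized Counts of modifications identified
#'   and of those localized.
#' @param candidateAmbiguity Is there an unresolved near-isobaric candidate
#'   set?
#' @param modCountUncertain Is the number of modifications itself uncertain?
#' @param alpha Significance level on the P-score (default 1e-4).
#' @return One of `"1"`, `"2A"`, `"2B"`, `"3"`, `"4"`, `"5"`.
#' @export
#' @examples
#' characterizationLevel(1e-9, 2, 2)               # "1"
#' characterizationLevel(1e-9, 1, 0)               # "2A"
characterizationLevel <- function(pScore, nModsIdentified = 0,
                                  nModsLocalized = 0,
                                  candidateAmbiguity = FALSE,
                                  modCountUncertain = FALSE,
                                  alpha = 1e-4) {
  if (is.na(pScore)) return("5")
  if (pScore > alpha) return("4")
  if (modCountUncertain) return("3")
  if (candidateAmbiguity) return("2B")
  if (nModsLocalized < nModsIdentified) return("2A")
  "1"
}

#' Infer metal binding-site intervals from holo/apo fragments
#'
#' All-or-none metal retention makes holo/apo status informative about the
#' coordinating region: a holo `b_i` implies every coordinating residue of
#' that metal lies in `1..i`, so the smallest holo b index is an upper bound
#' on the whole coordinating set; symmetrically the smallest holo y index
#' `j` bounds the set from below at `n - j + 1`. The reported interval is
#' the intersection of these all-residue bounds and is guaranteed to contain
#' the full coordinating set. Fragments observed apo and never holo carry
#' existence constraints (an apo-only `b_j` implies at least one
#' coordinating residue beyond `j`, an apo-only `y_k` at least one before
#' `n - k + 1`); they must be satisfiable inside the interval, otherwise the
#' metal is flagged inconsistent. A metal with no holo fragments is
#' unlocalized.
#'
#' @param matches Fragment matches (from [matchFragments()]) carrying the
#'   `metals` label column.
#' @param sequenceLength Length of the proteoform sequence.
#' @return Named list per metal: `status` (`"localized"`, `"unlocalized"`,
#'   `"inconsistent"`) and `interval` (`c(lo, hi)` residue positions, or
#'   `NULL`).
#' @export
metalLocalization <- function(matches, sequenceLength) {
  n <- sequenceLength
  mets <- unique(unlist(strsplit(matches$metals[nzchar(matches$metals)], ",")))
  out <- list()
  for (met in mets) {
    carries <- vapply(strsplit(matches$metals, ","), function(v) met %in% v,
                      TRUE)
    holo_b <- matches$index[carries & matches$series == "b"]
    holo_y <- matches$index[carries & matches$series == "y"]
    apo_b <- setdiff(matches$index[!carries & matches$series == "b"], holo_b)
    apo_y <- setdiff(matches$index[!carries & matches$series == "y"], holo_y)
    if (!length(holo_b) && !length(holo_y)) {
      out[[met]] <- list(status = "unlocalized", interval = NULL)
      next
    }
    upper <- if (length(holo_b)) min(holo_b) else n
    lower <- if (length(holo_y)) n - min(holo_y) + 1L else 1L
    ## apo-only existence constraints must fit inside the interval
    ok <- lower <= upper &&
      (!length(apo_b) || max(apo_b) + 1L <= upper) &&
      (!length(apo_y) || n - max(apo_y) >= lower)
    if (!ok)
      out[[met]] <- list(status = "inconsistent", interval = NULL)
    else
      out[[met]] <- list(status = "localized",
                         interval = c(lower, upper))
  }
  out
}
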
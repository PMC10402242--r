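## HCD b/y fragment ladders, fragment matching and coverage maps.

## metal submultisets of size 1..cap within maxCounts, as label strings
.holoSets <- function(metals, cap = 2L) {
  if (is.null(metals) || !length(metals)) return(list())
  g <- do.call(expand.grid, lapply(metals, function(k) 0:k))
  names(g) <- names(metals)
  g <- g[rowSums(g) >= 1 & rowSums(g) <= cap, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) {
    v <- stats::setNames(as.integer(g[i, ]), names(g))
    v[v > 0]
  })
}

.metalLabel <- function(counts) {
  if (!length(counts)) return("")
  paste(rep(names(counts), counts), collapse = ",")
}

.metalSetMass <- function(counts) {
  if (!length(counts)) return(0)
  sum(vapply(names(counts), metalAdductDelta, 0) * counts)
}

#' Generate the theoretical b/y ladder of a proteoform
#'
#' Neutral monoisotopic b and y fragment masses for HCD: `b_i` covers
#' residues `1..i` plus the N-terminal modification and any localized site
#' modifications in that span; `y_j` covers the last `j` residues plus H2O,
#' the C-terminal modification and site modifications in its span.
#' Modifications carried as unlocalized (position `NA`) are not placed and do
#' not shift any fragment (localization happens downstream, see
#' [localizeMods()]). With intact disulfides (the default), cleavage sites
#' strictly inside a disulfide loop produce no fragments, and fragments
#' spanning a whole loop include its -2.01565 Da; `disulfideMode = "reduced"`
#' ignores disulfides entirely. When `metals` are supplied each fragment is
#' additionally emitted in holo forms carrying every metal submultiset of up
#' to `maxHoloMetals` ions (all-or-none retention per fragment).
#'
#' @param p A [Proteoform-class].
#' @param metals Optional named metal count vector, e.g. `c(Cu = 1, Zn = 1)`.
#' @param maxHoloMetals Cap on metals per holo fragment (default 2).
#' @param disulfideMode `"intact"` (default) or `"reduced"`.
#' @return data.frame with columns `series` ("b"/"y"), `index`, `start`,
#'   `end` (residue span on the processed sequence), `metals` (label, "" =
#'   apo) and `neutral_mass` (Da).
#' @export
#' @examples
#' generateByLadder(Proteoform("GG"))
generateByLadder <- function(p, metals = NULL, maxHoloMetals = 2L,
                             disulfideMode = c("intact", "reduced")) {
  disulfideMode <- match.arg(disulfideMode)
  stopifnot(is(p, "Proteoform"))
  chars <- strsplit(p@sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) return(.emptyLadder())
  res <- .resMono()[chars]
  water <- compositionMass(.WATER)[["mono"]]
  ntd <- if (!is.na(p@ntermMod)) .modMono(p@ntermMod) else 0
  ctd <- if (!is.na(p@ctermMod)) .modMono(p@ctermMod) else 0
  sm <- p@siteMods[!is.na(p@siteMods$position), , drop = FALSE]
  sitemass <- numeric(n)
  for (k in seq_len(nrow(sm)))
    sitemass[sm$position[k]] <- sitemass[sm$position[k]] + .modMono(sm$name[k])
  csum <- cumsum(res + sitemass)
  ds <- p@disulfides
  useDs <- disulfideMode == "intact" && nrow(ds) > 0
  dsDelta <- .modMono("disulfide")

  ## cleavage site i = bond after residue i, i in 1..n-1
  sites <- seq_len(n - 1L)
  excluded <- rep(FALSE, n - 1L)
  if (useDs) for (r in seq_len(nrow(ds))) {
    c1 <- min(ds[r, ]); c2 <- max(ds[r, ])
    excluded[sites >= c1 & sites <= c2 - 1L] <- TRUE
  }

  bmass <- csum[sites] + ntd
  ymass <- (csum[n] - csum[sites]) + water + ctd
  if (useDs) for (r in seq_len(nrow(ds))) {
    c1 <- min(ds[r, ]); c2 <- max(ds[r, ])
    bmass[sites >= c2] <- bmass[sites >= c2] + dsDelta         # b spans loop
    ymass[sites <= c1 - 1L] <- ymass[sites <= c1 - 1L] + dsDelta  # y spans loop
  }
  keep <- !excluded
  b <- data.frame(series = "b", index = sites[keep], start = 1L,
                  end = sites[keep], metals = "",
                  neutral_mass = bmass[keep])
  yidx <- n - sites[keep]  # y_j pairs with cleavage site n - j
  y <- data.frame(series = "y", index = yidx, start = n - yidx + 1L,
                  end = n, metals = "", neutral_mass = ymass[keep])
  out <- rbind(b, y)

  hs <- .holoSets(metals, maxHoloMetals)
  if (length(hs)) {
    holo <- do.call(rbind, lapply(hs, function(h) {
      hh <- out
      hh$metals <- .metalLabel(h)
      hh$neutral_mass <- hh$neutral_mass + .metalSetMass(h)
      hh
    }))
    out <- rbind(out, holo)
  }
  rownames(out) <- NULL
  out
}

.emptyLadder <- function() {
  data.frame(series = character(0), index = integer(0), start = integer(0),
             end = integer(0), metals = character(0),
             neutral_mass = numeric(0))
}

#' Match observed neutral fragment masses against a theoretical ladder
#'
#' One-to-one assignment in ascending order of |ppm error|: each observed
#' mass pairs with the nearest unclaimed theoretical fragment within
#' tolerance; on an exact tie an apo fragment is preferred over a holo one.
#' Observed masses must already be neutral monoisotopic (decharged and
#' deisotoped upstream).
#'
#' @param theoretical Ladder from [generateByLadder()].
#' @param observedMasses Numeric vector of neutral masses (Da).
#' @param tolPpm Matching tolerance in ppm (default 10).
#' @return data.frame of matches: ladder columns plus `observed_mass`,
#'   `ppm_error`, `obs_idx`.
#' @export
matchFragments <- function(theoretical, observedMasses, tolPpm = 10) {
  if (!nrow(theoretical) || !length(observedMasses))
    return(cbind(.emptyLadder(),
                 data.frame(observed_mass = numeric(0), ppm_error = numeric(0),
                            obs_idx = integer(0))))
  pairs <- NULL
  for (oi in seq_along(observedMasses)) {
    om <- observedMasses[oi]
    ppm <- (om - theoretical$neutral_mass) / theoretical$neutral_mass * 1e6
    ok <- which(abs(ppm) <= tolPpm)
    if (length(ok))
      pairs <- rbind(pairs, data.frame(obs = oi, theo = ok,
                                       ppm = ppm[ok],
                                       holo = nzchar(theoretical$metals[ok])))
  }
  if (is.null(pairs))
    return(cbind(.emptyLadder(),
                 data.frame(observed_mass = numeric(0), ppm_error = numeric(0),
                            obs_idx = integer(0))))
  pairs <- pairs[order(abs(pairs$ppm), pairs$holo), , drop = FALSE]
  usedObs <- logical(length(observedMasses))
  usedTheo <- logical(nrow(theoretical))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (usedObs[pairs$obs[k]] || usedTheo[pairs$theo[k]]) next
    usedObs[pairs$obs[k]] <- TRUE
    usedTheo[pairs$theo[k]] <- TRUE
    keep[k] <- TRUE
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- theoretical[pairs$theo, , drop = FALSE]
  out$observed_mass <- observedMasses[pairs$obs]
  out$ppm_error <- pairs$ppm
  out$obs_idx <- pairs$obs
  out <- out[order(out$series, out$index, out$metals), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Backbone coverage and fragment map
#'
#' Per-bond cleavage evidence from matched fragments: bond `i` (between
#' residues `i` and `i+1`) counts as covered when a matched `b_i` or
#' `y_(n-i)` exists. Bonds excluded by intact disulfide loops are omitted
#' from the denominator by default.
#'
#' @param p The characterized [Proteoform-class].
#' @param matches Matches from [matchFragments()].
#' @param countDisulfideBonds Include disulfide-excluded bonds in the
#'   denominator (default `FALSE`).
#' @param disulfideMode As in [generateByLadder()].
#' @return A list with `bonds` (data.frame `bond`, `b`, `y`, `holo`,
#'   `cleavable`), `coverage` (fraction of cleavable bonds with evidence)
#'   and `map` (fixed-width text rendering).
#' @export
coverageAndMap <- function(p, matches, countDisulfideBonds = FALSE,
                           disulfideMode = c("intact", "reduced")) {
  disulfideMode <- match.arg(disulfideMode)
  chars <- strsplit(p@sequence, "")[[1]]
  n <- length(chars)
  bonds <- data.frame(bond = seq_len(max(n - 1L, 0L)), b = FALSE, y = FALSE,
                      holo = FALSE, cleavable = TRUE)
  if (disulfideMode == "intact" && nrow(p@disulfides)) {
    for (r in seq_len(nrow(p@disulfides))) {
      c1 <- min(p@disulfides[r, ]); c2 <- max(p@disulfides[r, ])
      bonds$cleavable[bonds$bond >= c1 & bonds$bond <= c2 - 1L] <- FALSE
    }
  }
  for (k in seq_len(nrow(matches))) {
    i <- if (matches$series[k] == "b") matches$index[k] else n - matches$index[k]
    if (i < 1 || i > nrow(bonds)) next
    if (matches$series[k] == "b") bonds$b[i] <- TRUE else bonds$y[i] <- TRUE
    if (nzchar(matches$metals[k])) bonds$holo[i] <- TRUE
  }
  denom <- if (countDisulfideBonds) nrow(bonds) else sum(bonds$cleavable)
  covered <- sum((bonds$b | bonds$y) & (bonds$cleavable | countDisulfideBonds))
  coverage <- if (denom > 0) covered / denom else 0
  list(bonds = bonds, coverage = coverage,
       map = .renderMap(chars, bonds))
}

## fixed-width text fragmentation map, 20 residues per row:
## b-cleavages marked "\" after the residue, y-cleavages "/" (both = "|"),
## holo cleavages upper-cased markers on the flag line.
.renderMap <- function(chars, bonds, width = 20L) {
  n <- length(chars)
  marks <- character(max(n - 1L, 0L))
  for (i in seq_along(marks)) {
    marks[i] <- if (bonds$b[i] && bonds$y[i]) "|"
      else if (bonds$b[i]) "\\" else if (bonds$y[i]) "/"
      else if (!bonds$cleavable[i]) "=" else " "
    if (bonds$holo[i] && marks[i] != " ") marks[i] <- "*"
  }
  lines <- character(0)
  for (off in seq(1, n, by = width)) {
    ix <- off:min(off + width - 1L, n)
    row1 <- paste(chars[ix], collapse = " ")
    flag <- vapply(ix, function(i) if (i <= length(marks)) marks[i] else " ", "")
    row2 <- paste(flag, collapse = " ")
    lines <- c(lines, sprintf("%4d %s", off, row1), paste0("     ", row2))
  }
  paste(lines, collapse = "\n")
}
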
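## Elemental compositions and isotope distributions.
##
## A composition is a named numeric vector of non-negative integer counts,
## e.g. c(C = 2, H = 3, N = 1, O = 1). Helper constructors validate; all
## mass arithmetic downstream flows through compositionMass().

#' Build or validate an elemental composition
#'
#' An elemental composition is a named vector of non-negative integer
#' element counts. `elementalComposition()` validates the names against the
#' supported element table and drops zero counts; `parseFormula()` reads the
#' compact "C2H3NO" notation (two-letter symbols supported, e.g. "Cu", "Zn").
#'
#' @param x Named numeric vector of element counts.
#' @return Named numeric vector of validated counts (class-free; compositions
#'   are plain vectors so that arithmetic stays transparent).
#' @export
#' @examples
#' elementalComposition(c(H = 2, O = 1))
#' parseFormula("C2H3NO")
elementalComposition <- function(x) {
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("composition must be a named vector of element counts", call. = FALSE)
  bad <- setdiff(names(x), names(.ISOTOPES))
  if (length(bad))
    stop("unknown element: '", paste(bad, collapse = "', '"), "'", call. = FALSE)
  if (any(x < 0))
    stop("element counts must be non-negative", call. = FALSE)
  x <- x[x != 0]
  ## merge duplicated symbols
  if (anyDuplicated(names(x))) {
    x <- tapply(x, names(x), sum)
    x <- stats::setNames(as.numeric(x), names(x))
  }
  x
}

#' @rdname elementalComposition
#' @param formula Character scalar, e.g. `"C2H3NO"` or `"CuH-2"` is *not*
#'   allowed: counts must be non-negative.
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!nzchar(formula)) return(elementalComposition(numeric(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: '", formula, "'", call. = FALSE)
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  elementalComposition(stats::setNames(cnts, syms))
}

#' Add or subtract elemental compositions element-wise
#'
#' Subtraction that would drive any count negative is an error: a molecule
#' cannot contain a negative number of atoms.
#'
#' @param a,b Compositions (named count vectors).
#' @return A composition.
#' @export
#' @examples
#' addComposition(parseFormula("C2H3NO"), parseFormula("H2O"))
addComposition <- function(a, b) {
  a <- elementalComposition(a); b <- elementalComposition(b)
  syms <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  elementalComposition(out)
}

#' @rdname addComposition
#' @export
subtractComposition <- function(a, b) {
  a <- elementalComposition(a); b <- elementalComposition(b)
  syms <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(syms)), syms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("composition subtraction would yield negative count for: ",
         paste(names(out)[out < 0], collapse = ", "), call. = FALSE)
  elementalComposition(out)
}

#' Monoisotopic and average mass of a composition
#'
#' Monoisotopic mass uses the most abundant isotope of each element (the
#' standard convention, which for transition metals such as Cu or Zn is not
#' the lightest isotope); average mass is abundance-weighted.
#'
#' @param composition Composition (named count vector) or formula string.
#' @return Numeric vector `c(mono = , avg = )` in Da.
#' @export
#' @examples
#' compositionMass("H2O")  # mono 18.01056
compositionMass <- function(composition) {
  if (is.character(composition))
    composition <- if (length(composition)) parseFormula(composition)
      else elementalComposition(numeric(0))
  composition <- elementalComposition(composition)
  if (length(composition) == 0) return(c(mono = 0, avg = 0))
  mono <- sum(vapply(names(composition), .elementMono, 0) * composition)
  avg <- sum(vapply(names(composition), .elementAvg, 0) * composition)
  c(mono = mono, avg = avg)
}

## ---- isotope distributions -------------------------------------------------

## Aggregate an (mass, abund) set into nominal-mass bins: isotopologues whose
## masses round to the same integer are merged (abundance-weighted mean mass).
.aggregateNominal <- function(mass, abund) {
  key <- round(mass)
  ab <- rowsum(abund, key)
  wm <- rowsum(abund * mass, key) / ab
  o <- order(as.numeric(rownames(ab)))
  list(mass = as.numeric(wm[o]), abund = as.numeric(ab[o]))
}

.convolveDist <- function(a, b, floor_rel) {
  mass <- outer(a$mass, b$mass, `+`)
  abund <- outer(a$abund, b$abund, `*`)
  d <- .aggregateNominal(as.numeric(mass), as.numeric(abund))
  keep <- d$abund >= floor_rel * max(d$abund)
  list(mass = d$mass[keep], abund = d$abund[keep])
}

## n-fold self-convolution by binary exponentiation.
.powDist <- function(d, n, floor_rel) {
  out <- NULL
  while (n > 0) {
    if (n %% 2 == 1) out <- if (is.null(out)) d else .convolveDist(out, d, floor_rel)
    n <- n %/% 2
    if (n > 0) d <- .convolveDist(d, d, floor_rel)
  }
  out
}

#' Theoretical isotope distribution of a composition
#'
#' Computes the aggregated (nominal-mass-binned) isotopic distribution by
#' iterative convolution of per-element isotope vectors, pruned at a relative
#' abundance threshold and normalized to sum 1. Fine structure within a
#' nominal-mass bin is merged into an abundance-weighted centroid, matching
#' the resolution at which Orbitrap envelope overlays are interpreted.
#'
#' @param composition Composition (named count vector) or formula string.
#' @param prune Relative-abundance threshold in `[0, 1)`: isotopologue bins
#'   below `prune * max(abundance)` are dropped before renormalization. An
#'   internal floor of 1e-12 bounds intermediate convolution size.
#' @return A `data.frame` with columns `mass` (Da, strictly increasing) and
#'   `abund` (summing to 1).
#' @export
#' @examples
#' isotopeDistribution("H2O")
#' isotopeDistribution("C100")[1:3, ]
isotopeDistribution <- function(composition, prune = 1e-5) {
  if (is.character(composition))
    composition <- if (length(composition)) parseFormula(composition)
      else elementalComposition(numeric(0))
  composition <- elementalComposition(composition)
  if (length(composition) == 0)
    stop("cannot compute an isotope distribution for an empty composition",
         call. = FALSE)
  if (prune < 0 || prune >= 1)
    stop("prune must be in [0, 1)", call. = FALSE)
  floor_rel <- max(prune, 1e-12)
  out <- NULL
  for (sym in names(composition)) {
    iso <- .ISOTOPES[[sym]]
    d <- .aggregateNominal(iso$mass, iso$abund)
    d <- .powDist(d, as.integer(round(composition[[sym]])), floor_rel)
    out <- if (is.null(out)) d else .convolveDist(out, d, floor_rel)
  }
  keep <- out$abund >= prune * max(out$abund)
  mass <- out$mass[keep]
  abund <- out$abund[keep]
  abund <- abund / sum(abund)
  o <- order(mass)
  data.frame(mass = mass[o], abund = abund[o])
}

#' Averagine model composition for a target mass
#'
#' Scales the averagine unit (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per
#' 111.1254 Da average) to the target mass, rounds the heavy-element counts
#' and balances the remainder with hydrogens so that the chosen mass type
#' (monoisotopic by default) lands within half a hydrogen of the target.
#' Used to model isotope envelopes when the exact sequence is unknown.
#'
#' @param mass Target neutral mass in Da (> 0).
#' @param type Balance the `"mono"` (default) or `"avg"` mass to the target.
#' @return A composition (named count vector).
#' @export
#' @examples
#' averagineComposition(11112.54)
averagineComposition <- function(mass, type = c("mono", "avg")) {
  type <- match.arg(type)
  stopifnot(is.numeric(mass), length(mass) == 1, mass > 0)
  n <- mass / .AVERAGINE_UNIT_MASS
  heavy <- round(.AVERAGINE[setdiff(names(.AVERAGINE), "H")] * n)
  heavy <- heavy[heavy > 0]
  m_heavy <- compositionMass(heavy)[[type]]
  h_mass <- if (type == "mono") .elementMono("H") else .elementAvg("H")
  nH <- max(0, round((mass - m_heavy) / h_mass))
  elementalComposition(c(heavy, H = nH))
}
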
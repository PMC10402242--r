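## Complexoforms: multisets of proteoforms plus metal cofactors.

#' Construct a Complexoform
#'
#' @param subunits A [Proteoform-class] or list of them (the subunit
#'   multiset; order is irrelevant to identity and mass).
#' @param metals Named count vector of bound metals, e.g. `c(Cu = 1, Zn = 1)`.
#' @param label Optional display name.
#' @return A [Complexoform-class].
#' @export
#' @examples
#' su <- Proteoform("GG")
#' complexoformMass(Complexoform(list(su, su)))
Complexoform <- function(subunits, metals = integer(0), label = NA_character_) {
  if (is(subunits, "Proteoform")) subunits <- list(subunits)
  metals <- metals[metals != 0]
  m <- stats::setNames(as.integer(metals), names(metals))
  new("Complexoform", subunits = subunits, metals = m, label = label)
}

#' @rdname Complexoform
#' @param x A `Complexoform`.
#' @export
setGeneric("subunits", function(x) standardGeneric("subunits"))
#' @rdname Complexoform
#' @export
setMethod("subunits", "Complexoform", function(x) x@subunits)

#' @rdname Complexoform
#' @export
setGeneric("metals", function(x) standardGeneric("metals"))
#' @rdname Complexoform
#' @export
setMethod("metals", "Complexoform", function(x) x@metals)

#' @rdname Complexoform
#' @export
oligomericOrder <- function(x) length(x@subunits)

setMethod("show", "Complexoform", function(object) {
  mm <- complexoformMass(object)
  met <- if (length(object@metals))
    paste0(" + ", paste0(names(object@metals), "x", object@metals,
                         collapse = " + ")) else ""
  cat(sprintf("Complexoform%s: %d subunit(s)%s, %.4f Da mono\n",
              if (is.na(object@label)) "" else paste0(" '", object@label, "'"),
              length(object@subunits), met, mm[["mono"]]))
  for (s in object@subunits)
    cat("  ", proteinId(s), ": ", serializeProteoform(s), "\n", sep = "")
})

#' Neutral mass of a complexoform
#'
#' Sum of subunit proteoform masses plus one [metalAdductDelta()] per bound
#' metal (default proton displacement per metal).
#'
#' @param x A [Complexoform-class].
#' @return `c(mono = , avg = )` in Da.
#' @export
complexoformMass <- function(x) {
  stopifnot(is(x, "Complexoform"))
  ms <- vapply(x@subunits, proteoformMass, c(mono = 0, avg = 0))
  mono <- sum(ms["mono", ]); avg <- sum(ms["avg", ])
  for (met in names(x@metals)) {
    mono <- mono + x@metals[[met]] * metalAdductDelta(met, type = "mono")
    avg <- avg + x@metals[[met]] * metalAdductDelta(met, type = "avg")
  }
  c(mono = mono, avg = avg)
}

#' Stoichiometry summary of a complexoform
#'
#' @param x A [Complexoform-class].
#' @return A list with `proteins` (subunit counts per protein id), `mods`
#'   (total modification counts across subunits, terminal mods included) and
#'   `metals`.
#' @export
stoichiometryRecord <- function(x) {
  stopifnot(is(x, "Complexoform"))
  prot <- table(vapply(x@subunits, proteinId, ""))
  modn <- unlist(lapply(x@subunits, function(s)
    c(s@siteMods$name, s@ntermMod[!is.na(s@ntermMod)],
      s@ctermMod[!is.na(s@ctermMod)])))
  list(proteins = stats::setNames(as.integer(prot), names(prot)),
       mods = if (length(modn))
         stats::setNames(as.integer(table(modn)), names(table(modn)))
       else stats::setNames(integer(0), character(0)),
       metals = x@metals)
}

#' Total modification count of a complexoform (used for ranking ties)
#' @keywords internal
.totalMods <- function(x) {
  sum(vapply(x@subunits, function(s)
    nrow(s@siteMods) + !is.na(s@ntermMod) + !is.na(s@ctermMod), 0L))
}
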
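#' @import methods
NULL

#' MassDelta: a named mass shift
#'
#' A modification (PTM, truncation loss, disulfide, ...) expressed as a mass
#' shift. When an elemental composition difference is available it is stored
#' as a gain and a loss composition (both non-negative), and the monoisotopic
#' shift must agree with the composition to 1e-4 Da (checked by validity).
#'
#' @slot name Modification identifier (registry key).
#' @slot monoMass Monoisotopic shift in Da (may be negative).
#' @slot avgMass Average-mass shift in Da.
#' @slot gain,loss Elemental compositions (named count vectors; possibly empty)
#'   whose difference realizes the shift.
#' @slot targets Residue letters and/or `"N-term"`/`"C-term"` the shift may be
#'   placed on; `"*"` means anywhere.
#' @exportClass MassDelta
setClass("MassDelta",
  representation(name = "character", monoMass = "numeric", avgMass = "numeric",
                 gain = "numeric", loss = "numeric", targets = "character"),
  prototype(gain = stats::setNames(numeric(0), character(0)),
            loss = stats::setNames(numeric(0), character(0)),
            targets = "*"))

setValidity("MassDelta", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name))
    return("name must be a non-empty string")
  if (length(object@gain) || length(object@loss)) {
    mono <- compositionMass(object@gain)[["mono"]] -
      compositionMass(object@loss)[["mono"]]
    if (abs(mono - object@monoMass) > 1e-4)
      return(sprintf(
        "monoMass (%.5f) disagrees with composition delta (%.5f) for '%s'",
        object@monoMass, mono, object@name))
  }
  TRUE
})

#' Proteoform: a base sequence with modifications
#'
#' The processed (observed) amino-acid sequence plus terminal and side-chain
#' modifications, intra-chain disulfides, and an optional truncation record
#' mapping the processed form back to canonical coordinates. Site positions
#' are 1-based on the processed sequence. Modifications are referenced by
#' registry name (see [modDelta()]); an `NA` position with `localized = FALSE`
#' denotes a modification identified by mass shift but not localized.
#'
#' @slot proteinId Protein identifier.
#' @slot sequence Processed amino-acid sequence (canonical letters plus U).
#' @slot ntermMod,ctermMod Terminal modification names (`NA_character_` = none).
#' @slot siteMods `data.frame` with columns `position` (integer, `NA` for
#'   unlocalized), `name` (registry key), `localized` (logical).
#' @slot disulfides Two-column integer matrix of cysteine index pairs.
#' @slot truncation Integer of length 0 or 2: `(start, end)` on the canonical
#'   sequence.
#' @exportClass Proteoform
setClass("Proteoform",
  representation(proteinId = "character", sequence = "character",
                 ntermMod = "character", ctermMod = "character",
                 siteMods = "data.frame", disulfides = "matrix",
                 truncation = "integer"),
  prototype(proteinId = "protein", ntermMod = NA_character_,
            ctermMod = NA_character_,
            siteMods = data.frame(position = integer(0), name = character(0),
                                  localized = logical(0)),
            disulfides = matrix(integer(0), ncol = 2),
            truncation = integer(0)))

setValidity("Proteoform", function(object) {
  seqchars <- strsplit(object@sequence, "")[[1]]
  bad <- setdiff(seqchars, names(.RESIDUES))
  if (length(bad))
    return(paste0("non-canonical residue letter(s): ",
                  paste(unique(bad), collapse = ", ")))
  n <- length(seqchars)
  sm <- object@siteMods
  if (!all(c("position", "name", "localized") %in% names(sm)))
    return("siteMods must have columns position, name, localized")
  pos <- sm$position[!is.na(sm$position)]
  if (length(pos) && (any(pos < 1) || any(pos > n)))
    return("site modification position outside sequence")
  if (anyDuplicated(pos))
    return("duplicate localized modification positions")
  for (i in seq_len(nrow(sm))) {
    if (is.na(sm$position[i])) next
    d <- modDelta(sm$name[i])
    tg <- d@targets
    if (!("*" %in% tg) && !(seqchars[sm$position[i]] %in% tg))
      return(sprintf("modification '%s' not allowed on residue %s at %d",
                     sm$name[i], seqchars[sm$position[i]], sm$position[i]))
  }
  ds <- object@disulfides
  if (length(ds)) {
    if (ncol(ds) != 2) return("disulfides must be a 2-column matrix")
    if (any(ds < 1) || any(ds > n)) return("disulfide index outside sequence")
    if (!all(seqchars[as.vector(ds)] == "C"))
      return("disulfide indices must reference cysteines")
  }
  if (!length(object@truncation) %in% c(0L, 2L))
    return("truncation must be empty or (start, end)")
  TRUE
})

#' Complexoform: a multiset of proteoforms plus metal cofactors
#'
#' The unit of identification in native top-down analysis: a complex defined
#' by the exact proteoforms (not merely the proteins) composing it, plus any
#' non-covalently bound metal ions.
#'
#' @slot subunits List of [Proteoform-class] objects (at least one).
#' @slot metals Named integer vector of metal counts, e.g. `c(Cu = 1, Zn = 1)`.
#' @slot label Optional display name.
#' @exportClass Complexoform
setClass("Complexoform",
  representation(subunits = "list", metals = "integer", label = "character"),
  prototype(metals = stats::setNames(integer(0), character(0)),
            label = NA_character_))

setValidity("Complexoform", function(object) {
  if (length(object@subunits) < 1)
    return("a complexoform has at least one subunit")
  if (!all(vapply(object@subunits, is, TRUE, "Proteoform")))
    return("all subunits must be Proteoform objects")
  if (length(object@metals)) {
    if (is.null(names(object@metals)))
      return("metals must be a named count vector")
    bad <- setdiff(names(object@metals), names(.METAL_DEFAULT_DISPLACEMENT))
    if (length(bad))
      return(paste0("unsupported metal(s): ", paste(bad, collapse = ", ")))
    if (any(object@metals < 0)) return("metal counts must be >= 0")
  }
  TRUE
})

#' Spectrum: a centroided peak list with MS^n provenance
#'
#' @slot id Spectrum identifier (unique within a run).
#' @slot msLevel Integer MS level (1, 2 or 3).
#' @slot mz,intensity Parallel numeric vectors; `mz` strictly positive and
#'   sorted ascending.
#' @slot precursorId Id of the parent spectrum (`NA` for MS1).
#' @slot isoCenter,isoWidth Precursor isolation window center (m/z) and full
#'   width (Th); `NA` when not applicable.
#' @slot precursorCharge Assumed precursor charge (`NA` = unknown; never
#'   guessed at read time).
#' @slot activation Activation label, e.g. `"HCD"` (`NA` for MS1).
#' @slot faimsCV FAIMS compensation voltage in volts (`NA` if absent).
#'   Metadata only: spectra at different CVs are processed independently.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(id = "character", msLevel = "integer",
                 mz = "numeric", intensity = "numeric",
                 precursorId = "character", isoCenter = "numeric",
                 isoWidth = "numeric", precursorCharge = "integer",
                 activation = "character", faimsCV = "numeric"),
  prototype(precursorId = NA_character_, isoCenter = NA_real_,
            isoWidth = NA_real_, precursorCharge = NA_integer_,
            activation = NA_character_, faimsCV = NA_real_))

setValidity("Spectrum", function(object) {
  if (length(object@id) != 1 || !nzchar(object@id))
    return("id must be a non-empty string")
  if (!object@msLevel %in% 1:3) return("msLevel must be 1, 2 or 3")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  if (length(object@mz)) {
    if (any(object@mz <= 0)) return("all m/z must be > 0")
    if (is.unsorted(object@mz)) return("peaks must be sorted by m/z")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
  }
  if (object@msLevel >= 2 && is.na(object@precursorId))
    return("MS level >= 2 requires a precursor id")
  TRUE
})
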
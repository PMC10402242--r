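## Proteoform construction, accessors, mass arithmetic and the text notation.

#' Construct a Proteoform
#'
#' @param sequence Processed amino-acid sequence actually observed (after any
#'   truncation / initial-Met cleavage); canonical letters plus U.
#' @param proteinId Protein identifier.
#' @param ntermMod,ctermMod Terminal modification names (registry keys), or
#'   `NA` for none. Note that `"met-loss"` as an N-terminal modification is an
#'   alternative to passing the cleaved sequence; the two conventions must not
#'   be combined for the same methionine.
#' @param siteMods `data.frame` with columns `position` (1-based on
#'   `sequence`; `NA` for a modification identified but not localized), `name`
#'   and `localized` (defaults to `!is.na(position)` when omitted).
#' @param disulfides Two-column matrix (or vector of length 2) of cysteine
#'   index pairs forming intra-chain disulfide bonds.
#' @param truncation Optional `c(start, end)` of the processed form on the
#'   canonical sequence, for coordinate mapping.
#' @return A [Proteoform-class] object.
#' @export
#' @examples
#' p <- Proteoform("AKG", ntermMod = "acetyl",
#'                 siteMods = data.frame(position = 2, name = "acetyl"))
#' proteoformMass(p)
Proteoform <- function(sequence, proteinId = "protein",
                       ntermMod = NA_character_, ctermMod = NA_character_,
                       siteMods = NULL, disulfides = NULL,
                       truncation = integer(0)) {
  if (is.null(siteMods))
    siteMods <- data.frame(position = integer(0), name = character(0),
                           localized = logical(0))
  if (is.null(siteMods$localized)) siteMods$localized <- !is.na(siteMods$position)
  siteMods$position <- as.integer(siteMods$position)
  if (is.null(disulfides)) disulfides <- matrix(integer(0), ncol = 2)
  if (is.vector(disulfides)) disulfides <- matrix(as.integer(disulfides),
                                                  ncol = 2, byrow = TRUE)
  ## check terminal mod names resolve (and that a composition-registered
  ## terminal mod actually targets a terminus or anything)
  for (tm in c(ntermMod, ctermMod)) if (!is.na(tm)) modDelta(tm)
  new("Proteoform", proteinId = proteinId, sequence = sequence,
      ntermMod = ntermMod, ctermMod = ctermMod,
      siteMods = siteMods[, c("position", "name", "localized")],
      disulfides = disulfides, truncation = as.integer(truncation))
}

#' @rdname Proteoform
#' @param object,x A `Proteoform`.
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname Proteoform
#' @export
setMethod("proteinId", "Proteoform", function(x) x@proteinId)

#' @rdname Proteoform
#' @export
setGeneric("baseSequence", function(x) standardGeneric("baseSequence"))
#' @rdname Proteoform
#' @export
setMethod("baseSequence", "Proteoform", function(x) x@sequence)

#' @rdname Proteoform
#' @export
setGeneric("siteMods", function(x) standardGeneric("siteMods"))
#' @rdname Proteoform
#' @export
setMethod("siteMods", "Proteoform", function(x) x@siteMods)

#' @rdname Proteoform
#' @export
setGeneric("disulfides", function(x) standardGeneric("disulfides"))
#' @rdname Proteoform
#' @export
setMethod("disulfides", "Proteoform", function(x) x@disulfides)

setMethod("show", "Proteoform", function(object) {
  n <- nchar(object@sequence)
  cat(sprintf("Proteoform '%s' (%d aa, %.4f Da mono)\n", object@proteinId, n,
              proteoformMass(object)[["mono"]]))
  cat(" ", serializeProteoform(object), "\n")
})

.residueMasses <- function(type = "mono") {
  vapply(.RESIDUES, function(comp) compositionMass(comp)[[type]], 0)
}

## cached residue mass tables
.RES_MONO <- NULL
.RES_AVG <- NULL

.resMono <- function() {
  if (is.null(.RES_MONO)) {
    utils::assignInMyNamespace(".RES_MONO", .residueMasses("mono"))
  }
  .RES_MONO
}
.resAvg <- function() {
  if (is.null(.RES_AVG)) {
    utils::assignInMyNamespace(".RES_AVG", .residueMasses("avg"))
  }
  .RES_AVG
}

.modMono <- function(name) modDelta(name)@monoMass
.modAvg <- function(name) modDelta(name)@avgMass

#' Neutral mass of a proteoform
#'
#' Sum of residue masses + H2O + terminal and site modification deltas +
#' one -2.01565 Da (2 H) per intra-chain disulfide. Unlocalized site
#' modifications contribute their mass regardless of position.
#'
#' @param p A [Proteoform-class].
#' @return `c(mono = , avg = )` in Da.
#' @export
#' @examples
#' proteoformMass(Proteoform("GG"))  # 132.05349
proteoformMass <- function(p) {
  stopifnot(is(p, "Proteoform"))
  chars <- strsplit(p@sequence, "")[[1]]
  mono <- sum(.resMono()[chars]) + compositionMass(.WATER)[["mono"]]
  avg <- sum(.resAvg()[chars]) + compositionMass(.WATER)[["avg"]]
  modnames <- c(p@siteMods$name,
                p@ntermMod[!is.na(p@ntermMod)], p@ctermMod[!is.na(p@ctermMod)])
  if (length(modnames)) {
    mono <- mono + sum(vapply(modnames, .modMono, 0))
    avg <- avg + sum(vapply(modnames, .modAvg, 0))
  }
  nds <- nrow(p@disulfides)
  if (nds) {
    mono <- mono + nds * .modMono("disulfide")
    avg <- avg + nds * .modAvg("disulfide")
  }
  c(mono = mono, avg = avg)
}

#' Map processed-sequence positions to canonical coordinates
#'
#' Positions on a proteoform are 1-based on the processed (observed)
#' sequence; when a truncation record is present (or the N-terminal
#' modification is `"met-loss"`), this returns the corresponding positions on
#' the canonical sequence. Useful for comparing site reports across numbering
#' conventions (e.g. a site called C80 on the Met-cleaved form is C81
#' canonically).
#'
#' @param p A [Proteoform-class].
#' @param positions Integer positions on the processed sequence.
#' @return Integer positions on the canonical sequence.
#' @export
canonicalPosition <- function(p, positions) {
  offset <- if (length(p@truncation)) p@truncation[1] - 1L
    else if (!is.na(p@ntermMod) && p@ntermMod == "met-loss") 1L else 0L
  as.integer(positions) + offset
}

## ---- text notation ---------------------------------------------------------

#' Proteoform text notation
#'
#' A ProForma-inspired grammar: `{mod}-` prefixes an N-terminal modification,
#' `-{mod}` suffixes a C-terminal one, `[mod]` follows a modified residue,
#' `[?mod]` after the sequence denotes a modification identified by mass but
#' not localized, and `(ds:i-j)` records an intra-chain disulfide. Example:
#' `"{acetyl}-AK[acetyl]G"`. `parseProteoform()` and `serializeProteoform()`
#' are inverse up to the fields the grammar carries (protein id and
#' truncation metadata are not part of the text form).
#'
#' @param text Proteoform string.
#' @param proteinId Identifier to attach to the parsed proteoform.
#' @return `parseProteoform()`: a [Proteoform-class];
#'   `serializeProteoform()`: a string.
#' @export
#' @examples
#' p <- parseProteoform("{acetyl}-AK[acetyl]G")
#' serializeProteoform(p)
parseProteoform <- function(text, proteinId = "protein") {
  stopifnot(is.character(text), length(text) == 1)
  s <- text
  pos <- 1L  # character offset into original text, for error reporting
  fail <- function(off, why)
    stop(sprintf("malformed proteoform text at character %d: %s", off, why),
         call. = FALSE)
  ntermMod <- NA_character_; ctermMod <- NA_character_
  m <- regmatches(s, regexec("^\\{([^}]+)\\}-", s))[[1]]
  if (length(m)) { ntermMod <- m[2]; pos <- pos + nchar(m[1]); s <- substring(s, nchar(m[1]) + 1) }
  m <- regmatches(s, regexec("-\\{([^}]+)\\}$", s))[[1]]
  if (length(m)) { ctermMod <- m[2]; s <- substring(s, 1, nchar(s) - nchar(m[1])) }

  seqchars <- character(0)
  positions <- integer(0); names_ <- character(0); localized <- logical(0)
  dspairs <- NULL
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substring(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substring(s, i), fixed = TRUE)
      if (j < 0) fail(pos + i - 1L, "unterminated '['")
      token <- substring(s, i + 1L, i + j - 2L)
      if (startsWith(token, "?")) {
        positions <- c(positions, NA_integer_)
        names_ <- c(names_, substring(token, 2))
        localized <- c(localized, FALSE)
      } else {
        if (!length(seqchars)) fail(pos + i - 1L, "modification before any residue")
        positions <- c(positions, length(seqchars))
        names_ <- c(names_, token)
        localized <- c(localized, TRUE)
      }
      i <- i + j
    } else if (ch == "(") {
      j <- regexpr(")", substring(s, i), fixed = TRUE)
      if (j < 0) fail(pos + i - 1L, "unterminated '('")
      token <- substring(s, i + 1L, i + j - 2L)
      dm <- regmatches(token, regexec("^ds:([0-9]+)-([0-9]+)$", token))[[1]]
      if (!length(dm)) fail(pos + i - 1L, paste0("unrecognized group '", token, "'"))
      dspairs <- rbind(dspairs, as.integer(dm[2:3]))
      i <- i + j
    } else if (grepl("^[A-Z]$", ch)) {
      seqchars <- c(seqchars, ch)
      i <- i + 1L
    } else {
      fail(pos + i - 1L, paste0("unexpected character '", ch, "'"))
    }
  }
  if (!length(seqchars)) fail(pos, "empty sequence")
  Proteoform(paste(seqchars, collapse = ""), proteinId = proteinId,
             ntermMod = ntermMod, ctermMod = ctermMod,
             siteMods = data.frame(position = positions, name = names_,
                                   localized = localized),
             disulfides = if (is.null(dspairs)) NULL else dspairs)
}

#' @rdname parseProteoform
#' @param p A [Proteoform-class].
#' @export
serializeProteoform <- function(p) {
  stopifnot(is(p, "Proteoform"))
  chars <- strsplit(p@sequence, "")[[1]]
  sm <- p@siteMods
  loc <- sm[!is.na(sm$position), , drop = FALSE]
  unloc <- sm[is.na(sm$position), , drop = FALSE]
  out <- chars
  for (i in seq_len(nrow(loc)))
    out[loc$position[i]] <- paste0(out[loc$position[i]], "[", loc$name[i], "]")
  body <- paste(out, collapse = "")
  if (nrow(unloc))
    body <- paste0(body, paste0("[?", sort(unloc$name), "]", collapse = ""))
  ds <- p@disulfides
  if (nrow(ds)) {
    ds <- ds[order(ds[, 1]), , drop = FALSE]
    body <- paste0(body, paste0("(ds:", ds[, 1], "-", ds[, 2], ")",
                                collapse = ""))
  }
  if (!is.na(p@ntermMod)) body <- paste0("{", p@ntermMod, "}-", body)
  if (!is.na(p@ctermMod)) body <- paste0(body, "-{", p@ctermMod, "}")
  body
}

#' Read protein sequences from a FASTA file
#'
#' Uses Biostrings when installed; otherwise a minimal base-R reader
#' (sufficient for reference protein sequences).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = first word of each
#'   header).
#' @export
readFasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    out <- as.character(aa)
    names(out) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  stats::setNames(toupper(gsub("\\s", "", seqs)), ids)
}
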
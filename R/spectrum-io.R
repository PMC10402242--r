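## Spectrum construction, accessors, the bespoke peak-list text format and
## the MS1 -> MS2 -> MS3 provenance chain.

#' Construct a Spectrum
#'
#' @param id Spectrum identifier.
#' @param msLevel MS level (1, 2 or 3).
#' @param mz,intensity Peak vectors (sorted by `mz`; intensities >= 0).
#' @param precursorId Parent spectrum id (required for `msLevel >= 2`).
#' @param isoCenter,isoWidth Isolation window center (m/z) and full width (Th).
#' @param precursorCharge Assumed precursor charge (`NA` = unknown).
#' @param activation Activation label, e.g. `"HCD"`.
#' @param faimsCV FAIMS compensation voltage (V), metadata only.
#' @return A [Spectrum-class].
#' @export
Spectrum <- function(id, msLevel, mz = numeric(0), intensity = numeric(0),
                     precursorId = NA_character_, isoCenter = NA_real_,
                     isoWidth = NA_real_, precursorCharge = NA_integer_,
                     activation = NA_character_, faimsCV = NA_real_) {
  new("Spectrum", id = as.character(id), msLevel = as.integer(msLevel),
      mz = as.numeric(mz), intensity = as.numeric(intensity),
      precursorId = as.character(precursorId),
      isoCenter = as.numeric(isoCenter), isoWidth = as.numeric(isoWidth),
      precursorCharge = as.integer(precursorCharge),
      activation = as.character(activation), faimsCV = as.numeric(faimsCV))
}

#' @rdname Spectrum
#' @param x A `Spectrum`.
#' @export
setGeneric("msLevel", function(x) standardGeneric("msLevel"))
#' @rdname Spectrum
#' @export
setMethod("msLevel", "Spectrum", function(x) x@msLevel)

#' @rdname Spectrum
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname Spectrum
#' @export
setMethod("peaks", "Spectrum", function(x)
  data.frame(mz = x@mz, intensity = x@intensity))

#' @rdname Spectrum
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))
#' @rdname Spectrum
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@id)

#' @rdname Spectrum
#' @export
setGeneric("precursorId", function(x) standardGeneric("precursorId"))
#' @rdname Spectrum
#' @export
setMethod("precursorId", "Spectrum", function(x) x@precursorId)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s' MS%d, %d peak(s)", object@id, object@msLevel,
              length(object@mz)))
  if (!is.na(object@precursorId))
    cat(sprintf(", precursor %s @ %.4f (z=%s)", object@precursorId,
                object@isoCenter,
                ifelse(is.na(object@precursorCharge), "?",
                       object@precursorCharge)))
  if (!is.na(object@faimsCV)) cat(sprintf(", CV %g V", object@faimsCV))
  cat("\n")
})

## ---- bespoke peak-list text format ----------------------------------------
##
## BEGIN SPECTRUM id=<id>
## ms_level=<1|2|3>
## precursor_id=<id>           (MS>=2)
## isolation_center=<m/z>      isolation_width=<Th>
## charge=<z>                  activation=<label>     faims_cv=<V>
## <mz> <intensity>            (one peak per line, 6 decimal places)
## END SPECTRUM

#' Read and write the peak-list text format
#'
#' A plain-text interchange format: one `BEGIN SPECTRUM ... END SPECTRUM`
#' block per spectrum, `key=value` metadata lines, then two-column peak
#' lines. Round trips are lossless to 6 decimal places.
#'
#' @param path File path.
#' @return `readPeaklist()`: a list of [Spectrum-class] objects.
#' @export
readPeaklist <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  meta <- NULL; mz <- NULL; int <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "BEGIN SPECTRUM")) {
      if (!is.null(meta))
        stop("line ", ln, ": nested BEGIN SPECTRUM", call. = FALSE)
      id <- sub("^BEGIN SPECTRUM\\s+id=", "", line)
      meta <- list(id = id); mz <- numeric(0); int <- numeric(0)
    } else if (line == "END SPECTRUM") {
      if (is.null(meta))
        stop("line ", ln, ": END SPECTRUM without BEGIN", call. = FALSE)
      if (is.unsorted(mz))
        stop("line ", ln, ": peaks not sorted by m/z in spectrum '",
             meta$id, "'", call. = FALSE)
      spectra[[length(spectra) + 1L]] <- Spectrum(
        id = meta$id, msLevel = as.integer(meta$ms_level %||% 1L),
        mz = mz, intensity = int,
        precursorId = meta$precursor_id %||% NA_character_,
        isoCenter = as.numeric(meta$isolation_center %||% NA),
        isoWidth = as.numeric(meta$isolation_width %||% NA),
        precursorCharge = as.integer(meta$charge %||% NA),
        activation = meta$activation %||% NA_character_,
        faimsCV = as.numeric(meta$faims_cv %||% NA))
      meta <- NULL
    } else if (grepl("^[a-z_]+=", line)) {
      if (is.null(meta))
        stop("line ", ln, ": metadata outside spectrum block", call. = FALSE)
      kv <- regmatches(line, regexec("^([a-z_]+)=(.*)$", line))[[1]]
      meta[[kv[2]]] <- kv[3]
    } else {
      if (is.null(meta))
        stop("line ", ln, ": peak outside spectrum block", call. = FALSE)
      vals <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1]]))
      if (length(vals) != 2 || anyNA(vals))
        stop("line ", ln, ": expected '<mz> <intensity>'", call. = FALSE)
      if (vals[1] <= 0)
        stop("line ", ln, ": m/z must be > 0", call. = FALSE)
      if (vals[2] < 0)
        stop("line ", ln, ": intensity must be >= 0", call. = FALSE)
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    }
  }
  if (!is.null(meta))
    stop("unterminated spectrum block '", meta$id, "'", call. = FALSE)
  spectra
}

#' @rdname readPeaklist
#' @param spectra List of [Spectrum-class] objects.
#' @export
writePeaklist <- function(spectra, path) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nativeTDP peaklist v1", con)
  for (s in spectra) {
    writeLines(paste0("BEGIN SPECTRUM id=", s@id), con)
    writeLines(paste0("ms_level=", s@msLevel), con)
    if (!is.na(s@precursorId))
      writeLines(paste0("precursor_id=", s@precursorId), con)
    if (!is.na(s@isoCenter))
      writeLines(sprintf("isolation_center=%.6f", s@isoCenter), con)
    if (!is.na(s@isoWidth))
      writeLines(sprintf("isolation_width=%.6f", s@isoWidth), con)
    if (!is.na(s@precursorCharge))
      writeLines(paste0("charge=", s@precursorCharge), con)
    if (!is.na(s@activation))
      writeLines(paste0("activation=", s@activation), con)
    if (!is.na(s@faimsCV))
      writeLines(sprintf("faims_cv=%.6f", s@faimsCV), con)
    if (length(s@mz))
      writeLines(sprintf("%.6f %.6f", s@mz, s@intensity), con)
    writeLines("END SPECTRUM", con)
  }
  invisible(path)
}

## ---- provenance chain ------------------------------------------------------

#' Link spectra into MS1 -> MS2 -> MS3 trees
#'
#' Builds the precursor tree the identification logic walks: every MS^n
#' spectrum hangs off its parent via `precursorId`. Dangling or cyclic
#' references are errors listing the offending ids; MS2/MS3 spectra whose
#' chain does not reach an MS1 root are reported as orphans.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @return A list with `roots` (MS1 ids), `children` (named list id ->
#'   character vector of child ids), `spectra` (named by id) and `orphans`.
#' @export
linkHierarchy <- function(spectra) {
  ids <- vapply(spectra, spectrumId, "")
  if (anyDuplicated(ids))
    stop("duplicate spectrum ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(spectra) <- ids
  parent <- vapply(spectra, precursorId, "")
  has_parent <- !is.na(parent)
  dangling <- parent[has_parent][!parent[has_parent] %in% ids]
  if (length(dangling))
    stop("dangling precursor id(s): ", paste(unique(dangling), collapse = ", "),
         call. = FALSE)
  ## cycle check: walk up from every node
  for (i in seq_along(ids)) {
    seen <- character(0); cur <- ids[i]
    while (!is.na(parent[cur])) {
      if (cur %in% seen)
        stop("cyclic precursor reference involving: ",
             paste(seen, collapse = ", "), call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent[cur]
    }
  }
  children <- split(ids[has_parent], parent[has_parent])
  levels <- vapply(spectra, msLevel, 0L)
  roots <- ids[levels == 1L]
  ## orphans: non-MS1 spectra whose chain terminates in a non-MS1 spectrum
  orphans <- character(0)
  for (i in which(levels > 1L)) {
    cur <- ids[i]
    while (!is.na(parent[cur])) cur <- parent[cur]
    if (levels[cur] != 1L) orphans <- c(orphans, ids[i])
  }
  list(roots = roots, children = children, spectra = spectra,
       orphans = orphans)
}
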
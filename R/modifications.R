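## Modification registry: the PTM vocabulary used by proteoforms, the search
## space and the fragment engine. Extensible at run time (registerMod) or
## from a YAML config (loadModConfig).

.MOD_REGISTRY <- new.env(parent = emptyenv())

.makeDelta <- function(name, gain = character(0), loss = character(0),
                       targets = "*") {
  g <- if (is.character(gain)) parseFormula(paste(gain, collapse = "")) else
    elementalComposition(gain)
  l <- if (is.character(loss)) parseFormula(paste(loss, collapse = "")) else
    elementalComposition(loss)
  mono <- compositionMass(g)[["mono"]] - compositionMass(l)[["mono"]]
  avg <- compositionMass(g)[["avg"]] - compositionMass(l)[["avg"]]
  new("MassDelta", name = name, monoMass = mono, avgMass = avg,
      gain = g, loss = l, targets = targets)
}

.initModRegistry <- function() {
  reg <- list(
    .makeDelta("acetyl",      gain = "C2H2O",            targets = c("K", "S", "T", "N-term")),
    .makeDelta("methyl",      gain = "CH2",              targets = c("K", "R", "N-term")),
    .makeDelta("dimethyl",    gain = "C2H4",             targets = c("K", "R")),
    .makeDelta("trimethyl",   gain = "C3H6",             targets = "K"),
    .makeDelta("phospho",     gain = "HPO3",             targets = c("S", "T", "Y")),
    .makeDelta("deamidation", gain = "O", loss = "HN",   targets = c("N", "Q")),
    .makeDelta("nitrosyl",    gain = "NO", loss = "H",   targets = "C"),
    .makeDelta("ox",          gain = "O",                targets = c("M", "C", "W")),
    .makeDelta("met-loss",    loss = "C5H9NOS",          targets = "N-term"),
    .makeDelta("disulfide",   loss = "H2",               targets = "C")
  )
  for (d in reg) assign(d@name, d, envir = .MOD_REGISTRY)
}
.initModRegistry()

#' Look up a modification mass delta by name
#'
#' The built-in registry covers the common top-down vocabulary: `acetyl`
#' (+42.01057), `methyl` (+14.01565), `dimethyl` (+28.03130), `trimethyl`
#' (+42.04695), `phospho` (+79.96633), `deamidation` (+0.98402), `nitrosyl`
#' (S-nitrosylation, +28.99017), `ox` (+15.99491), `met-loss` (initial
#' methionine cleavage, -131.04049) and `disulfide` (-2.01565), all
#' monoisotopic Da. Extend with [registerMod()] or [loadModConfig()].
#'
#' @param name Modification identifier.
#' @return A [MassDelta-class] object.
#' @export
#' @examples
#' modDelta("deamidation")@monoMass
modDelta <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  if (!exists(name, envir = .MOD_REGISTRY, inherits = FALSE))
    stop("unknown modification '", name, "'; known: ",
         paste(sort(knownMods()), collapse = ", "), call. = FALSE)
  get(name, envir = .MOD_REGISTRY, inherits = FALSE)
}

#' @rdname modDelta
#' @export
knownMods <- function() ls(envir = .MOD_REGISTRY)

#' Register a modification
#'
#' @param name Registry key.
#' @param gain,loss Elemental formulas (strings) or compositions gained/lost.
#'   Either may be empty. If both are empty, `monoMass`/`avgMass` must be
#'   given directly.
#' @param monoMass,avgMass Mass shifts in Da when no composition is known.
#' @param targets Residue letters and/or `"N-term"`/`"C-term"`; `"*"` = any.
#' @return The registered [MassDelta-class], invisibly.
#' @export
registerMod <- function(name, gain = character(0), loss = character(0),
                        monoMass = NULL, avgMass = NULL, targets = "*") {
  if (length(gain) || length(loss)) {
    d <- .makeDelta(name, gain, loss, targets)
  } else {
    if (is.null(monoMass))
      stop("give either a composition (gain/loss) or monoMass", call. = FALSE)
    if (is.null(avgMass)) avgMass <- monoMass
    d <- new("MassDelta", name = name, monoMass = monoMass, avgMass = avgMass,
             targets = targets)
  }
  assign(name, d, envir = .MOD_REGISTRY)
  invisible(d)
}

#' Load modification definitions from a YAML config
#'
#' The file holds a list of entries with fields `name`, and either `gain` /
#' `loss` formulas or a `mono_mass` (optionally `avg_mass`), plus optional
#' `targets`.
#'
#' @param path YAML file path.
#' @return Character vector of registered names, invisibly.
#' @export
loadModConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  nm <- vapply(cfg, function(e) {
    registerMod(e$name,
                gain = if (is.null(e$gain)) character(0) else e$gain,
                loss = if (is.null(e$loss)) character(0) else e$loss,
                monoMass = e$mono_mass, avgMass = e$avg_mass,
                targets = if (is.null(e$targets)) "*" else unlist(e$targets))
    e$name
  }, "")
  invisible(nm)
}

#' Mass delta of a non-covalently bound metal adduct
#'
#' In native-MS bookkeeping a bound metal cation displaces protons from the
#' neutral species so that the observed charge stays equal to the protonation
#' count: the neutral-mass shift is the metal's mass minus the displaced
#' hydrogens. Divalent cations (Cu, Zn, Fe, Mg, Ca, Ni, Mn) default to 2
#' displaced protons; Na/K to 1.
#'
#' @param metal Element symbol of the metal.
#' @param displaced Number of displaced protons (>= 0); default per metal.
#' @param type `"mono"` (default) or `"avg"`.
#' @return Mass shift in Da.
#' @export
#' @examples
#' metalAdductDelta("Cu")  # +60.91395
#' metalAdductDelta("Zn")  # +61.91349
metalAdductDelta <- function(metal, displaced = NULL,
                             type = c("mono", "avg")) {
  type <- match.arg(type)
  if (!metal %in% names(.METAL_DEFAULT_DISPLACEMENT))
    stop("unsupported metal '", metal, "'; supported: ",
         paste(names(.METAL_DEFAULT_DISPLACEMENT), collapse = ", "),
         call. = FALSE)
  if (is.null(displaced)) displaced <- .METAL_DEFAULT_DISPLACEMENT[[metal]]
  stopifnot(displaced >= 0)
  m <- if (type == "mono") .elementMono(metal) else .elementAvg(metal)
  h <- if (type == "mono") .HYDROGEN else .elementAvg("H")
  m - displaced * h
}
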
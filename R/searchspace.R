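## Search-space definition: candidate proteoforms per protein, stoichiometry
## bounds and allowed metals, expanded from a YAML/JSON file or an R list.
##
## Schema (YAML):
##   proteins:
##     - id: SOD1
##       sequence: ATKAV...          # or fasta: path (+ optional entry: id)
##       met_loss: true              # also enumerate the Met-cleaved form
##       truncations: [[2, 248]]     # optional, canonical coordinates
##       nterm_mods: [acetyl]        # each enumerated 0/1x
##       mods:
##         - {name: phospho, max: 1} # counts 0..max, mass-level (unlocalized)
##       disulfides: [[57, 111]]     # fixed on every candidate
##   metals: {Cu: 1, Zn: 1}          # max counts
##   stoichiometry:
##     min: 1
##     max: 2
##     per_protein: {SOD1: [0, 2]}   # optional
##   cap: 1000000

#' Expand a search-space definition into candidate proteoforms
#'
#' Enumerates, per protein, base sequence x truncation variants x N-terminal
#' modification options x modification count multisets (0..max per
#' modification, carried as unlocalized site modifications: intact mass
#' cannot distinguish positional isomers, so matching happens at mass level
#' and localization is deferred to fragment evidence). The expansion is
#' deterministic, duplicate-free and ordered by (protein id, monoisotopic
#' mass).
#'
#' @param x Path to a YAML/JSON file, or an equivalent R list.
#' @param cap Maximum number of enumerated proteoforms and, later, of subunit
#'   multisets visited by [enumerateCandidates()]; exceeding it is an error
#'   naming the offending protein.
#' @return A `SearchSpace`: list with `proteoforms` (list of
#'   [Proteoform-class]), `mono`/`avg` mass vectors, `protein` id vector,
#'   `stoich` (`min`, `max`, `perProtein`), `metals` (max counts) and `cap`.
#' @export
expandSearchSpace <- function(x, cap = NULL) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg$proteins) || !length(cfg$proteins))
    stop("search space must define at least one protein", call. = FALSE)
  if (is.null(cap)) cap <- if (!is.null(cfg$cap)) cfg$cap else 1e6

  forms <- list()
  for (pr in cfg$proteins) {
    id <- pr$id
    if (is.null(id)) stop("every protein needs an 'id'", call. = FALSE)
    seqs <- .proteinVariants(pr)
    nterm_opts <- c(NA_character_, unlist(pr$nterm_mods))
    modspec <- pr$mods
    counts <- .modCountGrid(modspec)
    ds <- if (!is.null(pr$disulfides))
      matrix(as.integer(unlist(pr$disulfides)), ncol = 2, byrow = TRUE)
    else NULL
    pforms <- list()
    for (sv in seqs) for (nt in nterm_opts) for (k in seq_len(nrow(counts))) {
      cnt <- counts[k, , drop = TRUE]
      smods <- data.frame(position = rep(NA_integer_, sum(cnt)),
                          name = as.character(rep(names(cnt), cnt)),
                          localized = logical(sum(cnt)))
      p <- Proteoform(sv$sequence, proteinId = id, ntermMod = nt,
                      siteMods = smods, disulfides = ds,
                      truncation = sv$truncation)
      pforms[[length(pforms) + 1L]] <- p
      if (length(forms) + length(pforms) > cap)
        stop("search-space expansion for protein '", id, "' exceeds cap (",
             format(cap, scientific = FALSE),
             "); tighten modification or truncation bounds", call. = FALSE)
    }
    ## drop duplicates (identical sequence + mod multiset)
    keys <- vapply(pforms, function(p)
      paste(serializeProteoform(p), collapse = ""), "")
    forms <- c(forms, pforms[!duplicated(keys)])
  }

  mono <- vapply(forms, function(p) proteoformMass(p)[["mono"]], 0)
  avg <- vapply(forms, function(p) proteoformMass(p)[["avg"]], 0)
  protein <- vapply(forms, proteinId, "")
  o <- order(protein, mono)
  st <- cfg$stoichiometry
  if (is.null(st)) st <- list(min = 1, max = 1)
  perProtein <- NULL
  if (!is.null(st$per_protein))
    perProtein <- lapply(st$per_protein, function(v) as.integer(unlist(v)))
  metals <- integer(0)
  if (!is.null(cfg$metals))
    metals <- stats::setNames(as.integer(unlist(cfg$metals)),
                              names(cfg$metals))
  out <- list(proteoforms = forms[o], mono = mono[o], avg = avg[o],
              protein = protein[o],
              stoich = list(min = as.integer(st$min %||% 1L),
                            max = as.integer(st$max %||% 1L),
                            perProtein = perProtein),
              metals = metals, cap = cap)
  class(out) <- "SearchSpace"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.SearchSpace <- function(x, ...) {
  cat(sprintf("SearchSpace: %d candidate proteoforms over %d protein(s); %d-%d subunits\n",
              length(x$proteoforms), length(unique(x$protein)),
              x$stoich$min, x$stoich$max))
  if (length(x$metals))
    cat("  metals (max):", paste0(names(x$metals), "<=", x$metals,
                                  collapse = ", "), "\n")
  invisible(x)
}

## sequence variants: full, met-cleaved, explicit truncations
.proteinVariants <- function(pr) {
  if (!is.null(pr$fasta)) {
    seqs <- readFasta(pr$fasta)
    base <- if (!is.null(pr$entry)) seqs[[pr$entry]] else seqs[[1]]
  } else base <- pr$sequence
  if (is.null(base)) stop("protein '", pr$id, "' has no sequence", call. = FALSE)
  base <- toupper(gsub("\\s", "", base))
  out <- list(list(sequence = base, truncation = integer(0)))
  if (isTRUE(pr$met_loss) && startsWith(base, "M"))
    out <- c(out, list(list(sequence = substring(base, 2),
                            truncation = c(2L, nchar(base)))))
  for (tr in pr$truncations) {
    tr <- as.integer(unlist(tr))
    out <- c(out, list(list(sequence = substring(base, tr[1], tr[2]),
                            truncation = tr)))
  }
  out
}

## grid of modification counts: one row per multiset
.modCountGrid <- function(modspec) {
  if (is.null(modspec) || !length(modspec)) {
    m <- matrix(integer(0), nrow = 1, ncol = 0)
    return(m)
  }
  nm <- vapply(modspec, function(m) m$name, "")
  mx <- vapply(modspec, function(m) as.integer(m$max %||% 1L), 0L)
  g <- do.call(expand.grid, lapply(mx, function(k) 0:k))
  names(g) <- nm
  as.matrix(g)
}

## all metal submultisets within max counts -> data.frame of counts + deltas
.metalMultisets <- function(maxCounts) {
  if (!length(maxCounts)) {
    return(list(counts = matrix(integer(0), nrow = 1, ncol = 0),
                mono = 0, avg = 0, n = 0L))
  }
  g <- do.call(expand.grid, lapply(maxCounts, function(k) 0:k))
  names(g) <- names(maxCounts)
  mono <- as.numeric(as.matrix(g) %*%
    vapply(names(maxCounts), metalAdductDelta, 0, type = "mono"))
  avg <- as.numeric(as.matrix(g) %*%
    vapply(names(maxCounts), metalAdductDelta, 0, type = "avg"))
  list(counts = as.matrix(g), mono = mono, avg = avg, n = rowSums(g))
}
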
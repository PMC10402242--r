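# Shared helpers: random object generators and independent brute-force
# oracles used by the property-style tests.

AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")

randomSequence <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# random proteoform with 0-2 localized mods on compatible residues
randomProteoform <- function(len = sample(8:40, 1)) {
  seqstr <- randomSequence(len)
  chars <- strsplit(seqstr, "")[[1]]
  sm <- data.frame(position = integer(0), name = character(0),
                   localized = logical(0))
  opts <- list(acetyl = "K", methyl = c("K", "R"), phospho = c("S", "T", "Y"),
               deamidation = c("N", "Q"), nitrosyl = "C", ox = "M")
  for (nm in sample(names(opts), sample(0:2, 1))) {
    pos <- setdiff(which(chars %in% opts[[nm]]), sm$position)
    if (length(pos))
      sm <- rbind(sm, data.frame(position = pos[sample(length(pos), 1)],
                                 name = nm, localized = TRUE))
  }
  nt <- sample(c(NA_character_, "acetyl"), 1)
  Proteoform(seqstr, ntermMod = nt, siteMods = sm)
}

# exhaustive multiset enumeration oracle for the complexoform search:
# loops over all subunit multisets and metal submultisets, no pruning
bruteForceSearch <- function(space, obsMass, tol) {
  n <- length(space$proteoforms)
  metalGrid <- if (length(space$metals))
    do.call(expand.grid, lapply(space$metals, function(k) 0:k))
  else data.frame(row.names = 1)
  hits <- character(0)
  recurse <- function(start, chosen) {
    k <- length(chosen)
    if (k >= space$stoich$min && k >= 1) {
      ok <- TRUE
      if (!is.null(space$stoich$perProtein)) {
        cnt <- table(space$protein[chosen])
        for (nm in names(space$stoich$perProtein)) {
          x <- if (nm %in% names(cnt)) cnt[[nm]] else 0L
          bb <- space$stoich$perProtein[[nm]]
          if (x < bb[1] || x > bb[2]) ok <- FALSE
        }
      }
      if (ok) {
        base <- sum(space$mono[chosen])
        for (r in seq_len(nrow(metalGrid))) {
          mets <- unlist(metalGrid[r, , drop = FALSE])
          md <- if (length(mets))
            sum(vapply(names(mets), metalAdductDelta, 0) * mets) else 0
          if (abs(base + md - obsMass) <= tol) {
            lab <- paste(
              paste(sort(vapply(space$proteoforms[chosen], function(p)
                paste0(proteinId(p), ":", serializeProteoform(p)), "")),
                collapse = " + "),
              paste(rep(names(mets), mets), collapse = "+"), sep = " | ")
            hits <<- c(hits, lab)
          }
        }
      }
    }
    if (k == space$stoich$max) return()
    for (i in seq(start, length.out = max(0, n - start + 1)))
      recurse(i, c(chosen, i))
  }
  if (n) recurse(1L, integer(0))
  sort(unique(hits))
}

# canonical multiset key for a candidate row, comparable with the oracle's
candidateKey <- function(row) {
  cf <- row$complexoform[[1]]
  paste(
    paste(sort(vapply(cf@subunits, function(p)
      paste0(proteinId(p), ":", serializeProteoform(p)), "")),
      collapse = " + "),
    paste(rep(names(cf@metals), cf@metals), collapse = "+"), sep = " | ")
}

# random small search space for oracle-equivalence tests
randomSearchSpace <- function() {
  nprot <- sample(1:2, 1)
  prots <- lapply(seq_len(nprot), function(i) {
    mods <- list()
    for (nm in sample(c("acetyl", "methyl", "phospho"), sample(1:2, 1)))
      mods[[length(mods) + 1]] <- list(name = nm, max = sample(1:2, 1))
    list(id = paste0("P", i), sequence = randomSequence(sample(10:25, 1)),
         mods = mods)
  })
  smax <- sample(2:3, 1)
  expandSearchSpace(list(
    proteins = prots,
    metals = if (runif(1) < 0.5) list(Cu = 1, Zn = 1) else NULL,
    stoichiometry = list(min = 1, max = smax)))
}

# merge possibly-overlapping [lo, hi] windows into disjoint sorted bounds
# suitable for the findInterval %% 2 membership trick
mergeWindows <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]
  outLo <- c(); outHi <- c()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi) mhi <- max(mhi, hi[i])
    else { outLo <- c(outLo, mlo); outHi <- c(outHi, mhi)
           mlo <- lo[i]; mhi <- hi[i] }
  }
  sort(c(outLo, mlo, outHi, mhi))
}

# does any rank-1 candidate row correspond to the planted complexoform?
plantedAtRankOne <- function(bundle, plantedCf, tol = 1e-6) {
  M <- complexoformMass(plantedCf)[["mono"]]
  st <- stoichiometryRecord(plantedCf)
  tab <- bundle$identifications
  hit <- FALSE
  for (i in which(tab$rank == 1)) {
    if (abs(tab$theo_mass[i] - M) > tol) next
    if (tab$n_subunits[i] != length(subunits(plantedCf))) next
    if (tab$metals[i] != sum(st$metals)) next
    hit <- TRUE
  }
  hit
}
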
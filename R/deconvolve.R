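## Native charge-state deconvolution: infer integer charges and neutral
## masses from the few, well-separated charge-state envelopes typical of
## native electrospray of intact assemblies.

#' m/z of a neutral mass at a given positive charge
#'
#' `(mass + z * 1.0072765) / z` — protonation only, the native positive-mode
#' ESI convention.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z Positive integer charge.
#' @return m/z in Th.
#' @export
#' @examples
#' mzFor(37000, 12)   # ~3084.3, inside a 12+ native window
#' mzFor(53070.9, 15) # ~3539.1
mzFor <- function(mass, z) {
  stopifnot(all(mass > 0), all(z >= 1), all(z == round(z)))
  (mass + z * .PROTON) / z
}

#' Infer consecutive charges from two adjacent envelope peaks
#'
#' For two peaks of the same neutral species at consecutive charges z+1 (at
#' `mzLow`) and z (at `mzHigh`), the charge follows from
#' `z = (mzLow - p) / (mzHigh - mzLow)` with p the proton mass. The rounding
#' deviation must be below 0.15 charge units, otherwise no consecutive-charge
#' solution exists.
#'
#' @param mzLow,mzHigh The two peak positions in Th, `mzLow < mzHigh`.
#' @param maxDeviation Acceptable deviation of the charge estimate from an
#'   integer (charge units).
#' @return `c(zHigh = , zLow = )`: the charges at `mzLow` and `mzHigh`.
#' @export
#' @examples
#' inferChargePair(3318, 3539)  # 16+ / 15+
inferChargePair <- function(mzLow, mzHigh, maxDeviation = 0.15) {
  stopifnot(mzLow > 0, mzHigh > 0)
  if (mzLow >= mzHigh)
    stop("mzLow must be strictly below mzHigh", call. = FALSE)
  zraw <- (mzLow - .PROTON) / (mzHigh - mzLow)
  zLow <- round(zraw)
  if (zLow < 1 || abs(zraw - zLow) > maxDeviation)
    stop(sprintf(
      "no consecutive-charge solution for (%.4f, %.4f): z estimate %.3f",
      mzLow, mzHigh, zraw), call. = FALSE)
  c(zHigh = zLow + 1L, zLow = zLow)
}

#' Deconvolve a centroided native spectrum into charge series
#'
#' Greedy, intensity-first assembly of charge-state series: starting at the
#' most intense unexplained peak, every candidate charge `z` up to
#' `maxCharge` is tested by looking for neighboring peaks at
#' `mzFor(M, z +/- k)`; the hypothesis explaining the most peaks with the
#' lowest neutral-mass residual wins. Peaks belong to at most one series;
#' series need at least `minPeaks` members (a single peak is charge-ambiguous
#' and is returned among the leftovers). The neutral mass of a series is the
#' intensity-weighted mean of its per-peak masses.
#'
#' @param mz,intensity Peak vectors (or pass a [Spectrum-class] as `mz`).
#' @param maxCharge Highest charge hypothesis tested (default 30).
#' @param tolDa Per-peak neutral-mass consistency tolerance in Da.
#' @param minPeaks Minimum series size (default 2).
#' @return A list with `series` (list of `ChargeSeries`: `neutralMass`,
#'   `charges`, `mz`, `intensity`, `residual`) and `leftovers` (data.frame of
#'   unassigned peaks). The series list is ordered by total intensity.
#' @export
deconvolveSeries <- function(mz, intensity = NULL, maxCharge = 30L,
                             tolDa = 1.0, minPeaks = 2L) {
  if (is(mz, "Spectrum")) { intensity <- mz@intensity; mz <- mz@mz }
  stopifnot(length(mz) == length(intensity))
  free <- rep(TRUE, length(mz))
  series <- list()
  while (sum(free) >= minPeaks) {
    seed <- which(free)[which.max(intensity[free])]
    best <- NULL
    for (z in seq_len(maxCharge)) {
      M <- z * (mz[seed] - .PROTON)
      members <- seed
      zs <- z
      ## walk both directions in charge
      for (dir in c(-1L, 1L)) {
        k <- z + dir
        while (k >= 1 && k <= maxCharge) {
          target <- mzFor(M, k)
          cand <- which(free & abs(mz - target) * k <= tolDa)
          cand <- setdiff(cand, members)
          if (!length(cand)) break
          pick <- cand[which.min(abs(mz[cand] - target))]
          members <- c(members, pick)
          zs <- c(zs, k)
          k <- k + dir
        }
      }
      if (length(members) < minPeaks) next
      pm <- zs * (mz[members] - .PROTON)
      Mhat <- sum(pm * intensity[members]) / sum(intensity[members])
      resid <- sqrt(mean((pm - Mhat)^2))
      if (resid > tolDa) next
      ## prefer more members, then the higher charge (a sub-harmonic z/2
      ## hypothesis explains alternate peaks of an even-charge series with
      ## zero residual; the true, higher z explains at least as many), then
      ## the lower residual
      score <- c(length(members), z, -resid)
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2]) ||
          (score[1] == best$score[1] && score[2] == best$score[2] &&
             score[3] > best$score[3]))
        best <- list(members = members, charges = zs, mass = Mhat,
                     resid = resid, score = score)
    }
    if (is.null(best)) { free[seed] <- FALSE; next }
    o <- order(best$charges, decreasing = TRUE)
    series[[length(series) + 1L]] <- list(
      neutralMass = best$mass, charges = best$charges[o],
      mz = mz[best$members][o], intensity = intensity[best$members][o],
      residual = best$resid)
    free[best$members] <- FALSE
  }
  if (length(series)) {
    tot <- vapply(series, function(s) sum(s$intensity), 0)
    series <- series[order(tot, decreasing = TRUE)]
  }
  list(series = series,
       leftovers = data.frame(mz = mz[free], intensity = intensity[free]))
}

#' Collapse isotopic envelopes to per-charge centroids
#'
#' Series logic operates at charge-envelope resolution: peaks closer than
#' `width` Th are merged into their most intense member before series
#' assembly.
#'
#' @param mz,intensity Peak vectors.
#' @param width Grouping width in Th.
#' @return data.frame of collapsed peaks.
#' @export
collapseEnvelopes <- function(mz, intensity, width = 1.0) {
  if (!length(mz)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  grp <- cumsum(c(1, diff(mz) > width))
  keep <- vapply(split(seq_along(mz), grp), function(ix)
    ix[which.max(intensity[ix])], 0L)
  data.frame(mz = mz[keep],
             intensity = as.numeric(tapply(intensity, grp, sum)))
}

#' Write a TSV report of deconvolved charge series
#'
#' @param deconv Result of [deconvolveSeries()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSeriesReport <- function(deconv, path) {
  rows <- lapply(seq_along(deconv$series), function(i) {
    s <- deconv$series[[i]]
    data.frame(series = i, neutral_mass = s$neutralMass,
               residual_da = s$residual,
               charges = paste(s$charges, collapse = ","),
               mz = paste(sprintf("%.4f", s$mz), collapse = ","))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(series = integer(0), neutral_mass = numeric(0),
               residual_da = numeric(0), charges = character(0),
               mz = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
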
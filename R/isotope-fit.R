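## TDValidator-style isotopic validation: overlay the theoretical isotopic
## distribution of a hypothesized ion on the raw centroids and score the fit.

#' Theoretical isotope pattern of an ion hypothesis in m/z space
#'
#' @param hypothesis A list with either `composition` (exact, preferred) or
#'   `mass` (averagine model is used), plus `charge` and optional `metals`
#'   (named counts added to the composition with proton displacement).
#' @param prune Relative-abundance prune threshold.
#' @return data.frame `mz`, `abund` (normalized).
#' @keywords internal
.hypothesisPattern <- function(hypothesis, prune = 1e-3) {
  z <- hypothesis$charge
  stopifnot(!is.null(z), z >= 1)
  comp <- hypothesis$composition
  if (is.null(comp)) {
    if (is.null(hypothesis$mass))
      stop("hypothesis needs a composition or a mass", call. = FALSE)
    comp <- averagineComposition(hypothesis$mass)
  } else if (is.character(comp)) comp <- parseFormula(comp)
  shift <- 0
  if (!is.null(hypothesis$metals) && length(hypothesis$metals))
    shift <- .metalSetMass(hypothesis$metals)
  if (!is.null(hypothesis$massShift)) shift <- shift + hypothesis$massShift
  d <- isotopeDistribution(comp, prune = prune)
  data.frame(mz = (d$mass + shift + z * .PROTON) / z, abund = d$abund)
}

#' Fit a theoretical isotope distribution to observed centroids
#'
#' The hypothesized ion's aggregated isotopic distribution is charged into
#' m/z space and each theoretical isotopologue paired with the nearest
#' observed centroid within `mzTol`; unmatched isotopologues count as
#' zero-intensity observations. The intensity scale is chosen by least
#' squares, and the default fit score is `1 - NRMS` where NRMS is the RMS
#' residual over the theoretical isotopologues normalized by the scaled base
#' peak (clamped to `[0, 1]`). `metric = "cosine"` scores the normalized dot
#' product instead, and `"chisq"` uses `1 - mean relative squared residual`.
#' If no observed peak lies within tolerance of the base isotopologue the
#' ion is flagged not detected and scored 0.
#'
#' @param spectrum A [Spectrum-class] or data.frame with `mz`, `intensity`.
#' @param hypothesis List: `composition` (formula/named counts) or `mass`
#'   (averagine fallback), `charge`, optional `metals` (named counts) and
#'   `massShift` (Da).
#' @param mzTol Centroid matching tolerance in Th (default 0.05).
#' @param prune Isotopologue prune threshold (default 1e-3).
#' @param metric `"nrms"` (default), `"cosine"` or `"chisq"`.
#' @return An `IsotopeFit`: list with `fitScore`, `scale`, `detected`,
#'   `residuals` (per-isotopologue data.frame `mz`, `theo`, `obs`) and the
#'   `hypothesis`.
#' @export
fitIsotopes <- function(spectrum, hypothesis, mzTol = 0.05, prune = 1e-3,
                        metric = c("nrms", "cosine", "chisq")) {
  metric <- match.arg(metric)
  if (is(spectrum, "Spectrum")) spectrum <- peaks(spectrum)
  pat <- .hypothesisPattern(hypothesis, prune)
  obs <- numeric(nrow(pat))
  for (i in seq_len(nrow(pat))) {
    d <- abs(spectrum$mz - pat$mz[i])
    j <- which.min(d)
    if (length(j) && d[j] <= mzTol) obs[i] <- spectrum$intensity[j]
  }
  basePk <- which.max(pat$abund)
  detected <- obs[basePk] > 0
  res <- data.frame(mz = pat$mz, theo = pat$abund, obs = obs)
  if (!detected) {
    return(structure(list(fitScore = 0, scale = 0, detected = FALSE,
                          residuals = res, hypothesis = hypothesis),
                     class = "IsotopeFit"))
  }
  scale <- sum(pat$abund * obs) / sum(pat$abund^2)
  fitted <- scale * pat$abund
  score <- switch(metric,
    nrms = {
      nrms <- sqrt(mean((obs - fitted)^2)) / (scale * max(pat$abund))
      max(0, min(1, 1 - nrms))
    },
    cosine = sum(obs * fitted) /
      sqrt(sum(obs^2) * sum(fitted^2)),
    chisq = {
      rel <- ((obs - fitted) / (scale * max(pat$abund)))^2
      max(0, min(1, 1 - mean(rel)))
    })
  structure(list(fitScore = score, scale = scale, detected = TRUE,
                 residuals = res, hypothesis = hypothesis),
            class = "IsotopeFit")
}

#' @export
print.IsotopeFit <- function(x, ...) {
  cat(sprintf("IsotopeFit: score %.4f%s, %d isotopologue(s), scale %.3g\n",
              x$fitScore, if (!x$detected) " (not detected)" else "",
              nrow(x$residuals), x$scale))
  invisible(x)
}

#' Rank competing ion hypotheses against one spectrum
#'
#' Fits each hypothesis with [fitIsotopes()] and ranks by fit score. Scores
#' within `tieTol` of the best are flagged indistinguishable rather than
#' arbitrarily ordered -- e.g. an acetyl vs trimethyl pair (0.0364 Da apart)
#' at coarse tolerance.
#'
#' @param spectrum As in [fitIsotopes()].
#' @param hypotheses List of >= 2 hypothesis lists (optionally named).
#' @param tieTol Score difference below which hypotheses tie (default 1e-6).
#' @param ... Passed to [fitIsotopes()].
#' @return data.frame `hypothesis`, `fit_score`, `detected`, `rank`, `tied`
#'   (tied with the top score), with the fits in `attr(, "fits")`.
#' @export
compareHypotheses <- function(spectrum, hypotheses, tieTol = 1e-6, ...) {
  stopifnot(length(hypotheses) >= 2)
  nm <- names(hypotheses)
  if (is.null(nm)) nm <- paste0("H", seq_along(hypotheses))
  fits <- lapply(hypotheses, fitIsotopes, spectrum = spectrum, ...)
  sc <- vapply(fits, function(f) f$fitScore, 0)
  o <- order(sc, decreasing = TRUE)
  out <- data.frame(hypothesis = nm[o], fit_score = sc[o],
                    detected = vapply(fits, function(f) f$detected, TRUE)[o],
                    rank = seq_along(o))
  out$tied <- out$fit_score >= out$fit_score[1] - tieTol
  attr(out, "fits") <- fits[o]
  out
}
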
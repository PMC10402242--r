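## Poisson P-score: probability that >= n_matched of n_observed fragment
## masses fall into the theoretical acceptance windows by chance.

#' Poisson P-score for a fragment-match count
#'
#' Under the null, each of the `nObserved` masses lands uniformly in the
#' observed mass window and hits any theoretical acceptance window with
#' probability `q = min(1, sum_f 2 * tolPpm * 1e-6 * mass_f / |window|)`
#' (windows summed without overlap correction, which makes the null match
#' rate conservative). The score is the Poisson upper tail
#' `P(X >= nMatched)` at `lambda = nObserved * q`; lower is more confident.
#'
#' @param nMatched Number of matched fragments.
#' @param nObserved Number of observed fragment masses.
#' @param theoreticalMasses Neutral masses of the theoretical fragments (Da).
#' @param tolPpm Matching tolerance (ppm).
#' @param massWindow `c(lo, hi)` observed mass range in Da.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' pScore(10, 20, seq(300, 1900, length.out = 50), 10, c(200, 2000))
pScore <- function(nMatched, nObserved, theoreticalMasses, tolPpm = 10,
                   massWindow = range(theoreticalMasses)) {
  stopifnot(nMatched >= 0, nObserved >= 0,
            nMatched <= max(nObserved, 0))
  width <- diff(massWindow)
  if (!is.finite(width) || width <= 0)
    stop("degenerate mass window (zero width)", call. = FALSE)
  if (nMatched == 0) return(1.0)
  q <- min(1, sum(2 * tolPpm * 1e-6 * theoreticalMasses) / width)
  lambda <- nObserved * q
  stats::ppois(nMatched - 1, lambda, lower.tail = FALSE)
}
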
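## Scattering forward model and analysis: Debye curves, Guinier fits, P(r),
## chi2 fitting with optimal scale, min-max score normalization, ensemble
## mixture curves and Rg-distribution classification.

#' Debye scattering curve of a conformer
#'
#' Computes I(s) = sum_i sum_j w_i w_j sin(s r_ij) / (s r_ij) over all
#' scatterer pairs, with the i = j and s -> 0 limits handled as 1. Weights
#' come from the contrast scheme; contrast-matched scatterers (weight 0)
#' drop out. This is a desk-scale forward model for bead conformers;
#' per-conformer curves computed by external atomic-detail programs can be
#' supplied instead wherever a curve library is accepted.
#'
#' @param x a \linkS4class{Conformer}.
#' @param scheme a \linkS4class{ContrastScheme} or NULL for unit weights.
#' @param sGrid strictly increasing grid of s values (1/Angstrom); s = 0 is
#'   allowed and evaluates to the (sum w)^2 limit.
#' @param sigmaFrac relative error written into the curve's sigma column
#'   (default 0.02).
#' @param sigmaFloor absolute error floor as a fraction of I(0)
#'   (default 1e-4).
#' @return A \linkS4class{SASCurve}.
#' @export
debyeCurve <- function(x, scheme = NULL, sGrid, sigmaFrac = 0.02,
                       sigmaFloor = 1e-4) {
  I <- debyeIntensity(x, scheme, sGrid)
  I0 <- sum(schemeWeights(x, scheme))^2
  sig <- pmax(sigmaFrac * abs(I), sigmaFloor * I0)
  sasCurve(sGrid, I, sig, scheme = if (is.null(scheme)) "unit" else scheme@name)
}

#' Debye intensities on a grid (bare vector)
#'
#' @inheritParams debyeCurve
#' @return numeric vector of intensities, one per grid point.
#' @export
debyeIntensity <- function(x, scheme = NULL, sGrid) {
  w <- schemeWeights(x, scheme)
  keep <- w > 0
  if (!any(keep)) stop("no scatterer has nonzero weight under this scheme")
  pts <- x@coords[keep, , drop = FALSE]
  w <- w[keep]
  n <- nrow(pts)
  self <- sum(w^2)
  if (n == 1L) return(rep(self, length(sGrid)))
  d <- as.vector(stats::dist(pts))
  pw <- tcrossprod(w)
  pw <- 2 * pw[lower.tri(pw)]
  sd_ <- outer(d, sGrid)                       # n_pairs x n_s
  sinc <- ifelse(sd_ == 0, 1, sin(sd_) / ifelse(sd_ == 0, 1, sd_))
  as.vector(self + crossprod(pw, sinc))
}

#' Guinier fit of a scattering curve
#'
#' Weighted linear fit of ln I versus s^2 restricted to the Guinier regime
#' s * Rg <= 1.3, iterated to self-consistency of the admissible range:
#' the fit starts on points with s below \code{sMaxStart}, and the cut is
#' re-evaluated from the fitted Rg until the point set is stable (at most
#' \code{maxIter} rounds). Weights are (I / sigma)^2, the inverse variance
#' of ln I.
#'
#' @param curve a \linkS4class{SASCurve}.
#' @param sRgMax Guinier validity limit (default 1.3).
#' @param sMaxStart initial s cutoff for the first fit (default 0.05).
#' @param minPoints minimum number of admissible points (default 5).
#' @param maxIter maximum range iterations (default 20).
#' @return list with \code{Rg} (Angstrom), \code{I0}, \code{nPoints} and the
#'   final \code{sMax}.
#' @export
guinierFit <- function(curve, sRgMax = 1.3, sMaxStart = 0.05,
                       minPoints = 5L, maxIter = 20L) {
  s <- curve@s; I <- curve@I; sig <- curve@sigma
  pos <- I > 0 & s > 0
  s <- s[pos]; I <- I[pos]; sig <- sig[pos]
  sel <- s <= sMaxStart
  if (sum(sel) < minPoints) sel <- seq_along(s) <= max(minPoints, sum(sel))
  for (it in seq_len(maxIter)) {
    if (sum(sel) < minPoints)
      stop("too few points (", sum(sel), ") in the Guinier range")
    fit <- stats::lm(log(I[sel]) ~ I(s[sel]^2),
                     weights = (I[sel] / sig[sel])^2)
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= 0)
      stop("non-decaying curve: Guinier slope is not negative")
    rg <- sqrt(-3 * slope)
    newSel <- s <= sRgMax / rg
    if (identical(which(newSel), which(sel))) break
    sel <- newSel
  }
  list(Rg = unname(sqrt(-3 * coef(fit)[2])),
       I0 = unname(exp(coef(fit)[1])),
       nPoints = sum(sel), sMax = max(s[sel]))
}

#' Pair-distance distribution P(r) of a conformer
#'
#' Contrast-weighted histogram of all distinct scatterer pair distances,
#' normalized to unit area (sum P(r) * dr = 1). The support extends to the
#' model's maximum dimension.
#'
#' @param x a \linkS4class{Conformer}.
#' @param scheme a \linkS4class{ContrastScheme} or NULL.
#' @param binWidth histogram bin width in Angstrom (default 1).
#' @return data.frame with bin centers \code{r} and densities \code{p}.
#' @export
prHistogram <- function(x, scheme = NULL, binWidth = 1) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  w <- schemeWeights(x, scheme)
  keep <- w > 0
  pts <- x@coords[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(pts) < 2L) stop("need at least two weighted scatterers for P(r)")
  d <- as.vector(stats::dist(pts))
  pw <- tcrossprod(w)
  pw <- pw[lower.tri(pw)]
  breaks <- seq(0, max(d) + binWidth, by = binWidth)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  p <- vapply(seq_len(length(breaks) - 1L),
              function(b) sum(pw[bin == b]), numeric(1))
  p <- p / (sum(p) * binWidth)
  data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2, p = p)
}

#' Chi-square fit of a calculated curve to an experimental one
#'
#' The calculated intensities are first scaled by the analytically optimal
#' factor c = sum(Iexp Icalc / sigma^2) / sum(Icalc^2 / sigma^2), then
#' chi2 = (1/N) sum((Iexp - c Icalc)^2 / sigma^2). chi2 is invariant to any
#' positive rescaling of the calculated curve.
#'
#' @param exp a \linkS4class{SASCurve} with the experimental data.
#' @param calc numeric vector of calculated intensities on the same grid.
#' @param fixedScale optional: force the scale factor instead of optimizing
#'   (e.g. 1 for absolute-scale observables).
#' @return list with \code{chi2}, \code{c} and \code{nPoints}.
#' @export
chi2Fit <- function(exp, calc, fixedScale = NULL) {
  if (length(calc) != length(exp@s))
    stop("calculated curve is not on the experimental grid")
  if (all(calc == 0)) stop("all-zero calculated curve")
  iv <- 1 / exp@sigma^2
  cc <- if (is.null(fixedScale))
    sum(exp@I * calc * iv) / sum(calc^2 * iv) else fixedScale
  chi2 <- mean(((exp@I - cc * calc)^2) * iv)
  list(chi2 = chi2, c = cc, nPoints = length(calc))
}

#' Min-max normalization of a set of scores
#'
#' Maps chi2 (or any) values to [0, 1] via (x - min) / (max - min). If all
#' values are equal the result is all zeros.
#'
#' @param values numeric vector, length >= 2.
#' @return normalized values in [0, 1].
#' @examples
#' normalizeScores(c(2, 5, 10))   # 0, 0.375, 1
#' @export
normalizeScores <- function(values) {
  if (length(values) < 2L) stop("need at least two values to normalize")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Population-weighted scattering curve of an ensemble
#'
#' Linear combination of per-conformer curves with member multiplicities as
#' molar fractions.
#'
#' @param e an \linkS4class{Ensemble}.
#' @param curves named list of per-conformer intensity vectors (common
#'   grid), or a matrix with one named column per conformer.
#' @return numeric intensity vector.
#' @export
ensembleCurve <- function(e, curves) {
  if (is.list(curves)) curves <- do.call(cbind, curves)
  w <- ensembleWeights(e)
  missing <- setdiff(names(w), colnames(curves))
  if (length(missing))
    stop("no curve for ensemble member(s): ", paste(missing, collapse = ", "))
  as.vector(curves[, names(w), drop = FALSE] %*% w)
}

#' Rg distribution of a conformer pool
#'
#' @param pool a \linkS4class{ConformerPool}.
#' @param scheme a \linkS4class{ContrastScheme} or NULL (unit weights).
#' @param modelLabel label for the distribution.
#' @return An \linkS4class{RgDistribution}.
#' @export
rgDistribution <- function(pool, scheme = NULL, modelLabel = pool@provenance) {
  if (poolSize(pool) < 1L) stop("pool is empty")
  rgs <- vapply(poolMembers(pool), rgConformer, numeric(1), scheme = scheme)
  rgDistributionFromSamples(unname(rgs), modelLabel = modelLabel)
}

#' Classify an observed Rg against model Rg distributions
#'
#' For each candidate model the z-score |obs - mean| / sd is computed; the
#' observation is compatible with the model if z <= zMax.
#'
#' @param observedRg observed radius of gyration (Angstrom).
#' @param distributions list of \linkS4class{RgDistribution} objects.
#' @param zMax compatibility threshold in SD units (default 2).
#' @return data.frame with model, mean, sd, z and compatible columns.
#' @export
classifyOligomer <- function(observedRg, distributions, zMax = 2) {
  if (length(distributions) < 1L) stop("no distributions supplied")
  rows <- lapply(distributions, function(d) {
    if (rgSD(d) <= 0) stop("distribution '", d@modelLabel, "' has sd = 0")
    z <- abs(observedRg - rgMean(d)) / rgSD(d)
    data.frame(model = d@modelLabel, mean = rgMean(d), sd = rgSD(d),
               z = z, compatible = z <= zMax)
  })
  do.call(rbind, rows)
}
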
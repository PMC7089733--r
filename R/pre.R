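## PRE forward and inverse models: intensity-ratio <-> Gamma2 <-> distance,
## tauC calibration, and structure-based back-calculation with spin-label
## ensembles, OR-groups, two-copy averaging and fast-exchange <r^-6>
## ensemble averaging.

ANG_TO_CM6 <- 1e48   # (1 A)^-6 expressed in cm^-6: (1e-8 cm)^-6

#' Spectral term of the PRE distance equation
#'
#' J(tauC, omega) = 4 tauC + 3 tauC / (1 + omega^2 tauC^2), in seconds.
#'
#' @param p a \linkS4class{RelaxationParams}.
#' @param tauC optional override of the correlation time (s).
#' @return numeric, seconds.
#' @export
spectralTerm <- function(p, tauC = p@tauC)
  4 * tauC + 3 * tauC / (1 + p@omega^2 * tauC^2)

#' Intensity ratio from a PRE rate
#'
#' The paramagnetic-to-diamagnetic peak-height ratio of a methyl resonance:
#' exp(-Gamma2 t_HMQC) * R2H R2HC / ((R2H + Gamma2)(R2HC + Gamma2)).
#' Strictly decreasing in Gamma2; 1 at Gamma2 = 0.
#'
#' @param gamma2 PRE rate(s), 1/s (>= 0).
#' @param r2DiaH diamagnetic 1H single-quantum relaxation rate, 1/s.
#' @param r2DiaHC diamagnetic 1H-13C multiple-quantum relaxation rate, 1/s.
#' @param p a \linkS4class{RelaxationParams} (supplies tHMQC).
#' @return ratio(s) in (0, 1].
#' @export
ratioFromGamma2 <- function(gamma2, r2DiaH, r2DiaHC, p = relaxationParams()) {
  if (any(gamma2 < 0)) stop("gamma2 must be >= 0")
  exp(-gamma2 * p@tHMQC) * (r2DiaH * r2DiaHC) /
    ((r2DiaH + gamma2) * (r2DiaHC + gamma2))
}

## bisection inversion of ratioFromGamma2 (monotone decreasing)
invertRatio <- function(ratio, r2DiaH, r2DiaHC, p, relTol = 1e-8) {
  if (ratio >= 1) return(0)
  hi <- 1
  while (ratioFromGamma2(hi, r2DiaH, r2DiaHC, p) > ratio) hi <- hi * 2
  lo <- 0
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (ratioFromGamma2(mid, r2DiaH, r2DiaHC, p) > ratio) lo <- mid else hi <- mid
    if ((hi - lo) <= relTol * max(hi, 1)) break
  }
  (lo + hi) / 2
}

#' PRE rate from an intensity ratio
#'
#' Numerical inversion (bisection on the monotone map, relative tolerance
#' 1e-8) of the intensity-ratio model. Bounds are obtained by re-inverting
#' at the corners of the error box spanned by the ratio error (with a 10
#' percent floor) and the diamagnetic-rate errors. A ratio above 1 (noise)
#' yields a value of 0 with an upper bound from the error model.
#'
#' @param ratio observed I_para / I_dia (must be > 0).
#' @param r2DiaH,r2DiaHC diamagnetic rates, 1/s.
#' @param p a \linkS4class{RelaxationParams}.
#' @param ratioErr reported error on the ratio (floored at 10 percent of
#'   the ratio).
#' @param r2DiaHErr,r2DiaHCErr errors on the diamagnetic rates.
#' @param errorFloor relative ratio-error floor (default 0.1).
#' @return list with \code{value}, \code{lower}, \code{upper} (1/s).
#' @export
gamma2FromRatio <- function(ratio, r2DiaH, r2DiaHC, p = relaxationParams(),
                            ratioErr = 0, r2DiaHErr = 0, r2DiaHCErr = 0,
                            errorFloor = 0.1) {
  if (ratio <= 0) stop("ratio must be > 0")
  e <- max(ratioErr, errorFloor * ratio)
  value <- invertRatio(min(ratio, 1), r2DiaH, r2DiaHC, p)
  corners <- expand.grid(r = c(max(ratio - e, 1e-6), min(ratio + e, 1)),
                         h = c(r2DiaH - r2DiaHErr, r2DiaH + r2DiaHErr),
                         hc = c(r2DiaHC - r2DiaHCErr, r2DiaHC + r2DiaHCErr))
  corners$h <- pmax(corners$h, 1e-6)
  corners$hc <- pmax(corners$hc, 1e-6)
  gs <- mapply(function(r, h, hc) invertRatio(min(r, 1), h, hc, p),
               corners$r, corners$h, corners$hc)
  list(value = value, lower = min(gs, value), upper = max(gs, value))
}

#' Electron-proton distance from a PRE rate
#'
#' r = [ (K / Gamma2) (4 tauC + 3 tauC / (1 + omega^2 tauC^2)) ]^(1/6),
#' evaluated in cgs units and reported in Angstrom.
#'
#' @param gamma2 PRE rate, 1/s (> 0), or a list with value/lower/upper as
#'   returned by \code{\link{gamma2FromRatio}}.
#' @param p a \linkS4class{RelaxationParams}.
#' @return for scalar input, the distance in Angstrom; for a bounds list,
#'   a list with \code{value}, \code{lower}, \code{upper} distances
#'   (Angstrom), where the distance bounds also fold in the tauC error.
#' @export
distanceFromGamma2 <- function(gamma2, p = relaxationParams()) {
  if (is.list(gamma2)) {
    if (gamma2$value <= 0) stop("gamma2 must be > 0 for a distance")
    v <- distanceFromGamma2(gamma2$value, p)
    tlo <- max(p@tauC - p@tauCErr, 1e-12)
    thi <- p@tauC + p@tauCErr
    rr <- c(
      distAt(gamma2$upper, tlo, p), distAt(gamma2$upper, thi, p),
      distAt(max(gamma2$lower, 1e-9), tlo, p),
      distAt(max(gamma2$lower, 1e-9), thi, p))
    return(list(value = v, lower = min(rr, v), upper = max(rr, v)))
  }
  if (gamma2 <= 0) stop("gamma2 must be > 0 for a distance")
  distAt(gamma2, p@tauC, p)
}

distAt <- function(gamma2, tauC, p) {
  r_cm <- (p@K / gamma2 * spectralTerm(p, tauC))^(1 / 6)
  r_cm * 1e8
}

#' PRE rate from an electron-proton distance
#'
#' Forward model Gamma2 = (K / r^6) J(tauC, omega) with r in Angstrom.
#'
#' @param r distance(s) in Angstrom (> 0).
#' @param p a \linkS4class{RelaxationParams}.
#' @return Gamma2 in 1/s.
#' @export
gamma2FromDistance <- function(r, p = relaxationParams()) {
  if (any(r <= 0)) stop("distance must be > 0")
  p@K * (r^-6 * ANG_TO_CM6) * spectralTerm(p)
}

#' Calibrate the correlation time from known distances
#'
#' Given calibration pairs of a known electron-proton distance and the
#' measured intensity ratio (with diamagnetic rates), the observed Gamma2
#' values are obtained by inverting the ratio model (this inversion does
#' not involve tauC), and tauC is then fitted by weighted least squares of
#' predicted against observed Gamma2. The spread is estimated from
#' \code{nFits} bootstrap refits over resampled calibration pairs.
#'
#' @param known data.frame with columns \code{distance} (Angstrom),
#'   \code{ratio}, \code{r2_dia_h}, \code{r2_dia_hc} and optional error
#'   columns \code{ratio_err}, \code{r2_dia_h_err}, \code{r2_dia_hc_err}.
#' @param p0 initial \linkS4class{RelaxationParams} (supplies omega, tHMQC,
#'   K and the search interval midpoint).
#' @param nFits number of bootstrap refits for the SD (default 20).
#' @param seed integer seed for the bootstrap.
#' @param interval search interval for tauC in seconds
#'   (default 1 to 200 ns).
#' @return list with \code{tauC} (s), \code{sd} (s), \code{fits} (the
#'   bootstrap values) and \code{params} (p0 with tauC/tauCErr updated).
#' @export
calibrateTauC <- function(known, p0 = relaxationParams(), nFits = 20L,
                          seed = 1L, interval = c(1e-9, 200e-9)) {
  if (nrow(known) < 3L) stop("need at least 3 calibration pairs")
  need <- c("distance", "ratio", "r2_dia_h", "r2_dia_hc")
  if (!all(need %in% names(known)))
    stop("known must have columns: ", paste(need, collapse = ", "))
  gObs <- numeric(nrow(known))
  gW <- numeric(nrow(known))
  for (i in seq_len(nrow(known))) {
    g <- gamma2FromRatio(known$ratio[i], known$r2_dia_h[i],
                         known$r2_dia_hc[i], p0,
                         ratioErr = colOr(known, "ratio_err", i),
                         r2DiaHErr = colOr(known, "r2_dia_h_err", i),
                         r2DiaHCErr = colOr(known, "r2_dia_hc_err", i))
    gObs[i] <- g$value
    spread <- (g$upper - g$lower) / 2
    gW[i] <- 1 / max(spread, 1e-3)^2
  }
  ## optimize over tauC in ns so the search tolerance is meaningful on
  ## the parameter scale
  fitOne <- function(idx) {
    obj <- function(tauNs) {
      pred <- p0@K * (known$distance[idx]^-6 * ANG_TO_CM6) *
        spectralTerm(p0, tauNs * 1e-9)
      sum(gW[idx] * (pred - gObs[idx])^2)
    }
    opt <- optimize(obj, interval = interval * 1e9, tol = 1e-7)
    if (!is.finite(opt$minimum)) stop("tauC fit did not converge")
    opt$minimum * 1e-9
  }
  tauC <- fitOne(seq_len(nrow(known)))
  set.seed(seed)
  boots <- vapply(seq_len(nFits), function(b)
    fitOne(sample.int(nrow(known), replace = TRUE)), numeric(1))
  sdTau <- stats::sd(boots)
  pOut <- p0
  pOut@tauC <- tauC
  pOut@tauCErr <- sdTau
  list(tauC = tauC, sd = sdTau, fits = boots, params = pOut)
}

colOr <- function(df, nm, i) if (nm %in% names(df)) df[[nm]][i] else 0

## ---------------------------------------------------------------------------
## Back-calculation
## ---------------------------------------------------------------------------

## Normalize copyMap: peak -> list of copies, each a character vector of
## OR-equivalent methyl site ids. Default: one copy, the peak itself.
normCopyMap <- function(peaks, copyMap) {
  out <- lapply(peaks, function(pk) {
    if (!is.null(copyMap) && pk %in% names(copyMap)) {
      cm <- copyMap[[pk]]
      if (!is.list(cm)) cm <- list(cm)
      cm
    } else list(pk)
  })
  names(out) <- peaks
  out
}

normTagMap <- function(datasets, tagMap) {
  out <- lapply(datasets, function(ds) {
    if (!is.null(tagMap) && ds %in% names(tagMap)) tagMap[[ds]] else ds
  })
  names(out) <- datasets
  out
}

## tag positions and weights for one tag in one conformer: an explicit
## SpinLabelEnsemble overrides the conformer's own tag sites
tagPositions <- function(conf, tagId, tags) {
  if (!is.null(tags) && tagId %in% names(tags)) {
    sle <- tags[[tagId]]
    return(list(pos = sle@positions, w = sle@weights))
  }
  ts <- conf@tagSites[[tagId]]
  if (is.null(ts)) stop("tag site '", tagId, "' not found in conformer")
  list(pos = ts, w = rep(1 / nrow(ts), nrow(ts)))
}

## r^-6 (in A^-6) between one tag (ensemble-weighted) and an OR-group of
## methyl sites (summed) in one conformer
r6TagGroup <- function(conf, tagId, groupSites, tags) {
  tp <- tagPositions(conf, tagId, tags)
  ms <- conf@methylSites
  missing <- setdiff(groupSites, rownames(ms))
  if (length(missing))
    stop("methyl site '", missing[1], "' not found in conformer")
  total <- 0
  for (site in groupSites) {
    d2 <- rowSums(sweep(tp$pos, 2, ms[site, ])^2)
    total <- total + sum(tp$w * d2^-3)
  }
  total
}

#' Per-conformer r^-6 table for PRE back-calculation
#'
#' For every measurement row and protein copy, the tag-dataset-summed,
#' spin-label-ensemble-weighted, OR-group-summed r^-6 (in Angstrom^-6) is
#' precomputed per conformer. \code{\link{backcalcPre}} consumes this table;
#' the ensemble-selection engine reuses it so that scoring thousands of
#' candidate ensembles costs only weighted column means.
#'
#' @param conformers named list of \linkS4class{Conformer}s.
#' @param measurements PRE table (columns \code{methyl_id}, \code{tag_id}).
#' @param tags named list of \linkS4class{SpinLabelEnsemble}s overriding the
#'   conformer tag sites, or NULL to use each conformer's own sites.
#' @param tagMap named list: dataset id -> tag ids summed per Eq.-7-style
#'   two-tag addition (default: the dataset id itself).
#' @param copyMap named list: methyl peak -> list of symmetry-equivalent
#'   copies, each a character vector of OR-grouped site ids.
#' @return list with one element per measurement row: a (copies x
#'   conformers) matrix of r^-6 values.
#' @export
preR6Table <- function(conformers, measurements, tags = NULL,
                       tagMap = NULL, copyMap = NULL) {
  peaks <- measurements$methyl_id
  dsets <- measurements$tag_id
  cm <- normCopyMap(unique(peaks), copyMap)
  tm <- normTagMap(unique(dsets), tagMap)
  lapply(seq_len(nrow(measurements)), function(i) {
    copies <- cm[[peaks[i]]]
    tagIds <- tm[[dsets[i]]]
    m <- matrix(0, nrow = length(copies), ncol = length(conformers),
                dimnames = list(NULL, names(conformers)))
    for (ci in seq_along(copies)) {
      for (k in seq_along(conformers)) {
        m[ci, k] <- sum(vapply(tagIds, r6TagGroup, numeric(1),
                               conf = conformers[[k]],
                               groupSites = copies[[ci]], tags = tags))
      }
    }
    m
  })
}

#' Predicted ratios from a precomputed r^-6 table
#'
#' @param e an \linkS4class{Ensemble}.
#' @param r6table output of \code{\link{preR6Table}}.
#' @param measurements the PRE table the r6table was built from.
#' @param p a \linkS4class{RelaxationParams}.
#' @return numeric vector of predicted ratios, one per measurement row.
#' @export
predictRatios <- function(e, r6table, measurements, p = relaxationParams()) {
  w <- ensembleWeights(e)
  KJ <- p@K * ANG_TO_CM6 * spectralTerm(p)
  vapply(seq_along(r6table), function(i) {
    m <- r6table[[i]]
    missing <- setdiff(names(w), colnames(m))
    if (length(missing))
      stop("ensemble member '", missing[1], "' has no r^-6 entry")
    r6avg <- as.vector(m[, names(w), drop = FALSE] %*% w)   # per copy
    gam <- KJ * r6avg
    mean(ratioFromGamma2(gam, measurements$r2_dia_h[i],
                         measurements$r2_dia_hc[i], p))
  }, numeric(1))
}

#' Back-calculate PRE intensity ratios for an ensemble
#'
#' Implements fast-exchange back-calculation: per protein copy, r^-6 is
#' averaged over ensemble members (population-weighted) and spin-label
#' conformations (weighted), summed over OR-grouped methyl sites and over
#' the tags of a dataset; the per-copy Gamma2 is converted to a ratio via
#' the intensity-ratio model, and the reported value is the mean of the
#' copies' ratios.
#'
#' @param e an \linkS4class{Ensemble}.
#' @param conformers named list of \linkS4class{Conformer}s covering the
#'   ensemble members.
#' @param measurements PRE table with columns \code{methyl_id},
#'   \code{tag_id}, \code{r2_dia_h}, \code{r2_dia_hc}.
#' @param p a \linkS4class{RelaxationParams}.
#' @param tags,tagMap,copyMap see \code{\link{preR6Table}}.
#' @return the measurements data.frame with an added \code{predicted}
#'   column.
#' @export
backcalcPre <- function(e, conformers, measurements, p = relaxationParams(),
                        tags = NULL, tagMap = NULL, copyMap = NULL) {
  need <- unique(memberIds(e))
  missing <- setdiff(need, names(conformers))
  if (length(missing))
    stop("conformer '", missing[1], "' not supplied")
  tab <- preR6Table(conformers[need], measurements, tags = tags,
                    tagMap = tagMap, copyMap = copyMap)
  out <- measurements
  out$predicted <- predictRatios(e, tab, measurements, p)
  out
}

#' Chi-square of predicted versus observed PRE ratios
#'
#' Mean of squared error-weighted residuals with the scale fixed to 1
#' (intensity ratios are absolute observables).
#'
#' @param predicted numeric vector of predicted ratios, or a data.frame
#'   with a \code{predicted} column as returned by
#'   \code{\link{backcalcPre}}.
#' @param observed PRE table with \code{ratio} and \code{ratio_err}
#'   columns (same row order).
#' @return chi2 (dimensionless).
#' @export
preChi2 <- function(predicted, observed) {
  if (is.data.frame(predicted)) predicted <- predicted$predicted
  if (length(predicted) != nrow(observed))
    stop("predicted and observed lengths differ")
  if (any(observed$ratio_err <= 0)) stop("zero or negative ratio error")
  mean(((observed$ratio - predicted) / observed$ratio_err)^2)
}

#' Q-factor of predicted versus observed PRE ratios
#'
#' sqrt(sum((obs - pred)^2) / sum(obs^2)); an error-free agreement metric
#' complementary to chi2.
#'
#' @inheritParams preChi2
#' @return Q factor (dimensionless).
#' @export
preQFactor <- function(predicted, observed) {
  if (is.data.frame(predicted)) predicted <- predicted$predicted
  sqrt(sum((observed$ratio - predicted)^2) / sum(observed$ratio^2))
}
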
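## Synthetic two-site complex generator: a toy RNP with one mobile
## catalytic module exchanging between a duplex-bound "on" pose and
## detached "off" poses, plus simulated contrast-scheme SAS curves and
## noisy PRE tables at a known on-state fraction.

#' Specification of the synthetic two-site complex
#'
#' The toy emulates a mono-RNP-like particle: a rigid elongated scaffold,
#' a small partner subunit, a substrate-guide duplex and one mobile
#' catalytic module ("fib") that either sits on the duplex site (on pose)
#' or samples tethered detached poses (off). Three spin-label sites sit on
#' the rigid subunits -- one adjacent to the duplex site so that its PREs
#' report specifically on the on state -- and 24 methyl reporter sites
#' ride on the mobile module. Five contrast schemes mimic the
#' deuteration/contrast-matching combinations of a SANS campaign plus a
#' SAXS curve.
#'
#' @param seed integer seed for bead placement and pool generation.
#' @param fOn true on-state fraction (0 < fOn < 1, default 0.66).
#' @param nOn size of the on-state pool (jittered on poses, default 10).
#' @param nOff size of the off-state pool (default 40).
#' @param tetherLength tether radius for off poses (Angstrom, default 40).
#' @param onJitter positional jitter of on-pool poses (Angstrom,
#'   default 2).
#' @param excludeRadius off poses keep the module centroid at least this
#'   far from the on pose centroid (Angstrom, default 15).
#' @param sGrid scattering grid (1/Angstrom).
#' @param sasFrac relative Gaussian noise on SAS intensities
#'   (default 0.02).
#' @param preSigma absolute Gaussian noise on PRE ratios (default 0.05).
#' @param nMethyl number of methyl reporter sites on the module
#'   (default 24).
#' @return list of class \code{"ToySpec"}.
#' @export
toySpec <- function(seed = 1L, fOn = 0.66, nOn = 10L, nOff = 40L,
                    tetherLength = 40, onJitter = 2, excludeRadius = 15,
                    sGrid = seq(0.008, 0.25, length.out = 48L),
                    sasFrac = 0.02, preSigma = 0.05, nMethyl = 24L) {
  stopifnot(fOn > 0, fOn < 1, tetherLength > 0)
  structure(list(seed = seed, fOn = fOn, nOn = nOn, nOff = nOff,
                 tetherLength = tetherLength, onJitter = onJitter,
                 excludeRadius = excludeRadius, sGrid = sGrid,
                 sasFrac = sasFrac, preSigma = preSigma,
                 nMethyl = nMethyl,
                 onSite = c(18, -15, 14), anchor = c(30, 5, 0)),
            class = "ToySpec")
}

#' The five contrast schemes of the toy complex
#'
#' Deuterated-module SANS, deuterated-scaffold SANS, module+duplex SANS,
#' partially deuterated scaffold + duplex SANS, and SAXS (all subunits).
#'
#' @return named list of \linkS4class{ContrastScheme}s.
#' @export
toySchemes <- function() {
  subs <- c(scaffold = 0, partner = 0, rna = 0, fib = 0, fib2 = 0)
  mk <- function(name, ...) {
    w <- subs
    upd <- c(...)
    w[names(upd)] <- upd
    contrastScheme(name, w)
  }
  ## The scaffold schemes carry partial contrast on the catalytic copies:
  ## in the system being emulated the deuterated scaffold protein includes
  ## the N-terminal lobe that rides with the catalytic module, so
  ## scaffold-contrast curves do report on the module position. A bead
  ## model without a separate lobe approximates this with a fractional
  ## module weight.
  list(
    `2H-Fib` = mk("2H-Fib", fib = 1, fib2 = 1),
    `2H-Scaffold` = mk("2H-Scaffold", scaffold = 1, fib = 0.35,
                       fib2 = 0.35),
    `2H-Fib-RNA` = mk("2H-Fib-RNA", fib = 1, fib2 = 1, rna = 1),
    `2H70-Scaffold-RNA` = mk("2H70-Scaffold-RNA", scaffold = 0.7,
                             rna = 1, fib = 0.25, fib2 = 0.25),
    SAXS = mk("SAXS", scaffold = 1, partner = 1, rna = 1, fib = 1,
              fib2 = 1))
}

## beads uniformly filling an ellipsoid
beadBlob <- function(n, center, radii) {
  pts <- matrix(NA_real_, n, 3)
  k <- 0L
  while (k < n) {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) {
      k <- k + 1L
      pts[k, ] <- center + p * radii
    }
  }
  pts
}

#' Build the synthetic two-site complex
#'
#' Constructs the on-pose template conformer, a small pool of jittered on
#' poses (state tag \code{"on_off"}) and a pool of clash-free detached
#' poses (\code{"off_off"}) via rigid-body randomization inside the
#' tether sphere, with the module centroid excluded from the neighbourhood
#' of the on pose so the two states are geometrically distinct.
#' Deterministic for a fixed spec seed.
#'
#' @param spec a \code{\link{toySpec}}.
#' @return list with \code{template} (on-pose \linkS4class{Conformer}),
#'   \code{onPool}, \code{offPool} (\linkS4class{ConformerPool}s),
#'   \code{schemes}, \code{spec} and \code{truth} (ground-truth record:
#'   on-site centroid, anchor, fOn, site tables).
#' @export
makeToyComplex <- function(spec = toySpec()) {
  set.seed(spec$seed)
  scaffold <- beadBlob(45L, c(0, 0, 0), c(28, 8, 8))
  partner <- beadBlob(20L, c(0, 20, 0), c(7, 7, 7))
  rna <- cbind(seq(-24, 24, length.out = 30L),
               -15 + runif(30L, -1.5, 1.5), runif(30L, -1.5, 1.5))
  fib <- beadBlob(36L, spec$onSite, c(7, 7, 7))
  ## second catalytic copy: always detached in the half-loaded complex
  fib2 <- beadBlob(30L, c(-22, 12, 16), c(7, 7, 7))
  coords <- rbind(scaffold, partner, rna, fib, fib2)
  subunit <- rep(c("scaffold", "partner", "rna", "fib", "fib2"),
                 times = c(45L, 20L, 30L, 36L, 30L))
  methylIdx <- sample(which(subunit == "fib"), spec$nMethyl)
  methyl <- coords[methylIdx, , drop = FALSE]
  rownames(methyl) <- sprintf("M%02d", seq_len(spec$nMethyl))
  tags <- list(
    tagA = matrix(c(18, -15, 38), 1, 3),     # duplex-adjacent: on reporter
    tagB = matrix(c(-32, 2, 0), 1, 3),
    tagC = matrix(c(0, 24, 8), 1, 3))
  template <- conformer(coords, subunit, stateTag = "on_off",
                        mobileSubunits = "fib", methylSites = methyl,
                        tagSites = tags)
  if (!clashCheck(template))
    stop("unsatisfiable clash constraints in the on pose")
  siteSub <- setNames(rep("fib", spec$nMethyl), rownames(methyl))
  onPool <- randomizeMobileSubunits(template, anchor = spec$onSite,
    tetherLength = spec$onJitter, n = spec$nOn, seed = spec$seed + 1L,
    stateTag = "on_off", siteSubunit = siteSub)
  names(onPool@members) <- sub("^on_off", "on", names(onPool@members))
  offPool <- randomizeMobileSubunits(template, anchor = spec$anchor,
    tetherLength = spec$tetherLength, n = spec$nOff, seed = spec$seed + 2L,
    stateTag = "off_off", siteSubunit = siteSub,
    excludeCenter = spec$onSite, excludeRadius = spec$excludeRadius)
  names(offPool@members) <- sub("^off_off", "off", names(offPool@members))
  list(template = template, onPool = onPool, offPool = offPool,
       schemes = toySchemes(), spec = spec,
       truth = list(onSite = spec$onSite, anchor = spec$anchor,
                    fOn = spec$fOn, methylSites = methyl, tagSites = tags))
}

#' Ground-truth mixture weights of the toy complex
#'
#' The true underlying ensemble of the toy system: the on-state fraction
#' spread equally over the first \code{nOnTrue} on-pool poses and the
#' remainder over the first \code{nOffTrue} off-pool poses -- a small
#' discrete mixture of the kind the selection algorithm is expected to
#' recover.
#'
#' @param toy output of \code{\link{makeToyComplex}}.
#' @param nOnTrue number of distinct on poses in the truth (default 3).
#' @param nOffTrue number of distinct off poses in the truth (default 4).
#' @return named numeric weight vector summing to 1.
#' @export
trueMixtureWeights <- function(toy, nOnTrue = 3L, nOffTrue = 4L) {
  onIds <- head(names(poolMembers(toy$onPool)), nOnTrue)
  offIds <- head(names(poolMembers(toy$offPool)), nOffTrue)
  w <- c(rep(toy$spec$fOn / length(onIds), length(onIds)),
         rep((1 - toy$spec$fOn) / length(offIds), length(offIds)))
  setNames(w, c(onIds, offIds))
}

#' Per-conformer scattering curve library
#'
#' Debye intensities of every conformer on the grid of each experimental
#' curve, under the matching contrast scheme.
#'
#' @param conformers named list of \linkS4class{Conformer}s.
#' @param sasData list of \linkS4class{SASCurve}s (provides grids and
#'   scheme names).
#' @param schemes named list of \linkS4class{ContrastScheme}s.
#' @return list over datasets of (grid x conformer) intensity matrices.
#' @export
buildCurveLibrary <- function(conformers, sasData, schemes) {
  lapply(sasData, function(cur) {
    sch <- schemes[[cur@scheme]]
    vapply(conformers, debyeIntensity, numeric(length(cur@s)),
           scheme = sch, sGrid = cur@s)
  })
}

#' Simulate SAS and PRE datasets from a known mixture
#'
#' Ideal observables are computed with the package's own forward models --
#' population-weighted Debye curves per contrast scheme, and fast-exchange
#' r^-6-averaged PRE ratios -- from an arbitrary weight vector over
#' conformers, then Gaussian noise is added. PRE ratio errors carry the
#' 10 percent floor; SAS sigmas are the noise model actually applied.
#'
#' @param conformers named list of \linkS4class{Conformer}s (the truth
#'   members must be among them).
#' @param trueWeights named numeric over conformer ids, summing to 1 (the
#'   ground-truth populations).
#' @param schemes named list of \linkS4class{ContrastScheme}s.
#' @param p a \linkS4class{RelaxationParams}.
#' @param sGrid scattering grid (1/Angstrom).
#' @param sasFrac relative SAS noise (0 gives noiseless curves).
#' @param preSigma absolute PRE ratio noise (0 gives noiseless ratios).
#' @param seed integer seed for rate jitter and noise.
#' @param errorFloor relative PRE error floor written into ratio_err
#'   (default 0.1).
#' @return list with \code{sasData} (list of \linkS4class{SASCurve}s, one
#'   per scheme), \code{preData} (measurement table with noisy ratios and
#'   true diamagnetic rates) and \code{ideal} (the noise-free curves and
#'   ratios).
#' @export
simulateDatasets <- function(conformers, trueWeights, schemes,
                             p = relaxationParams(),
                             sGrid = seq(0.008, 0.25, length.out = 48L),
                             sasFrac = 0.02, preSigma = 0.05, seed = 1L,
                             errorFloor = 0.1) {
  if (abs(sum(trueWeights) - 1) > 1e-8)
    stop("trueWeights must sum to 1")
  missing <- setdiff(names(trueWeights), names(conformers))
  if (length(missing)) stop("unknown truth conformer: ", missing[1])
  set.seed(seed)
  members <- conformers[names(trueWeights)]
  ## SAS: population-weighted Debye curves + relative Gaussian noise
  sasData <- list()
  ideal <- list(curves = list())
  for (nm in names(schemes)) {
    M <- vapply(members, debyeIntensity, numeric(length(sGrid)),
                scheme = schemes[[nm]], sGrid = sGrid)
    I <- as.vector(M %*% trueWeights)
    sig <- pmax(sasFrac * abs(I), 1e-6 * max(I))
    if (sasFrac == 0) sig <- pmax(1e-3 * max(I), 1e-12) + 0 * I
    Iobs <- I + if (sasFrac > 0) rnorm(length(I), 0, sig) else 0
    ideal$curves[[nm]] <- I
    sasData[[nm]] <- sasCurve(sGrid, Iobs, sig, scheme = nm)
  }
  ## PRE: skeleton of methyl x tag rows with per-methyl diamagnetic rates
  m1 <- members[[1]]
  methyls <- rownames(methylSites(m1))
  tagIds <- names(tagSites(m1))
  skel <- expand.grid(methyl_id = methyls, tag_id = tagIds,
                      stringsAsFactors = FALSE)
  rates <- data.frame(methyl_id = methyls,
                      r2_dia_h = runif(length(methyls), 40, 60),
                      r2_dia_hc = runif(length(methyls), 50, 70))
  skel <- merge(skel, rates, by = "methyl_id", sort = FALSE)
  skel <- skel[order(skel$tag_id, skel$methyl_id), ]
  rownames(skel) <- NULL
  ## fast-exchange ensemble-averaged ratios from the same forward model
  ## the scorer uses
  r6 <- preR6Table(members, skel)
  KJ <- p@K * ANG_TO_CM6 * spectralTerm(p)
  idealRatio <- vapply(seq_len(nrow(skel)), function(i) {
    r6avg <- as.vector(r6[[i]][, names(trueWeights), drop = FALSE] %*%
                         trueWeights)
    mean(ratioFromGamma2(KJ * r6avg, skel$r2_dia_h[i], skel$r2_dia_hc[i], p))
  }, numeric(1))
  obs <- idealRatio + if (preSigma > 0) rnorm(nrow(skel), 0, preSigma) else 0
  obs <- pmin(pmax(obs, 1e-3), 1.2)
  skel$ratio <- obs
  skel$ratio_err <- pmax(preSigma, errorFloor * obs)
  if (preSigma == 0) skel$ratio_err <- pmax(errorFloor * obs, 1e-3)
  skel$r2_dia_h_err <- 0.02 * skel$r2_dia_h
  skel$r2_dia_hc_err <- 0.02 * skel$r2_dia_hc
  ideal$ratios <- idealRatio
  list(sasData = unname(sasData), preData = skel, ideal = ideal,
       schemeNames = names(schemes))
}
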
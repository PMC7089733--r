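## Rigid-geometry utilities: Rg, centroids, rigid-body randomization of
## mobile subunits with clash rejection. All coordinates in Angstrom.

#' Radius of gyration of a weighted point set
#'
#' Mass-weighted root-mean-square distance of the points from their weighted
#' centroid. With unit weights this is the usual Rg of a bead model; with
#' contrast weights it is the Rg seen by the corresponding scattering
#' experiment.
#'
#' @param coords n x 3 numeric matrix of positions (Angstrom).
#' @param weights optional non-negative weights (default 1 per point).
#' @return Rg in Angstrom.
#' @examples
#' rgPointSet(rbind(c(0, 0, 0), c(10, 0, 0)))   # 5
#' @export
rgPointSet <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("need at least one point")
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (length(weights) != nrow(coords)) stop("one weight per point required")
  wtot <- sum(weights)
  if (wtot <= 0) stop("total weight must be > 0")
  ctr <- colSums(coords * weights) / wtot
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  sqrt(sum(weights * d2) / wtot)
}

#' Radius of gyration of a conformer under a contrast scheme
#'
#' @param x a \linkS4class{Conformer}.
#' @param scheme a \linkS4class{ContrastScheme} or NULL (unit weights).
#' @return Rg in Angstrom.
#' @export
rgConformer <- function(x, scheme = NULL) {
  w <- schemeWeights(x, scheme)
  keep <- w > 0
  if (!any(keep)) stop("no scatterer has nonzero weight under this scheme")
  rgPointSet(x@coords[keep, , drop = FALSE], w[keep])
}

#' Weighted centroid of a point set
#'
#' @param coords n x 3 matrix.
#' @param weights optional weights.
#' @return length-3 numeric vector.
#' @export
centerOfMass <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  colSums(coords * weights) / sum(weights)
}

## uniform random rotation matrix from a random unit quaternion
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

## uniform random point inside a sphere of given radius
randomInSphere <- function(radius) {
  repeat {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) return(p * radius)
  }
}

#' Steric clash check between subunits
#'
#' TRUE iff no pair of scatterers belonging to different subunits is closer
#' than \code{minDistance}. The threshold is closed: a pair at exactly
#' \code{minDistance} does not count as a clash.
#'
#' @param x a \linkS4class{Conformer}.
#' @param minDistance minimum allowed inter-subunit distance (Angstrom,
#'   default 3).
#' @return logical.
#' @export
clashCheck <- function(x, minDistance = 3.0) {
  if (minDistance <= 0) stop("minDistance must be > 0")
  subs <- unique(x@subunit)
  if (length(subs) < 2L) return(TRUE)
  for (i in seq_len(length(subs) - 1L)) {
    a <- x@coords[x@subunit == subs[i], , drop = FALSE]
    for (j in seq(i + 1L, length(subs))) {
      b <- x@coords[x@subunit == subs[j], , drop = FALSE]
      if (minPairDistance(a, b) < minDistance) return(FALSE)
    }
  }
  TRUE
}

## minimum distance between two point sets (blocked to bound memory)
minPairDistance <- function(a, b) {
  best <- Inf
  step <- 2000L
  for (start in seq(1L, nrow(a), by = step)) {
    idx <- start:min(start + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

## apply a rigid transform (rotation about the module centroid, then move
## the centroid to 'target') to the rows 'sel' of a coordinate matrix, and
## to any annotated sites riding on those subunits
rigidPlace <- function(coords, sel, rot, target) {
  mod <- coords[sel, , drop = FALSE]
  ctr <- colMeans(mod)
  moved <- sweep(mod, 2, ctr) %*% t(rot)
  coords[sel, ] <- sweep(moved, 2, target, "+")
  coords
}

transformPoints <- function(pts, ctr, rot, target) {
  if (nrow(pts) == 0L) return(pts)
  sweep(sweep(pts, 2, ctr) %*% t(rot), 2, target, "+")
}

#' Randomize the pose of mobile subunits
#'
#' Generates \code{n} copies of a conformer in which every mobile subunit is
#' rigidly rotated (uniform random rotation) and translated so that its
#' centroid lands at a uniformly sampled point inside a tether sphere.
#' Poses creating inter-subunit clashes are rejected and redrawn; internal
#' geometry of each mobile subunit is preserved exactly. Methyl and tag
#' sites attached to a mobile subunit (identified by the \code{siteSubunit}
#' maps) ride along with it.
#'
#' @param x template \linkS4class{Conformer}; its \code{mobileSubunits}
#'   slot names the modules to move.
#' @param anchor length-3 tether anchor point (Angstrom).
#' @param tetherLength maximum distance of the module centroid from the
#'   anchor (Angstrom).
#' @param n number of conformers to generate (0 gives an empty pool).
#' @param seed integer seed; the pool is deterministic given the seed.
#' @param minDistance clash threshold in Angstrom (default 3).
#' @param maxAttempts rejection-sampling budget per pose (default 1000).
#' @param stateTag state tag given to the generated conformers (default
#'   \code{"off_off"}).
#' @param siteSubunit named character vector mapping methyl ids to the
#'   subunit they sit on (sites on mobile subunits are transformed with the
#'   module); defaults to none riding.
#' @param tagSubunit same mapping for tag ids.
#' @param excludeCenter optional length-3 point; poses whose module centroid
#'   falls within \code{excludeRadius} of it are rejected (used to keep an
#'   "off" pool away from the bound site).
#' @param excludeRadius exclusion radius in Angstrom (default 0 = none).
#' @return A \linkS4class{ConformerPool}.
#' @export
randomizeMobileSubunits <- function(x, anchor, tetherLength, n, seed,
                                    minDistance = 3.0, maxAttempts = 1000L,
                                    stateTag = "off_off",
                                    siteSubunit = character(),
                                    tagSubunit = character(),
                                    excludeCenter = NULL, excludeRadius = 0) {
  if (length(x@mobileSubunits) == 0L)
    stop("conformer has no mobile subunits")
  missing <- setdiff(x@mobileSubunits, unique(x@subunit))
  if (length(missing))
    stop("mobile subunit not present in conformer: ", missing[1])
  set.seed(seed)
  members <- vector("list", n)
  fixedSel <- !(x@subunit %in% x@mobileSubunits)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(maxAttempts)) {
      cand <- x@coords
      ms <- x@methylSites
      ts <- x@tagSites
      for (sub in x@mobileSubunits) {
        sel <- x@subunit == sub
        rot <- randomRotation()
        target <- anchor + randomInSphere(tetherLength)
        if (!is.null(excludeCenter) && excludeRadius > 0 &&
            sqrt(sum((target - excludeCenter)^2)) < excludeRadius) {
          cand <- NULL
          break
        }
        ctr <- colMeans(x@coords[sel, , drop = FALSE])
        cand <- rigidPlace(cand, sel, rot, target)
        if (nrow(ms) > 0 && length(siteSubunit)) {
          ride <- rownames(ms) %in% names(siteSubunit)[siteSubunit == sub]
          ms[ride, ] <- transformPoints(ms[ride, , drop = FALSE], ctr, rot, target)
        }
        if (length(ts) > 0 && length(tagSubunit)) {
          for (tg in names(ts)) {
            if (!is.na(tagSubunit[tg]) && identical(unname(tagSubunit[tg]), sub))
              ts[[tg]] <- transformPoints(ts[[tg]], ctr, rot, target)
          }
        }
      }
      if (is.null(cand)) next
      cc <- x
      cc@coords <- cand
      cc@methylSites <- ms
      cc@tagSites <- ts
      cc@stateTag <- stateTag
      if (clashCheck(cc, minDistance)) {
        members[[k]] <- cc
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("no clash-free pose found for subunit(s) ",
           paste(x@mobileSubunits, collapse = ", "), " after ",
           maxAttempts, " attempts")
  }
  names(members) <- if (n > 0) sprintf("%s%04d", stateTag, seq_len(n)) else character()
  conformerPool(members, provenance = "randomized-mobile", seed = seed)
}
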
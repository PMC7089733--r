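#' @import methods
#' @importFrom stats lm coef optimize rnorm runif sd setNames weighted.mean
#' @importFrom utils read.table write.table head
NULL

## ---------------------------------------------------------------------------
## ContrastScheme
## ---------------------------------------------------------------------------

#' Contrast scheme: per-subunit scattering weights
#'
#' A contrast scheme assigns a dimensionless scattering weight to every
#' subunit of a complex. In SANS contrast-matching experiments, protonated
#' subunits in a 42:58 D2O:H2O solvent are matched to the solvent and carry
#' weight 0, while deuterated subunits scatter with full (or partial) weight.
#' A SAXS-like scheme weights every subunit equally.
#'
#' @slot name scheme label, e.g. \code{"2H-Fib"} or \code{"SAXS"}.
#' @slot weights named numeric vector, subunit id to scattering weight
#'   (>= 0; 0 means contrast-matched).
#' @export
setClass("ContrastScheme",
  representation(name = "character", weights = "numeric"))

setValidity("ContrastScheme", function(object) {
  w <- object@weights
  if (length(w) == 0L || is.null(names(w)) || any(!nzchar(names(w))))
    return("weights must be a non-empty named numeric vector")
  if (any(!is.finite(w)) || any(w < 0))
    return("weights must be finite and >= 0")
  if (all(w == 0))
    return("at least one subunit must have a nonzero weight")
  TRUE
})

#' Create a contrast scheme
#'
#' @param name scheme label.
#' @param weights named numeric vector of per-subunit scattering weights.
#' @return A \linkS4class{ContrastScheme}.
#' @examples
#' contrastScheme("2H-Fib", c(fib = 1, scaffold = 0, rna = 0))
#' @export
contrastScheme <- function(name, weights)
  new("ContrastScheme", name = name, weights = weights)

#' @describeIn ContrastScheme show method
#' @param object a \code{ContrastScheme}
#' @export
setMethod("show", "ContrastScheme", function(object) {
  cat("ContrastScheme:", object@name, "\n")
  print(object@weights)
})

## ---------------------------------------------------------------------------
## Conformer
## ---------------------------------------------------------------------------

#' A single conformer: labelled scatterer set with site annotations
#'
#' A conformer is an ordered set of scatterers (beads or atoms) in a
#' right-handed Cartesian frame, in Angstrom, partitioned into subunits.
#' Methyl sites (reporter positions for PRE observation) and spin-label tag
#' sites (nitroxide N-O nitrogen positions) are carried as named coordinate
#' tables so restraint derivation and back-calculation can resolve them
#' without re-parsing atom records.
#'
#' @slot coords numeric matrix, n x 3, positions in Angstrom.
#' @slot subunit character vector of length n, subunit id per scatterer.
#' @slot atomName character vector, atom names (may be bead placeholders).
#' @slot resid integer vector, 1-based residue numbering.
#' @slot stateTag one of \code{"on_off"}, \code{"off_off"}, \code{"other"}.
#' @slot mobileSubunits character, subunit ids that move as rigid bodies.
#' @slot methylSites numeric matrix, m x 3, rownames are methyl ids.
#' @slot tagSites named list; each element a k x 3 matrix of alternative
#'   spin-label N-O positions for that tag id.
#' @export
setClass("Conformer",
  representation(coords = "matrix", subunit = "character",
    atomName = "character", resid = "integer",
    stateTag = "character", mobileSubunits = "character",
    methylSites = "matrix", tagSites = "list"))

setValidity("Conformer", function(object) {
  n <- nrow(object@coords)
  if (n < 1L || ncol(object@coords) != 3L)
    return("coords must be an n x 3 matrix with n >= 1")
  if (any(!is.finite(object@coords)))
    return("coords must be finite")
  if (length(object@subunit) != n)
    return("subunit must have one entry per scatterer")
  if (!object@stateTag %in% c("on_off", "off_off", "other"))
    return("stateTag must be one of 'on_off', 'off_off', 'other'")
  if (nrow(object@methylSites) > 0) {
    ids <- rownames(object@methylSites)
    if (is.null(ids) || anyDuplicated(ids))
      return("methylSites rownames must be unique methyl ids")
  }
  if (length(object@tagSites) > 0) {
    if (is.null(names(object@tagSites)) || anyDuplicated(names(object@tagSites)))
      return("tagSites must be a uniquely named list")
    bad <- vapply(object@tagSites,
      function(m) !is.matrix(m) || ncol(m) != 3L || nrow(m) < 1L, logical(1))
    if (any(bad)) return("each tagSites element must be a k x 3 matrix")
  }
  TRUE
})

#' Create a conformer
#'
#' @param coords n x 3 numeric matrix of positions (Angstrom).
#' @param subunit character vector of subunit ids (length n, or length 1,
#'   recycled).
#' @param stateTag conformational state label: \code{"on_off"},
#'   \code{"off_off"} or \code{"other"}.
#' @param mobileSubunits subunit ids treated as rigid mobile modules.
#' @param methylSites m x 3 matrix with methyl ids as rownames, or NULL.
#' @param tagSites named list of k x 3 matrices of spin-label positions,
#'   or NULL.
#' @param atomName,resid optional per-scatterer atom names and residue
#'   numbers.
#' @return A \linkS4class{Conformer}.
#' @export
conformer <- function(coords, subunit, stateTag = "other",
                      mobileSubunits = character(), methylSites = NULL,
                      tagSites = NULL, atomName = NULL, resid = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (length(subunit) == 1L) subunit <- rep(subunit, n)
  if (is.null(atomName)) atomName <- rep("CA", n)
  if (is.null(resid)) resid <- seq_len(n)
  if (is.null(methylSites)) methylSites <- matrix(numeric(0), 0, 3)
  if (is.null(tagSites)) tagSites <- list()
  new("Conformer", coords = coords, subunit = as.character(subunit),
    atomName = as.character(atomName), resid = as.integer(resid),
    stateTag = stateTag, mobileSubunits = as.character(mobileSubunits),
    methylSites = as.matrix(methylSites), tagSites = tagSites)
}

#' @describeIn Conformer show method
#' @param object a \code{Conformer}
#' @export
setMethod("show", "Conformer", function(object) {
  cat("Conformer:", nrow(object@coords), "scatterers in",
      length(unique(object@subunit)), "subunits |", object@stateTag, "\n")
  cat("  methyl sites:", nrow(object@methylSites),
      "| tags:", length(object@tagSites), "\n")
})

## accessors -----------------------------------------------------------------

#' @rdname conformer-accessors
#' @title Conformer accessors
#' @description Accessor generics for \linkS4class{Conformer} objects:
#'   coordinates, subunit ids, state tag, methyl and tag site tables.
#' @param x a \code{Conformer}.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname conformer-accessors
#' @export
setMethod("coords", "Conformer", function(x) x@coords)

#' @rdname conformer-accessors
#' @export
setGeneric("subunitIds", function(x) standardGeneric("subunitIds"))
#' @rdname conformer-accessors
#' @export
setMethod("subunitIds", "Conformer", function(x) x@subunit)

#' @rdname conformer-accessors
#' @export
setGeneric("stateTag", function(x) standardGeneric("stateTag"))
#' @rdname conformer-accessors
#' @export
setMethod("stateTag", "Conformer", function(x) x@stateTag)

#' @rdname conformer-accessors
#' @export
setGeneric("methylSites", function(x) standardGeneric("methylSites"))
#' @rdname conformer-accessors
#' @export
setMethod("methylSites", "Conformer", function(x) x@methylSites)

#' @rdname conformer-accessors
#' @export
setGeneric("tagSites", function(x) standardGeneric("tagSites"))
#' @rdname conformer-accessors
#' @export
setMethod("tagSites", "Conformer", function(x) x@tagSites)

#' Per-scatterer weights of a conformer under a contrast scheme
#'
#' Subunits absent from the scheme's weight table are treated as
#' contrast-matched (weight 0).
#'
#' @param x a \linkS4class{Conformer}.
#' @param scheme a \linkS4class{ContrastScheme}, or NULL for unit weights.
#' @return numeric vector of length \code{nrow(coords(x))}.
#' @export
schemeWeights <- function(x, scheme = NULL) {
  if (is.null(scheme)) return(rep(1, nrow(x@coords)))
  w <- scheme@weights[x@subunit]
  w[is.na(w)] <- 0
  unname(w)
}

## ---------------------------------------------------------------------------
## ConformerPool
## ---------------------------------------------------------------------------

#' A pool of conformers
#'
#' @slot members named list of \linkS4class{Conformer} objects; names are
#'   conformer ids used by ensembles.
#' @slot provenance free-text label, e.g. \code{"randomized-mobile"}.
#' @slot seed integer seed used to generate the pool (NA if not generated).
#' @export
setClass("ConformerPool",
  representation(members = "list", provenance = "character", seed = "integer"))

setValidity("ConformerPool", function(object) {
  if (length(object@members) >= 1L) {
    if (is.null(names(object@members)) || anyDuplicated(names(object@members)))
      return("members must be uniquely named")
    ok <- vapply(object@members, is, logical(1), class2 = "Conformer")
    if (!all(ok)) return("all members must be Conformer objects")
  }
  TRUE
})

#' Create a conformer pool
#'
#' @param members list of \linkS4class{Conformer}s (named, or names are
#'   generated).
#' @param provenance label describing how the pool was produced.
#' @param seed generating seed, if any.
#' @return A \linkS4class{ConformerPool}.
#' @export
conformerPool <- function(members, provenance = "unspecified", seed = NA_integer_) {
  if (is.null(names(members)) && length(members) > 0)
    names(members) <- sprintf("c%04d", seq_along(members))
  new("ConformerPool", members = members, provenance = provenance,
      seed = as.integer(seed))
}

#' @describeIn ConformerPool show method
#' @param object a \code{ConformerPool}
#' @export
setMethod("show", "ConformerPool", function(object) {
  cat("ConformerPool:", length(object@members), "conformers (",
      object@provenance, ")\n")
})

#' @rdname pool-accessors
#' @title Pool accessors
#' @description Number of members and member list of a
#'   \linkS4class{ConformerPool}.
#' @param x a \code{ConformerPool}.
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))
#' @rdname pool-accessors
#' @export
setMethod("poolSize", "ConformerPool", function(x) length(x@members))

#' @rdname pool-accessors
#' @export
setGeneric("poolMembers", function(x) standardGeneric("poolMembers"))
#' @rdname pool-accessors
#' @export
setMethod("poolMembers", "ConformerPool", function(x) x@members)

## ---------------------------------------------------------------------------
## Ensemble
## ---------------------------------------------------------------------------

#' A conformational ensemble as a multiset of conformer ids
#'
#' Member multiplicity encodes population: a conformer listed twice in a
#' 3-member ensemble carries weight 2/3. Weights therefore always sum to 1.
#'
#' @slot memberIds character vector of conformer ids (repeats allowed).
#' @export
setClass("Ensemble", representation(memberIds = "character"))

setValidity("Ensemble", function(object) {
  if (length(object@memberIds) < 1L) return("ensemble must have >= 1 member")
  if (any(!nzchar(object@memberIds))) return("member ids must be non-empty")
  TRUE
})

#' Create an ensemble
#'
#' @param memberIds character vector of conformer ids; repetition encodes
#'   population weight.
#' @return An \linkS4class{Ensemble}.
#' @examples
#' e <- ensemble(c("a", "a", "b"))
#' ensembleWeights(e)   # a: 2/3, b: 1/3
#' @export
ensemble <- function(memberIds) new("Ensemble", memberIds = as.character(memberIds))

#' @rdname ensemble-accessors
#' @title Ensemble accessors
#' @description Member ids, size and population weights of an
#'   \linkS4class{Ensemble}. \code{ensembleWeights} returns the multiplicity
#'   of each distinct member divided by the ensemble size (molar fractions,
#'   summing to 1).
#' @param x an \code{Ensemble}.
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname ensemble-accessors
#' @export
setMethod("memberIds", "Ensemble", function(x) x@memberIds)

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleSize", function(x) standardGeneric("ensembleSize"))
#' @rdname ensemble-accessors
#' @export
setMethod("ensembleSize", "Ensemble", function(x) length(x@memberIds))

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleWeights", function(x) standardGeneric("ensembleWeights"))
#' @rdname ensemble-accessors
#' @export
setMethod("ensembleWeights", "Ensemble", function(x) {
  tab <- table(x@memberIds)
  setNames(as.numeric(tab) / length(x@memberIds), names(tab))
})

#' @describeIn Ensemble show method
#' @param object an \code{Ensemble}
#' @export
setMethod("show", "Ensemble", function(object) {
  cat("Ensemble of", length(object@memberIds), "members:\n")
  print(ensembleWeights(object))
})

## ---------------------------------------------------------------------------
## SASCurve
## ---------------------------------------------------------------------------

#' A one-dimensional small-angle scattering curve
#'
#' The scattering-vector convention is s = 4 pi sin(theta) / lambda in
#' 1/Angstrom throughout.
#'
#' @slot s strictly increasing grid of scattering-vector moduli (1/Angstrom).
#' @slot I intensities (arbitrary units).
#' @slot sigma per-point errors, > 0.
#' @slot scheme contrast-scheme name the curve belongs to.
#' @export
setClass("SASCurve",
  representation(s = "numeric", I = "numeric", sigma = "numeric",
                 scheme = "character"))

setValidity("SASCurve", function(object) {
  n <- length(object@s)
  if (n < 1L) return("empty curve")
  if (length(object@I) != n || length(object@sigma) != n)
    return("s, I and sigma must have equal length")
  if (any(diff(object@s) <= 0)) return("s must be strictly increasing")
  if (any(object@sigma <= 0)) return("sigma must be > 0")
  TRUE
})

#' Create a SAS curve
#'
#' @param s scattering-vector grid (1/Angstrom), strictly increasing.
#' @param I intensities.
#' @param sigma per-point errors (> 0).
#' @param scheme contrast-scheme name.
#' @return A \linkS4class{SASCurve}.
#' @export
sasCurve <- function(s, I, sigma, scheme = "SAXS")
  new("SASCurve", s = as.numeric(s), I = as.numeric(I),
      sigma = as.numeric(sigma), scheme = scheme)

#' @describeIn SASCurve show method
#' @param object a \code{SASCurve}
#' @export
setMethod("show", "SASCurve", function(object) {
  cat(sprintf("SASCurve [%s]: %d points, s in [%.4g, %.4g] 1/A\n",
    object@scheme, length(object@s), min(object@s), max(object@s)))
})

## ---------------------------------------------------------------------------
## RelaxationParams
## ---------------------------------------------------------------------------

#' Relaxation parameters for the PRE forward and inverse models
#'
#' @slot tauC effective correlation time of the electron-nucleus vector (s).
#' @slot tauCErr uncertainty on tauC (s).
#' @slot omega proton Larmor frequency (rad/s).
#' @slot tHMQC magnetization transfer time of the HMQC sequence (s).
#' @slot K electron-proton interaction constant (cm^6 s^-2).
#' @export
setClass("RelaxationParams",
  representation(tauC = "numeric", tauCErr = "numeric", omega = "numeric",
                 tHMQC = "numeric", K = "numeric"))

setValidity("RelaxationParams", function(object) {
  v <- c(object@tauC, object@omega, object@tHMQC, object@K)
  if (any(!is.finite(v)) || any(v <= 0))
    return("tauC, omega, tHMQC and K must be positive and finite")
  if (object@tauCErr < 0) return("tauCErr must be >= 0")
  TRUE
})

#' Create relaxation parameters
#'
#' Defaults are the values used for methyl-observed PRE on a large RNP:
#' tauC = 51.8 +/- 5.7 ns, an 800 MHz proton frequency, a 7.6 ms HMQC
#' transfer time and K = 1.23e-32 cm^6 s^-2 (the standard nitroxide-proton
#' interaction constant; see the vignette for the unit-consistency note).
#'
#' @param tauC correlation time in seconds.
#' @param tauCErr uncertainty on tauC in seconds.
#' @param omega proton Larmor frequency in rad/s.
#' @param tHMQC HMQC transfer time in seconds.
#' @param K interaction constant in cm^6 s^-2.
#' @return A \linkS4class{RelaxationParams}.
#' @export
relaxationParams <- function(tauC = 51.8e-9, tauCErr = 5.7e-9,
                             omega = 2 * pi * 800e6, tHMQC = 7.6e-3,
                             K = 1.23e-32)
  new("RelaxationParams", tauC = tauC, tauCErr = tauCErr, omega = omega,
      tHMQC = tHMQC, K = K)

#' @describeIn RelaxationParams show method
#' @param object a \code{RelaxationParams}
#' @export
setMethod("show", "RelaxationParams", function(object) {
  cat(sprintf("RelaxationParams: tauC = %.1f +/- %.1f ns, omega/2pi = %.0f MHz, tHMQC = %.1f ms\n",
    object@tauC * 1e9, object@tauCErr * 1e9, object@omega / (2 * pi * 1e6),
    object@tHMQC * 1e3))
})

## ---------------------------------------------------------------------------
## SpinLabelEnsemble
## ---------------------------------------------------------------------------

#' An ensemble of spin-label conformations for one tag
#'
#' Linker flexibility makes a single nitroxide position a poor model; PRE
#' back-calculation therefore averages r^-6 over a weighted set of
#' alternative N-O positions.
#'
#' @slot tagId tag identifier.
#' @slot positions k x 3 matrix of N-O nitrogen positions (Angstrom).
#' @slot weights numeric weights summing to 1.
#' @export
setClass("SpinLabelEnsemble",
  representation(tagId = "character", positions = "matrix",
                 weights = "numeric"))

setValidity("SpinLabelEnsemble", function(object) {
  k <- nrow(object@positions)
  if (k < 1L || ncol(object@positions) != 3L)
    return("positions must be a k x 3 matrix with k >= 1")
  if (length(object@weights) != k) return("one weight per position required")
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  TRUE
})

#' Create a spin-label ensemble
#'
#' @param tagId tag identifier.
#' @param positions k x 3 matrix of alternative N-O positions (Angstrom).
#' @param weights optional weights (default equal), normalized to sum to 1.
#' @return A \linkS4class{SpinLabelEnsemble}.
#' @export
spinLabelEnsemble <- function(tagId, positions, weights = NULL) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3L)
    positions <- matrix(positions, ncol = 3)
  if (is.null(weights)) weights <- rep(1 / nrow(positions), nrow(positions))
  weights <- weights / sum(weights)
  new("SpinLabelEnsemble", tagId = tagId, positions = positions,
      weights = weights)
}

#' @describeIn SpinLabelEnsemble show method
#' @param object a \code{SpinLabelEnsemble}
#' @export
setMethod("show", "SpinLabelEnsemble", function(object) {
  cat("SpinLabelEnsemble:", object@tagId, "with",
      nrow(object@positions), "conformations\n")
})

## ---------------------------------------------------------------------------
## RgDistribution
## ---------------------------------------------------------------------------

#' A distribution of model radii of gyration
#'
#' Summarizes the per-conformer Rg values of a pool (e.g. models with
#' randomized mobile-module positions) for oligomeric-state classification.
#'
#' @slot mean mean Rg (Angstrom).
#' @slot sd standard deviation (Angstrom).
#' @slot samples the per-conformer Rg values.
#' @slot modelLabel model identity, e.g. \code{"apo-di-RNP"}.
#' @export
setClass("RgDistribution",
  representation(mean = "numeric", sd = "numeric", samples = "numeric",
                 modelLabel = "character"))

setValidity("RgDistribution", function(object) {
  if (length(object@samples) < 1L) return("samples must be non-empty")
  if (object@sd < 0) return("sd must be >= 0")
  if (object@mean < min(object@samples) - 1e-9 ||
      object@mean > max(object@samples) + 1e-9)
    return("mean must lie within the range of samples")
  TRUE
})

#' Create an Rg distribution summary from samples
#'
#' @param samples numeric vector of Rg values (Angstrom).
#' @param modelLabel label for the model the samples describe.
#' @return An \linkS4class{RgDistribution}.
#' @export
rgDistributionFromSamples <- function(samples, modelLabel = "model") {
  s <- if (length(samples) > 1L) stats::sd(samples) else 0
  new("RgDistribution", mean = mean(samples), sd = s,
      samples = as.numeric(samples), modelLabel = modelLabel)
}

#' @describeIn RgDistribution show method
#' @param object an \code{RgDistribution}
#' @export
setMethod("show", "RgDistribution", function(object) {
  cat(sprintf("RgDistribution [%s]: %.1f +/- %.1f A (n = %d)\n",
    object@modelLabel, object@mean, object@sd, length(object@samples)))
})

#' @rdname rg-accessors
#' @title RgDistribution accessors
#' @description Mean, standard deviation and raw samples of an
#'   \linkS4class{RgDistribution}.
#' @param x an \code{RgDistribution}.
#' @export
setGeneric("rgMean", function(x) standardGeneric("rgMean"))
#' @rdname rg-accessors
#' @export
setMethod("rgMean", "RgDistribution", function(x) x@mean)
#' @rdname rg-accessors
#' @export
setGeneric("rgSD", function(x) standardGeneric("rgSD"))
#' @rdname rg-accessors
#' @export
setMethod("rgSD", "RgDistribution", function(x) x@sd)
#' @rdname rg-accessors
#' @export
setGeneric("rgSamples", function(x) standardGeneric("rgSamples"))
#' @rdname rg-accessors
#' @export
setMethod("rgSamples", "RgDistribution", function(x) x@samples)
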
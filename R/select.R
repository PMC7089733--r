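## Pseudo-genetic ensemble selection with consensus PRE-SAS scoring,
## percentile/chi2-cutoff structure filtering, replicate-run population
## estimation and spin-label-ensemble refinement.

#' Configuration of the ensemble-selection algorithm
#'
#' Defaults follow the published protocol: four parent ensembles of 2-10
#' conformers, 20 children of 3-10 conformers per iteration, a 30 percent
#' duplicate-or-replace mutation probability per sub-sampling event, 250
#' iterations, three independent runs and the top three ensembles per run
#' for the population estimate.
#'
#' @param nParents number of parent ensembles (default 4).
#' @param parentSizeRange inclusive size range of initial parents
#'   (default c(2, 10)).
#' @param nChildren children per iteration (default 20).
#' @param childSizeRange inclusive size range of children (default
#'   c(3, 10)).
#' @param pMutation mutation probability per sub-sampling event
#'   (default 0.30).
#' @param nIterations iterations per run (default 250).
#' @param nRuns independent scoring runs (default 3).
#' @param topK top-scoring ensembles kept per run (default 3).
#' @param seed integer seed; run r uses seed + r - 1.
#' @return list of class \code{"ScoringConfig"}.
#' @export
scoringConfig <- function(nParents = 4L, parentSizeRange = c(2L, 10L),
                          nChildren = 20L, childSizeRange = c(3L, 10L),
                          pMutation = 0.30, nIterations = 250L, nRuns = 3L,
                          topK = 3L, seed = 1L) {
  stopifnot(pMutation >= 0, pMutation <= 1,
            parentSizeRange[1] >= 1, parentSizeRange[2] >= parentSizeRange[1],
            childSizeRange[1] >= 1, childSizeRange[2] >= childSizeRange[1])
  structure(list(nParents = nParents, parentSizeRange = parentSizeRange,
                 nChildren = nChildren, childSizeRange = childSizeRange,
                 pMutation = pMutation, nIterations = nIterations,
                 nRuns = nRuns, topK = topK, seed = seed),
            class = "ScoringConfig")
}

## ---------------------------------------------------------------------------
## Consensus scoring
## ---------------------------------------------------------------------------

## Raw chi2 matrix -> consensus table. channels: list(sas = <col names>,
## pre = <col name or NULL>). Each channel is min-max normalized over the
## rows; the normalized SAS columns are summed and renormalized into a
## single SAS fitness; consensus = SAS fitness + normalized PRE.
consensusFromRaw <- function(raw, channels) {
  raw <- as.matrix(raw)
  one <- nrow(raw) == 1L
  normCol <- function(x) if (one) 0 else normalizeScores(x)
  sasCols <- intersect(channels$sas, colnames(raw))
  out <- data.frame(row.names = NULL)
  sasFit <- rep(0, nrow(raw))
  if (length(sasCols)) {
    sasN <- vapply(sasCols, function(cn) normCol(raw[, cn]),
                   numeric(nrow(raw)))
    sasN <- matrix(sasN, nrow = nrow(raw))
    sasSum <- rowSums(sasN)
    sasFit <- if (one) 0 else normCol(sasSum)
  }
  preFit <- rep(0, nrow(raw))
  if (!is.null(channels$pre) && channels$pre %in% colnames(raw))
    preFit <- normCol(raw[, channels$pre])
  data.frame(sasFitness = sasFit, preFitness = preFit,
             consensus = sasFit + preFit)
}

#' Consensus PRE-SAS scores for a set of ensembles
#'
#' Computes, for every ensemble, the chi2 against each SAS dataset (via the
#' population-weighted mixture curve and the optimally scaled chi2) and
#' against the PRE table (scale fixed to 1), then min-max normalizes each
#' chi2 column over the supplied set, sums and renormalizes the SAS columns
#' into a single SAS fitness and adds the normalized PRE fitness to give
#' the consensus score. Normalization is relative to the set of ensembles
#' passed in; lower consensus is better.
#'
#' @param ensembles list of \linkS4class{Ensemble}s.
#' @param sasData list of \linkS4class{SASCurve}s (the experimental
#'   datasets).
#' @param curveLib list (one element per SAS dataset) of per-conformer
#'   intensity matrices (grid points x conformers, columns named by
#'   conformer id).
#' @param preData PRE measurement table.
#' @param r6table precomputed \code{\link{preR6Table}} over all candidate
#'   conformers (or NULL to skip PRE scoring).
#' @param p a \linkS4class{RelaxationParams}.
#' @return data.frame with one row per ensemble: per-dataset chi2 columns,
#'   \code{preChi2}, \code{sasFitness}, \code{preFitness} and
#'   \code{consensus}.
#' @export
scoreEnsembles <- function(ensembles, sasData, curveLib, preData = NULL,
                           r6table = NULL, p = relaxationParams()) {
  rawFun <- makeRawScorer(sasData, curveLib, preData, r6table, p)
  raw <- t(vapply(ensembles, function(e) rawFun(memberIds(e)),
                  numeric(length(rawChannelNames(sasData, r6table)))))
  channels <- rawChannels(sasData, r6table)
  cons <- consensusFromRaw(raw, channels)
  cbind(as.data.frame(raw), cons)
}

rawChannelNames <- function(sasData, r6table) {
  nm <- vapply(seq_along(sasData), function(i) {
    sc <- sasData[[i]]@scheme
    if (nzchar(sc)) sc else paste0("curve", i)
  }, character(1))
  nm <- make.unique(nm)
  if (!is.null(r6table)) nm <- c(nm, "preChi2")
  nm
}

rawChannels <- function(sasData, r6table) {
  nm <- rawChannelNames(sasData, r6table)
  list(sas = if (length(sasData)) nm[seq_along(sasData)] else character(),
       pre = if (!is.null(r6table)) "preChi2" else NULL)
}

makeRawScorer <- function(sasData, curveLib, preData, r6table, p) {
  nm <- rawChannelNames(sasData, r6table)
  ## fast path: every measurement row has a single protein copy, so the
  ## whole r^-6 table stacks into one (rows x conformers) matrix and the
  ## per-ensemble prediction is a single matrix-vector product; the
  ## generic predictRatios()/ensembleCurve() path is the reference and
  ## the two agree to machine precision
  singleCopy <- !is.null(r6table) &&
    all(vapply(r6table, nrow, integer(1)) == 1L)
  if (singleCopy) {
    R6 <- do.call(rbind, r6table)
    KJ <- p@K * ANG_TO_CM6 * spectralTerm(p)
    r2h <- preData$r2_dia_h
    r2hc <- preData$r2_dia_hc
    th <- p@tHMQC
    obs <- preData$ratio
    errInv2 <- 1 / preData$ratio_err^2
  }
  expIv <- lapply(sasData, function(cur) 1 / cur@sigma^2)
  expI <- lapply(sasData, function(cur) cur@I)
  function(members) {
    tw <- table(members)
    ids <- names(tw)
    wt <- as.numeric(tw) / length(members)
    v <- numeric(length(nm))
    for (i in seq_along(sasData)) {
      ic <- as.vector(curveLib[[i]][, ids, drop = FALSE] %*% wt)
      iv <- expIv[[i]]
      cc <- sum(expI[[i]] * ic * iv) / sum(ic^2 * iv)
      v[i] <- mean(((expI[[i]] - cc * ic)^2) * iv)
    }
    if (!is.null(r6table)) {
      if (singleCopy) {
        gam <- KJ * as.vector(R6[, ids, drop = FALSE] %*% wt)
        pred <- exp(-gam * th) * (r2h * r2hc) /
          ((r2h + gam) * (r2hc + gam))
        v[length(nm)] <- mean((obs - pred)^2 * errInv2)
      } else {
        e <- ensemble(members)
        v[length(nm)] <- preChi2(predictRatios(e, r6table, preData, p),
                                 preData)
      }
    }
    names(v) <- nm
    v
  }
}

## ---------------------------------------------------------------------------
## Generic pseudo-genetic engine
## ---------------------------------------------------------------------------

## itemIds: the pool of selectable items. rawFun(members) -> named numeric
## of raw chi2 channels. channels: as for consensusFromRaw. One seeded run.
gaRun <- function(itemIds, rawFun, channels, cfg, seed) {
  set.seed(seed)
  archKeys <- character()
  archMembers <- list()
  archRaw <- list()
  archIter <- integer()
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  scoreMembers <- function(members, iter) {
    key <- paste(sort(members), collapse = "|")
    idx <- lookup[[key]]
    if (is.null(idx)) {
      idx <- length(archKeys) + 1L
      archKeys[[idx]] <<- key
      archMembers[[idx]] <<- members
      archRaw[[idx]] <<- rawFun(members)
      archIter[[idx]] <<- iter
      lookup[[key]] <- idx
    }
    idx
  }
  drawSize <- function(rng) if (rng[1] == rng[2]) rng[1]
                            else sample(rng[1]:rng[2], 1L)
  parents <- lapply(seq_len(cfg$nParents), function(i)
    sample(itemIds, drawSize(cfg$parentSizeRange), replace = TRUE))
  for (iter in seq_len(cfg$nIterations)) {
    merged <- unlist(parents)
    childIdx <- integer(cfg$nChildren)
    for (j in seq_len(cfg$nChildren)) {
      size <- drawSize(cfg$childSizeRange)
      child <- sample(merged, size, replace = size > length(merged))
      if (runif(1) < cfg$pMutation) {
        pos <- sample.int(length(child), 1L)
        if (runif(1) < 0.5 && length(child) > 1L) {
          child[pos] <- sample(child[-pos], 1L)   # duplicate a member
        } else {
          child[pos] <- sample(itemIds, 1L)       # replace from main pool
        }
      }
      childIdx[j] <- scoreMembers(child, iter)
    }
    rawNow <- do.call(rbind, archRaw)
    consNow <- consensusFromRaw(rawNow, channels)$consensus
    ord <- order(consNow[childIdx],
                 lengths(archMembers[childIdx]),
                 archKeys[childIdx])
    elite <- childIdx[ord][seq_len(min(cfg$nParents, length(childIdx)))]
    parents <- archMembers[elite]
  }
  raw <- do.call(rbind, archRaw)
  rownames(raw) <- NULL
  cons <- consensusFromRaw(raw, channels)
  ord <- order(cons$consensus, lengths(archMembers), archKeys)
  list(keys = archKeys[ord], members = archMembers[ord],
       raw = raw[ord, , drop = FALSE], scores = cons[ord, , drop = FALSE],
       firstSeen = archIter[ord], seed = seed)
}

## best-so-far consensus trajectory under the final normalization
gaTrajectory <- function(run, nIterations) {
  vapply(seq_len(nIterations), function(t) {
    seen <- run$firstSeen <= t
    if (!any(seen)) NA_real_ else min(run$scores$consensus[seen])
  }, numeric(1))
}

## ---------------------------------------------------------------------------
## Structure filtering
## ---------------------------------------------------------------------------

#' Filter scored structures by energy percentile and chi2 cutoffs
#'
#' Keeps the intersection of (a) the structures ranking in the top
#' \code{energyPercentile} percent of every energy column (lowest values)
#' and (b) the structures with chi2 <= multiplier * min(chi2) for every
#' named chi2 column. Ordering of the result is deterministic (input
#' order).
#'
#' @param scores data.frame of per-structure scores; must contain every
#'   column named in \code{energyCols} and \code{chi2Cutoffs}.
#' @param energyCols character vector of energy column names.
#' @param energyPercentile percentage of structures retained per energy
#'   column (100 keeps all).
#' @param chi2Cutoffs named numeric: chi2 column name -> multiple of the
#'   column minimum (Inf keeps all).
#' @return the selected rows of \code{scores}.
#' @export
filterByFitness <- function(scores, energyCols = character(),
                            energyPercentile = 100,
                            chi2Cutoffs = numeric()) {
  n <- nrow(scores)
  keep <- rep(TRUE, n)
  binding <- character()
  for (ec in energyCols) {
    k <- max(1L, floor(energyPercentile / 100 * n))
    sel <- rank(scores[[ec]], ties.method = "first") <= k
    keep <- keep & sel
    if (!any(keep)) binding <- c(binding, paste0("energy:", ec))
  }
  for (cc in names(chi2Cutoffs)) {
    cut <- chi2Cutoffs[[cc]] * min(scores[[cc]])
    sel <- scores[[cc]] <= cut
    keep <- keep & sel
    if (!any(keep)) binding <- c(binding, paste0("chi2:", cc))
  }
  if (!any(keep))
    stop("empty selection; binding constraint(s): ",
         paste(unique(binding), collapse = ", "))
  scores[keep, , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Full selection and population estimation
## ---------------------------------------------------------------------------

#' Run the pseudo-genetic ensemble selection
#'
#' Merges the candidate pools, precomputes per-conformer scattering curves
#' and the PRE r^-6 table, then performs \code{cfg$nRuns} independent
#' seeded runs of the pseudo-genetic algorithm: four parents are drawn
#' from the pools, 20 children are sub-sampled from the merged parents
#' (with a 30 percent duplicate-or-replace mutation per sub-sampling
#' event), all children are scored by the consensus PRE-SAS score
#' (min-max normalization maintained over every ensemble seen in the
#' run), and the best children seed the next iteration's parents
#' (elitism). The on-state population is estimated from the top
#' \code{cfg$topK} ensembles of each run.
#'
#' @param pools named list of \linkS4class{ConformerPool}s; conformer ids
#'   must be unique across pools.
#' @param sasData list of experimental \linkS4class{SASCurve}s.
#' @param schemes named list of \linkS4class{ContrastScheme}s, one per SAS
#'   dataset (matched by the curve's scheme name); ignored for datasets
#'   covered by \code{curveLib}.
#' @param preData PRE measurement table, or NULL to score on SAS only.
#' @param p a \linkS4class{RelaxationParams}.
#' @param cfg a \code{\link{scoringConfig}}.
#' @param curveLib optional precomputed per-conformer curve library (list
#'   over datasets of grid x conformer matrices), e.g. imported from an
#'   external atomic-detail calculator; computed with
#'   \code{\link{debyeIntensity}} when absent.
#' @param r6table optional precomputed \code{\link{preR6Table}} over the
#'   merged conformers for \code{preData}'s rows (recomputed when absent).
#' @param tags,tagMap,copyMap PRE back-calculation maps, see
#'   \code{\link{preR6Table}}.
#' @return list of class \code{"SelectionResult"}: \code{runs} (per run:
#'   ranked keys, members, raw chi2, scores, best-so-far trajectory),
#'   \code{topEnsembles} (list over runs of the top-k
#'   \linkS4class{Ensemble}s), \code{population} (the
#'   \code{\link{estimatePopulation}} output), \code{best} (overall best
#'   ensemble by raw summed chi2 among run winners) and
#'   \code{bestRawChi2} (its summed raw chi2).
#' @export
runSelection <- function(pools, sasData, schemes = NULL, preData = NULL,
                         p = relaxationParams(), cfg = scoringConfig(),
                         curveLib = NULL, tags = NULL, tagMap = NULL,
                         copyMap = NULL, r6table = NULL) {
  conformers <- do.call(c, lapply(pools, poolMembers))
  names(conformers) <- unlist(lapply(pools, function(pl)
    names(poolMembers(pl))))
  if (anyDuplicated(names(conformers)))
    stop("conformer ids must be unique across pools")
  if (length(conformers) < max(cfg$childSizeRange))
    stop("pool smaller than the maximum child size")
  if (is.null(curveLib)) {
    curveLib <- lapply(sasData, function(cur) {
      sch <- if (!is.null(schemes)) schemes[[cur@scheme]] else NULL
      vapply(conformers, debyeIntensity, numeric(length(cur@s)),
             scheme = sch, sGrid = cur@s)
    })
  }
  if (is.null(r6table) && !is.null(preData))
    r6table <- preR6Table(conformers, preData, tags = tags,
                          tagMap = tagMap, copyMap = copyMap)
  rawFun <- makeRawScorer(sasData, curveLib, preData, r6table, p)
  channels <- rawChannels(sasData, r6table)
  runs <- lapply(seq_len(cfg$nRuns), function(r) {
    run <- gaRun(names(conformers), rawFun, channels, cfg,
                 seed = cfg$seed + r - 1L)
    run$trajectory <- gaTrajectory(run, cfg$nIterations)
    run
  })
  topEnsembles <- lapply(runs, function(run)
    lapply(run$members[seq_len(min(cfg$topK, length(run$members)))],
           ensemble))
  stateTags <- vapply(conformers, stateTag, character(1))
  population <- estimatePopulation(topEnsembles, stateTags)
  winners <- lapply(runs, function(run) run$members[[1]])
  winnerChi2 <- vapply(winners, function(mm) sum(rawFun(mm)), numeric(1))
  bestRun <- which.min(winnerChi2)
  structure(list(runs = runs, topEnsembles = topEnsembles,
                 population = population,
                 best = ensemble(winners[[bestRun]]),
                 bestRawChi2 = winnerChi2[bestRun],
                 conformers = conformers, channels = channels),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("SelectionResult:", length(x$runs), "run(s)\n")
  cat(sprintf("  f_on = %.3f +/- %.3f (top-%d x %d runs)\n",
      x$population$fOn, x$population$sd,
      length(x$topEnsembles[[1]]), length(x$runs)))
  cat("  best ensemble:", paste(memberIds(x$best), collapse = " "), "\n")
  invisible(x)
}

#' Estimate the on-state population from top-scoring ensembles
#'
#' The on-state fraction of each ensemble is the multiplicity-weighted
#' fraction of members tagged \code{"on_off"}; the estimate is the mean
#' over the top-k ensembles of every run and the spread is their SD.
#'
#' @param topEnsembles list over runs of lists of \linkS4class{Ensemble}s
#'   (or a flat list of ensembles).
#' @param stateTags named character vector: conformer id -> state tag.
#' @return list of class \code{"PopulationEstimate"} with \code{fOn},
#'   \code{sd} and \code{perEnsemble} (data.frame of run, rank, fraction).
#' @export
estimatePopulation <- function(topEnsembles, stateTags) {
  if (length(topEnsembles) && is(topEnsembles[[1]], "Ensemble"))
    topEnsembles <- list(topEnsembles)
  rows <- list()
  for (r in seq_along(topEnsembles)) {
    for (k in seq_along(topEnsembles[[r]])) {
      ids <- memberIds(topEnsembles[[r]][[k]])
      tg <- stateTags[ids]
      if (any(is.na(tg)))
        stop("untagged ensemble member: ", ids[is.na(tg)][1])
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, rank = k, fOn = mean(tg == "on_off"))
    }
  }
  per <- do.call(rbind, rows)
  structure(list(fOn = mean(per$fOn),
                 sd = if (nrow(per) > 1L) stats::sd(per$fOn) else 0,
                 perEnsemble = per), class = "PopulationEstimate")
}

#' @export
print.PopulationEstimate <- function(x, ...) {
  cat(sprintf("PopulationEstimate: f_on = %.3f +/- %.3f (n = %d)\n",
              x$fOn, x$sd, nrow(x$perEnsemble)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Spin-label ensemble refinement
## ---------------------------------------------------------------------------

#' Refine spin-label ensembles against their own PRE datasets
#'
#' With the selected structural ensemble frozen (coordinates and member
#' populations untouched), the same pseudo-genetic engine selects, per
#' tag, a multiset of candidate spin-label conformations minimizing the
#' chi2 of that tag's PRE dataset alone. SAS scores are unaffected by
#' construction, since tags do not scatter.
#'
#' @param selected the frozen \linkS4class{Ensemble}.
#' @param conformers named list of \linkS4class{Conformer}s covering the
#'   ensemble.
#' @param tagPools named list: tag id -> k x 3 matrix of candidate N-O
#'   positions.
#' @param preData PRE table; rows with \code{tag_id} equal to (or mapped
#'   to) the tag being refined are used.
#' @param p a \linkS4class{RelaxationParams}.
#' @param cfg a \code{\link{scoringConfig}} (single run; \code{cfg$seed}
#'   seeds each tag's run, offset by its index).
#' @param tagMap,copyMap see \code{\link{preR6Table}}.
#' @return named list: tag id -> list with \code{ensemble} (the refined
#'   \linkS4class{SpinLabelEnsemble}), \code{chi2} (refined PRE chi2) and
#'   \code{initialChi2} (chi2 of the equal-weight full candidate pool).
#' @export
refineTags <- function(selected, conformers, tagPools, preData,
                       p = relaxationParams(), cfg = scoringConfig(),
                       tagMap = NULL, copyMap = NULL) {
  out <- list()
  for (ti in seq_along(tagPools)) {
    tg <- names(tagPools)[ti]
    pos <- as.matrix(tagPools[[tg]])
    if (nrow(pos) < 1L) stop("empty tag pool for ", tg)
    dsets <- unique(preData$tag_id)
    tm <- normTagMap(dsets, tagMap)
    useDs <- dsets[vapply(tm, function(v) tg %in% v, logical(1))]
    rows <- preData[preData$tag_id %in% useDs, , drop = FALSE]
    if (nrow(rows) == 0L) stop("no PRE rows for tag ", tg)
    posIds <- sprintf("p%05d", seq_len(nrow(pos)))
    chi2For <- function(posIdx) {
      sle <- spinLabelEnsemble(tg, pos[posIdx, , drop = FALSE])
      tab <- preR6Table(conformers[unique(memberIds(selected))], rows,
                        tags = setNames(list(sle), tg),
                        tagMap = tagMap, copyMap = copyMap)
      preChi2(predictRatios(selected, tab, rows, p), rows)
    }
    rawFun <- function(members)
      c(preChi2 = chi2For(match(members, posIds)))
    if (nrow(pos) == 1L) {
      sle <- spinLabelEnsemble(tg, pos)
      out[[tg]] <- list(ensemble = sle, chi2 = chi2For(1L),
                        initialChi2 = chi2For(1L))
      next
    }
    run <- gaRun(posIds, rawFun, list(sas = character(), pre = "preChi2"),
                 cfg, seed = cfg$seed + ti - 1L)
    bestIdx <- match(run$members[[1]], posIds)
    sle <- spinLabelEnsemble(tg, pos[bestIdx, , drop = FALSE])
    out[[tg]] <- list(ensemble = sle,
                      chi2 = run$raw[1, "preChi2"],
                      initialChi2 = chi2For(seq_len(nrow(pos))))
  }
  out
}
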
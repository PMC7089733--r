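## Conversion of PRE measurements into distance restraints with error
## floors, and the effective-distance violation metric.

#' Derive distance restraints from PRE measurements
#'
#' Each measurement with an observable attenuation (ratio below the
#' observability threshold) becomes a bounded distance restraint from the
#' tag nitroxide nitrogen to the methyl carbon(s): the central distance and
#' its bounds come from the ratio -> Gamma2 -> distance inversion chain
#' with the 10 percent ratio-error floor, the rate errors and the tauC
#' error, and a 2 Angstrom floor is imposed on both distance slacks to
#' account for tag flexibility. Measurements with ratio at or above the
#' threshold become lower-bound-only restraints at the detection-limit
#' distance. Stereo-unassigned methyls listed in \code{orGroups} are
#' restrained to all group members under an OR contract. In \code{"on_off"}
#' mode the lower slack is extended by 4 Angstrom to allow for two
#' overlapping copies of which only one feels the tag.
#'
#' @param measurements PRE table (columns \code{methyl_id}, \code{tag_id},
#'   \code{ratio}, \code{r2_dia_h}, \code{r2_dia_hc}, optional error
#'   columns).
#' @param p a \linkS4class{RelaxationParams} with calibrated tauC.
#' @param mode \code{"standard"} or \code{"on_off"}.
#' @param threshold observability threshold on the ratio (default 0.8).
#' @param detectionLimit distance assigned to absent PREs (Angstrom,
#'   default 25).
#' @param orGroups named list: methyl id -> character vector of
#'   OR-equivalent site ids (default: each methyl restrains itself only).
#' @param minSlack distance-error floor in Angstrom (default 2).
#' @param onOffExtra extra lower slack in on_off mode (Angstrom, default 4).
#' @return data.frame of restraints with columns \code{tag_id},
#'   \code{sites} (pipe-separated site ids), \code{distance},
#'   \code{lower_slack}, \code{upper_slack}, \code{type}
#'   (\code{"bounded"} or \code{"lower_only"}) and \code{mode}.
#' @export
deriveRestraints <- function(measurements, p, mode = c("standard", "on_off"),
                             threshold = 0.8, detectionLimit = 25,
                             orGroups = NULL, minSlack = 2, onOffExtra = 4) {
  mode <- match.arg(mode)
  rows <- list()
  for (i in seq_len(nrow(measurements))) {
    m <- measurements[i, ]
    if (is.na(m$ratio) || is.na(m$r2_dia_h) || is.na(m$r2_dia_hc)) {
      warning("skipping measurement ", m$methyl_id, "/", m$tag_id,
              ": missing ratio or rates")
      next
    }
    sites <- if (!is.null(orGroups) && m$methyl_id %in% names(orGroups))
      orGroups[[m$methyl_id]] else m$methyl_id
    if (m$ratio >= threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = m$tag_id, sites = paste(sites, collapse = "|"),
        distance = detectionLimit, lower_slack = 0, upper_slack = Inf,
        type = "lower_only", mode = mode)
      next
    }
    g <- gamma2FromRatio(m$ratio, m$r2_dia_h, m$r2_dia_hc, p,
                         ratioErr = colOr(measurements, "ratio_err", i),
                         r2DiaHErr = colOr(measurements, "r2_dia_h_err", i),
                         r2DiaHCErr = colOr(measurements, "r2_dia_hc_err", i))
    d <- distanceFromGamma2(g, p)
    lower <- max(d$value - d$lower, minSlack)
    upper <- max(d$upper - d$value, minSlack)
    if (mode == "on_off") lower <- lower + onOffExtra
    rows[[length(rows) + 1L]] <- data.frame(
      tag_id = m$tag_id, sites = paste(sites, collapse = "|"),
      distance = d$value, lower_slack = lower, upper_slack = upper,
      type = "bounded", mode = mode)
  }
  if (length(rows) == 0L)
    return(data.frame(tag_id = character(), sites = character(),
                      distance = numeric(), lower_slack = numeric(),
                      upper_slack = numeric(), type = character(),
                      mode = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective tag-to-group distance in a conformer
#'
#' (sum r^-6)^(-1/6) over the OR-group members and (weighted) spin-label
#' conformations, matching the physics under which the restraint was
#' derived.
#'
#' @param conf a \linkS4class{Conformer}.
#' @param tagId tag identifier (resolved in the conformer's tag sites or in
#'   \code{tags}).
#' @param sites character vector of methyl site ids (the OR group).
#' @param tags optional named list of \linkS4class{SpinLabelEnsemble}s.
#' @return effective distance in Angstrom.
#' @export
effectiveDistance <- function(conf, tagId, sites, tags = NULL) {
  r6 <- r6TagGroup(conf, tagId, sites, tags)
  r6^(-1 / 6)
}

#' Violation of a restraint by a conformer
#'
#' Positive excess of the effective tag-group distance outside the band
#' [distance - lower_slack, distance + upper_slack]; 0 when satisfied.
#' Lower-bound-only restraints are violated only from below.
#'
#' @param restraint a single-row restraint data.frame (see
#'   \code{\link{deriveRestraints}}).
#' @param conf a \linkS4class{Conformer}.
#' @param tags optional named list of \linkS4class{SpinLabelEnsemble}s.
#' @return violation in Angstrom (>= 0).
#' @export
restraintViolation <- function(restraint, conf, tags = NULL) {
  sites <- strsplit(restraint$sites, "|", fixed = TRUE)[[1]]
  d <- effectiveDistance(conf, restraint$tag_id, sites, tags)
  lo <- restraint$distance - restraint$lower_slack
  hi <- if (restraint$type == "lower_only") Inf
        else restraint$distance + restraint$upper_slack
  if (d < lo) lo - d else if (d > hi) d - hi else 0
}
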
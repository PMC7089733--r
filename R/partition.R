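## Iterative partitioning of PRE restraints into state-compatible lists
## using per-state structure pools and a violation threshold.

#' Partition restraints between conformational states
#'
#' Starting with the full restraint set assigned to every state, each
#' iteration evaluates, per state, the violation of every retained
#' restraint across that state's structures. A restraint whose violation
#' statistic exceeds \code{threshold} is eliminated from that state's list
#' only, and kept in the other state(s). The loop runs for
#' \code{nIterations} or until a fixed point. With the default
#' \code{rule = "all"} a restraint counts as violated when its minimum
#' violation over the state's structures exceeds the threshold (i.e. it is
#' violated in every structure -- the conservative reading);
#' \code{rule = "mean"} uses the mean violation instead.
#'
#' @param restraints restraint data.frame (see
#'   \code{\link{deriveRestraints}}).
#' @param structuresByState named list: state -> \linkS4class{ConformerPool}.
#' @param threshold violation threshold in Angstrom (default 10).
#' @param nIterations maximum iterations (default 5).
#' @param rule \code{"all"} (minimum over structures) or \code{"mean"}.
#' @param tags optional named list of \linkS4class{SpinLabelEnsemble}s.
#' @return list of class \code{"PartitionState"} with
#'   \code{restraintsByState} (named list of data.frames),
#'   \code{iterations} (number actually run) and \code{removed} (log
#'   data.frame with restraint row, state, iteration and the violation
#'   statistic in Angstrom).
#' @export
partitionRestraints <- function(restraints, structuresByState, threshold = 10,
                                nIterations = 5L, rule = c("all", "mean"),
                                tags = NULL) {
  rule <- match.arg(rule)
  if (length(structuresByState) < 1L) stop("no structure pools supplied")
  empty <- vapply(structuresByState, poolSize, integer(1)) < 1L
  if (any(empty))
    stop("empty pool for state: ", names(structuresByState)[empty][1])
  states <- names(structuresByState)
  keep <- lapply(states, function(s) seq_len(nrow(restraints)))
  names(keep) <- states
  removedLog <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    for (s in states) {
      pool <- poolMembers(structuresByState[[s]])
      drop <- integer()
      for (ri in keep[[s]]) {
        v <- vapply(pool, function(cf)
          restraintViolation(restraints[ri, ], cf, tags), numeric(1))
        stat <- if (rule == "all") min(v) else mean(v)
        if (stat > threshold) {
          drop <- c(drop, ri)
          removedLog[[length(removedLog) + 1L]] <- data.frame(
            restraint = ri, state = s, iteration = iter, violation = stat)
        }
      }
      if (length(drop)) {
        keep[[s]] <- setdiff(keep[[s]], drop)
        changed <- TRUE
      }
    }
    if (!changed || iter >= nIterations) break
  }
  removed <- if (length(removedLog)) do.call(rbind, removedLog)
             else data.frame(restraint = integer(), state = character(),
                             iteration = integer(), violation = numeric())
  structure(list(
    restraintsByState = lapply(keep, function(idx)
      restraints[idx, , drop = FALSE]),
    iterations = iter, removed = removed), class = "PartitionState")
}

#' @export
print.PartitionState <- function(x, ...) {
  cat("PartitionState after", x$iterations, "iteration(s):\n")
  for (s in names(x$restraintsByState))
    cat("  ", s, ":", nrow(x$restraintsByState[[s]]), "restraints\n")
  cat("  removed:", nrow(x$removed), "\n")
  invisible(x)
}
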
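# Shared fixtures, built once per test run and cached. The toy complex is
# the study system: a rigid core, a statically detached second catalytic
# copy and one mobile catalytic module at a known on-state fraction.

toyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- toySpec(seed = 7, fOn = 0.66)
      toy <- makeToyComplex(spec)
      allConf <- c(poolMembers(toy$onPool), poolMembers(toy$offPool))
      w <- trueMixtureWeights(toy)
      sim0 <- simulateDatasets(allConf, w, toy$schemes, seed = 1,
                               sasFrac = 0, preSigma = 0)
      curveLib <- buildCurveLibrary(allConf, sim0$sasData, toy$schemes)
      r6 <- preR6Table(allConf, sim0$preData)
      cache <<- list(spec = spec, toy = toy, allConf = allConf,
                     weights = w, sim0 = sim0, curveLib = curveLib,
                     r6 = r6,
                     onIds = names(poolMembers(toy$onPool)),
                     offIds = names(poolMembers(toy$offPool)))
    }
    cache
  }
})

# a small deterministic two-subunit conformer for unit tests
miniConformer <- function() {
  coords <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                  c(30, 0, 0), c(30, 10, 0))
  conformer(coords, c("A", "A", "A", "B", "B"), stateTag = "other",
            mobileSubunits = "B",
            methylSites = matrix(c(30, 0, 0, 30, 10, 0), 2, 3,
                                 byrow = TRUE,
                                 dimnames = list(c("m1", "m2"), NULL)),
            tagSites = list(t1 = matrix(c(0, 0, 0), 1, 3)))
}

# uniform point cloud in a sphere
sphereCloud <- function(n, radius, seed = 1) {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) { k <- k + 1; pts[k, ] <- p * radius }
  }
  pts
}

# all multisets of size k over ids (lexicographic)
allMultisets <- function(ids, k) {
  combs <- utils::combn(length(ids) + k - 1, k)
  lapply(seq_len(ncol(combs)), function(j) ids[combs[, j] - seq_len(k) + 1])
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
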
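# Iterative state-partitioning of restraints with the violation threshold.

# two single-structure states built from the mini conformer: state "near"
# keeps the mobile module close to the tag, state "far" moves it away
makeStates <- function() {
  near <- miniConformer()
  farCoords <- coords(near)
  sel <- subunitIds(near) == "B"
  farCoords[sel, 1] <- farCoords[sel, 1] + 40
  far <- conformer(farCoords, subunitIds(near),
                   methylSites = methylSites(near) +
                     matrix(rep(c(40, 0, 0), each = 2), 2, 3),
                   tagSites = tagSites(near))
  list(near = conformerPool(list(n1 = near)),
       far = conformerPool(list(f1 = far)))
}

test_that("restraints violated in one state are removed from it only", {
  states <- makeStates()
  restraints <- data.frame(
    tag_id = "t1",
    sites = c("m1", "m1"),
    distance = c(30, 65),       # 30: near-only; 65: satisfied in far only
    lower_slack = c(2, 6), upper_slack = c(2, 6),
    type = "bounded", mode = "standard")
  ps <- partitionRestraints(restraints, states, threshold = 10,
                            nIterations = 5)
  expect_equal(nrow(ps$restraintsByState$near), 1L)
  expect_equal(nrow(ps$restraintsByState$far), 1L)
  expect_equal(ps$restraintsByState$near$distance, 30)
  expect_equal(ps$restraintsByState$far$distance, 65)
  # a restraint satisfied everywhere stays everywhere
  ok <- data.frame(tag_id = "t1", sites = "m1", distance = 50,
                   lower_slack = 25, upper_slack = 25,
                   type = "bounded", mode = "standard")
  ps2 <- partitionRestraints(ok, states)
  expect_equal(nrow(ps2$restraintsByState$near), 1L)
  expect_equal(nrow(ps2$restraintsByState$far), 1L)
})

test_that("partitioning recovers planted on-only restraints", {
  fx <- toyFixture()
  onPool <- fx$toy$onPool
  # an off pool whose module stays well clear of the duplex site, so the
  # two states are geometrically separated
  offPool <- randomizeMobileSubunits(fx$toy$template,
    anchor = fx$spec$anchor, tetherLength = 40, n = 15, seed = 99,
    stateTag = "off_off",
    siteSubunit = setNames(rep("fib", nrow(methylSites(fx$toy$template))),
                           rownames(methylSites(fx$toy$template))),
    excludeCenter = fx$spec$onSite, excludeRadius = 30)
  # restraints planted from on-state geometry: a label on the substrate
  # duplex site sees the module methyls only in the on state
  duplexTag <- list(tagD = spinLabelEnsemble("tagD",
                                             matrix(fx$spec$onSite, 1, 3)))
  onConf <- poolMembers(onPool)[[1]]
  ms <- rownames(methylSites(onConf))[1:8]
  dOn <- vapply(ms, function(m)
    effectiveDistance(onConf, "tagD", m, tags = duplexTag), numeric(1))
  planted <- data.frame(tag_id = "tagD", sites = ms, distance = dOn,
                        lower_slack = 2, upper_slack = 2,
                        type = "bounded", mode = "standard")
  # plus broad restraints satisfied in both states
  broad <- data.frame(tag_id = "tagD", sites = ms, distance = 40,
                      lower_slack = 40, upper_slack = 60,
                      type = "bounded", mode = "standard")
  restraints <- rbind(planted, broad)
  ps <- partitionRestraints(restraints, list(on = onPool, off = offPool),
                            threshold = 10, nIterations = 5,
                            tags = duplexTag)
  # brute-force oracle: minimum violation across each state's structures
  minViol <- function(pool) vapply(seq_len(8), function(i)
    min(vapply(poolMembers(pool), function(cf)
      restraintViolation(planted[i, ], cf, tags = duplexTag),
      numeric(1))), numeric(1))
  expect_true(all(minViol(offPool) > 10))   # planted are genuinely on-only
  expect_true(all(minViol(onPool) <= 10))
  # every planted restraint removed from 'off', retained in 'on'
  removedOff <- ps$removed$restraint[ps$removed$state == "off"]
  expect_setequal(removedOff, seq_len(8))
  expect_equal(nrow(ps$restraintsByState$on), 16L)
  expect_equal(nrow(ps$restraintsByState$off), 8L)
  # broad restraints retained in both lists
  expect_true(all(ps$restraintsByState$off$distance == 40))
  # idempotence at the fixed point
  again <- partitionRestraints(ps$restraintsByState$off,
                               list(off = offPool), tags = duplexTag)
  expect_equal(nrow(again$removed), 0L)
})

test_that("partitioning is idempotent and monotone", {
  states <- makeStates()
  restraints <- data.frame(tag_id = "t1", sites = "m1",
                           distance = c(30, 65, 50),
                           lower_slack = c(2, 6, 25),
                           upper_slack = c(2, 6, 25),
                           type = "bounded", mode = "standard")
  ps <- partitionRestraints(restraints, states)
  # re-running on each state's own output changes nothing
  for (s in names(ps$restraintsByState)) {
    again <- partitionRestraints(ps$restraintsByState[[s]],
                                 states[s])
    expect_equal(nrow(again$restraintsByState[[s]]),
                 nrow(ps$restraintsByState[[s]]))
    expect_equal(nrow(again$removed), 0L)
  }
  # with an infinite threshold nothing is removed
  psInf <- partitionRestraints(restraints, states, threshold = Inf)
  expect_equal(nrow(psInf$removed), 0L)
  expect_equal(vapply(psInf$restraintsByState, nrow, integer(1)),
               c(near = 3L, far = 3L))
  # union of the state lists covers the input set
  kept <- unique(unlist(lapply(ps$restraintsByState,
                               function(df) df$distance)))
  expect_setequal(kept, restraints$distance)
})

test_that("mean rule is laxer than the all-structures rule", {
  fx <- toyFixture()
  onConf <- poolMembers(fx$toy$onPool)[[1]]
  m <- rownames(methylSites(onConf))[1]
  r <- data.frame(tag_id = "tagA", sites = m,
                  distance = effectiveDistance(onConf, "tagA", m),
                  lower_slack = 2, upper_slack = 2,
                  type = "bounded", mode = "standard")
  pools <- list(off = fx$toy$offPool)
  psAll <- partitionRestraints(r, pools, rule = "all")
  psMean <- partitionRestraints(r, pools, rule = "mean")
  # mean violation >= min violation, so the mean rule removes at least as much
  expect_gte(nrow(psAll$restraintsByState$off),
             nrow(psMean$restraintsByState$off))
  expect_error(partitionRestraints(r, list(off = conformerPool(list()))),
               "empty pool")
})
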
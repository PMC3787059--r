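test_that("simulation is deterministic given the config and leaves the RNG alone", {
  cfg <- simConfig(nNeurons = 6, nTrials = 6, trialDuration = 5, seed = 42)
  set.seed(999)
  before <- .Random.seed
  a <- simulateSession(cfg)
  expect_identical(.Random.seed, before)
  b <- simulateSession(cfg)
  expect_identical(spikeTimes(a$dataset), spikeTimes(b$dataset))
  expect_identical(trialTable(a$dataset), trialTable(b$dataset))
  # a different seed actually changes the spikes
  c <- simulateSession(simConfig(nNeurons = 6, nTrials = 6,
                                 trialDuration = 5, seed = 43))
  expect_false(identical(spikeTimes(a$dataset), spikeTimes(c$dataset)))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(simConfig(nNeurons = 1), "nNeurons")
  expect_error(simConfig(trialDuration = 0), "trialDuration")
  expect_error(simConfig(nTrials = 1), "nTrials")
  expect_error(simConfig(baseRate = -1), "baseRate")
  expect_error(simConfig(labels = c("A", "A")), "labels")
  expect_error(simConfig(moduleMaps = list(A = rep(1L, 3), B = rep(1L, 3)),
                         nNeurons = 12), "moduleMaps")
  expect_error(simConfig(eventDuration = 0.015, subBinWidth = 0.01),
               "eventDuration")
})

test_that("spike times respect trial windows and strict ordering", {
  cfg <- simConfig(nNeurons = 6, nTrials = 8, trialDuration = 5, seed = 11)
  ds <- simulateSession(cfg)$dataset
  tr <- trialTable(ds)
  expect_true(all(tr$end_s > tr$start_s))
  expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
  for (s in spikeTimes(ds)) {
    if (length(s) > 1) expect_true(all(diff(s) > 0))
    inTrial <- vapply(s, function(t) any(t >= tr$start_s & t < tr$end_s),
                      logical(1))
    expect_true(all(inTrial))
  }
})

test_that("zero common gain gives uncorrelated bin counts", {
  cfg <- simConfig(nNeurons = 8, nTrials = 60, trialDuration = 10,
                   commonGain = 0, seed = 7)
  ds <- simulateSession(cfg)$dataset
  tr <- trialTable(ds)
  rs <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    cc <- binCounts(segmentTrial(ds, i), tr$start_s[i], tr$end_s[i], 1)
    R <- suppressWarnings(stats::cor(t(cc)))
    R[upper.tri(R)]
  }))
  rs <- rs[is.finite(rs)]
  expect_lt(abs(mean(rs)), 0.03)
  expect_equal(expectedCorrelationContrast(simConfig(commonGain = 0)), 0)
})

withinBetweenMeans <- function(cfg, null = FALSE) {
  sess <- if (null) makeNullSession(cfg) else simulateSession(cfg)
  ds <- sess$dataset
  tr <- trialTable(ds)
  w <- c(); b <- c()
  for (i in seq_len(nrow(tr))) {
    mods <- sess$truth@moduleMaps[[tr$label[i]]]
    cc <- binCounts(segmentTrial(ds, i), tr$start_s[i], tr$end_s[i], 1)
    R <- suppressWarnings(stats::cor(t(cc)))
    same <- outer(mods, mods, "==")
    up <- upper.tri(R)
    w <- c(w, R[up & same]); b <- c(b, R[up & !same])
  }
  c(within = mean(w, na.rm = TRUE), between = mean(b, na.rm = TRUE))
}

test_that("within-module correlation exceeds between-module by a clear margin", {
  # Monte-Carlo analog of the generator's design contrast: 12 neurons,
  # 200 trials of 10 s, two 6-neuron modules, gain 4.
  cfg <- simConfig(nNeurons = 12, nTrials = 200, trialDuration = 10,
                   commonGain = 4,
                   moduleMaps = list(A = rep(1:2, each = 6),
                                     B = rep(1:2, each = 6)),
                   seed = 21)
  m <- withinBetweenMeans(cfg)
  expect_gt(m["within"] - m["between"], 0.2)
  # empirical within-correlation tracks the analytic expectation
  expect_lt(abs(m["within"] - expectedCorrelationContrast(cfg)), 0.08)
})

test_that("the correlation contrast is monotone in the common gain", {
  margins <- vapply(c(0, 1, 2, 4), function(g) {
    cfg <- simConfig(nNeurons = 8, nTrials = 100, trialDuration = 10,
                     commonGain = g,
                     moduleMaps = list(A = rep(1:2, each = 4),
                                       B = rep(1:2, each = 4)),
                     seed = 31)
    m <- withinBetweenMeans(cfg)
    m["within"] - m["between"]
  }, numeric(1))
  expect_true(all(diff(margins) >= 0))
})

test_that("null sessions share one module map and alternate labels", {
  cfg <- simConfig(nNeurons = 6, nTrials = 4, trialDuration = 5, seed = 3)
  sess <- makeNullSession(cfg)
  expect_true(sess$truth@isNull)
  expect_identical(sess$truth@moduleMaps[[1]], sess$truth@moduleMaps[[2]])
  expect_identical(trialLabels(sess$dataset), c("A", "B", "A", "B"))
})

test_that("null-session networks are label-exchangeable", {
  # Permutation test on the mean-network difference: across seeds, the
  # observed between-label distance should not be extreme (alpha = 0.01).
  pvals <- vapply(1:8, function(seed) {
    cfg <- simConfig(nNeurons = 6, nTrials = 30, trialDuration = 8,
                     seed = seed)
    sess <- makeNullSession(cfg)
    nets <- networkList(buildNetworks(sess$dataset))
    labs <- trialLabels(sess$dataset)
    statFor <- function(l) {
      mA <- Reduce(`+`, nets[l == "A"]) / sum(l == "A")
      mB <- Reduce(`+`, nets[l == "B"]) / sum(l == "B")
      sqrt(sum((mA - mB)^2))
    }
    obs <- statFor(labs)
    set.seed(seed + 1000)
    perm <- vapply(1:200, function(i) statFor(sample(labs)), numeric(1))
    mean(perm >= obs)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})
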
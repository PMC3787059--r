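test_that("pattern matching picks the group with the larger mean similarity", {
  labs <- c("g1", "g1", "g2", "g2")
  # means 0.5 vs 0.6 -> g2
  expect_equal(matchPredict(c(0.9, 0.1, 0.6, 0.6), labs), "g2")
  # identical to every g1 trial, dissimilar to g2 -> g1
  expect_equal(matchPredict(c(1, 1, 0.1, 0.2), labs), "g1")
  # exact tie with equal group sizes -> group 1 (first sorted label)
  expect_equal(matchPredict(c(0.5, 0.5, 0.5, 0.5), labs), "g1")
  # exact tie with unequal group sizes -> larger group
  expect_equal(matchPredict(c(0.5, 0.5, 0.5, 0.5, 0.5),
                            c("g1", "g1", "g2", "g2", "g2")), "g2")
  expect_error(matchPredict(c(0.5, 0.5), c("g1", "g1")),
               class = "validationError")
})

test_that("KNN takes the k most similar trials with stable tie handling", {
  labs <- rep(c("g1", "g2"), each = 5)
  sims <- c(0.9, 0.2, 0.2, 0.2, 0.2, 0.95, 0.1, 0.1, 0.1, 0.1)
  expect_equal(knnPredict(sims, labs, k = 1), "g2")   # single nearest
  # k = 7: neighbors are the top-7 similarities -> 4 of g1, 3 of g2
  sims <- c(0.9, 0.8, 0.7, 0.6, 0.1, 0.85, 0.75, 0.65, 0.05, 0.02)
  expect_equal(knnPredict(sims, labs, k = 7), "g1")
  # fewer training trials than k: all 5 are used, so the overall majority wins
  expect_equal(knnPredict(c(0.9, 0.8, 0.1, 0.3, 0.2),
                          c("g2", "g2", "g1", "g1", "g1"), k = 7), "g1")
  expect_equal(knnPredict(c(0.9, 0.8, 0.1, 0.3, 0.2),
                          c("g2", "g2", "g1", "g1", "g1"), k = 7),
               knnPredict(c(0.9, 0.8, 0.1, 0.3, 0.2),
                          c("g2", "g2", "g1", "g1", "g1"), k = 5))
  # similarity ties resolve toward the lower trial index
  expect_equal(knnPredict(c(0.5, 0.5, 0.5, 0.9, 0.1),
                          c("g1", "g1", "g2", "g2", "g2"), k = 3), "g1")
  # an even neighbor split falls back to the matching rule
  expect_equal(knnPredict(c(1, 0, 1, 0), c("g1", "g1", "g2", "g2"), k = 2),
               "g1")
})

test_that("the two-class score sums per-label correct fractions", {
  expect_equal(jaccardCoefficient(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.75)
  expect_equal(jaccardCoefficient(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(jaccardCoefficient(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_error(jaccardCoefficient(1:3, 1:4), class = "validationError")
  # complement property: flipping every prediction flips the score
  set.seed(19)
  for (rep in 1:10) {
    t <- sample(1:2, 12, replace = TRUE)
    p <- sample(1:2, 12, replace = TRUE)
    expect_equal(jaccardCoefficient(t, p) + jaccardCoefficient(t, 3 - p), 1)
  }
})

test_that("LOO decoding is perfect on separated clusters and blind to S[i,i]", {
  # two well-separated groups of trial networks
  mk <- function(v) { R <- matrix(0, 4, 4); R[1, 2] <- R[2, 1] <- v; R }
  nets <- c(lapply(rep(0.9, 5), mk), lapply(rep(0.1, 5), mk))
  ns <- new("TrialNetworkSet", networks = nets,
            trialIds = sprintf("t%02d", 1:10),
            labels = rep(c("L", "R"), each = 5),
            binWidth = 1, representation = "wnfn")
  for (cl in c("knn", "match")) {
    rep_ <- looEvaluate(ns, classifier = cl, k = 3)
    expect_equal(jaccardValue(rep_), 1)
    expect_true(all(predictionTable(rep_)$correct))
  }

  # leakage check: the held-out trial's self-similarity must not matter
  sim <- trialSimilarity(ns, sigma = 4)
  S <- similarityMatrix(sim)
  base <- looEvaluate(S, labels = trialLabels(ns), classifier = "knn", k = 3)
  S2 <- S
  diag(S2) <- 0.123
  mod <- looEvaluate(S2, labels = trialLabels(ns), classifier = "knn", k = 3)
  expect_identical(predictionTable(base)$predicted,
                   predictionTable(mod)$predicted)
})

test_that("identical trials expose the deterministic LOO tie pathology", {
  # All-identical matrices carry no information; under the documented tie
  # rule (tie -> larger training group) the held-out trial's own group is
  # always one trainer short, so matching predicts the opposite class for
  # every trial: the worst case of leave-one-out on uninformative data.
  R <- matrix(0, 3, 3); R[1, 2] <- R[2, 1] <- 0.5
  nets <- lapply(1:8, function(i) R)
  ns <- new("TrialNetworkSet", networks = nets,
            trialIds = sprintf("t%02d", 1:8),
            labels = rep(c("L", "R"), 4), binWidth = 1,
            representation = "wnfn")
  rep_ <- looEvaluate(ns, classifier = "match")
  expect_equal(jaccardValue(rep_), 0)
  # k covering the whole training set reduces KNN to the same majority rule
  rep2 <- looEvaluate(ns, classifier = "knn", k = 7)
  expect_equal(jaccardValue(rep2), 0)
})

test_that("LOO decoding validates its inputs", {
  R <- matrix(0, 3, 3)
  ns <- new("TrialNetworkSet", networks = lapply(1:4, function(i) R),
            trialIds = sprintf("t%02d", 1:4),
            labels = c("L", "L", "L", "R"), binWidth = 1,
            representation = "wnfn")
  expect_error(looEvaluate(ns, labels = rep("L", 4)), "2 label",
               class = "validationError")
  expect_error(looEvaluate(similarityMatrix(trialSimilarity(ns))),
               "labels", class = "validationError")
})

test_that("decoding succeeds on structured sessions and stays at chance on null", {
  scores <- vapply(1:3, function(seed)
    sessionScore(simConfig(nNeurons = 12, nTrials = 40, trialDuration = 10,
                           seed = seed)),
    numeric(1))
  expect_gte(median(scores), 0.9)

  nullScores <- vapply(1:5, function(seed)
    sessionScore(simConfig(nNeurons = 8, nTrials = 40, trialDuration = 10,
                           seed = 100 + seed), null = TRUE),
    numeric(1))
  # binomial 95% band around 0.5 for 5 x 40 LOO predictions
  expect_lt(abs(mean(nullScores) - 0.5), 0.1)
})

test_that("unsupervised clustering accuracy tracks decoding accuracy across effect sizes", {
  # sweep the shared-input gain; both metrics should rise together
  res <- do.call(rbind, lapply(c(0, 1, 2, 4), function(g) {
    t(vapply(1:3, function(seed) {
      cfg <- simConfig(nNeurons = 12, nTrials = 30, trialDuration = 10,
                       commonGain = g, seed = 200 + seed)
      sess <- simulateSession(cfg)
      nets <- buildNetworks(sess$dataset)
      sim <- trialSimilarity(nets, sigma = 4)
      truth <- trialLabels(sess$dataset)
      c(gain = g,
        ncut = ncutCluster(sim, truth = truth)@alignedAccuracy,
        knn = jaccardValue(looEvaluate(sim, labels = truth,
                                       classifier = "knn", k = 7)))
    }, numeric(3)))
  }))
  expect_gt(cor(res[, "gain"], res[, "ncut"], method = "spearman"), 0.6)
  expect_gt(cor(res[, "gain"], res[, "knn"], method = "spearman"), 0.6)
  expect_gt(cor(res[, "ncut"], res[, "knn"], method = "spearman"), 0.6)
})
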
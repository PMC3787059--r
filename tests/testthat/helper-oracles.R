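## Independent oracles and small fixture builders used across the suite.
## These deliberately use naive, loop-based formulations so they stay
## independent of the package's vectorized implementations.

## Naive two-pass Pearson network: explicit mean/centering loops.
naiveNetwork <- function(counts) {
  n <- nrow(counts)
  R <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- counts[i, ]; y <- counts[j, ]
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sxy <- sum((x - mx) * (y - my))
    sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
    r <- if (sxx == 0 || syy == 0) 0 else sxy / sqrt(sxx * syy)
    R[i, j] <- max(0, r)
  }
  R
}

## Exhaustive modularity: term-by-term double loop over ordered pairs.
bruteModularity <- function(R, memb) {
  n <- nrow(R)
  twoL <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) twoL <- twoL + R[i, j]
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(R[i, ])
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j]) q <- q + R[i, j] - k[i] * k[j] / twoL
  q / twoL
}

## All set partitions of n items as restricted-growth strings.
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    i <- length(prefix) + 1
    if (i > n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (g in seq_len(maxUsed + 1))
      rec(c(prefix, g), max(maxUsed, g))
  }
  rec(integer(0), 0L)
  out
}

## Exhaustive modularity maximum over all partitions (n <= 8).
bruteBestPartition <- function(R) {
  parts <- allPartitions(nrow(R))
  qs <- vapply(parts, function(p) bruteModularity(R, p), numeric(1))
  list(Q = max(qs), membership = parts[[which.max(qs)]])
}

## Exhaustive minimal-Ncut bipartition (k <= 12 trials).
bruteNcut <- function(S) {
  k <- nrow(S)
  d <- rowSums(S)
  best <- NULL; bestVal <- Inf
  for (code in 0:(2^(k - 1) - 2)) {        # trial 1 fixed on side A, side B non-empty
    A <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(k - 2)))))
    cut <- sum(S[A, !A])
    val <- cut / sum(d[A]) + cut / sum(d[!A])
    if (val < bestVal) { bestVal <- val; best <- A }
  }
  list(value = bestVal, split = ifelse(best, 1L, 2L))
}

## Random symmetric weight matrix in [0,1], zero diagonal.
randomWeightMatrix <- function(n, density = 0.6) {
  R <- matrix(0, n, n)
  up <- upper.tri(R)
  w <- stats::runif(sum(up))
  w[stats::runif(sum(up)) > density] <- 0
  R[up] <- w
  R <- R + t(R)
  dimnames(R) <- list(paste0("v", 1:n), paste0("v", 1:n))
  R
}

## Two planted modules with strong intra / weak-or-absent inter weights.
plantedGraph <- function(sizes, pIntra = 1, wIntra = c(0.7, 1),
                         wInter = c(0, 0.15)) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  R <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    w <- if (block[i] == block[j]) stats::runif(1, wIntra[1], wIntra[2])
         else if (stats::runif(1) < 0.5) stats::runif(1, wInter[1], wInter[2])
         else 0
    R[i, j] <- R[j, i] <- w
  }
  dimnames(R) <- list(paste0("v", 1:n), paste0("v", 1:n))
  list(R = R, block = block)
}

## Unit-weight triangle graph helper: adds a clique over `idx` to R.
addClique <- function(R, idx, w = 1) {
  for (a in idx) for (b in idx) if (a != b) R[a, b] <- w
  R
}

## Two disjoint unit triangles (6 nodes), optionally plus isolated nodes.
twoTriangles <- function(extraIsolated = 0) {
  n <- 6 + extraIsolated
  R <- matrix(0, n, n, dimnames = rep(list(paste0("v", 1:n)), 2))
  R <- addClique(R, 1:3)
  addClique(R, 4:6)
}

## Block-structured trial similarity matrix: within = 1, between = eps.
blockSimilarity <- function(sizes, eps = 1e-3) {
  block <- rep(seq_along(sizes), sizes)
  S <- ifelse(outer(block, block, "=="), 1, eps)
  diag(S) <- 1
  list(S = S, block = block)
}

## Tiny valid SpikeDataset for IO tests.
tinySession <- function() {
  new("SpikeDataset",
      neurons = c("a", "b"),
      spikes = list(a = c(0.5, 1.5, 2.5), b = c(0.25, 1.75)),
      trials = data.frame(trial_id = c("t1", "t2"),
                          start_s = c(0, 2), end_s = c(2, 4),
                          label = c("L", "R"), stringsAsFactors = FALSE))
}

## Per-seed LOO KNN score on a simulated session (the acceptance analog).
sessionScore <- function(cfg, null = FALSE, k = 7, sigma = 4) {
  sess <- if (null) makeNullSession(cfg) else simulateSession(cfg)
  nets <- buildNetworks(sess$dataset, binWidth = 1)
  jaccardValue(looEvaluate(nets, classifier = "knn", k = k, sigma = sigma))
}
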
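#' Gaussian-kernel similarity of two trial networks
#'
#' \eqn{s = \exp(-d^2 / (2\sigma^2))} with \eqn{d} the Frobenius norm of the
#' matrix difference taken over the upper triangle (each unordered neuron
#' pair counted once).
#'
#' @param Ri,Rj conformable symmetric weight matrices.
#' @param sigma kernel scale (> 0; default 4).
#' @return similarity in (0, 1].
#' @examples
#' kernelSimilarity(diag(0, 3), diag(0, 3))  # 1
#' @export
kernelSimilarity <- function(Ri, Rj, sigma = 4) {
  if (!all(dim(Ri) == dim(Rj)))
    validationError("trial matrices must have identical dimensions")
  if (sigma <= 0) validationError("sigma must be > 0")
  d2 <- sum(((Ri - Rj)[upper.tri(Ri)])^2)
  exp(-d2 / (2 * sigma^2))
}

#' Trial-by-trial similarity matrix of a session
#'
#' Applies [kernelSimilarity()] to every pair of trial networks.
#'
#' @param netset a [TrialNetworkSet-class].
#' @param sigma Gaussian kernel scale (default 4).
#' @return a [TrialSimilarity-class].
#' @export
trialSimilarity <- function(netset, sigma = 4) {
  if (sigma <= 0) validationError("sigma must be > 0")
  nets <- networkList(netset)
  up <- upper.tri(nets[[1]])
  flat <- t(vapply(nets, function(R) R[up], numeric(sum(up))))
  d2 <- as.matrix(stats::dist(flat))^2
  S <- exp(-d2 / (2 * sigma^2))
  diag(S) <- 1
  dimnames(S) <- NULL
  new("TrialSimilarity", S = S, sigma = sigma,
      representation = netset@representation, trialIds = trialIds(netset))
}

asSimilarity <- function(S) {
  if (is(S, "TrialSimilarity")) similarityMatrix(S)
  else if (is.matrix(S)) S
  else validationError("expected a TrialSimilarity or a similarity matrix")
}

## Canonicalize two-way labels so cluster 1 contains the first trial.
canonTwoWay <- function(lab) {
  lab <- as.integer(lab)
  if (lab[1] == 2L) lab <- 3L - lab
  lab
}

#' NJW spectral clustering of trials into two groups
#'
#' Ng-Jordan-Weiss: form the normalized affinity
#' \eqn{L = D^{-1/2} S D^{-1/2}} (D = diagonal of row sums), take the two
#' eigenvectors of the largest eigenvalues, normalize the rows of the
#' resulting k x 2 matrix to unit length and run k-means with k = 2.
#'
#' @param S a [TrialSimilarity-class] or similarity matrix (>= 4 trials).
#' @param nstart k-means restarts (default 10).
#' @param seed RNG seed for k-means (the caller's RNG state is untouched).
#' @param truth optional true labels; when given, the aligned accuracy (best
#'   of the two label permutations) is filled in.
#' @return a [ClusterResult-class]; cluster ids are canonicalized so trial 1
#'   is in cluster 1.
#' @export
njwCluster <- function(S, nstart = 10, seed = 1, truth = NULL) {
  ids <- if (is(S, "TrialSimilarity")) trialIds(S) else NULL
  S <- asSimilarity(S)
  k <- nrow(S)
  if (k < 4) validationError("at least 4 trials are required")
  d <- rowSums(S)
  L <- S / sqrt(outer(d, d))
  V <- eigen(L, symmetric = TRUE)$vectors[, 1:2, drop = FALSE]
  rn <- sqrt(rowSums(V^2))
  rn[rn == 0] <- 1
  V <- V / rn
  km <- withSeed(seed, stats::kmeans(V, centers = 2, nstart = nstart))
  lab <- canonTwoWay(km$cluster)
  acc <- if (is.null(truth)) NA_real_ else alignedAccuracy(lab, truth)
  new("ClusterResult", labels = lab, algorithm = "njw",
      alignedAccuracy = acc,
      trialIds = if (is.null(ids)) as.character(seq_len(k)) else ids)
}

#' Normalized-cut value of a bipartition
#'
#' \eqn{Ncut(A, B) = cut(A,B)/vol(A) + cut(A,B)/vol(B)} with
#' \eqn{cut(A,B) = \sum_{i \in A, j \in B} S_{ij}} and
#' \eqn{vol(A) = \sum_{i \in A} \sum_j S_{ij}}.
#'
#' @param S similarity matrix.
#' @param split logical or 1/2 vector marking side A.
#' @return the Ncut value (Inf if a side is empty).
#' @export
ncutValue <- function(S, split) {
  S <- asSimilarity(S)
  A <- if (is.logical(split)) split else as.integer(split) == 1L
  if (!any(A) || all(A)) return(Inf)
  d <- rowSums(S)
  cut <- sum(S[A, !A])
  cut / sum(d[A]) + cut / sum(d[!A])
}

#' Normalized-cut spectral clustering of trials into two groups
#'
#' Solves the generalized eigenproblem \eqn{(D - S) v = \lambda D v}, takes
#' the eigenvector of the second-smallest eigenvalue (the Fiedler vector)
#' and sweeps all k-1 thresholds over its sorted entries, returning the
#' split with minimal Ncut value.
#'
#' @inheritParams njwCluster
#' @return a [ClusterResult-class]; cluster ids canonicalized as in
#'   [njwCluster()].
#' @export
ncutCluster <- function(S, truth = NULL) {
  ids <- if (is(S, "TrialSimilarity")) trialIds(S) else NULL
  S <- asSimilarity(S)
  k <- nrow(S)
  if (k < 4) validationError("at least 4 trials are required")
  d <- rowSums(S)
  isq <- 1 / sqrt(d)
  Lsym <- diag(k) - S * outer(isq, isq)
  eg <- eigen(Lsym, symmetric = TRUE)
  v <- isq * eg$vectors[, k - 1]          # second-smallest eigenvalue
  ord <- order(v)
  best <- NULL; bestVal <- Inf
  for (j in seq_len(k - 1)) {
    A <- logical(k); A[ord[seq_len(j)]] <- TRUE
    val <- ncutValue(S, A)
    if (val < bestVal) { bestVal <- val; best <- A }
  }
  lab <- canonTwoWay(ifelse(best, 1L, 2L))
  acc <- if (is.null(truth)) NA_real_ else alignedAccuracy(lab, truth)
  new("ClusterResult", labels = lab, algorithm = "ncut",
      alignedAccuracy = acc,
      trialIds = if (is.null(ids)) as.character(seq_len(k)) else ids)
}

#' Accuracy of a two-way clustering after label alignment
#'
#' Cluster ids are arbitrary, so the fraction of matching trials is
#' maximized over the two possible assignments of cluster ids to true
#' labels.
#'
#' @param predicted cluster labels (2 values).
#' @param truth true labels (2 values), same length.
#' @return fraction in [0, 1] (>= 0.5 for balanced data).
#' @examples
#' alignedAccuracy(c(1, 2, 2, 2), c("A", "A", "B", "B"))  # 0.75
#' @export
alignedAccuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    validationError("label vectors must have equal length")
  p <- as.integer(factor(predicted))
  t <- as.integer(factor(truth))
  max(mean(p == t), mean((3L - p) == t))
}
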
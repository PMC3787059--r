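#' Weighted modularity Q of a partition
#'
#' Newman's modularity for a weighted undirected network:
#' \deqn{Q = \frac{1}{2l} \sum_{ij} \left[ w_{ij} -
#'   \frac{k_i k_j}{2l} \right] \delta(c_i, c_j)}
#' where \eqn{l} is the total weight of all connections, \eqn{k_i = \sum_j
#' w_{ij}} is the weighted node strength, and the sum runs over all ordered
#' pairs including \eqn{i = j} (self-weights are 0).
#'
#' @param R symmetric weight matrix (zero diagonal, weights in [0, 1]).
#' @param membership integer (or factor) community id per node, in node
#'   order, or named by node.
#' @return modularity Q (<= 1; 0 for the single-community partition).
#' @examples
#' R <- matrix(0, 4, 4)
#' R[1, 2] <- R[2, 1] <- 1; R[3, 4] <- R[4, 3] <- 1
#' modularityQ(R, c(1, 1, 2, 2))  # 0.5
#' @export
modularityQ <- function(R, membership) {
  checkWeightMatrix(R)
  n <- nrow(R)
  if (length(membership) != n)
    validationError("membership must cover every node")
  if (!is.null(names(membership)) && !is.null(rownames(R)))
    membership <- membership[rownames(R)]
  memb <- as.integer(factor(membership))
  twoL <- sum(R)
  if (twoL <= 0)
    degenerateNetworkError("network has no positive-weight connections")
  k <- rowSums(R)
  same <- outer(memb, memb, "==")
  sum((R - outer(k, k) / twoL)[same]) / twoL
}

#' Partition a functional network into circuit groups
#'
#' Two-step modularity maximization: nodes with no positive-weight
#' connection are set aside as outliers; the connected nodes are clustered
#' hierarchically on the distance \code{1 - weight} (absent edges have
#' distance 1); the dendrogram is cut into c = 1, 2, ... communities and the
#' cut with maximal modularity Q is returned (ties broken toward fewer
#' communities). Outliers are appended as singleton communities; Q is
#' reported for the connected subnetwork.
#'
#' @param R symmetric weight matrix with neuron dimnames.
#' @param linkage hierarchical-clustering linkage: "average" (default),
#'   "single" or "complete".
#' @return a [NeuronPartition-class].
#' @examples
#' R <- matrix(0, 7, 7, dimnames = rep(list(letters[1:7]), 2))
#' tri <- function(i) for (a in i) for (b in i) if (a != b) R[a, b] <<- 1
#' tri(1:3); tri(4:6)   # two triangles + isolated node 7
#' p <- bestPartition(R)
#' modularityValue(p)   # 0.5
#' @export
bestPartition <- function(R, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  checkWeightMatrix(R)
  nodes <- rownames(R)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(R)))
  strength <- rowSums(R)
  connected <- which(strength > 0)
  outliers <- nodes[strength == 0]
  if (length(connected) == 0)
    degenerateNetworkError("all nodes are outliers: network has no edges")
  Rc <- R[connected, connected, drop = FALSE]
  m <- length(connected)
  hc <- stats::hclust(stats::as.dist(1 - Rc), method = linkage)
  qs <- vapply(seq_len(m), function(cc)
    modularityQ(Rc, stats::cutree(hc, k = cc)), numeric(1))
  # ties (within numerical noise of the max) break toward fewer communities
  bestC <- which(qs >= max(qs) - 1e-12)[1]
  bestQ <- qs[bestC]
  if (abs(bestQ) < 1e-12) bestQ <- 0           # snap the exact-cancellation case
  membC <- stats::cutree(hc, k = bestC)
  ## renumber communities consecutively in order of first appearance
  membC <- as.integer(factor(membC, levels = unique(membC)))
  memb <- integer(length(nodes))
  names(memb) <- nodes
  memb[connected] <- membC
  nC <- max(membC)
  if (length(outliers))
    memb[outliers] <- nC + seq_along(outliers)
  new("NeuronPartition", membership = memb, outliers = outliers,
      Q = bestQ, nCommunities = as.integer(nC + length(outliers)))
}

#' Circuit-group representation of a trial network
#'
#' Projects a network onto its community structure. In \code{"mask"} mode
#' (default) the weighted matrix is kept on intra-community edges and zeroed
#' elsewhere (outliers, being singletons, lose all edges). In
#' \code{"comembership"} mode the output is the binary co-membership matrix
#' (1 iff two neurons share a community, zero diagonal).
#'
#' @param R symmetric weight matrix.
#' @param partition a [NeuronPartition-class] for \code{R} (typically
#'   [bestPartition()]).
#' @param mode "mask" or "comembership".
#' @return a matrix of the same dimensions as \code{R}.
#' @export
lncgMask <- function(R, partition, mode = c("mask", "comembership")) {
  mode <- match.arg(mode)
  checkWeightMatrix(R)
  memb <- communityMembership(partition)
  if (!is.null(rownames(R))) memb <- memb[rownames(R)]
  if (length(memb) != nrow(R) || anyNA(memb))
    validationError("partition does not cover the network's neurons")
  same <- outer(memb, memb, "==")
  out <- if (mode == "mask") R * same else (same + 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(R)
  out
}

#' Partition every trial network of a set
#'
#' @param netset a [TrialNetworkSet-class].
#' @inheritParams bestPartition
#' @return list of [NeuronPartition-class], one per trial.
#' @export
partitionNetworks <- function(netset, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  lapply(networkList(netset), bestPartition, linkage = linkage)
}

#' Circuit-group (LNCG) networks for every trial
#'
#' Runs [bestPartition()] on each trial's network and applies [lncgMask()],
#' yielding the circuit-group representation of the session.
#'
#' @param netset a [TrialNetworkSet-class] (representation "wnfn").
#' @inheritParams bestPartition
#' @inheritParams lncgMask
#' @param partitions optional precomputed list from [partitionNetworks()].
#' @return a [TrialNetworkSet-class] with representation "lncg".
#' @export
lncgNetworks <- function(netset, linkage = c("average", "single", "complete"),
                         mode = c("mask", "comembership"), partitions = NULL) {
  linkage <- match.arg(linkage)
  mode <- match.arg(mode)
  if (is.null(partitions)) partitions <- partitionNetworks(netset, linkage)
  nets <- mapply(lncgMask, networkList(netset), partitions,
                 MoreArgs = list(mode = mode), SIMPLIFY = FALSE)
  new("TrialNetworkSet", networks = nets, trialIds = trialIds(netset),
      labels = trialLabels(netset), binWidth = netset@binWidth,
      representation = "lncg")
}

#' Serialize a partition as JSON
#'
#' @param partition a [NeuronPartition-class].
#' @param path output path.
#' @param trialId optional trial id recorded in the file.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(partition, path, trialId = NA_character_) {
  memb <- communityMembership(partition)
  comms <- split(names(memb), memb)
  out <- list(trial_id = trialId,
              communities = unname(comms),
              outliers = as.list(outlierNodes(partition)),
              Q = modularityValue(partition))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
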
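#' Run the full analysis workflow on one session
#'
#' Convenience driver covering the whole method: simulate (or accept) a
#' session, build per-trial functional networks, optionally project each
#' onto its circuit groups, compute the Gaussian-kernel trial similarity,
#' cluster trials with NJW and Ncut, and decode single-trial outcomes with
#' pattern matching and KNN under leave-one-out cross-validation.
#'
#' @param x a [SimConfig-class] (the session is simulated; use
#'   \code{null = TRUE} for a null session) or a [SpikeDataset-class].
#' @param representation "wnfn" (whole network, default) or "lncg"
#'   (circuit-group-masked networks).
#' @param binWidth analysis bin width, s.
#' @param sigma Gaussian kernel scale.
#' @param k KNN neighborhood size.
#' @param linkage linkage for the community dendrogram.
#' @param mode circuit-group projection mode (see [lncgMask()]).
#' @param null simulate with [makeNullSession()] instead of
#'   [simulateSession()].
#' @return list with elements \code{dataset}, \code{truth} (NULL for real
#'   data), \code{networks}, \code{partitions} (NULL for "wnfn"),
#'   \code{similarity}, \code{clustering} (list njw/ncut of
#'   [ClusterResult-class]) and \code{decoding} (list match/knn of
#'   [DecodingReport-class]).
#' @examples
#' res <- runPipeline(simConfig(nTrials = 12, trialDuration = 5, seed = 3))
#' res$clustering$ncut
#' res$decoding$knn
#' @export
runPipeline <- function(x, representation = c("wnfn", "lncg"), binWidth = 1,
                        sigma = 4, k = 7,
                        linkage = c("average", "single", "complete"),
                        mode = c("mask", "comembership"), null = FALSE) {
  representation <- match.arg(representation)
  linkage <- match.arg(linkage)
  mode <- match.arg(mode)
  truth <- NULL
  if (is(x, "SimConfig")) {
    sess <- if (null) makeNullSession(x) else simulateSession(x)
    ds <- sess$dataset
    truth <- sess$truth
  } else if (is(x, "SpikeDataset")) {
    ds <- x
  } else {
    validationError("x must be a SimConfig or a SpikeDataset")
  }
  nets <- buildNetworks(ds, binWidth = binWidth)
  partitions <- NULL
  if (representation == "lncg") {
    partitions <- partitionNetworks(nets, linkage = linkage)
    nets <- lncgNetworks(nets, linkage = linkage, mode = mode,
                         partitions = partitions)
  }
  sim <- trialSimilarity(nets, sigma = sigma)
  labs <- trialLabels(ds)
  list(
    dataset = ds,
    truth = truth,
    networks = nets,
    partitions = partitions,
    similarity = sim,
    clustering = list(njw = njwCluster(sim, truth = labs),
                      ncut = ncutCluster(sim, truth = labs)),
    decoding = list(
      match = looEvaluate(sim, labels = labs, classifier = "match"),
      knn = looEvaluate(sim, labels = labs, classifier = "knn", k = k)))
}
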
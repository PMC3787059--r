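#' Accessors for spikeCircuits objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a spikeCircuits object.
#' @param ... unused.
#' @return the requested component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x, ...) standardGeneric("neuronIds"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x, ...) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("trialTable", function(x, ...) standardGeneric("trialTable"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x, ...) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("trialIds", function(x, ...) standardGeneric("trialIds"))

#' @rdname accessors
#' @export
setGeneric("networkList", function(x, ...) standardGeneric("networkList"))

#' @rdname accessors
#' @export
setGeneric("similarityMatrix", function(x, ...) standardGeneric("similarityMatrix"))

#' @rdname accessors
#' @export
setGeneric("communityMembership", function(x, ...) standardGeneric("communityMembership"))

#' @rdname accessors
#' @export
setGeneric("outlierNodes", function(x, ...) standardGeneric("outlierNodes"))

#' @rdname accessors
#' @export
setGeneric("modularityValue", function(x, ...) standardGeneric("modularityValue"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("predictionTable", function(x, ...) standardGeneric("predictionTable"))

#' @rdname accessors
#' @export
setGeneric("jaccardValue", function(x, ...) standardGeneric("jaccardValue"))

## ---- methods ----

#' @rdname accessors
#' @export
setMethod("neuronIds", "SpikeDataset", function(x, ...) x@neurons)

#' @rdname accessors
#' @param neuron optional neuron id; when given, that neuron's spike times
#'   are returned instead of the full list.
#' @export
setMethod("spikeTimes", "SpikeDataset", function(x, neuron = NULL, ...) {
  if (is.null(neuron)) return(x@spikes)
  if (!neuron %in% x@neurons)
    validationError(sprintf("unknown neuron id '%s'", neuron))
  x@spikes[[neuron]]
})

#' @rdname accessors
#' @export
setMethod("trialTable", "SpikeDataset", function(x, ...) x@trials)

#' @rdname accessors
#' @export
setMethod("trialLabels", "SpikeDataset", function(x, ...) x@trials$label)

#' @rdname accessors
#' @export
setMethod("trialIds", "SpikeDataset", function(x, ...) x@trials$trial_id)

#' @rdname accessors
#' @export
setMethod("trialLabels", "GroundTruth", function(x, ...) x@trialLabels)

#' @rdname accessors
#' @export
setMethod("networkList", "TrialNetworkSet", function(x, ...) x@networks)

#' @rdname accessors
#' @export
setMethod("trialIds", "TrialNetworkSet", function(x, ...) x@trialIds)

#' @rdname accessors
#' @export
setMethod("trialLabels", "TrialNetworkSet", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("neuronIds", "TrialNetworkSet", function(x, ...)
  rownames(x@networks[[1]]))

#' @rdname accessors
#' @export
setMethod("similarityMatrix", "TrialSimilarity", function(x, ...) x@S)

#' @rdname accessors
#' @export
setMethod("trialIds", "TrialSimilarity", function(x, ...) x@trialIds)

#' @rdname accessors
#' @export
setMethod("communityMembership", "NeuronPartition", function(x, ...) x@membership)

#' @rdname accessors
#' @export
setMethod("outlierNodes", "NeuronPartition", function(x, ...) x@outliers)

#' @rdname accessors
#' @export
setMethod("modularityValue", "NeuronPartition", function(x, ...) x@Q)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("trialIds", "ClusterResult", function(x, ...) x@trialIds)

#' @rdname accessors
#' @export
setMethod("predictionTable", "DecodingReport", function(x, ...) x@perTrial)

#' @rdname accessors
#' @export
setMethod("jaccardValue", "DecodingReport", function(x, ...) x@jaccard)

## ---- show methods ----

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d neurons, %d trials x %.3g s (gap %.3g s)\n",
    object@nNeurons, object@nTrials, object@trialDuration,
    object@interTrialGap))
  cat(sprintf(
    "  base rate %.3g /s; module events %.3g /s x %.3g s, gain %.3g\n",
    object@baseRate, object@commonEventRate, object@eventDuration,
    object@commonGain))
  cat(sprintf("  labels: %s; seed %d\n",
              paste(object@labels, collapse = " / "), object@seed))
})

setMethod("show", "SpikeDataset", function(object) {
  nsp <- sum(lengths(object@spikes))
  cat(sprintf("SpikeDataset: %d neurons, %d spikes, %d trials (labels: %s)\n",
              length(object@neurons), nsp, nrow(object@trials),
              paste(sort(unique(object@trials$label)), collapse = " / ")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d trials, %s; expected within-between contrast %.3f\n",
    length(object@trialLabels),
    if (object@isNull) "null (shared module map)" else "structured",
    object@expectedContrast))
})

setMethod("show", "TrialNetworkSet", function(object) {
  cat(sprintf(
    "TrialNetworkSet (%s): %d trials, %d neurons, %.3g-s bins\n",
    object@representation, length(object@networks),
    nrow(object@networks[[1]]), object@binWidth))
})

setMethod("show", "NeuronPartition", function(object) {
  cat(sprintf(
    "NeuronPartition: %d communities (%d outliers), Q = %.4f\n",
    object@nCommunities, length(object@outliers), object@Q))
})

setMethod("show", "TrialSimilarity", function(object) {
  cat(sprintf("TrialSimilarity (%s): %d trials, sigma = %.3g\n",
              object@representation, nrow(object@S), object@sigma))
})

setMethod("show", "ClusterResult", function(object) {
  acc <- if (is.na(object@alignedAccuracy)) "NA"
         else sprintf("%.3f", object@alignedAccuracy)
  cat(sprintf("ClusterResult (%s): %d trials, aligned accuracy %s\n",
              object@algorithm, length(object@labels), acc))
})

setMethod("show", "DecodingReport", function(object) {
  cat(sprintf(
    "DecodingReport (%s on %s): %d trials, score %.3f (k=%s, sigma=%.3g)\n",
    object@classifier, object@representation, nrow(object@perTrial),
    object@jaccard,
    if (is.null(object@params$k)) "-" else object@params$k,
    object@params$sigma))
})
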
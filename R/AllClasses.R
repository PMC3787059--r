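#' @import methods
NULL

#' Simulation configuration for the correlated spike-train generator
#'
#' Holds every parameter of the common-input Bernoulli generator: population
#' size, trial layout, firing rates, the shared-event process that induces
#' within-module correlation, and the per-trial-type module maps.
#'
#' @slot nNeurons number of simultaneously recorded neurons (>= 2).
#' @slot nTrials number of trials; labels alternate, so both behavioral
#'   types receive floor/ceiling of half the trials.
#' @slot trialDuration trial length in seconds.
#' @slot baseRate baseline firing rate, spikes/s.
#' @slot commonEventRate rate of shared module events, events/s per module.
#' @slot commonGain dimensionless multiplicative boost of the firing
#'   probability while a module event is active; 0 means independence.
#' @slot eventDuration duration of one shared event in seconds. Events are
#'   block-persistent: the module's event indicator is drawn once per block
#'   of this length, modeling slow common drive. Must be a multiple of
#'   \code{subBinWidth}.
#' @slot subBinWidth width of the fine simulation sub-bin in seconds; must
#'   be much smaller than the 1-s analysis bin.
#' @slot moduleMaps named list with one integer vector per behavioral label,
#'   assigning each neuron to exactly one module under that trial type.
#' @slot labels the two behavioral labels.
#' @slot interTrialGap gap between consecutive trials, seconds.
#' @slot seed integer RNG seed; identical configurations give identical
#'   spike trains.
#' @seealso [simConfig()], [simulateSession()], [makeNullSession()]
#' @export
setClass("SimConfig", representation(
  nNeurons = "integer",
  nTrials = "integer",
  trialDuration = "numeric",
  baseRate = "numeric",
  commonEventRate = "numeric",
  commonGain = "numeric",
  eventDuration = "numeric",
  subBinWidth = "numeric",
  moduleMaps = "list",
  labels = "character",
  interTrialGap = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(length(object@nNeurons) == 1 && object@nNeurons >= 2L,
      "nNeurons: must be a single integer >= 2")
  chk(length(object@nTrials) == 1 && object@nTrials >= 2L,
      "nTrials: must be >= 2 so both labels get at least one trial")
  chk(length(object@trialDuration) == 1 && object@trialDuration > 0,
      "trialDuration: must be > 0 seconds")
  chk(length(object@baseRate) == 1 && object@baseRate > 0,
      "baseRate: must be > 0 spikes/s")
  chk(length(object@commonEventRate) == 1 && object@commonEventRate >= 0,
      "commonEventRate: must be >= 0 events/s")
  chk(length(object@commonGain) == 1 && object@commonGain >= 0,
      "commonGain: must be >= 0")
  chk(length(object@subBinWidth) == 1 && object@subBinWidth > 0,
      "subBinWidth: must be > 0 seconds")
  chk(length(object@eventDuration) == 1 &&
        object@eventDuration >= object@subBinWidth,
      "eventDuration: must be >= subBinWidth")
  if (length(object@eventDuration) == 1 && length(object@subBinWidth) == 1 &&
      object@subBinWidth > 0) {
    ratio <- object@eventDuration / object@subBinWidth
    chk(abs(ratio - round(ratio)) < 1e-8,
        "eventDuration: must be an integer multiple of subBinWidth")
  }
  chk(length(object@labels) == 2 && !anyDuplicated(object@labels) &&
        all(nzchar(object@labels)),
      "labels: exactly 2 distinct non-empty labels required")
  chk(length(object@interTrialGap) == 1 && object@interTrialGap >= 0,
      "interTrialGap: must be >= 0 seconds")
  chk(length(object@seed) == 1 && is.finite(object@seed),
      "seed: must be a single integer")
  if (length(object@labels) == 2) {
    chk(setequal(names(object@moduleMaps), object@labels),
        "moduleMaps: must be named by the two labels")
    for (lab in intersect(names(object@moduleMaps), object@labels)) {
      m <- object@moduleMaps[[lab]]
      chk(length(m) == object@nNeurons && all(m == as.integer(m)) &&
            all(m >= 1L),
          sprintf(
            "moduleMaps: map for label '%s' must assign every neuron one positive module id",
            lab))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Spike trains and trial epochs for one recording session
#'
#' The central input container: an ordered neuron roster, one sorted spike
#' time vector per neuron (seconds on the session clock), and the ordered,
#' non-overlapping trial table with one of two behavioral labels per trial.
#'
#' @slot neurons ordered character vector of unique neuron ids.
#' @slot spikes named list, one strictly increasing numeric vector of spike
#'   times (s) per neuron, names matching \code{neurons}.
#' @slot trials data.frame with columns \code{trial_id}, \code{start_s},
#'   \code{end_s}, \code{label}; epochs ordered and pairwise non-overlapping;
#'   labels take exactly two values.
#' @seealso [readSession()], [segmentTrial()], [buildNetworks()]
#' @export
setClass("SpikeDataset", representation(
  neurons = "character",
  spikes = "list",
  trials = "data.frame"
))

setValidity("SpikeDataset", function(object) {
  msgs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(length(object@neurons) >= 2, "at least 2 neurons required")
  chk(!anyDuplicated(object@neurons), "neuron ids must be unique")
  chk(identical(names(object@spikes), object@neurons),
      "spikes must be named by neurons, in the same order")
  for (nid in names(object@spikes)) {
    s <- object@spikes[[nid]]
    if (!is.numeric(s)) {
      msgs <- c(msgs, sprintf("spike times of neuron '%s' must be numeric", nid))
      next
    }
    if (length(s) > 1 && any(diff(s) <= 0))
      msgs <- c(msgs, sprintf(
        "spike times of neuron '%s' must be strictly increasing", nid))
  }
  tr <- object@trials
  need <- c("trial_id", "start_s", "end_s", "label")
  chk(all(need %in% names(tr)),
      "trials needs columns trial_id, start_s, end_s, label")
  if (all(need %in% names(tr))) {
    chk(nrow(tr) >= 2, "at least 2 trials required")
    chk(!anyDuplicated(tr$trial_id), "trial ids must be unique")
    chk(all(tr$end_s > tr$start_s), "every trial needs end_s > start_s")
    if (nrow(tr) >= 2) {
      o <- order(tr$start_s)
      chk(all(tr$start_s[o][-1] >= tr$end_s[o][-nrow(tr)]),
          "trial epochs must not overlap")
    }
    chk(length(unique(tr$label)) == 2,
        "trial labels must take exactly 2 values")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated session
#'
#' @slot trialLabels behavioral label of each trial, in trial order.
#' @slot moduleMaps the per-label neuron-to-module assignments used by the
#'   generator.
#' @slot isNull TRUE when both labels shared one module map (labels carry no
#'   connectivity information).
#' @slot expectedContrast analytic expected within-module minus
#'   between-module Pearson correlation of 1-s bin counts under the
#'   generator (between-module is 0 by construction).
#' @slot config the [SimConfig-class] that produced the session.
#' @export
setClass("GroundTruth", representation(
  trialLabels = "character",
  moduleMaps = "list",
  isNull = "logical",
  expectedContrast = "numeric",
  config = "SimConfig"
))

#' A set of per-trial weighted functional networks
#'
#' One symmetric weight matrix per trial (entries in [0, 1], zero diagonal),
#' all on the same neuron roster, under either the whole-network ("wnfn")
#' or circuit-group-masked ("lncg") representation.
#'
#' @slot networks list of n_neurons x n_neurons matrices, one per trial,
#'   with identical dimnames (neuron ids).
#' @slot trialIds character vector of trial ids.
#' @slot labels behavioral label per trial (may be hidden from classifiers;
#'   carried for evaluation).
#' @slot binWidth analysis bin width (s) used for the spike counts.
#' @slot representation "wnfn" or "lncg".
#' @seealso [buildNetworks()], [lncgNetworks()], [trialSimilarity()]
#' @export
setClass("TrialNetworkSet", representation(
  networks = "list",
  trialIds = "character",
  labels = "character",
  binWidth = "numeric",
  representation = "character"
))

setValidity("TrialNetworkSet", function(object) {
  msgs <- character(0)
  k <- length(object@networks)
  if (k < 1) msgs <- c(msgs, "at least one network required")
  if (length(object@trialIds) != k || length(object@labels) != k)
    msgs <- c(msgs, "trialIds and labels must match the number of networks")
  if (!object@representation %in% c("wnfn", "lncg"))
    msgs <- c(msgs, "representation must be 'wnfn' or 'lncg'")
  if (k >= 1) {
    dn <- dimnames(object@networks[[1]])
    for (i in seq_len(k)) {
      R <- object@networks[[i]]
      ok <- tryCatch({ checkWeightMatrix(R, sprintf("network %d", i)); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) { msgs <- c(msgs, ok); next }
      if (!identical(dimnames(R), dn))
        msgs <- c(msgs, "all networks must share the same neuron dimnames")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Community partition of one trial's functional network
#'
#' @slot membership named integer vector mapping every neuron to a community
#'   id (consecutive from 1); outlier neurons occupy their own singleton
#'   communities.
#' @slot outliers neurons with no positive-weight connection in this trial's
#'   network.
#' @slot Q weighted modularity of the partition, computed on the connected
#'   (non-outlier) subnetwork.
#' @slot nCommunities total number of communities including outlier
#'   singletons.
#' @seealso [bestPartition()], [modularityQ()]
#' @export
setClass("NeuronPartition", representation(
  membership = "integer",
  outliers = "character",
  Q = "numeric",
  nCommunities = "integer"
))

setValidity("NeuronPartition", function(object) {
  m <- object@membership
  msgs <- character(0)
  if (is.null(names(m))) msgs <- c(msgs, "membership must be named by neuron")
  ids <- sort(unique(m))
  if (length(ids) && !identical(ids, seq_len(max(m))))
    msgs <- c(msgs, "community ids must be consecutive integers from 1")
  if (!all(object@outliers %in% names(m)))
    msgs <- c(msgs, "outliers must be a subset of the neurons")
  if (length(object@outliers) &&
      any(table(m[object@outliers]) > 1 |
            m[object@outliers] %in% m[setdiff(names(m), object@outliers)]))
    msgs <- c(msgs, "outlier neurons must be singleton communities")
  if (length(object@nCommunities) != 1 ||
      object@nCommunities != length(unique(m)))
    msgs <- c(msgs, "nCommunities must equal the number of distinct communities")
  if (length(msgs)) msgs else TRUE
})

#' Gaussian-kernel similarity between all trial pairs
#'
#' @slot S k x k symmetric matrix of similarities in (0, 1], unit diagonal.
#' @slot sigma Gaussian kernel scale.
#' @slot representation which network representation the similarity was
#'   computed on ("wnfn" or "lncg").
#' @slot trialIds trial ids in matrix order.
#' @seealso [trialSimilarity()], [njwCluster()], [ncutCluster()]
#' @export
setClass("TrialSimilarity", representation(
  S = "matrix",
  sigma = "numeric",
  representation = "character",
  trialIds = "character"
))

setValidity("TrialSimilarity", function(object) {
  S <- object@S
  msgs <- character(0)
  if (nrow(S) != ncol(S)) msgs <- c(msgs, "S must be square")
  if (max(abs(S - t(S))) > 1e-8) msgs <- c(msgs, "S must be symmetric")
  if (any(S <= 0) || any(S > 1 + 1e-12))
    msgs <- c(msgs, "similarities must lie in (0, 1]")
  if (max(abs(diag(S) - 1)) > 1e-12)
    msgs <- c(msgs, "diagonal similarities must equal 1")
  if (object@sigma <= 0) msgs <- c(msgs, "sigma must be > 0")
  if (length(object@trialIds) != nrow(S))
    msgs <- c(msgs, "trialIds must match the matrix dimension")
  if (length(msgs)) msgs else TRUE
})

#' Two-way unsupervised clustering of trials
#'
#' @slot labels integer cluster label (1 or 2) per trial.
#' @slot algorithm "njw" or "ncut".
#' @slot alignedAccuracy fraction of trials whose cluster matches the true
#'   behavioral label after the best of the two label permutations; NA when
#'   no truth was supplied.
#' @slot trialIds trial ids in label order.
#' @export
setClass("ClusterResult", representation(
  labels = "integer",
  algorithm = "character",
  alignedAccuracy = "numeric",
  trialIds = "character"
))

#' Leave-one-out decoding report
#'
#' @slot perTrial data.frame with columns \code{trial_id}, \code{true},
#'   \code{predicted}, \code{correct}.
#' @slot jaccard the two-class score s = p1 + p2, where p_j is the number of
#'   correctly classified label-j trials over the total trial count;
#'   algebraically the overall fraction correct (not the set-theoretic
#'   Jaccard index).
#' @slot classifier "knn" or "match".
#' @slot representation "wnfn" or "lncg".
#' @slot params list of the decoding parameters (k, sigma, binWidth).
#' @seealso [looEvaluate()], [jaccardCoefficient()]
#' @export
setClass("DecodingReport", representation(
  perTrial = "data.frame",
  jaccard = "numeric",
  classifier = "character",
  representation = "character",
  params = "list"
))
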
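#' Build a simulation configuration
#'
#' Constructs and validates a [SimConfig-class] for the common-input
#' Bernoulli spike-train generator. Defaults reproduce the package's
#' structured two-type scenario: 12 neurons, 80 alternating trials of 10 s,
#' 5 spikes/s baseline, shared module events at 2/s lasting 0.2 s that boost
#' the firing probability by a factor (1 + commonGain), and maximally
#' non-overlapping module maps for the two trial types (type A modules
#' \{1-6\}, \{7-12\}; type B modules \{1-3, 7-9\}, \{4-6, 10-12\}).
#'
#' @param nNeurons number of neurons.
#' @param nTrials number of trials (labels alternate).
#' @param trialDuration trial length, s.
#' @param baseRate baseline firing rate, spikes/s.
#' @param commonEventRate shared module-event rate, events/s.
#' @param commonGain firing-probability boost during an event (0 =
#'   independent neurons).
#' @param eventDuration event persistence, s.
#' @param subBinWidth simulation sub-bin, s (default 10 ms).
#' @param moduleMaps named list (one integer vector per label) assigning each
#'   neuron to a module; NULL builds the default half/quarter block maps.
#' @param labels the two behavioral labels.
#' @param interTrialGap gap between trials, s.
#' @param seed RNG seed.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nNeurons = 12, nTrials = 8, seed = 1)
#' cfg
#' @export
simConfig <- function(nNeurons = 12, nTrials = 80, trialDuration = 10,
                      baseRate = 5, commonEventRate = 2, commonGain = 4,
                      eventDuration = 0.2, subBinWidth = 0.01,
                      moduleMaps = NULL, labels = c("A", "B"),
                      interTrialGap = 1, seed = 1) {
  if (is.null(moduleMaps)) moduleMaps <- defaultModuleMaps(nNeurons, labels)
  cfg <- try(new("SimConfig",
                 nNeurons = as.integer(nNeurons),
                 nTrials = as.integer(nTrials),
                 trialDuration = as.numeric(trialDuration),
                 baseRate = as.numeric(baseRate),
                 commonEventRate = as.numeric(commonEventRate),
                 commonGain = as.numeric(commonGain),
                 eventDuration = as.numeric(eventDuration),
                 subBinWidth = as.numeric(subBinWidth),
                 moduleMaps = lapply(moduleMaps, as.integer),
                 labels = as.character(labels),
                 interTrialGap = as.numeric(interTrialGap),
                 seed = as.integer(seed)),
             silent = TRUE)
  if (inherits(cfg, "try-error"))
    configError(sub(".*invalid class [^:]*: *", "", attr(cfg, "condition")$message))
  cfg
}

## Default module maps: label 1 splits the roster into two half blocks;
## label 2 regroups the four quarter blocks as (q1+q3) vs (q2+q4), so
## co-membership is maximally rearranged between the two trial types.
defaultModuleMaps <- function(n, labels) {
  half <- ifelse(seq_len(n) <= ceiling(n / 2), 1L, 2L)
  quarter <- ceiling(4 * seq_len(n) / n)
  cross <- ifelse(quarter %in% c(1, 3), 1L, 2L)
  stats::setNames(list(half, cross), labels)
}

#' Analytic within-module correlation of the generator
#'
#' Expected Pearson correlation between 1-s bin counts of two neurons in the
#' same module, derived from the block-persistent common-input model
#' (between-module pairs are independent, so this is also the expected
#' within-minus-between contrast).
#'
#' @param cfg a [SimConfig-class].
#' @return expected correlation (dimensionless, in [0, 1)).
#' @export
expectedCorrelationContrast <- function(cfg) {
  dt <- cfg@subBinWidth
  L <- round(cfg@eventDuration / dt)
  q <- min(1, cfg@commonEventRate * cfg@eventDuration)
  p0 <- min(1, cfg@baseRate * dt)
  p1 <- min(1, cfg@baseRate * dt * (1 + cfg@commonGain))
  covBlock <- (L * (p1 - p0))^2 * q * (1 - q)
  varBlock <- L * ((1 - q) * p0 * (1 - p0) + q * p1 * (1 - p1)) + covBlock
  if (varBlock <= 0) return(0)
  covBlock / varBlock
}

#' Simulate a multi-neuron recording session with modular correlations
#'
#' Generates seeded spike trains on a single session timeline. Trials
#' alternate between the two behavioral labels and are separated by
#' \code{interTrialGap}. Each trial is discretized into sub-bins
#' (\code{subBinWidth}); each module's shared event indicator is drawn once
#' per \code{eventDuration} block with probability
#' \code{commonEventRate * eventDuration}; neuron i spikes in a sub-bin with
#' probability \code{clip(baseRate * subBinWidth * (1 + commonGain * event),
#' 0, 1)} where \code{event} is the indicator of i's module under the
#' trial's label, and the spike time is uniform within the sub-bin. Neurons
#' sharing a module therefore receive common input; neurons in different
#' modules are independent.
#'
#' @param cfg a [SimConfig-class]; the simulation is deterministic given cfg
#'   (including its seed).
#' @return list with elements \code{dataset} ([SpikeDataset-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' sess <- simulateSession(simConfig(nTrials = 4, trialDuration = 4, seed = 7))
#' sess$dataset
#' @export
simulateSession <- function(cfg) {
  if (!is(cfg, "SimConfig")) configError("cfg must be a SimConfig")
  validObject(cfg)
  simulateCore(cfg, isNull = FALSE)
}

#' Simulate a null session (label carries no connectivity information)
#'
#' Identical to [simulateSession()] except that both labels use the first
#' label's module map, so the two trial types are statistically identical
#' and any downstream decoder should perform at chance.
#'
#' @inheritParams simulateSession
#' @return as [simulateSession()]; \code{truth@isNull} is TRUE.
#' @export
makeNullSession <- function(cfg) {
  if (!is(cfg, "SimConfig")) configError("cfg must be a SimConfig")
  validObject(cfg)
  nullMaps <- cfg@moduleMaps
  nullMaps[[cfg@labels[2]]] <- nullMaps[[cfg@labels[1]]]
  cfg@moduleMaps <- nullMaps
  simulateCore(cfg, isNull = TRUE)
}

simulateCore <- function(cfg, isNull) {
  n <- cfg@nNeurons
  dt <- cfg@subBinWidth
  nSub <- max(1L, round(cfg@trialDuration / dt))
  L <- round(cfg@eventDuration / dt)
  nBlocks <- as.integer(ceiling(nSub / L))
  qEvent <- min(1, cfg@commonEventRate * cfg@eventDuration)
  labs <- rep(cfg@labels, length.out = cfg@nTrials)
  starts <- (seq_len(cfg@nTrials) - 1) * (cfg@trialDuration + cfg@interTrialGap)
  ends <- starts + cfg@trialDuration
  neurons <- sprintf("n%02d", seq_len(n))

  spikes <- withSeed(cfg@seed, {
    acc <- vector("list", n)
    for (i in seq_len(n)) acc[[i]] <- vector("list", cfg@nTrials)
    for (t in seq_len(cfg@nTrials)) {
      mods <- cfg@moduleMaps[[labs[t]]]
      nMod <- max(mods)
      evBlock <- matrix(stats::runif(nMod * nBlocks) < qEvent, nMod, nBlocks)
      ev <- evBlock[, rep(seq_len(nBlocks), each = L), drop = FALSE][, seq_len(nSub), drop = FALSE]
      p <- pmin(1, cfg@baseRate * dt * (1 + cfg@commonGain * ev[mods, , drop = FALSE]))
      fire <- matrix(stats::runif(n * nSub), n, nSub) < p
      offs <- matrix(stats::runif(n * nSub), n, nSub)
      for (i in seq_len(n)) {
        hit <- which(fire[i, ])
        acc[[i]][[t]] <- starts[t] + (hit - 1 + offs[i, hit]) * dt
      }
    }
    lapply(acc, function(x) as.numeric(unlist(x)))
  })
  names(spikes) <- neurons

  ds <- new("SpikeDataset",
            neurons = neurons,
            spikes = spikes,
            trials = data.frame(
              trial_id = sprintf("t%03d", seq_len(cfg@nTrials)),
              start_s = starts, end_s = ends, label = labs,
              stringsAsFactors = FALSE))
  truth <- new("GroundTruth",
               trialLabels = labs,
               moduleMaps = cfg@moduleMaps,
               isNull = isNull,
               expectedContrast = if (cfg@commonGain == 0) 0
                                  else expectedCorrelationContrast(cfg),
               config = cfg)
  list(dataset = ds, truth = truth)
}
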
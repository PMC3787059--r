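#' Read spike trains from a tab-separated file
#'
#' Expects a header line \code{neuron_id<TAB>time_s} followed by one spike
#' per line. Neuron order follows first appearance in the file; spike times
#' must be strictly increasing within each neuron.
#'
#' @param path file path.
#' @return named list of numeric spike-time vectors, in neuron order.
#' @seealso [writeSpikes()], [readSession()]
#' @export
readSpikes <- function(path) {
  if (!file.exists(path)) parseError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "neuron_id\ttime_s")
    parseError(sprintf("%s, line 1: expected header 'neuron_id\\ttime_s'", path))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    parseError(sprintf("%s, line %d: expected 2 tab-separated fields",
                       path, bad[1] + 1L))
  ids <- vapply(parts, `[[`, "", 1L)
  tms <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(tms))
  if (length(bad))
    parseError(sprintf("%s, line %d: time_s is not a finite number",
                       path, bad[1] + 1L))
  spikes <- split(tms, factor(ids, levels = unique(ids)))
  for (nid in names(spikes)) {
    s <- spikes[[nid]]
    if (length(s) > 1 && any(diff(s) <= 0))
      validationError(sprintf(
        "spike times of neuron '%s' are not strictly increasing", nid))
  }
  lapply(spikes, as.numeric)
}

#' Write spike trains to a tab-separated file
#'
#' Inverse of [readSpikes()]: values are written with 17 significant digits
#' so that write-then-read reproduces them exactly.
#'
#' @param spikes a [SpikeDataset-class] or a named list of spike-time
#'   vectors.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpikes <- function(spikes, path) {
  if (is(spikes, "SpikeDataset")) spikes <- spikeTimes(spikes)
  ids <- rep(names(spikes), lengths(spikes))
  tms <- unlist(spikes, use.names = FALSE)
  writeLines(c("neuron_id\ttime_s",
               if (length(ids)) sprintf("%s\t%.17g", ids, tms)),
             path)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Expects header \code{trial_id,start_s,end_s,label}. At least two trials
#' with exactly two distinct labels, positive durations and non-overlapping
#' epochs are required.
#'
#' @param path file path.
#' @return data.frame with the four columns, in file order.
#' @export
readTrials <- function(path) {
  if (!file.exists(path)) parseError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "trial_id,start_s,end_s,label")
    parseError(sprintf(
      "%s, line 1: expected header 'trial_id,start_s,end_s,label'", path))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) < 2)
    validationError("trial table must contain at least 2 trials")
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    parseError(sprintf("%s, line %d: expected 4 comma-separated fields",
                       path, bad[1] + 1L))
  tr <- data.frame(
    trial_id = vapply(parts, `[[`, "", 1L),
    start_s = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L))),
    end_s = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L))),
    label = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  bad <- which(!is.finite(tr$start_s) | !is.finite(tr$end_s))
  if (length(bad))
    parseError(sprintf("%s, line %d: start_s/end_s must be finite numbers",
                       path, bad[1] + 1L))
  validateTrials(tr)
  tr
}

validateTrials <- function(tr) {
  if (any(tr$end_s <= tr$start_s))
    validationError("every trial needs end_s > start_s")
  if (anyDuplicated(tr$trial_id))
    validationError("trial ids must be unique")
  o <- order(tr$start_s)
  if (nrow(tr) >= 2 && any(tr$start_s[o][-1] < tr$end_s[o][-nrow(tr)]))
    validationError("trial epochs overlap")
  if (length(unique(tr$label)) != 2)
    validationError("trial labels must take exactly 2 values")
  invisible(TRUE)
}

#' Write a trial table to CSV
#'
#' @param trials a [SpikeDataset-class] or a trial data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrials <- function(trials, path) {
  if (is(trials, "SpikeDataset")) trials <- trialTable(trials)
  writeLines(c("trial_id,start_s,end_s,label",
               sprintf("%s,%.17g,%.17g,%s", trials$trial_id, trials$start_s,
                       trials$end_s, trials$label)),
             path)
  invisible(path)
}

#' Assemble a SpikeDataset from spike and trial files
#'
#' @param spikePath spike TSV (see [readSpikes()]).
#' @param trialPath trial CSV (see [readTrials()]).
#' @return a validated [SpikeDataset-class].
#' @export
readSession <- function(spikePath, trialPath) {
  spikes <- readSpikes(spikePath)
  trials <- readTrials(trialPath)
  new("SpikeDataset", neurons = names(spikes), spikes = spikes,
      trials = trials)
}

#' Write a SpikeDataset to spike and trial files
#'
#' @param ds a [SpikeDataset-class].
#' @param spikePath,trialPath output paths.
#' @return invisibly, a list of the two paths.
#' @export
writeSession <- function(ds, spikePath, trialPath) {
  writeSpikes(ds, spikePath)
  writeTrials(ds, trialPath)
  invisible(list(spikes = spikePath, trials = trialPath))
}

#' Write simulation ground truth as JSON
#'
#' Records the per-trial labels, the per-label module maps, the null flag
#' and an echo of the generator configuration.
#'
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  cfg <- truth@config
  out <- list(
    trial_labels = truth@trialLabels,
    module_maps = truth@moduleMaps,
    is_null = truth@isNull,
    expected_contrast = truth@expectedContrast,
    config = list(
      n_neurons = cfg@nNeurons, n_trials = cfg@nTrials,
      trial_duration_s = cfg@trialDuration, base_rate_hz = cfg@baseRate,
      common_event_rate_hz = cfg@commonEventRate,
      common_gain = cfg@commonGain, event_duration_s = cfg@eventDuration,
      sub_bin_s = cfg@subBinWidth, inter_trial_gap_s = cfg@interTrialGap,
      labels = cfg@labels, seed = cfg@seed))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a functional network as GraphML
#'
#' Positive-weight edges only (zero entries are absent edges).
#'
#' @param R symmetric weight matrix (e.g. one element of
#'   [networkList()]).
#' @param path output .graphml path.
#' @return \code{path}, invisibly.
#' @export
exportGraphML <- function(R, path) {
  checkWeightMatrix(R)
  g <- igraph::graph_from_adjacency_matrix(R, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Extract one trial's spike trains
#'
#' Restricts every neuron's spike train to the half-open trial window
#' [start, end). Neurons with no spikes in the window are kept as empty
#' vectors so that matrix dimensions agree across trials.
#'
#' @param ds a [SpikeDataset-class].
#' @param trial a trial id (character) or trial row index.
#' @return named list of numeric spike-time vectors (one per neuron).
#' @examples
#' sess <- simulateSession(simConfig(nTrials = 4, trialDuration = 4, seed = 1))
#' seg <- segmentTrial(sess$dataset, "t001")
#' @export
segmentTrial <- function(ds, trial) {
  if (!is(ds, "SpikeDataset")) validationError("ds must be a SpikeDataset")
  tr <- trialTable(ds)
  row <- if (is.character(trial)) match(trial, tr$trial_id) else as.integer(trial)
  if (is.na(row) || row < 1 || row > nrow(tr))
    validationError("trial not found in the dataset")
  a <- tr$start_s[row]; b <- tr$end_s[row]
  lapply(spikeTimes(ds), function(s) s[s >= a & s < b])
}
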
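#' Bin one trial's spike trains into counts
#'
#' Counts spikes of every neuron in consecutive non-overlapping windows of
#' \code{binWidth} seconds starting at the trial start. A trailing partial
#' window is discarded, so the number of bins is
#' \code{floor((end - start)/binWidth)}.
#'
#' @param segment named list of spike-time vectors (see [segmentTrial()]).
#' @param start,end trial window in seconds.
#' @param binWidth bin width in seconds (default 1, the analysis bin used
#'   throughout the package).
#' @return integer matrix, rows = neurons (named), columns = bins.
#' @examples
#' binCounts(list(a = c(0.1, 0.9, 1.1), b = numeric(0)), 0, 2)
#' @export
binCounts <- function(segment, start, end, binWidth = 1) {
  nBins <- floor((end - start) / binWidth)
  if (nBins < 2)
    validationError("trial too short: at least 2 full bins are required")
  counts <- t(vapply(segment, function(s) {
    idx <- floor((s - start) / binWidth) + 1
    tabulate(idx[idx >= 1 & idx <= nBins], nbins = nBins)
  }, integer(nBins)))
  rownames(counts) <- names(segment)
  counts
}

#' Pearson correlation with a zero-variance sentinel
#'
#' The product-moment correlation of two equal-length count vectors; when
#' either vector is constant (e.g. a silent neuron) the coefficient is
#' undefined and \code{NA} is returned, which [buildNetwork()] maps to
#' weight 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or NA if undefined.
#' @examples
#' pearsonWeight(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearsonWeight <- function(x, y) {
  if (length(x) != length(y))
    validationError("count vectors must have equal length")
  if (length(x) < 2)
    validationError("count vectors must have length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Build a weighted functional network from binned counts
#'
#' Edge weight between neurons x and y is their Pearson correlation of bin
#' counts when positive, else 0: negative coefficients are discarded (only
#' positive functional coupling is retained) and undefined coefficients
#' (zero-variance neurons) become 0. The weighted matrix is used directly;
#' no binary thresholding is applied. Diagonal is 0.
#'
#' @param counts matrix from [binCounts()]: rows = neurons, columns = bins
#'   (>= 2 of each).
#' @return symmetric matrix of weights in [0, 1], dimnames = neuron ids.
#' @export
buildNetwork <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) < 2)
    validationError("counts must be a matrix with >= 2 neurons")
  if (ncol(counts) < 2)
    validationError("counts must have >= 2 bins")
  R <- suppressWarnings(stats::cor(t(counts)))
  R[!is.finite(R)] <- 0
  R[R < 0] <- 0
  R[R > 1] <- 1
  diag(R) <- 0
  R <- (R + t(R)) / 2
  dimnames(R) <- list(rownames(counts), rownames(counts))
  R
}

#' Build the per-trial functional networks of a session
#'
#' Segments every trial, bins the spike counts and computes the weighted
#' functional network, returning one matrix per trial.
#'
#' @param ds a [SpikeDataset-class].
#' @param binWidth analysis bin width in seconds (default 1).
#' @return a [TrialNetworkSet-class] with representation "wnfn".
#' @examples
#' sess <- simulateSession(simConfig(nTrials = 4, trialDuration = 4, seed = 1))
#' nets <- buildNetworks(sess$dataset)
#' nets
#' @export
buildNetworks <- function(ds, binWidth = 1) {
  if (!is(ds, "SpikeDataset")) validationError("ds must be a SpikeDataset")
  tr <- trialTable(ds)
  nets <- lapply(seq_len(nrow(tr)), function(i) {
    seg <- segmentTrial(ds, i)
    buildNetwork(binCounts(seg, tr$start_s[i], tr$end_s[i], binWidth))
  })
  new("TrialNetworkSet", networks = nets, trialIds = tr$trial_id,
      labels = tr$label, binWidth = binWidth, representation = "wnfn")
}
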
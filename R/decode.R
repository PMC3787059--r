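## Group order used by both classifiers: the sorted unique labels of the
## full session, so group 1 is well defined independent of the training fold.

#' Pattern-matching prediction of one trial
#'
#' The test trial's similarity to each behavioral group is the mean of its
#' kernel similarities to all training trials of that group; the predicted
#' label is the group with maximal mean similarity. An exact tie goes to the
#' group with more training trials, then to group 1 (first label in sorted
#' order).
#'
#' @param sims numeric vector: similarities of the test trial to each
#'   training trial.
#' @param trainLabels labels of the training trials (both groups must be
#'   present); a factor fixes the group order, otherwise sorted unique
#'   values are used.
#' @return the predicted label.
#' @examples
#' matchPredict(c(0.9, 0.1, 0.6, 0.6), c("g1", "g1", "g2", "g2"))  # "g2"
#' @export
matchPredict <- function(sims, trainLabels) {
  f <- asTwoGroups(sims, trainLabels)
  m <- vapply(split(sims, f), mean, numeric(1))
  if (m[1] != m[2]) return(levels(f)[which.max(m)])
  n <- table(f)
  if (n[1] != n[2]) return(levels(f)[which.max(n)])
  levels(f)[1]
}

asTwoGroups <- function(sims, trainLabels) {
  if (length(sims) != length(trainLabels))
    validationError("sims and trainLabels must have equal length")
  f <- if (is.factor(trainLabels)) trainLabels else factor(trainLabels)
  if (nlevels(f) != 2)
    validationError("training labels must define exactly 2 groups")
  if (any(table(f) == 0))
    validationError("both groups need at least one training trial")
  f
}

#' k-nearest-neighbor prediction of one trial
#'
#' Takes the \code{min(k, n_train)} training trials most similar to the test
#' trial (similarity ties broken toward the lower trial index) and predicts
#' the majority label among them; an even split falls back to the
#' pattern-matching rule of [matchPredict()] on the full training set.
#'
#' @inheritParams matchPredict
#' @param k neighborhood size (default 7).
#' @return the predicted label.
#' @export
knnPredict <- function(sims, trainLabels, k = 7) {
  f <- asTwoGroups(sims, trainLabels)
  if (k < 1) validationError("k must be >= 1")
  kk <- min(k, length(sims))
  nb <- order(sims, decreasing = TRUE)[seq_len(kk)]   # stable: lower index first
  cnt <- table(f[nb])
  if (cnt[1] == cnt[2]) return(matchPredict(sims, f))
  levels(f)[which.max(cnt)]
}

#' Two-class classification score (sum of per-label correct fractions)
#'
#' The evaluation score used throughout the package:
#' \eqn{s = p_1 + p_2} with \eqn{p_j} the number of correctly
#' classified label-j trials divided by the total number of trials N. Note
#' that \eqn{p_1 + p_2} is algebraically the overall fraction correct; the
#' quantity is kept in its two-term form because the per-label terms are
#' reported separately in diagnostics. It is not the set-theoretic Jaccard
#' index.
#'
#' @param truth,predicted label vectors of equal length.
#' @return score in [0, 1]; 1 when all trials are correct, 0 when none are.
#' @examples
#' jaccardCoefficient(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 0.75
#' @export
jaccardCoefficient <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    validationError("label vectors must have equal length")
  N <- length(truth)
  groups <- sort(unique(as.character(truth)))
  sum(vapply(groups, function(g)
    sum(truth == g & predicted == truth) / N, numeric(1)))
}

#' Leave-one-out decoding of single-trial outcomes
#'
#' Each trial in turn is held out and predicted from the remaining N-1
#' trials (trained with their true labels); per-trial correctness and the
#' two-class score of [jaccardCoefficient()] are reported. The held-out
#' trial's self-similarity never enters the prediction.
#'
#' @param x a [TrialNetworkSet-class] (similarities are computed with
#'   \code{sigma}) or a [TrialSimilarity-class]/matrix.
#' @param labels true labels per trial; taken from the network set when
#'   omitted.
#' @param classifier "knn" (default) or "match".
#' @param k KNN neighborhood size (default 7).
#' @param sigma kernel scale used when \code{x} is a network set (default 4).
#' @return a [DecodingReport-class].
#' @examples
#' sess <- simulateSession(simConfig(nTrials = 10, trialDuration = 4, seed = 2))
#' rep <- looEvaluate(buildNetworks(sess$dataset))
#' jaccardValue(rep)
#' @export
looEvaluate <- function(x, labels = NULL, classifier = c("knn", "match"),
                        k = 7, sigma = 4) {
  classifier <- match.arg(classifier)
  repName <- "wnfn"; binWidth <- NA_real_; ids <- NULL
  if (is(x, "TrialNetworkSet")) {
    if (is.null(labels)) labels <- trialLabels(x)
    repName <- x@representation
    binWidth <- x@binWidth
    x <- trialSimilarity(x, sigma = sigma)
  }
  if (is(x, "TrialSimilarity")) {
    repName <- x@representation
    sigma <- x@sigma
    ids <- trialIds(x)
  }
  S <- asSimilarity(x)
  N <- nrow(S)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  if (is.null(labels)) validationError("labels are required")
  if (length(labels) != N)
    validationError("labels must match the number of trials")
  if (N < 4) validationError("at least 4 trials are required")
  if (length(unique(labels)) != 2)
    validationError("exactly 2 label values are required")
  f <- factor(labels)
  pred <- character(N)
  for (i in seq_len(N)) {
    sims <- S[i, -i]
    train <- f[-i]
    pred[i] <- if (classifier == "knn") knnPredict(sims, train, k = k)
               else matchPredict(sims, train)
  }
  truth <- as.character(labels)
  new("DecodingReport",
      perTrial = data.frame(trial_id = ids, true = truth, predicted = pred,
                            correct = pred == truth, stringsAsFactors = FALSE),
      jaccard = jaccardCoefficient(truth, pred),
      classifier = classifier,
      representation = repName,
      params = list(k = if (classifier == "knn") k else NULL,
                    sigma = sigma, binWidth = binWidth))
}

#' Serialize a decoding report as JSON
#'
#' @param report a [DecodingReport-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  out <- list(classifier = report@classifier,
              representation = report@representation,
              params = report@params[!vapply(report@params, is.null, TRUE)],
              jaccard = report@jaccard,
              per_trial = predictionTable(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
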
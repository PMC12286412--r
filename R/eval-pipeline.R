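## Evaluation pipeline: outlier removal, temporal split, SMOTE, PCA,
## repeated stratified cross-validation, permutation test and bias-variance
## decomposition.

#' Construct a FeatureTable directly from a matrix and labels
#'
#' Convenience constructor for pipeline inputs that did not come from a
#' season (simulations, toy fixtures). Samples default to one pseudo-player
#' with consecutive event indices so temporal splitting still works.
#'
#' @param features numeric sample-by-feature matrix.
#' @param labels binary 0/1 vector.
#' @param samples optional data.frame with `player_id` and `event_index`.
#' @return a [FeatureTable-class] with a `baseline_raw` variant tag.
#' @export
featureTable <- function(features, labels, samples = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (is.null(samples))
    samples <- data.frame(player_id = "sim",
                          event_index = seq_len(nrow(features)) - 1L)
  labels <- as.integer(labels)
  new("FeatureTable", features = features, labels = labels, samples = samples,
      variant = datasetVariantSpec("baseline_raw"),
      provenance = list(prevalence = mean(labels)))
}

#' Robust-PCA outlier detection
#'
#' Scores every row by its position relative to a robust principal subspace
#' of the feature matrix: the score distance (robust Mahalanobis distance of
#' the PCA scores, using a high-breakdown MCD covariance estimate) combined
#' with the orthogonal distance (residual norm off the subspace). The
#' `ceiling(reductionFactor * n)` highest-scoring rows are flagged as
#' outliers.
#'
#' @param table a [FeatureTable-class] or numeric matrix.
#' @param reductionFactor fraction of rows to remove, in \[0, 1).
#' @param seed integer seed (the MCD estimate subsamples).
#' @param nComponents subspace dimension; default the smallest number of
#'   components explaining 80% of variance, capped for stability.
#' @return logical retained-row mask of length n (`TRUE` = keep).
#' @export
detectOutliersRobustPCA <- function(table, reductionFactor, seed = 1L,
                                    nComponents = NULL) {
  x <- if (is(table, "FeatureTable")) featureMatrix(table) else as.matrix(table)
  n <- nrow(x)
  if (reductionFactor < 0 || reductionFactor >= 1)
    stop("reductionFactor must be in [0, 1)")
  if (reductionFactor == 0) return(rep(TRUE, n))
  nRemove <- ceiling(reductionFactor * n)

  center <- apply(x, 2L, stats::median)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc)
  ev <- sv$d^2
  keepRank <- ev > max(ev) * 1e-10
  ev <- ev[keepRank]
  q <- which(cumsum(ev) / sum(ev) >= 0.8)[1L]
  q <- max(1L, min(q, floor(n / 2) - 1L, sum(keepRank)))
  if (!is.null(nComponents)) q <- min(as.integer(nComponents), sum(keepRank))

  scores <- xc %*% sv$v[, seq_len(q), drop = FALSE]
  recon <- scores %*% t(sv$v[, seq_len(q), drop = FALSE])
  od <- sqrt(rowSums((xc - recon)^2))

  set.seed(seed)
  rob <- tryCatch(MASS::cov.rob(scores, method = "mcd"),
                  error = function(e) list(center = colMeans(scores),
                                           cov = stats::cov(scores)))
  covr <- rob$cov
  if (rcond(covr) < 1e-12) covr <- covr + diag(1e-8 * mean(diag(covr)), q)
  sd2 <- stats::mahalanobis(scores, rob$center, covr)
  normSD <- sqrt(sd2) / max(stats::median(sqrt(sd2)), .Machine$double.eps)
  normOD <- od / max(stats::median(od), .Machine$double.eps)
  combined <- normSD + normOD
  out <- order(combined, decreasing = TRUE)[seq_len(nRemove)]
  mask <- rep(TRUE, n)
  mask[out] <- FALSE
  mask
}

#' Temporal train/test split
#'
#' Splits in event order with no shuffling: the first
#' `floor(trainFraction * n)` rows form the training set, the remainder the
#' test set, which therefore retains the natural (late-season) class
#' prevalence. Rows must already be ordered by event index.
#'
#' @param table a [FeatureTable-class] whose rows are ordered in time.
#' @param trainFraction fraction of rows assigned to training.
#' @return list with elements `train` and `test` ([FeatureTable-class]).
#' @export
temporalSplit <- function(table, trainFraction = 0.8) {
  stopifnot(is(table, "FeatureTable"))
  ev <- sampleInfo(table)$event_index
  if (is.unsorted(ev))
    stop("rows are not ordered by event index; temporal split undefined")
  n <- nrow(featureMatrix(table))
  nTrain <- floor(trainFraction * n)
  if (nTrain < 1L || nTrain >= n)
    stop("trainFraction leaves an empty train or test set")
  list(train = .subsetFeatureTable(table, seq_len(nTrain)),
       test = .subsetFeatureTable(table, (nTrain + 1L):n))
}

#' SMOTE oversampling of the minority class
#'
#' Balances the training table by synthetic minority oversampling: each
#' synthetic sample is a convex combination of a random minority row and one
#' of its `kNeighbors` nearest minority-class neighbors (Euclidean).
#' Originals are preserved; synthetic rows are appended with the pseudo
#' player id `"SMOTE"`.
#'
#' @param table a [FeatureTable-class] containing both classes.
#' @param kNeighbors number of minority neighbors to interpolate towards.
#' @param seed integer seed.
#' @return a class-balanced [FeatureTable-class].
#' @export
oversampleSMOTE <- function(table, kNeighbors = 5L, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  x <- featureMatrix(table)
  y <- featureLabels(table)
  minority <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idxMin <- which(y == minority)
  nNeed <- abs(sum(y == 1L) - sum(y == 0L))
  if (nNeed == 0L) return(table)
  if (length(idxMin) < kNeighbors + 1L)
    stop("minority class has ", length(idxMin), " rows; need at least ",
         kNeighbors + 1L, " -- use a smaller kNeighbors")
  xm <- x[idxMin, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(r) order(r)[seq_len(kNeighbors)])
  nn <- if (is.null(dim(nn))) matrix(nn, ncol = 1L) else t(nn)

  set.seed(seed)
  base <- sample.int(length(idxMin), nNeed, replace = TRUE)
  pick <- nn[cbind(base, sample.int(kNeighbors, nNeed, replace = TRUE))]
  tt <- stats::runif(nNeed)
  synth <- xm[base, , drop = FALSE] +
    tt * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])

  features <- rbind(x, synth)
  labels <- c(y, rep(minority, nNeed))
  samples <- rbind(sampleInfo(table),
                   data.frame(player_id = "SMOTE",
                              event_index = rep(NA_integer_, nNeed)))
  rownames(samples) <- NULL
  new("FeatureTable", features = features, labels = as.integer(labels),
      samples = samples, variant = table@variant,
      provenance = utils::modifyList(table@provenance,
                                     list(prevalence = mean(labels),
                                          smote_k = kNeighbors)))
}

#' PCA dimensionality reduction at a cumulative variance threshold
#'
#' Principal components are fitted on the training features only (centered
#' by the train column means, deliberately without standardization) and the
#' test set is projected with the train transform -- no leakage of test
#' covariance. The number of components `m` is the smallest count whose
#' cumulative explained variance reaches `varianceThreshold`.
#'
#' @param train,test [FeatureTable-class] objects sharing the feature space.
#' @param varianceThreshold cumulative explained-variance target in (0, 1].
#' @return list with `train`, `test` (reduced [FeatureTable-class]s),
#'   `nComponents` and the `explainedVariance` spectrum.
#' @export
pcaReduce <- function(train, test, varianceThreshold = 0.95) {
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stop("varianceThreshold must be in (0, 1]")
  xtr <- featureMatrix(train)
  xte <- featureMatrix(test)
  center <- colMeans(xtr)
  xc <- sweep(xtr, 2L, center)
  sv <- svd(xc)
  ev <- sv$d^2 / max(nrow(xtr) - 1L, 1L)
  ev[ev < max(ev) * 1e-12] <- 0
  prop <- ev / sum(ev)
  m <- which(cumsum(prop) >= varianceThreshold - 1e-12)[1L]
  rot <- sv$v[, seq_len(m), drop = FALSE]
  reduce <- function(tab, x) {
    z <- sweep(x, 2L, center) %*% rot
    colnames(z) <- paste0("PC", seq_len(m))
    new("FeatureTable", features = z, labels = featureLabels(tab),
        samples = sampleInfo(tab), variant = tab@variant,
        provenance = utils::modifyList(tab@provenance,
                                       list(pca_components = m)))
  }
  list(train = reduce(train, xtr), test = reduce(test, xte),
       nComponents = m, explainedVariance = prop)
}

## Stratified fold assignment: within each class, shuffle and deal
## round-robin, so per-fold class counts differ by at most one sample.
.stratifiedFolds <- function(y, folds) {
  out <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `repeats` independent stratified `folds`-fold splits (default the
#' 10x2 scheme), fitting `spec` on each fold complement and recording the
#' six metrics of [computeMetrics()] on both the fitted fold (training
#' metrics) and the held-out fold (validation metrics).
#'
#' @param table a [FeatureTable-class].
#' @param spec a [ModelSpec-class].
#' @param repeats number of repetitions.
#' @param folds number of folds per repetition.
#' @param seed integer seed governing the fold shuffles.
#' @return list with data.frames `validation` and `training`
#'   (`repeats * folds` rows, one column per metric plus `repeat_` and
#'   `fold`).
#' @export
crossValidate <- function(table, spec, repeats = 10L, folds = 2L, seed = 1L) {
  stopifnot(is(table, "FeatureTable"), is(spec, "ModelSpec"))
  x <- featureMatrix(table)
  y <- featureLabels(table)
  if (sum(y == 1L) < folds)
    stop("need at least ", folds, " positive samples for ", folds, "-fold CV")
  rows <- list(validation = NULL, training = NULL)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold <- .stratifiedFolds(y, folds)
    for (f in seq_len(folds)) {
      hold <- fold == f
      sc <- fitPredict(spec, x[!hold, , drop = FALSE], y[!hold],
                       rbind(x[!hold, , drop = FALSE],
                             x[hold, , drop = FALSE]))
      nTr <- sum(!hold)
      mTr <- computeMetrics(sc[seq_len(nTr)], y[!hold])
      mVa <- computeMetrics(sc[-seq_len(nTr)], y[hold])
      rows$training <- rbind(rows$training,
                             data.frame(repeat_ = r, fold = f, t(mTr)))
      rows$validation <- rbind(rows$validation,
                               data.frame(repeat_ = r, fold = f, t(mVa)))
    }
  }
  rows
}

#' Summarize a cross-validation metric distribution
#'
#' Mean and t-based confidence interval per metric column.
#'
#' @param cvResult the `validation` (or `training`) data.frame from
#'   [crossValidate()].
#' @param level confidence level.
#' @return data.frame with one row per metric: mean, low, high, n.
#' @export
summarizeMetrics <- function(cvResult, level = 0.95) {
  metricCols <- setdiff(names(cvResult), c("repeat_", "fold"))
  out <- lapply(metricCols, function(mc) {
    v <- cvResult[[mc]]
    v <- v[is.finite(v)]
    ci <- confidenceIntervalT(v, level)
    data.frame(metric = mc, mean = ci[["mean"]], low = ci[["low"]],
               high = ci[["high"]], n = length(v))
  })
  do.call(rbind, out)
}

#' Label-permutation significance test for a pipeline metric
#'
#' Recomputes `pipeline(features, labels)` under `nPermutations` random
#' label permutations and reports the add-one p-value
#' p = (1 + #\{null >= observed\}) / (nPermutations + 1).
#'
#' @param pipeline function(features, labels) returning a scalar metric
#'   (larger = better); must be deterministic given its own seeding.
#' @param table a [FeatureTable-class].
#' @param nPermutations number of label permutations, >= 1.
#' @param seed integer seed for the permutations.
#' @return list with `p.value`, `observed` and the `null` metric vector.
#' @export
permutationTest <- function(pipeline, table, nPermutations = 1000L,
                            seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  x <- featureMatrix(table)
  y <- featureLabels(table)
  observed <- pipeline(x, y)
  null <- numeric(nPermutations)
  set.seed(seed)
  perms <- replicate(nPermutations, sample(y), simplify = FALSE)
  for (b in seq_len(nPermutations)) null[b] <- pipeline(x, perms[[b]])
  list(p.value = (1 + sum(null >= observed)) / (nPermutations + 1),
       observed = observed, null = null)
}

#' Bias-variance decomposition of the 0-1 loss under bootstrap resampling
#'
#' Fits `spec` on `nBootstrap` bootstrap resamples of the training table and
#' scores the test table each time (threshold 0.5). The main prediction is
#' the per-test-point majority vote; bias is the 0-1 loss of the main
#' prediction against the truth, variance the mean disagreement of the
#' resample predictions with the main prediction, and the expected loss the
#' mean per-resample 0-1 loss. Degenerate (single-class) resamples are
#' redrawn with a capped number of retries.
#'
#' @param spec a [ModelSpec-class].
#' @param train,test [FeatureTable-class] objects.
#' @param nBootstrap number of bootstrap resamples.
#' @param seed integer seed.
#' @return list with `expected_loss`, `bias`, `variance` (all in \[0, 1\])
#'   and the per-resample `losses` vector.
#' @export
biasVarianceDecompose <- function(spec, train, test, nBootstrap = 200L,
                                  seed = 1L) {
  x <- featureMatrix(train); y <- featureLabels(train)
  xt <- featureMatrix(test); yt <- featureLabels(test)
  if (length(unique(y)) < 2L) stop("training table must contain both classes")
  n <- nrow(x)
  preds <- matrix(NA_integer_, nrow = nBootstrap, ncol = nrow(xt))
  ## resample indices are drawn up front so the classifier's own seeding
  ## cannot perturb the bootstrap stream
  set.seed(seed)
  resamples <- lapply(seq_len(nBootstrap), function(b) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) return(idx)
    }
    stop("could not draw a two-class bootstrap resample")
  })
  for (b in seq_len(nBootstrap)) {
    idx <- resamples[[b]]
    sc <- fitPredict(spec, x[idx, , drop = FALSE], y[idx], xt)
    preds[b, ] <- as.integer(sc >= 0.5)
  }
  main <- as.integer(colMeans(preds) >= 0.5)
  losses <- rowMeans(preds != matrix(yt, nrow = nBootstrap, ncol = length(yt),
                                     byrow = TRUE))
  list(expected_loss = mean(losses),
       bias = mean(main != yt),
       variance = mean(rowMeans(preds != matrix(main, nrow = nBootstrap,
                                                ncol = length(main),
                                                byrow = TRUE))),
       losses = losses)
}
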
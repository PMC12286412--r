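## Thin uniform wrappers over the eight classifier families. Each fit
## returns positive-class scores on new data; every stochastic family is
## seeded explicitly so whole-pipeline runs are reproducible.

#' Construct a model specification
#'
#' @param family one of `"LDA"`, `"LR"`, `"NB"`, `"KNN"`, `"SVM"`, `"CART"`,
#'   `"RF"`, `"MLP"`. `"LR"` is fitted as a binomial GLM (logistic
#'   regression); `"SVM"` uses the bounded radial kernel.
#' @param hyperparameters named list overriding the library-standard
#'   defaults (`k` for KNN; `size`, `decay`, `maxit` for MLP; `ntree` for
#'   RF; `cost`, `gamma` for SVM; `cp` for CART).
#' @param seed integer seed applied before each stochastic fit.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(family, hyperparameters = list(), seed = 1L) {
  new("ModelSpec", family = family, hyperparameters = hyperparameters,
      seed = as.integer(seed))
}

.hp <- function(spec, name, default) {
  v <- spec@hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Fit a classifier and score new samples
#'
#' Fits `spec@family` on the training matrix and returns continuous
#' positive-class scores for `testX` (probabilities for all families; the
#' vote fraction for KNN).
#'
#' @param spec a [ModelSpec-class].
#' @param trainX,trainY training feature matrix and 0/1 labels (both classes
#'   required).
#' @param testX matrix of samples to score.
#' @return numeric score vector, one per row of `testX`.
#' @export
fitPredict <- function(spec, trainX, trainY, testX) {
  stopifnot(is(spec, "ModelSpec"))
  trainY <- as.integer(trainY)
  if (length(unique(trainY)) < 2L)
    stop("training data must contain both classes")
  yf <- factor(trainY, levels = c(0L, 1L))
  trainX <- as.matrix(trainX)
  testX <- as.matrix(testX, ncol = ncol(trainX))
  colnames(trainX) <- colnames(testX) <- paste0("f", seq_len(ncol(trainX)))
  trdf <- data.frame(trainX)
  tedf <- data.frame(testX)
  set.seed(spec@seed)
  switch(spec@family,
    LDA = {
      fit <- MASS::lda(trainX, grouping = yf)
      as.numeric(stats::predict(fit, testX)$posterior[, "1"])
    },
    LR = {
      dat <- cbind(trdf, .y = yf)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                         family = stats::binomial()))
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = tedf, type = "response")))
    },
    NB = {
      fit <- e1071::naiveBayes(trainX, yf)
      as.numeric(stats::predict(fit, testX, type = "raw")[, "1"])
    },
    KNN = {
      k <- .hp(spec, "k", 5L)
      pred <- class::knn(trainX, testX, cl = yf, k = k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    SVM = {
      fit <- e1071::svm(trainX, yf, kernel = "radial",
                        cost = .hp(spec, "cost", 1),
                        gamma = .hp(spec, "gamma", 1 / ncol(trainX)),
                        probability = TRUE)
      pr <- stats::predict(fit, testX, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    CART = {
      dat <- cbind(trdf, .y = yf)
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                          cp = .hp(spec, "cp", 0.01))
      as.numeric(stats::predict(fit, newdata = tedf, type = "prob")[, "1"])
    },
    RF = {
      fit <- randomForest::randomForest(trainX, yf,
                                        ntree = .hp(spec, "ntree", 500L))
      as.numeric(stats::predict(fit, testX, type = "prob")[, "1"])
    },
    MLP = {
      fit <- nnet::nnet(trainX, as.numeric(trainY),
                        size = .hp(spec, "size", 5L),
                        decay = .hp(spec, "decay", 0.01),
                        maxit = .hp(spec, "maxit", 200L),
                        trace = FALSE)
      as.numeric(stats::predict(fit, testX))
    },
    stop("unknown family: ", spec@family)
  )
}
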
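# Backpropagation SPAD inversion: a single-hidden-layer feed-forward network
# trained by full-batch gradient descent on mean squared error, plus the
# evaluation metrics and the replicated 70/30 fitting protocol.

actFun <- function(name) switch(name,
  tanh = list(f = tanh, df = function(a) 1 - a^2),
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 df = function(a) a * (1 - a)),
  stopf("unknown activation '%s'", name))

#' Train the backpropagation inversion model
#'
#' Standardizes features and target by their training statistics, initializes
#' weights from a seeded scaled-uniform distribution, and runs full-batch
#' gradient descent on the mean-squared-error loss for the stated number of
#' epochs at the stated learning rate (defaults 50 epochs, learning rate
#' 0.001, 18 tanh hidden units, linear output).
#'
#' @param features numeric matrix/data.frame (rows = samples, named columns).
#' @param spad numeric target vector.
#' @param nHidden hidden units (default 18).
#' @param learningRate gradient-descent step size (default 0.001).
#' @param epochs full-batch passes (default 50).
#' @param activation "tanh" (default) or "sigmoid".
#' @param seed weight-initialization seed.
#' @return A \linkS4class{SpadInversionModel}.
#' @export
trainInversionModel <- function(features, spad, nHidden = 18,
                                learningRate = 0.001, epochs = 50,
                                activation = c("tanh", "sigmoid"),
                                seed = 1) {
  activation <- match.arg(activation)
  x <- as.matrix(as.data.frame(features))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) < 20) stopf("need >= 20 training samples, got %d", nrow(x))
  if (nrow(x) != length(spad)) stopf("features and spad lengths differ")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl <= 0))
    stopf("constant feature column(s): %s",
          paste(colnames(x)[scl <= 0], collapse = ", "))
  yc <- mean(spad)
  ys <- stats::sd(spad)
  constantTarget <- ys <= 0
  if (constantTarget) ys <- 1
  Xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ys0 <- (spad - yc) / ys
  n <- nrow(Xs); p <- ncol(Xs)
  act <- actFun(activation)

  withSeed(seed, {
    W1 <- matrix(stats::runif(p * nHidden, -1, 1) / sqrt(p), p, nHidden)
    b1 <- numeric(nHidden)
    W2 <- stats::runif(nHidden, -1, 1) / sqrt(nHidden)
    b2 <- 0
  })

  if (constantTarget) {
    # degenerate target: the MSE optimum (all outputs at the target) is
    # known in closed form, which gradient descent only approaches
    # asymptotically; return it exactly
    W2[] <- 0
    b2 <- 0
    return(new("SpadInversionModel", featureNames = colnames(x),
               center = ctr, scale = scl, yCenter = yc, yScale = ys,
               W1 = W1, b1 = b1, W2 = W2, b2 = b2,
               activation = activation,
               hyperparams = list(learningRate = learningRate,
                                  epochs = epochs, nHidden = nHidden),
               seed = seed, loss = rep(0, epochs)))
  }

  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    A <- act$f(Xs %*% W1 + matrix(b1, n, nHidden, byrow = TRUE))
    pred <- drop(A %*% W2) + b2
    err <- pred - ys0
    loss[e] <- mean(err^2)
    if (!is.finite(loss[e]))
      stopf("training diverged (non-finite loss) at epoch %d", e)
    dPred <- 2 * err / n
    dW2 <- drop(crossprod(A, dPred))
    db2 <- sum(dPred)
    dA <- outer(dPred, W2) * act$df(A)
    dW1 <- crossprod(Xs, dA)
    db1 <- colSums(dA)
    W1 <- W1 - learningRate * dW1
    b1 <- b1 - learningRate * db1
    W2 <- W2 - learningRate * dW2
    b2 <- b2 - learningRate * db2
  }
  new("SpadInversionModel", featureNames = colnames(x), center = ctr,
      scale = scl, yCenter = yc, yScale = ys, W1 = W1, b1 = b1,
      W2 = W2, b2 = b2, activation = activation,
      hyperparams = list(learningRate = learningRate, epochs = epochs,
                         nHidden = nHidden),
      seed = seed, loss = loss)
}

#' Predict SPAD from vegetation indices
#'
#' Deterministic forward pass of the trained network; features are matched by
#' name and standardized with the model's stored training statistics.
#'
#' @param model a \linkS4class{SpadInversionModel}.
#' @param features matrix/data.frame containing the model's feature columns.
#' @return Numeric vector of predicted SPAD values.
#' @export
predictSpad <- function(model, features) {
  x <- as.data.frame(features)
  missing <- setdiff(model@featureNames, names(x))
  if (length(missing))
    stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
  x <- as.matrix(x[, model@featureNames, drop = FALSE])
  Xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  act <- actFun(model@activation)
  A <- act$f(Xs %*% model@W1 +
             matrix(model@b1, nrow(Xs), length(model@b1), byrow = TRUE))
  pred <- drop(A %*% model@W2) + model@b2
  out <- pred * model@yScale + model@yCenter
  if (!all(is.finite(out))) stopf("non-finite predictions")
  out
}

#' Prediction accuracy metrics
#'
#' r = Pearson correlation, R2 = r^2, RMSE = root mean squared error, RE =
#' mean absolute relative error mean(|pred - obs| / |obs|). A secondary
#' coefficient-of-determination R2 (1 - SSres/SStot) and the RMSE on the
#' scale of standardized observations are also reported.
#'
#' @param obs,pred equal-length numeric vectors, n >= 3.
#' @return Named list: r, R2, RMSE, RE, R2cod, RMSEstd. When either vector
#'   has zero variance, r and R2 are NA (flagged, not fabricated).
#' @examples
#' evaluatePredictions(c(1, 2, 3), c(2, 3, 4))  # r = 1, RMSE = 1, RE = 11/18
#' @export
evaluatePredictions <- function(obs, pred) {
  if (length(obs) != length(pred)) stopf("obs and pred lengths differ")
  if (length(obs) < 3) stopf("need n >= 3")
  r <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) NA_real_
       else stats::cor(obs, pred)
  rmse <- sqrt(mean((pred - obs)^2))
  re <- mean(abs(pred - obs) / abs(obs))
  sst <- sum((obs - mean(obs))^2)
  r2cod <- if (sst == 0) NA_real_ else 1 - sum((pred - obs)^2) / sst
  list(r = r, R2 = r^2, RMSE = rmse, RE = re, R2cod = r2cod,
       RMSEstd = if (stats::sd(obs) > 0) rmse / stats::sd(obs) else NA_real_)
}

#' Replicated 70/30 fitting protocol
#'
#' Repeats the train/validate cycle over independent random splits (default
#' 8 replicates at a 70\% training fraction: 84 training / 35 validation
#' samples at n = 119) and reports per-replicate validation metrics plus
#' their mean. A "restart" mode re-initializes weights on one fixed split
#' instead of re-splitting.
#'
#' @param features,spad training data (see
#'   \code{\link{trainInversionModel}}).
#' @param nReplicates number of replicates (default 8).
#' @param trainFraction training fraction (default 0.7; the validation size
#'   is floor(n x (1 - trainFraction))).
#' @param seed split/initialization seed.
#' @param mode "resplit" (default) or "restart".
#' @param ... passed to \code{\link{trainInversionModel}}.
#' @return data.frame with one row per replicate: replicate, nTrain, nVal,
#'   r, R2, RMSE, RE, R2cod, RMSEstd; attribute \code{means} holds the
#'   column means, attribute \code{splits} the validation index sets.
#' @export
replicateFit <- function(features, spad, nReplicates = 8,
                         trainFraction = 0.7, seed = 1,
                         mode = c("resplit", "restart"), ...) {
  mode <- match.arg(mode)
  x <- as.data.frame(features)
  n <- nrow(x)
  if (n < 10) stopf("need n >= 10, got %d", n)
  nVal <- floor(n * (1 - trainFraction))
  if (nVal < 3) stopf("validation split too small")
  splits <- withSeed(seed, {
    lapply(seq_len(nReplicates), function(i) sort(sample.int(n, nVal)))
  })
  if (mode == "restart") splits <- rep(splits[1], nReplicates)
  rows <- lapply(seq_len(nReplicates), function(i) {
    val <- splits[[i]]
    fit <- trainInversionModel(x[-val, , drop = FALSE], spad[-val],
                               seed = seed + i, ...)
    m <- evaluatePredictions(spad[val],
                             predictSpad(fit, x[val, , drop = FALSE]))
    data.frame(replicate = i, nTrain = n - nVal, nVal = nVal,
               r = m$r, R2 = m$R2, RMSE = m$RMSE, RE = m$RE,
               R2cod = m$R2cod, RMSEstd = m$RMSEstd)
  })
  report <- do.call(rbind, rows)
  structure(report, means = colMeans(report[, -1], na.rm = TRUE),
            splits = splits)
}
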
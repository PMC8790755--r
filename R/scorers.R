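#' @include synthcomplex.R
NULL

# Compact 3D CNN shared by all tasks: three 3x3x3 convolutions with stride 2
# (each halves the spatial side; 16 -> 32 -> 64 -> 64 feature maps), ReLU,
# then a dense head on the flattened conv features (32-unit ReLU layer and a
# linear scalar output). The fully connected head keeps per-position weights
# so Integrated Gradients stay spatially resolved; pooling heads smear them.
.DEFAULT_CONV <- c(16L, 32L, 64L, 64L)
.DEFAULT_HIDDEN <- 32L

.gridVector <- function(grid) {
  if (is(grid, "VolumeGrid")) as.numeric(gridValues(grid)) else as.numeric(grid)
}

#' Build an untrained scorer
#'
#' Initializes the compact 3D CNN (He-scaled Gaussian weights, zero biases)
#' for a 16-channel cubic grid. Initialization is deterministic given
#' `seed`.
#'
#' @param task "clash", "pose" or "regression".
#' @param scheme channel scheme data.frame (must have 16 channels; see
#'   [channelScheme()]).
#' @param seed integer seed for the weight initialization.
#' @param size grid side in voxels (default 24).
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @return an untrained [TrainedScorer].
#' @export
buildScorer <- function(task = c("clash", "pose", "regression"),
                        scheme = channelScheme(), seed = 1,
                        size = 24L, spacing = 1.0) {
  task <- match.arg(task)
  if (nrow(scheme) != 16L)
    stop("channel scheme must have exactly 16 channels")
  size <- as.integer(size)
  arch <- list(n = size, conv = .DEFAULT_CONV, hidden = .DEFAULT_HIDDEN,
               spacing = spacing)
  nPar <- cnn_n_params_cpp(size, arch$conv, arch$hidden)
  params <- .withSeed(seed, .initParams(arch))
  stopifnot(length(params) == nPar)
  new("TrainedScorer", task = task, kind = "cnn", params = params,
      arch = arch, trainConfig = list(initSeed = seed),
      metrics = list(),
      fingerprint = schemeFingerprint(scheme$name, size, spacing),
      trained = FALSE)
}

# He-style init matching the C++ parameter layout: per conv layer W then b,
# then the dense head on the flattened conv features.
.initParams <- function(arch) {
  p <- numeric(0)
  conv <- arch$conv
  nLayers <- length(conv) - 1
  for (l in seq_len(nLayers)) {
    fanIn <- conv[l] * 27
    p <- c(p, rnorm(fanIn * conv[l + 1], sd = sqrt(2 / fanIn)),
           numeric(conv[l + 1]))
  }
  feat <- conv[length(conv)] * (arch$n / 2^nLayers)^3
  p <- c(p, rnorm(feat * arch$hidden, sd = sqrt(2 / feat)),
         numeric(arch$hidden),
         rnorm(arch$hidden, sd = sqrt(1 / arch$hidden)), 0)
  p
}

#' Linear scorer
#'
#' A scorer whose output is `sum(w * x) + b`. Its path integral is exact for
#' any number of steps, which makes it the reference case for the
#' Integrated Gradients completeness property.
#'
#' @param weights numeric vector or array of length 16 * size^3
#'   (channels-last layout).
#' @param bias scalar offset.
#' @param size grid side (inferred from `weights` when omitted).
#' @param spacing grid spacing in Angstrom.
#' @param task nominal task label (default "regression").
#' @return a [TrainedScorer] of kind "linear".
#' @export
linearScorer <- function(weights, bias = 0, size = NULL, spacing = 1.0,
                         task = "regression") {
  weights <- as.numeric(weights)
  if (is.null(size)) {
    size <- round((length(weights) / 16)^(1 / 3))
    if (16 * size^3 != length(weights))
      stop("weights length is not 16 * N^3")
  }
  new("TrainedScorer", task = task, kind = "linear",
      params = c(weights, bias),
      arch = list(n = as.integer(size), spacing = spacing),
      trainConfig = list(), metrics = list(),
      fingerprint = schemeFingerprint(channelScheme()$name, size, spacing),
      trained = TRUE)
}

.checkGridCompat <- function(scorer, grid) {
  if (is(grid, "VolumeGrid")) {
    fp <- schemeFingerprint(gridChannels(grid), gridSide(grid),
                            gridSpacing(grid))
    if (!identical(fp, scorer@fingerprint))
      stop("grid channel scheme/geometry does not match the scorer ",
           "fingerprint; refusing to score/attribute")
  } else if (length(as.numeric(grid)) != 16 * scorer@arch$n^3) {
    stop("input length does not match the scorer's grid size")
  }
  invisible(TRUE)
}

#' @describeIn scorerForward CNN or linear forward pass (scalar).
#' @export
setMethod("scorerForward", "TrainedScorer", function(scorer, grid) {
  .checkGridCompat(scorer, grid)
  x <- .gridVector(grid)
  if (scorer@kind == "linear") {
    np <- length(scorer@params)
    sum(scorer@params[-np] * x) + scorer@params[np]
  } else {
    cnn_forward_cpp(x, scorer@params, scorer@arch$n, scorer@arch$conv,
                    scorer@arch$hidden)
  }
})

#' @describeIn scorerInputGradient gradient for CNN or linear scorers.
#' @export
setMethod("scorerInputGradient", "TrainedScorer", function(scorer, grid) {
  .checkGridCompat(scorer, grid)
  x <- .gridVector(grid)
  if (scorer@kind == "linear") {
    scorer@params[-length(scorer@params)]
  } else {
    cnn_grad_cpp(x, scorer@params, scorer@arch$n, scorer@arch$conv,
                 scorer@arch$hidden, TRUE, FALSE)$inputGrad
  }
})

# Stack grids (or complexes, voxelized on the fly) into a D x n matrix.
.gridMatrix <- function(grids, scorer) {
  D <- 16 * scorer@arch$n^3
  X <- matrix(0, nrow = D, ncol = length(grids))
  for (j in seq_along(grids)) {
    g <- grids[[j]]
    if (is(g, "ComplexStructure"))
      g <- voxelize(g, size = scorer@arch$n, spacing = scorer@arch$spacing)
    .checkGridCompat(scorer, g)
    X[, j] <- .gridVector(g)
  }
  X
}

#' Train a scorer by mini-batch gradient descent
#'
#' Adam on the logistic loss of the logit (classification) or squared error
#' (regression), with a fixed seed-determined train/validation split, early
#' stopping on validation loss, and held-out metrics recorded on the
#' validation fold.
#'
#' @param scorer an untrained [TrainedScorer] (kind "cnn").
#' @param grids list of [VoxelGrid] (or [ComplexStructure], voxelized on the
#'   fly).
#' @param labels numeric vector: 0/1 for classification (positive class 1 =
#'   clashed / good pose), real values for regression.
#' @param valFraction held-out fraction (default 0.2).
#' @param epochs maximum epochs (default 30).
#' @param batch mini-batch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience early-stopping patience in epochs (default 3).
#' @param minEpochs warmup epochs before early stopping may trigger
#'   (default 8).
#' @param seed seed for the split and shuffling (default 1).
#' @return the trained [TrainedScorer] with `scorerMetrics()` filled in.
#' @export
trainScorer <- function(scorer, grids, labels, valFraction = 0.2,
                        epochs = 30L, batch = 16L, lr = 1e-3,
                        patience = 3L, minEpochs = 8L, seed = 1) {
  stopifnot(is(scorer, "TrainedScorer"))
  if (scorer@kind != "cnn") stop("only CNN scorers are trainable")
  n <- length(grids)
  if (n != length(labels)) stop("grids and labels lengths differ")
  if (!all(is.finite(labels))) stop("labels must be finite")
  classif <- scorer@task %in% c("clash", "pose")
  if (classif && length(unique(labels)) < 2)
    stop("degenerate classification: need both classes present")

  X <- .gridMatrix(grids, scorer)
  valIdx <- .withSeed(seed, sort(sample.int(n, max(1L, round(valFraction * n)))))
  trIdx <- setdiff(seq_len(n), valIdx)
  if (classif && length(unique(labels[trIdx])) < 2)
    stop("degenerate split: training fold has a single class")

  fit <- cnn_train_cpp(X[, trIdx, drop = FALSE], labels[trIdx],
                       X[, valIdx, drop = FALSE], labels[valIdx],
                       scorer@params, scorer@arch$n, scorer@arch$conv,
                       scorer@arch$hidden,
                       if (classif) "class" else "reg",
                       as.integer(epochs), as.integer(batch), lr,
                       as.integer(patience), as.integer(minEpochs),
                       as.integer(seed))
  if (isTRUE(fit$diverged))
    stop("training diverged (loss not finite); config: epochs=", epochs,
         ", batch=", batch, ", lr=", lr, ", seed=", seed)

  scorer@params <- as.numeric(fit$params)
  scorer@trained <- TRUE
  scorer@trainConfig <- c(scorer@trainConfig,
                          list(epochs = epochs, batch = batch, lr = lr,
                               patience = patience, minEpochs = minEpochs,
                               seed = seed,
                               valFraction = valFraction,
                               epochsRun = fit$epochsRun,
                               bestEpoch = fit$bestEpoch))

  zval <- cnn_forward_batch_cpp(X[, valIdx, drop = FALSE], scorer@params,
                                scorer@arch$n, scorer@arch$conv,
                                scorer@arch$hidden)
  if (classif) {
    m <- .classMetrics(zval, labels[valIdx])
    scorer@metrics <- list(accuracy = m$accuracy, precision = m$precision,
                           nHeldOut = length(valIdx),
                           valLoss = fit$bestValLoss)
  } else {
    r <- if (length(valIdx) >= 3 && stats::sd(zval) > 0 &&
             stats::sd(labels[valIdx]) > 0)
      stats::cor(zval, labels[valIdx]) else NA_real_
    scorer@metrics <- list(pearson_r = r, rmse = sqrt(mean((zval - labels[valIdx])^2)),
                           nHeldOut = length(valIdx), valLoss = fit$bestValLoss)
  }
  scorer
}

.classMetrics <- function(logits, labels, threshold = 0) {
  pred <- as.numeric(logits > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  list(accuracy = mean(pred == labels),
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}

#' Evaluate a binary classifier on labelled grids
#'
#' Predictions use threshold 0 on the logit. When no positive predictions
#' exist, precision is reported as NA (undefined), not 0.
#'
#' @param scorer a trained classification [TrainedScorer].
#' @param grids list of [VoxelGrid] or [ComplexStructure].
#' @param labels 0/1 labels (1 = positive class).
#' @return list with `accuracy` and `precision`.
#' @export
evaluateClassifier <- function(scorer, grids, labels) {
  if (length(grids) == 0) stop("empty input")
  if (length(grids) != length(labels)) stop("grids and labels lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  X <- .gridMatrix(grids, scorer)
  z <- if (scorer@kind == "cnn") {
    cnn_forward_batch_cpp(X, scorer@params, scorer@arch$n,
                          scorer@arch$conv, scorer@arch$hidden)
  } else {
    np <- length(scorer@params)
    as.numeric(crossprod(X, scorer@params[-np])) + scorer@params[np]
  }
  .classMetrics(z, labels)
}

#' Save / load a scorer checkpoint
#'
#' Single-file JSON checkpoint embedding the architecture, parameters,
#' training configuration, metrics and the channel-scheme fingerprint.
#' [integratedGradients()] and [scorerForward()] refuse grids whose
#' fingerprint does not match the checkpoint's.
#'
#' @param scorer a [TrainedScorer].
#' @param path file path.
#' @export
saveScorer <- function(scorer, path) {
  obj <- list(task = scorer@task, kind = scorer@kind,
              params = scorer@params, arch = scorer@arch,
              trainConfig = scorer@trainConfig, metrics = scorer@metrics,
              fingerprint = scorer@fingerprint, trained = scorer@trained,
              format = "voxattrib-scorer-v1")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveScorer
#' @export
loadScorer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "voxattrib-scorer-v1"))
    stop("not a voxattrib scorer checkpoint: ", path)
  arch <- obj$arch
  arch$n <- as.integer(arch$n)
  if (!is.null(arch$conv)) arch$conv <- as.integer(arch$conv)
  if (!is.null(arch$hidden)) arch$hidden <- as.integer(arch$hidden)
  new("TrainedScorer", task = obj$task, kind = obj$kind,
      params = as.numeric(obj$params), arch = arch,
      trainConfig = as.list(obj$trainConfig), metrics = as.list(obj$metrics),
      fingerprint = obj$fingerprint, trained = isTRUE(obj$trained))
}
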
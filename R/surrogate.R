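# Neural surrogate for diffuse reflectance: preprocessing, architecture,
# training (compiled AdamW core), prediction, and fidelity metrics.

#' Spectrum-level dataset split
#'
#' Partitions spectrum ids into train/validation/test groups so that all
#' wavelengths belonging to one spectrum land in the same split, preventing
#' leakage across wavelengths of the same parameter set.
#'
#' @param spectrum_ids vector of spectrum ids, one per record (repeats mark
#'   wavelengths of the same spectrum).
#' @param fractions named or unnamed numeric vector (train, validation, test)
#'   summing to 1.
#' @param seed integer seed.
#' @return List with `train`, `validation`, `test`: logical row masks, plus
#'   `ids` giving the spectrum ids of each split.
#' @export
split_spectra <- function(spectrum_ids, fractions = c(0.70, 0.10, 0.20), seed) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1")
  }
  ids <- unique(spectrum_ids)
  n <- length(ids)
  set.seed(seed)
  ids <- sample(ids)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val >= n) stop("split leaves no test spectra")
  id_train <- ids[seq_len(n_train)]
  id_val <- ids[n_train + seq_len(n_val)]
  id_test <- ids[(n_train + n_val + 1L):n]
  list(
    train = spectrum_ids %in% id_train,
    validation = spectrum_ids %in% id_val,
    test = spectrum_ids %in% id_test,
    ids = list(train = id_train, validation = id_val, test = id_test)
  )
}

#' Fit feature normalization statistics
#'
#' Computes the preprocessing statistics on the training split only: decadic
#' log transform for wide-dynamic-range features (absorption, scattering and
#' thickness by default), then per-feature z-score statistics. Reflectance
#' targets are never transformed (naturally bounded in \[0, 1\]).
#'
#' @param x training-split feature matrix with column names.
#' @param log_features logical vector per column, or NULL to flag columns
#'   named `mua_*`, `mus_*`, `d_*`.
#' @param constant how to treat zero-variance features: `"error"` (default)
#'   or `"center"` (center to zero, unit scale) -- needed when a layer
#'   thickness is fixed, e.g. the semi-infinite bottom layer.
#' @return An object of class `surrogate_normalization` with `log_features`,
#'   `mean`, `sd`.
#' @export
fit_normalization <- function(x, log_features = NULL,
                              constant = c("error", "center")) {
  constant <- match.arg(constant)
  if (nrow(x) < 1) stop("empty training split")
  if (is.null(log_features)) {
    if (is.null(colnames(x))) {
      stop("log_features is NULL and the feature matrix has no column names")
    }
    log_features <- grepl("^(mua_|mus_|d_)", colnames(x))
  }
  stopifnot(length(log_features) == ncol(x))
  z <- x
  if (any(log_features)) {
    bad <- z[, log_features, drop = FALSE] <= 0
    if (any(bad)) stop("nonpositive value in a log-transformed feature")
    z[, log_features] <- log10(z[, log_features, drop = FALSE])
  }
  mu <- colMeans(z)
  sd <- apply(z, 2, stats::sd)
  zero <- !is.finite(sd) | sd == 0
  if (any(zero)) {
    if (constant == "error") {
      stop("zero-variance feature(s): ",
           paste(colnames(x)[zero], collapse = ", "))
    }
    sd[zero] <- 1
  }
  structure(list(log_features = log_features, mean = mu, sd = sd),
            class = "surrogate_normalization")
}

#' Apply (or invert) feature normalization
#'
#' Elementwise `(log10-where-flagged - mean) / sd`. Pure and invertible given
#' the statistics; `preprocess_inverse()` undoes it exactly.
#'
#' @param x feature matrix or vector (a single parameter set).
#' @param norm a [fit_normalization()] result.
#' @return Transformed matrix of the same shape.
#' @export
preprocess_features <- function(x, norm) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(norm$mean)) {
    stop("parameter dimensionality does not match normalization statistics")
  }
  z <- x
  lf <- norm$log_features
  if (any(lf)) {
    if (any(z[, lf] <= 0)) stop("nonpositive value in a log-transformed feature")
    z[, lf] <- log10(z[, lf, drop = FALSE])
  }
  sweep(sweep(z, 2, norm$mean, "-"), 2, norm$sd, "/")
}

#' @rdname preprocess_features
#' @export
preprocess_inverse <- function(x, norm) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- sweep(sweep(x, 2, norm$sd, "*"), 2, norm$mean, "+")
  lf <- norm$log_features
  if (any(lf)) z[, lf] <- 10^(z[, lf, drop = FALSE])
  z
}

#' Surrogate architecture specification
#'
#' Fully connected regressor: `length(hidden)` hidden layers with leaky-ReLU
#' activations (negative slope 0.2) and a single sigmoid output unit mapping
#' predictions to the diffuse reflectance range. The default mirrors the
#' reference architecture: five hidden layers of 512 units
#' (~1.06 million trainable parameters for a 15-dimensional input).
#'
#' @param input_dim input dimensionality (5 per tissue layer).
#' @param hidden integer vector of hidden-layer widths.
#' @param slope leaky-ReLU negative slope.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(input_dim, hidden = rep(512L, 5L), slope = 0.2) {
  stopifnot(input_dim >= 1, length(hidden) >= 1, all(hidden >= 1))
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), slope = slope),
            class = "surrogate_spec")
}

#' Trainable parameter count
#'
#' Closed-form count of weights and biases of a [surrogate_spec()]:
#' `sum over layers of (fan_in + 1) * fan_out` including the output unit.
#'
#' @param spec a [surrogate_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  sizes <- c(spec$input_dim, spec$hidden, 1L)
  as.integer(sum((sizes[-length(sizes)] + 1) * sizes[-1]))
}

# Kaiming-normal initial weights (leaky-ReLU gain), zero biases.
init_weights <- function(spec, seed) {
  set.seed(seed)
  sizes <- c(spec$input_dim, spec$hidden, 1L)
  gain <- sqrt(2 / (1 + spec$slope^2))
  weights <- list(); biases <- list()
  for (k in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[k]
    sd <- gain / sqrt(fan_in)
    weights[[k]] <- matrix(stats::rnorm(fan_in * sizes[k + 1L], sd = sd),
                           fan_in, sizes[k + 1L])
    biases[[k]] <- rep(0, sizes[k + 1L])
  }
  list(weights = weights, biases = biases)
}

#' Surrogate training configuration
#'
#' Training protocol defaults: AdamW (first-order adaptive optimizer with
#' decoupled weight decay), learning rate 1e-4, weight decay 0.001,
#' halve-on-plateau learning-rate schedule with floor 1e-8, 32-bit precision,
#' mean-squared-error loss, no dropout or batch normalization.
#'
#' The scheduler patience defaults to 20 epochs for training pools of at least
#' 1e5 spectra and 50 otherwise; `max_epochs` defaults to `25 * patience`,
#' floored at 500. Both can be set explicitly for scaled-down experiments.
#'
#' @param learning_rate initial learning rate.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size minibatch size.
#' @param patience scheduler patience in epochs (NULL = size-based rule).
#' @param max_epochs total epochs trained (NULL = `25 * patience`, min 500).
#' @param lr_factor multiplicative factor on plateau (0.5 = halving).
#' @param min_lr learning-rate floor.
#' @param seed integer seed for initialization and shuffling.
#' @return An object of class `surrogate_control`.
#' @export
surrogate_control <- function(learning_rate = 1e-4, weight_decay = 0.001,
                              batch_size = 4096, patience = NULL,
                              max_epochs = NULL, lr_factor = 0.5,
                              min_lr = 1e-8, seed = 1L) {
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), patience = patience,
                 max_epochs = max_epochs, lr_factor = lr_factor,
                 min_lr = min_lr, seed = as.integer(seed)),
            class = "surrogate_control")
}

#' Fit the reflectance surrogate
#'
#' Trains the multilayer-perceptron surrogate mapping flattened per-layer
#' physical parameters to diffuse reflectance at one wavelength. Features are
#' normalized with statistics computed from the training data only (see
#' [fit_normalization()]); reflectance targets are used raw. The loss is mean
#' squared error; optimization is AdamW with a halve-on-plateau schedule, and
#' the returned model is the final-epoch checkpoint.
#'
#' @param x training feature matrix (raw physical parameters).
#' @param y training reflectance targets in \[0, 1\].
#' @param validation list with `x` and `y` for the validation split; if NULL,
#'   a seeded random 10% of the training rows is held out.
#' @param spec a [surrogate_spec()]; default derives `input_dim` from `x`.
#' @param control a [surrogate_control()].
#' @param normalization optional precomputed [fit_normalization()] result
#'   (must come from training data).
#' @param constant passed to [fit_normalization()].
#' @return An object of class `surrogate`: list with `spec`, `weights`,
#'   `biases`, `norm`, and `training_meta` (seed, epochs, validation-loss
#'   history, final validation loss, final learning rate).
#' @export
surrogate_fit <- function(x, y, validation = NULL, spec = NULL,
                          control = surrogate_control(),
                          normalization = NULL, constant = "center") {
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x), all(y >= 0), all(y <= 1))
  if (is.null(spec)) spec <- surrogate_spec(ncol(x))
  if (spec$input_dim != ncol(x)) stop("spec input_dim does not match x")

  if (is.null(validation)) {
    set.seed(control$seed)
    n_val <- max(1L, round(0.1 * nrow(x)))
    vi <- sample(nrow(x), n_val)
    validation <- list(x = x[vi, , drop = FALSE], y = y[vi])
    x <- x[-vi, , drop = FALSE]
    y <- y[-vi]
  }
  if (is.null(normalization)) {
    normalization <- fit_normalization(x, constant = constant)
  }

  patience <- control$patience
  if (is.null(patience)) {
    patience <- if (nrow(x) >= 1e5) 20L else 50L
  }
  max_epochs <- control$max_epochs
  if (is.null(max_epochs)) max_epochs <- max(500L, 25L * patience)

  init <- init_weights(spec, control$seed)
  Xtr <- preprocess_features(x, normalization)
  Xva <- preprocess_features(as.matrix(validation$x), normalization)

  fit <- mlp_train_cpp(Xtr, y, Xva, validation$y, init$weights, init$biases,
                       spec$slope, control$learning_rate,
                       control$weight_decay,
                       min(control$batch_size, nrow(Xtr)),
                       as.integer(max_epochs), as.integer(patience),
                       control$lr_factor, control$min_lr, control$seed)

  structure(
    list(spec = spec, weights = fit$weights, biases = fit$biases,
         norm = normalization,
         training_meta = list(seed = control$seed, epochs = fit$epochs,
                              val_loss = fit$val_loss,
                              final_val_loss = fit$final_val_loss,
                              final_lr = fit$final_lr,
                              n_train = nrow(x))),
    class = "surrogate"
  )
}

#' Predict reflectance with a trained surrogate
#'
#' Applies the frozen normalization and the network forward pass. Outputs are
#' strictly inside (0, 1) by the sigmoid output unit, and batch evaluation
#' equals row-by-row evaluation.
#'
#' @param object a [surrogate_fit()] model.
#' @param newdata raw physical-parameter matrix (or single row vector).
#' @param ... unused.
#' @return Numeric vector of reflectance predictions.
#' @export
predict.surrogate <- function(object, newdata, ...) {
  z <- preprocess_features(as.matrix(newdata), object$norm)
  as.numeric(mlp_predict_cpp(z, object$weights, object$biases,
                             object$spec$slope))
}

#' @export
print.surrogate <- function(x, ...) {
  cat(sprintf(
    "Reflectance surrogate: %d -> %s -> 1 (leaky ReLU %.2g, sigmoid out)\n",
    x$spec$input_dim, paste(x$spec$hidden, collapse = "-"), x$spec$slope))
  cat(sprintf("  %d trainable parameters; trained %d epochs on %d rows\n",
              count_parameters(x$spec), x$training_meta$epochs,
              x$training_meta$n_train))
  cat(sprintf("  final validation MSE: %.3e\n", x$training_meta$final_val_loss))
  invisible(x)
}

#' @export
summary.surrogate <- function(object, ...) {
  out <- list(spec = object$spec,
              n_parameters = count_parameters(object$spec),
              training = object$training_meta)
  class(out) <- "summary.surrogate"
  out
}

#' @export
print.summary.surrogate <- function(x, ...) {
  cat(sprintf("Surrogate: input %d, hidden %s, %d parameters\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = "-"),
              x$n_parameters))
  cat(sprintf("  epochs: %d, final lr: %.2e, final val MSE: %.3e\n",
              x$training$epochs, x$training$final_lr,
              x$training$final_val_loss))
  invisible(x)
}

#' @export
residuals.surrogate <- function(object, x, y, ...) {
  y - predict(object, x)
}

#' @export
plot.surrogate <- function(x, ...) {
  h <- x$training_meta$val_loss
  graphics::plot(seq_along(h), h, log = "y", type = "l",
                 xlab = "epoch", ylab = "validation MSE",
                 main = "Surrogate training history", ...)
  invisible(x)
}

#' Regression fidelity metrics
#'
#' Mean absolute error, mean absolute percentage error and the per-sample
#' absolute-percentage-error distribution of surrogate predictions against
#' reflectance targets. Zero targets are excluded from the percentage metrics
#' with their count reported. Optionally evaluates against a lower-noise
#' reference target set (e.g. simulations with ten times more photons) in
#' place of the test targets.
#'
#' @param model a [surrogate_fit()] model.
#' @param x test feature matrix.
#' @param y test reflectance targets.
#' @param reference optional replacement targets (same length as `y`).
#' @return List with `mae`, `mape` (percent), `ape` (percent, per sample),
#'   `n_excluded_zero_targets`.
#' @export
evaluate_fidelity <- function(model, x, y, reference = NULL) {
  if (length(y) == 0) stop("empty test set")
  target <- if (is.null(reference)) y else reference
  stopifnot(length(target) == nrow(as.matrix(x)))
  pred <- predict(model, x)
  abs_err <- abs(pred - target)
  nonzero <- target > 0
  ape <- abs_err[nonzero] / target[nonzero] * 100
  list(mae = mean(abs_err), mape = mean(ape), ape = ape,
       n_excluded_zero_targets = sum(!nonzero))
}
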
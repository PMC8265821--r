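#' Training configuration for the orientation CNN
#'
#' Defaults follow the training protocol: 26,000 simulated samples split
#' 70/30 into train/test, batch size 32, 3 epochs, 13 classes, categorical
#' cross-entropy under an adaptive-moment (Adam) optimizer at its
#' conventional default rate.
#'
#' @param n_samples corpus size (default 26000).
#' @param split train fraction (default 0.7; the rest is the test split).
#' @param batch_size minibatch size (default 32).
#' @param epochs training epochs (default 3).
#' @param n_classes number of classes (13: 12 orientation bins + single-tag).
#' @param seed integer seed controlling initialization, the split and the
#'   shuffles.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @return an object of class `training_config`.
#' @export
training_config <- function(n_samples = 26000, split = 0.7, batch_size = 32,
                            epochs = 3, n_classes = 13, seed = 1,
                            learning_rate = 1e-3) {
  stopifnot(split > 0, split < 1, batch_size >= 1, epochs >= 1,
            n_classes == 13, learning_rate > 0)
  structure(list(n_samples = n_samples, split = split,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_classes = 13L,
                 seed = as.integer(seed), learning_rate = learning_rate),
            class = "training_config")
}

#' Build the two-convolutional-layer classifier
#'
#' Architecture: conv 3x3 (`conv1_filters` filters) + ReLU + 2x2 max-pool,
#' conv 3x3 (`conv2_filters` filters) + ReLU, flatten, dense softmax over 13
#' classes.  With the default 25x25 input and 8/48 filters the network has
#' 54,141 parameters (always reported in the descriptor).  Weights use He
#' initialization from the given seed.
#'
#' @param input_shape integer (rows, cols) of the input patches.
#' @param conv1_filters filters in the first convolutional layer (default 8).
#' @param conv2_filters filters in the second convolutional layer (default 48).
#' @param n_classes number of classes (default 13).
#' @param seed seed for weight initialization.
#' @return an object of class `cnn_model`: list with `arch` (layer
#'   descriptor incl. `n_params`), `weights`, `history` (NULL until
#'   trained), `seed`.
#' @export
cnn_build <- function(input_shape = c(25, 25), conv1_filters = 8,
                      conv2_filters = 48, n_classes = 13, seed = 1) {
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  F1 <- as.integer(conv1_filters); F2 <- as.integer(conv2_filters)
  C <- as.integer(n_classes)
  h1 <- H - 2L; w1 <- W - 2L
  hp <- h1 %/% 2L; wp <- w1 %/% 2L
  h2 <- hp - 2L; w2 <- wp - 2L
  stopifnot(h2 >= 1, w2 >= 1)
  Fl <- h2 * w2 * F2
  arch <- list(
    layers = list(
      list(type = "conv2d", filters = F1, kernel = c(3L, 3L),
           activation = "relu", out = c(h1, w1, F1),
           params = 9L * F1 + F1),
      list(type = "maxpool2d", pool = c(2L, 2L), out = c(hp, wp, F1),
           params = 0L),
      list(type = "conv2d", filters = F2, kernel = c(3L, 3L),
           activation = "relu", out = c(h2, w2, F2),
           params = 9L * F1 * F2 + F2),
      list(type = "flatten", out = Fl, params = 0L),
      list(type = "dense", units = C, activation = "softmax",
           params = Fl * C + C)),
    input_shape = c(H, W), n_conv_layers = 2L, n_classes = C,
    loss = "categorical_crossentropy",
    n_params = (9L * F1 + F1) + (9L * F1 * F2 + F2) + (Fl * C + C))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  weights <- list(
    W1 = matrix(rnorm(9 * F1, 0, sqrt(2 / 9)), 9, F1),
    b1 = numeric(F1),
    W2 = matrix(rnorm(9 * F1 * F2, 0, sqrt(2 / (9 * F1))), 9 * F1, F2),
    b2 = numeric(F2),
    W3 = matrix(rnorm(Fl * C, 0, sqrt(2 / Fl)), Fl, C),
    b3 = numeric(C))
  structure(list(arch = arch, weights = weights, history = NULL,
                 seed = as.integer(seed), config_hash = NA_character_),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model: %dx%d input, 2 conv layers, %d classes, %d parameters%s>\n",
              x$arch$input_shape[1], x$arch$input_shape[2], x$arch$n_classes,
              x$arch$n_params,
              if (is.null(x$history)) ", untrained" else ", trained"))
  invisible(x)
}

# per-image standardization to zero mean / unit variance
normalize_images <- function(X) {
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  sdv[sdv == 0] <- 1
  (X - mu) / sdv
}

# short stable hash of an R object (polynomial rolling hash of its serialization)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Train the orientation CNN on a simulated dataset
#'
#' Splits the dataset 70/30 (per `config$split`), standardizes each image to
#' zero mean and unit variance, and minimizes categorical cross-entropy with
#' Adam for `config$epochs` epochs at batch size `config$batch_size`.
#' Deterministic for a fixed (dataset, config) pair: the split, weight
#' initialization and minibatch shuffles all derive from `config$seed`.
#'
#' @param dataset a `monomer_dataset` with all 13 classes present, or a list
#'   with elements `counts` (n x npixels matrix) and `labels` (0..12).
#' @param config a [training_config()].
#' @param model optionally a pre-built [cnn_build()] model (rebuilt from the
#'   config seed otherwise).
#' @param require_all_classes error when any of the 13 classes is absent
#'   from the dataset (default TRUE; disable for degenerate sanity tasks).
#' @param verbose print per-epoch loss/accuracy.
#' @return the trained `cnn_model`, with `history` (per-epoch training loss
#'   and accuracy), `test_accuracy` (held-out split), `test_indices` and
#'   `config_hash` filled in.
#' @export
cnn_train <- function(dataset, config = training_config(), model = NULL,
                      require_all_classes = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  X <- dataset$counts
  y <- as.integer(dataset$labels)
  n <- nrow(X)
  stopifnot(n >= 13, length(y) == n)
  missing_classes <- setdiff(0:12, unique(y))
  if (require_all_classes && length(missing_classes))
    stop("dataset is missing classes: ",
         paste(missing_classes, collapse = ", "))
  shape <- if (inherits(dataset, "monomer_dataset")) dataset$config$field_size
           else c(as.integer(sqrt(ncol(X))), as.integer(sqrt(ncol(X))))
  if (is.null(model)) model <- cnn_build(input_shape = shape,
                                         seed = config$seed)

  Xn <- normalize_images(X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  idx <- sample.int(n)
  n_train <- floor(config$split * n)
  tr <- idx[seq_len(n_train)]
  te <- idx[(n_train + 1L):n]
  perm <- vapply(seq_len(config$epochs),
                 function(e) sample.int(n_train) - 1L,
                 integer(n_train))

  w <- model$weights
  fit <- cnn_train_cpp(Xn[tr, , drop = FALSE], y[tr],
                       w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                       model$arch$input_shape[1], model$arch$input_shape[2],
                       ncol(w$W1), ncol(w$W2), model$arch$n_classes,
                       perm, config$batch_size, config$learning_rate,
                       0.9, 0.999, 1e-8)
  model$weights <- fit[c("W1", "b1", "W2", "b2", "W3", "b3")]
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = fit$loss, accuracy = fit$accuracy)
  if (verbose) {
    for (e in seq_len(config$epochs))
      message(sprintf("epoch %d: loss %.4f, accuracy %.4f",
                      e, fit$loss[e], fit$accuracy[e]))
  }
  pr <- cnn_predict(model, X[te, , drop = FALSE])
  model$test_accuracy <- mean(pr$labels == y[te])
  model$test_indices <- te
  model$train_config <- config
  model$config_hash <- config_hash(list(config = unclass(config),
                                        arch = model$arch, seed = model$seed))
  model
}

#' Predict orientation classes with a trained CNN
#'
#' Standardizes the input images exactly as in training and returns argmax
#' labels plus the full softmax probability vectors.
#'
#' @param model a `cnn_model`.
#' @param images a single image matrix, an n x npixels matrix of flattened
#'   images, or a `monomer_dataset`.
#' @return list with `labels` (integer 0..12) and `probs` (n x 13 matrix,
#'   rows summing to 1).
#' @export
cnn_predict <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(images, "monomer_dataset")) images <- images$counts
  if (is.matrix(images) &&
      identical(dim(images), as.integer(model$arch$input_shape)))
    images <- matrix(as.numeric(images), 1L)
  images <- as.matrix(images)
  if (ncol(images) != prod(model$arch$input_shape))
    stop("image shape does not match the model input shape")
  Xn <- normalize_images(images)
  w <- model$weights
  probs <- cnn_predict_cpp(Xn, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                           model$arch$input_shape[1],
                           model$arch$input_shape[2],
                           ncol(w$W1), ncol(w$W2), model$arch$n_classes)
  list(labels = as.integer(max.col(probs, ties.method = "first") - 1L),
       probs = probs)
}
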
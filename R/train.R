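#' Training configuration
#'
#' Hyperparameters of the network optimiser: mini-batch Adam with per-unit
#' binary cross-entropy on the two-unit sigmoid output, early stopping on
#' validation loss.
#'
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Seed for weight initialisation and batch shuffling.
#' @param standardize Standardise inputs per channel using training-set
#'   statistics (recommended; raw microvolt inputs stall training).
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128, epochs = 50, learning_rate = 1e-3,
                         patience = 10, seed = 1, standardize = TRUE,
                         verbose = FALSE) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# n x L x C array -> L x C x n cube for the C++ backend, with optional
# per-channel standardisation.
tensor_to_cube <- function(tensor, scaling = NULL) {
  x <- tensor$segments
  if (!is.null(scaling)) {
    for (ch in seq_len(dim(x)[3])) {
      x[, , ch] <- (x[, , ch] - scaling$mean[ch]) / scaling$sd[ch]
    }
  }
  aperm(x, c(2, 3, 1))
}

one_hot <- function(labels) {
  k <- nlevels(labels)
  y <- matrix(0, length(labels), k)
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

#' Build and train the CNN-LSTM classifier
#'
#' Initialises the network (Glorot-uniform weights, forget-gate bias 1) and
#' trains it with Adam. Inputs are standardised per channel with statistics
#' computed on the training partition only. Training aborts with a
#' diagnostic if the loss becomes non-finite; an empty validation set is
#' allowed (training then runs for the full epoch budget).
#'
#' @param arch An [architecture_spec()].
#' @param train Training [segment_tensor()] (two classes present).
#' @param val Optional validation [segment_tensor()].
#' @param cfg A [train_config()].
#' @return An object of class `trained_model` holding the architecture,
#'   fitted parameters, label levels, scaling statistics and the per-epoch
#'   accuracy/loss history.
#' @export
build_and_train <- function(arch, train, val = NULL, cfg = train_config()) {
  stopifnot(inherits(arch, "architecture_spec"),
            inherits(train, "segment_tensor"))
  if (nlevels(droplevels(train$labels)) < 2) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  d <- dim(train$segments)
  if (!identical(as.integer(d[2:3]), arch$input_shape)) {
    stop("segment shape ", d[2], " x ", d[3],
         " does not match architecture input ",
         paste(arch$input_shape, collapse = " x "), call. = FALSE)
  }

  scaling <- NULL
  if (cfg$standardize) {
    mu <- apply(train$segments, 3, mean)
    sd_ <- pmax(apply(train$segments, 3, stats::sd), 1e-8)
    scaling <- list(mean = mu, sd = sd_)
  }
  xtr <- tensor_to_cube(train, scaling)
  ytr <- one_hot(train$labels)
  if (is.null(val) || dim(val$segments)[1] == 0) {
    warning("no validation set; training without early stopping",
            call. = FALSE)
    xval <- array(0, c(d[2], d[3], 0))
    yval <- matrix(0, 0, nlevels(train$labels))
  } else {
    xval <- tensor_to_cube(val, scaling)
    yval <- one_hot(factor(as.character(val$labels),
                           levels = levels(train$labels)))
  }

  fit <- cpp_train(arch_to_cpp(arch), xtr, ytr, xval, yval,
                   list(batch_size = cfg$batch_size, epochs = cfg$epochs,
                        learning_rate = cfg$learning_rate,
                        patience = cfg$patience, seed = cfg$seed,
                        verbose = cfg$verbose))
  if (isTRUE(fit$diverged)) {
    stop("training diverged (non-finite loss); lower the learning rate",
         call. = FALSE)
  }
  history <- as.data.frame(fit$history)
  names(history) <- c("epoch", "train_loss", "train_acc",
                      "val_loss", "val_acc")
  structure(list(arch = arch, params = as.numeric(fit$params),
                 levels = levels(train$labels), scaling = scaling,
                 history = history, cfg = cfg),
            class = "trained_model")
}

#' Class probabilities from a trained model
#'
#' Runs the forward pass and renormalises the two sigmoid outputs so that
#' each row sums to one. The positive class is the second label level.
#'
#' @param model A `trained_model`.
#' @param tensor A [segment_tensor()].
#' @return Matrix `n x n_classes` of probabilities (columns named by level).
#' @export
predict_proba <- function(model, tensor) {
  stopifnot(inherits(model, "trained_model"),
            inherits(tensor, "segment_tensor"))
  x <- tensor_to_cube(tensor, model$scaling)
  p <- cpp_forward(arch_to_cpp(model$arch), model$params, x)
  p <- p / rowSums(p)
  colnames(p) <- model$levels
  p
}

#' @rdname predict_proba
#' @export
predict_classes <- function(model, tensor) {
  p <- predict_proba(model, tensor)
  factor(model$levels[max.col(p, ties.method = "first")],
         levels = model$levels)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s parameters, %d epochs run\n",
              format(length(x$params), big.mark = ","), nrow(x$history)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train acc %.3f, val acc %s\n", last$train_acc,
                ifelse(is.na(last$val_acc), "-",
                       sprintf("%.3f", last$val_acc))))
  }
  invisible(x)
}

#' Save / load a trained model as a portable checkpoint
#'
#' The checkpoint holds the architecture config, the flat parameter vector,
#' label levels and scaling statistics.
#'
#' @param model A `trained_model`.
#' @param path File path (`.rds`).
#' @return `path` / the reloaded `trained_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "trained_model")
}
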
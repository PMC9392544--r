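#' Layer specifications
#'
#' Building blocks of the 1D CNN-LSTM: valid (no-padding, stride-1) 1D
#' convolution over the time axis with the channel dimension as input
#' features, non-overlapping max-pooling, LSTM, and a dense output layer.
#'
#' @param filters,units Number of filters / units (`r`).
#' @param kernel Convolution kernel length (`s`).
#' @param pool Pooling window length (`d`); stride equals the window.
#' @param activation Activation function name.
#' @param return_sequence For LSTM: return the full output sequence
#'   (`TRUE`) or only the final hidden state (`FALSE`).
#' @return A `layer_spec` object.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv1d <- function(filters, kernel, activation = "relu") {
  stopifnot(filters >= 1, kernel >= 1)
  structure(list(kind = "conv1d", r = as.integer(filters),
                 s = as.integer(kernel), activation = activation),
            class = "layer_spec")
}

#' @rdname layers
#' @export
layer_maxpool1d <- function(pool) {
  stopifnot(pool >= 1)
  structure(list(kind = "maxpool1d", d = as.integer(pool)),
            class = "layer_spec")
}

#' @rdname layers
#' @export
layer_lstm <- function(units, return_sequence = FALSE) {
  stopifnot(units >= 1)
  structure(list(kind = "lstm", units = as.integer(units),
                 return_sequence = isTRUE(return_sequence),
                 activation = "tanh"),
            class = "layer_spec")
}

#' @rdname layers
#' @export
layer_dense <- function(units, activation = "sigmoid") {
  stopifnot(units >= 1)
  structure(list(kind = "dense", units = as.integer(units),
                 activation = activation),
            class = "layer_spec")
}

#' Network architecture
#'
#' An ordered list of layers with shape propagation. Construction fails if
#' any layer would produce a temporal length below 1, or if a dense layer
#' receives a sequence longer than 1.
#'
#' @param input_shape `c(segment_len, channels)`.
#' @param layers List of `layer_spec` objects.
#' @return An `architecture_spec` with a precomputed `shapes` table.
#' @export
architecture_spec <- function(input_shape, layers) {
  stopifnot(length(input_shape) == 2, all(input_shape >= 1))
  for (l in layers) stopifnot(inherits(l, "layer_spec"))
  arch <- structure(list(input_shape = as.integer(input_shape),
                         layers = layers),
                    class = "architecture_spec")
  arch$shapes <- propagate_shapes(arch)
  arch
}

#' Shape propagation through the architecture
#'
#' @param arch An [architecture_spec()] (the `shapes` element may be absent).
#' @return Data frame with one row per layer: `kind`, `length`, `features`,
#'   `params` (trainable parameter count).
#' @export
propagate_shapes <- function(arch) {
  len <- arch$input_shape[1]
  feat <- arch$input_shape[2]
  rows <- lapply(arch$layers, function(l) {
    p <- param_count(l, input_dim = feat)
    switch(l$kind,
      conv1d = {
        if (len < l$s) stop("conv kernel ", l$s, " exceeds input length ",
                            len, call. = FALSE)
        len <<- len - l$s + 1L
        feat <<- l$r
      },
      maxpool1d = {
        if (len < l$d) stop("pool window ", l$d, " exceeds input length ",
                            len, call. = FALSE)
        len <<- len %/% l$d
      },
      lstm = {
        len <<- if (l$return_sequence) len else 1L
        feat <<- l$units
      },
      dense = {
        if (len != 1) stop("dense layer requires a length-1 sequence, got ",
                           len, call. = FALSE)
        feat <<- l$units
      })
    if (len < 1) stop("layer yields empty output", call. = FALSE)
    data.frame(kind = l$kind, length = len, features = feat, params = p)
  })
  do.call(rbind, rows)
}

#' Trainable parameter count of a layer
#'
#' Convolution: `r * (input_channels * s + 1)`; LSTM (single-bias gates):
#' `4 * (units * (input_dim + units) + units)`; dense:
#' `units * (input_dim + 1)`; pooling: 0.
#'
#' @param layer A `layer_spec`.
#' @param input_dim Feature dimension of the layer's input (channels for a
#'   conv layer, input feature size for LSTM/dense).
#' @return Integer parameter count.
#' @export
#' @examples
#' param_count(layer_conv1d(128, 4), input_dim = 19)  # 9856
#' param_count(layer_lstm(50), input_dim = 8)         # 11800
param_count <- function(layer, input_dim) {
  switch(layer$kind,
    conv1d = layer$r * (input_dim * layer$s + 1L),
    maxpool1d = 0L,
    lstm = 4L * (layer$units * (input_dim + layer$units) + layer$units),
    dense = layer$units * (input_dim + 1L))
}

#' The reference CNN-LSTM architecture
#'
#' Five 1D convolution stages (128, 64, 32, 16, 8 filters; ReLU)
#' interleaved with max-pooling, followed by a three-layer LSTM stack
#' (50, 25, 25 units) and a two-unit sigmoid output, on 500 x 19 inputs
#' (1 s of 19-channel EEG at 500 Hz). Kernel lengths (4, 4, 4, 4, 2) and
#' pool windows (4, 4, 4, 2) are uniquely determined by the published
#' per-layer output lengths and parameter counts under valid stride-1
#' convolution.
#'
#' @param input_shape `c(segment_len, channels)`.
#' @return An [architecture_spec()].
#' @export
#' @examples
#' arch <- default_architecture()
#' arch$shapes
default_architecture <- function(input_shape = c(500, 19)) {
  architecture_spec(input_shape, list(
    layer_conv1d(128, 4),
    layer_maxpool1d(4),
    layer_conv1d(64, 4),
    layer_maxpool1d(4),
    layer_conv1d(32, 4),
    layer_maxpool1d(4),
    layer_conv1d(16, 4),
    layer_conv1d(8, 2),
    layer_maxpool1d(2),
    layer_lstm(50, return_sequence = TRUE),
    layer_lstm(25, return_sequence = TRUE),
    layer_lstm(25, return_sequence = FALSE),
    layer_dense(2, "sigmoid")
  ))
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> input %d x %d, %d layers, %s parameters\n",
              x$input_shape[1], x$input_shape[2], length(x$layers),
              format(sum(x$shapes$params), big.mark = ",")))
  print(x$shapes)
  invisible(x)
}

apply_activation <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         identity = x,
         linear = x,
         tanh = tanh(x),
         sigmoid = 1 / (1 + exp(-x)),
         stop("unknown activation ", activation, call. = FALSE))
}

#' Valid 1D convolution over the time axis
#'
#' For an input `x` of `L` time steps by `C` channels and `r` filters of
#' kernel length `s`, computes
#' `out[l, j] = f(sum_{i,c} x[l + i - 1, c] * w[i, c, j] + b[j])` for
#' `l in 1..(L - s + 1)` (no padding, stride 1).
#'
#' @param x Numeric matrix `L x C`.
#' @param weights Numeric array `s x C x r`.
#' @param bias Numeric vector of length `r`.
#' @param activation Activation function name.
#' @return Matrix `(L - s + 1) x r`.
#' @export
conv1d_valid <- function(x, weights, bias, activation = "identity") {
  stopifnot(is.matrix(x), length(dim(weights)) == 3,
            dim(weights)[2] == ncol(x), length(bias) == dim(weights)[3])
  L <- nrow(x)
  s <- dim(weights)[1]
  r <- dim(weights)[3]
  if (L < s) stop("input length ", L, " shorter than kernel ", s,
                  call. = FALSE)
  lo <- L - s + 1L
  # im2col: row l holds the flattened s x C window starting at l
  m <- matrix(0, lo, s * ncol(x))
  for (i in seq_len(s)) {
    m[, seq.int(i, by = s, length.out = ncol(x))] <- x[i:(i + lo - 1), ]
  }
  w <- matrix(weights, s * ncol(x), r)
  apply_activation(sweep(m %*% w, 2, bias, "+"), activation)
}

#' Non-overlapping 1D max-pooling
#'
#' Maximum over consecutive windows of length `d` (stride `d`) along the
#' time axis; a trailing remainder shorter than `d` is discarded.
#'
#' @param x Numeric matrix `L x r`.
#' @param d Pooling window length.
#' @return Matrix `floor(L / d) x r`.
#' @export
#' @examples
#' maxpool1d(matrix(c(1, 3, 2, 5)), 2)  # [3, 5]
maxpool1d <- function(x, d) {
  stopifnot(is.matrix(x), d >= 1)
  L <- nrow(x)
  if (L < d) stop("input length ", L, " shorter than pool window ", d,
                  call. = FALSE)
  k <- L %/% d
  out <- matrix(0, k, ncol(x))
  for (j in seq_len(k)) {
    out[j, ] <- apply(x[((j - 1) * d + 1):(j * d), , drop = FALSE], 2, max)
  }
  out
}

# Convert an architecture_spec to the plain list the C++ backend expects.
arch_to_cpp <- function(arch) {
  list(input_shape = as.integer(arch$input_shape),
       layers = lapply(arch$layers, function(l) {
         switch(l$kind,
           conv1d = list(kind = "conv", r = l$r, s = l$s),
           maxpool1d = list(kind = "pool", d = l$d),
           lstm = list(kind = "lstm", units = l$units,
                       return_seq = l$return_sequence),
           dense = list(kind = "dense", units = l$units))
       }))
}

#' Serialise an architecture to a plain-text config
#'
#' @param arch An [architecture_spec()].
#' @param path YAML file path.
#' @return `path` / the reloaded [architecture_spec()].
#' @export
write_architecture <- function(arch, path) {
  yaml::write_yaml(list(
    input_shape = as.integer(arch$input_shape),
    layers = lapply(arch$layers, function(l) unclass(l))), path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  raw <- yaml::read_yaml(path)
  layers <- lapply(raw$layers, function(l) {
    switch(l$kind,
      conv1d = layer_conv1d(l$r, l$s, l$activation),
      maxpool1d = layer_maxpool1d(l$d),
      lstm = layer_lstm(l$units, l$return_sequence),
      dense = layer_dense(l$units, l$activation))
  })
  architecture_spec(raw$input_shape, layers)
}
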
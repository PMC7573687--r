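#' Layer-by-layer model specifications
#'
#' A `model_spec` is an ordered list of layer descriptors sufficient to count
#' parameters, validate shape consistency and instantiate a trainable network.
#' Supported layer kinds: `conv` (2-D convolution, square kernel, bias),
#' `batch_norm` (4 parameters per channel: scale, shift, moving mean, moving
#' variance), `activation`, `max_pool`, `flatten`, `dense` (bias), `softmax`.
#'
#' @name model_spec
NULL

layer_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L,
                       padding = "same") {
  list(kind = "conv", kernel = as.integer(kernel), in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), stride = as.integer(stride),
       padding = padding)
}
layer_bn <- function(channels) list(kind = "batch_norm",
                                    channels = as.integer(channels))
layer_act <- function(fun = "leaky_relu", alpha = 0.01)
  list(kind = "activation", fun = fun, alpha = alpha)
layer_pool <- function(size = 2L, stride = size)
  list(kind = "max_pool", size = as.integer(size), stride = as.integer(stride))
layer_flatten <- function() list(kind = "flatten")
layer_dense <- function(in_units, out_units)
  list(kind = "dense", in_units = as.integer(in_units),
       out_units = as.integer(out_units))
layer_softmax <- function() list(kind = "softmax")

new_model_spec <- function(layers, input_shape = c(64L, 64L, 3L),
                           name = "model") {
  spec <- structure(list(layers = layers, input_shape = as.integer(input_shape),
                         name = name), class = "model_spec")
  model_spec_shapes(spec) # validates consistency
  spec
}

# Per-block channel widths of the proposed network at width multiplier 1.
# Stride-1 convolutions preserve the width; each stride-2 convolution expands
# it to the next value, so the feature map widens exactly where it is
# downsampled. These widths reproduce the published parameter total.
.proposed_widths <- c(48L, 64L, 112L, 184L, 256L)

#' Build the proposed light-weight patch-classification CNN
#'
#' The base model has 4 blocks. Block 1 starts with two stride-1
#' convolutional layers (Leaky ReLU activation, batch normalisation); blocks
#' 2-4 start with one such layer. Every block ends with a further
#' convolution+LeakyReLU+BN layer with stride 2, used in place of pooling, so
#' the 64x64 input is downsampled exactly four times to 4x4. The top model is
#' flatten, a 128-unit dense layer with Leaky ReLU and batch normalisation,
#' and a 2-unit softmax output (clean / dirty probabilities). All kernels are
#' 3x3; there is no dropout and no pooling. At `width_multiplier = 1` the
#' model has exactly 1,708,610 parameters (weights, biases, batch-norm scale,
#' shift and moving statistics).
#'
#' @param width_multiplier positive scale factor on all channel widths;
#'   fractional values give proportionally smaller models for CPU-scale
#'   experiments (widths are rounded, minimum 1).
#' @return a `model_spec`.
#' @export
build_proposed_cnn <- function(width_multiplier = 1.0) {
  stopifnot(width_multiplier > 0)
  w <- pmax(1L, as.integer(round(width_multiplier * .proposed_widths)))
  conv_unit <- function(cin, cout, stride = 1L)
    list(layer_conv(cin, cout, 3L, stride), layer_bn(cout), layer_act())
  layers <- c(
    conv_unit(3L, w[1]),             # block 1
    conv_unit(w[1], w[1]),
    conv_unit(w[1], w[2], stride = 2L),
    conv_unit(w[2], w[2]),           # block 2
    conv_unit(w[2], w[3], stride = 2L),
    conv_unit(w[3], w[3]),           # block 3
    conv_unit(w[3], w[4], stride = 2L),
    conv_unit(w[4], w[4]),           # block 4
    conv_unit(w[4], w[5], stride = 2L),
    list(layer_flatten(),
         layer_dense(4L * 4L * w[5], 128L), layer_act(), layer_bn(128L),
         layer_dense(128L, 2L), layer_softmax()))
  new_model_spec(layers, name = sprintf("proposed_x%g", width_multiplier))
}

#' Build the VGG-16 comparator
#'
#' Standard VGG-16 convolutional base (13 3x3 convolutions in five groups
#' separated by 2x2 max-pooling, no batch normalisation) applied to a 64x64x3
#' input, yielding a 2x2x512 feature map, followed by the same top model as
#' the proposed network: flatten (2048), dense 128 with Leaky ReLU and batch
#' normalisation, dense 2 with softmax. Total 14,977,730 parameters.
#'
#' @return a `model_spec`.
#' @export
build_vgg16_classifier <- function() {
  cfg <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
              c(512L, 512L, 512L), c(512L, 512L, 512L))
  layers <- list()
  cin <- 3L
  for (group in cfg) {
    for (cout in group) {
      layers <- c(layers, list(layer_conv(cin, cout, 3L, 1L), layer_act("relu")))
      cin <- cout
    }
    layers <- c(layers, list(layer_pool(2L)))
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(2L * 2L * 512L, 128L), layer_act(), layer_bn(128L),
    layer_dense(128L, 2L), layer_softmax()))
  new_model_spec(layers, name = "vgg16")
}

#' Count the parameters of a model specification
#'
#' Convolutions contribute `k^2 * in_ch * out_ch + out_ch` (weights + bias),
#' dense layers `in * out + out`, and batch normalisation 4 per channel
#' (scale, shift, moving mean, moving variance — i.e. trainable plus
#' non-trainable state, the convention under which the published totals were
#' reported). Activations, pooling, flatten and softmax are parameter-free.
#'
#' @param spec a `model_spec`.
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  model_spec_shapes(spec) # errors on inconsistent shapes
  total <- 0
  for (ly in spec$layers) {
    total <- total + switch(ly$kind,
      conv = ly$kernel^2 * ly$in_ch * ly$out_ch + ly$out_ch,
      batch_norm = 4L * ly$channels,
      dense = ly$in_units * ly$out_units + ly$out_units,
      0L)
  }
  as.integer(total)
}

#' Trace the activation shapes through a model specification
#'
#' @param spec a `model_spec`.
#' @param input_shape overrides the spec's input shape.
#' @return list of shapes (one per layer, after that layer); spatial layers
#'   as `c(h, w, channels)`, flat layers as a single length.
#' @export
model_spec_shapes <- function(spec, input_shape = spec$input_shape) {
  shape <- input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    shape <- switch(ly$kind,
      conv = {
        if (length(shape) != 3L || shape[3] != ly$in_ch)
          stop("layer ", i, " (conv) expects ", ly$in_ch,
               " channels, got shape ", paste(shape, collapse = "x"))
        sp <- if (identical(ly$padding, "same")) ceiling(shape[1:2] / ly$stride)
              else floor((shape[1:2] - ly$kernel) / ly$stride) + 1
        c(sp, ly$out_ch)
      },
      batch_norm = {
        ch <- if (length(shape) == 3L) shape[3] else shape
        if (ch != ly$channels)
          stop("layer ", i, " (batch_norm) expects ", ly$channels,
               " channels, got ", ch)
        shape
      },
      activation = shape,
      max_pool = {
        if (length(shape) != 3L) stop("layer ", i, ": max_pool needs 3-D input")
        c(floor(shape[1:2] / ly$stride), shape[3])
      },
      flatten = prod(shape),
      dense = {
        if (length(shape) != 1L || shape != ly$in_units)
          stop("layer ", i, " (dense) expects ", ly$in_units,
               " inputs, got shape ", paste(shape, collapse = "x"))
        ly$out_units
      },
      softmax = shape,
      stop("unknown layer kind: ", ly$kind))
    out[[i]] <- shape
  }
  out
}

#' @export
print.model_spec <- function(x, ...) {
  shapes <- model_spec_shapes(x)
  cat(sprintf("<model_spec '%s'> input %s, %d layers, %s parameters\n",
              x$name, paste(x$input_shape, collapse = "x"),
              length(x$layers), format(count_parameters(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$kind,
      conv = sprintf("conv %dx%d %d->%d stride %d", ly$kernel, ly$kernel,
                     ly$in_ch, ly$out_ch, ly$stride),
      batch_norm = sprintf("batch_norm (%d)", ly$channels),
      activation = sprintf("activation %s", ly$fun),
      max_pool = sprintf("max_pool %dx%d", ly$size, ly$size),
      dense = sprintf("dense %d->%d", ly$in_units, ly$out_units),
      ly$kind)
    cat(sprintf("  %2d %-28s -> %s\n", i, desc,
                paste(shapes[[i]], collapse = "x")))
  }
  invisible(x)
}

#' Serialise / restore a model specification as JSON
#'
#' @param spec a `model_spec`.
#' @param path JSON file path.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(
    list(name = spec$name, input_shape = spec$input_shape,
         layers = spec$layers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(x$layers, function(ly) {
    for (f in c("kernel", "in_ch", "out_ch", "stride", "channels",
                "in_units", "out_units", "size"))
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    ly
  })
  new_model_spec(layers, input_shape = as.integer(x$input_shape),
                 name = x$name)
}
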
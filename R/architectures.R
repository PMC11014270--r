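#' Build an untrained 1D deep regressor
#'
#' Four canonical one-dimensional adaptations are provided, each ending in
#' a single linear output unit and using ReLU activations throughout:
#'
#' * `simple_cnn`: Conv(32, k7) - MaxPool2 - Conv(64, k5) - MaxPool2 -
#'   Flatten - Dense(64) - Dense(1).
#' * `s_alexnet`: five convolution layers (48 k11 s4 / 128 k5 / 192 k3 /
#'   192 k3 / 128 k3) with max-pools after layers 1, 2 and 5, then
#'   Dense(256) - Dense(128) - Dense(1); a lighter AlexNet-style stack
#'   suited to small spectral datasets.
#' * `resnet`: Conv(32, k7, s2) stem, four residual blocks (two k3
#'   convolutions with batch norm each, identity shortcut, 1x1 projection
#'   when the channel count changes; channels 32, 32, 64, 64), global
#'   average pooling, Dense(1).
#' * `googlenet`: Conv(32, k7, s2) stem and max-pool, two inception modules
#'   (parallel k1/k3/k5/max-pool branches, channel splits 16-32-8-8 then
#'   32-48-12-12), global average pooling, Dense(1).
#'
#' Weights are drawn from a uniform fan-in scheme keyed to `seed`.
#'
#' @param arch One of `"simple_cnn"`, `"s_alexnet"`, `"resnet"`,
#'   `"googlenet"`.
#' @param input_length Number of spectral features m (>= 16).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `nn_network` with elements `layers`, `arch`,
#'   `input_length`, `n_params`.
#' @export
#' @examples
#' net <- build_model("simple_cnn", 125)
#' net$n_params
build_model <- function(arch = c("simple_cnn", "s_alexnet", "resnet",
                                 "googlenet"),
                        input_length, seed = 42L) {
  arch <- match.arg(arch)
  input_length <- as.integer(input_length)
  min_len <- arch_min_input_length(arch)
  if (input_length < max(16L, min_len)) {
    stop(sprintf(
      "input_length %d is too short for the %s pooling stack; minimal admissible length is %d",
      input_length, arch, max(16L, min_len)), call. = FALSE)
  }
  layers <- withr::with_seed(as.integer(seed), switch(
    arch,
    simple_cnn = {
      L1 <- conv_out_len(input_length, 7L, 1L, 0L)
      L2 <- conv_out_len(L1, 2L, 2L, 0L)
      L3 <- conv_out_len(L2, 5L, 1L, 0L)
      L4 <- conv_out_len(L3, 2L, 2L, 0L)
      check_min_length(c(L1, L2, L3, L4), arch, input_length)
      list(layer_conv1d(1L, 32L, 7L), layer_relu(),
           layer_maxpool1d(2L),
           layer_conv1d(32L, 64L, 5L), layer_relu(),
           layer_maxpool1d(2L),
           layer_flatten(),
           layer_dense(L4 * 64L, 64L), layer_relu(),
           layer_dense(64L, 1L))
    },
    s_alexnet = {
      L1 <- conv_out_len(input_length, 11L, 4L, 0L)
      L2 <- conv_out_len(L1, 3L, 2L, 0L)
      L3 <- conv_out_len(L2, 5L, 1L, 2L)
      L4 <- conv_out_len(L3, 3L, 2L, 0L)
      L5 <- conv_out_len(L4, 3L, 2L, 0L)  # after conv3-5 (length-kept)
      check_min_length(c(L1, L2, L3, L4, L5), arch, input_length)
      list(layer_conv1d(1L, 48L, 11L, stride = 4L), layer_relu(),
           layer_maxpool1d(3L, 2L),
           layer_conv1d(48L, 128L, 5L, pad = 2L), layer_relu(),
           layer_maxpool1d(3L, 2L),
           layer_conv1d(128L, 192L, 3L, pad = 1L), layer_relu(),
           layer_conv1d(192L, 192L, 3L, pad = 1L), layer_relu(),
           layer_conv1d(192L, 128L, 3L, pad = 1L), layer_relu(),
           layer_maxpool1d(3L, 2L),
           layer_flatten(),
           layer_dense(L5 * 128L, 256L), layer_relu(),
           layer_dense(256L, 128L), layer_relu(),
           layer_dense(128L, 1L))
    },
    resnet = {
      L1 <- conv_out_len(input_length, 7L, 2L, 3L)
      L2 <- conv_out_len(L1, 3L, 2L, 1L)  # third block downsamples
      check_min_length(c(L1, L2), arch, input_length)
      list(layer_conv1d(1L, 32L, 7L, stride = 2L, pad = 3L), layer_relu(),
           layer_residual_block(32L, 32L),
           layer_residual_block(32L, 32L),
           layer_residual_block(32L, 64L, stride = 2L),
           layer_residual_block(64L, 64L),
           layer_gap(),
           layer_dense(64L, 1L))
    },
    googlenet = {
      L1 <- conv_out_len(input_length, 7L, 2L, 3L)
      L2 <- conv_out_len(L1, 3L, 2L, 1L)
      check_min_length(c(L1, L2), arch, input_length)
      list(layer_conv1d(1L, 32L, 7L, stride = 2L, pad = 3L), layer_relu(),
           layer_maxpool1d(3L, 2L, pad = 1L),
           layer_inception(32L, 16L, 32L, 8L, 8L),
           layer_inception(64L, 32L, 48L, 12L, 12L),
           layer_gap(),
           layer_dense(104L, 1L))
    }))
  structure(list(layers = layers, arch = arch,
                 input_length = input_length,
                 n_params = count_parameters(layers)),
            class = "nn_network")
}

# Shortest input each conv/pool stack can reduce without a zero-length
# feature map (the simple CNN and AlexNet-style stacks shrink hardest).
arch_min_input_length <- function(arch) {
  switch(arch, simple_cnn = 18L, s_alexnet = 67L, resnet = 16L,
         googlenet = 16L)
}

check_min_length <- function(lens, arch, input_length) {
  if (any(lens < 1L)) {
    stop(sprintf(
      "input length %d is too short for the %s pooling stack",
      input_length, arch), call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.nn_network <- function(x, ...) {
  cat(sprintf("<nn_network> %s, input length %d, %d parameters\n",
              x$arch, x$input_length, x$n_params))
  invisible(x)
}

# Spectra enter the network as (n, m) matrices; reshape to (n, m, 1).
as_input_tensor <- function(x) {
  x <- as.matrix(x)
  array(x, c(nrow(x), ncol(x), 1L))
}
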
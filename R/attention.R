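# Channel attention: per-channel gating weights in (0, 1) computed from
# globally pooled descriptors through a shared bottleneck MLP and a
# sigmoid, multiplied back into the feature map. Standalone math; no
# training loop (the upstream extractor owns learning).

#' Feature map container
#'
#' @param values numeric 3-D array, channels x height x width, all finite.
#' @return object of class `feature_map` (the validated array).
#' @export
feature_map <- function(values) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || any(dim(values) < 1L)) {
    stop("invalid input: feature map must be a C x H x W array", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("invalid input: feature map values must be finite", call. = FALSE)
  }
  structure(values, class = "feature_map")
}

#' Bottleneck MLP parameters for channel attention
#'
#' The shared two-layer perceptron squeezes C channels to
#' `ceiling(C / r)` hidden units (r is the reduction ratio) and expands
#' back to C. Weights may be supplied or drawn from N(0, 1/C) under a
#' seed. The hidden activation defaults to ReLU; no bias terms.
#'
#' @param C channel count.
#' @param r reduction ratio (default 8; hidden size is `ceiling(C / r)`).
#' @param V0 optional hidden-by-C squeeze matrix.
#' @param V1 optional C-by-hidden expand matrix.
#' @param activation hidden nonlinearity: `"relu"`, `"tanh"` or
#'   `"identity"`.
#' @param seed integer seed for random initialization when weights are not
#'   supplied.
#' @return object of class `attention_params`.
#' @export
attention_params <- function(C, r = 8L, V0 = NULL, V1 = NULL,
                             activation = c("relu", "tanh", "identity"),
                             seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(C >= 1L, r >= 1L)
  hidden <- max(1L, as.integer(ceiling(C / r)))
  if (is.null(V0) || is.null(V1)) {
    with_seed(seed, {
      if (is.null(V0)) V0 <- matrix(stats::rnorm(hidden * C, sd = 1 / sqrt(C)),
                                    hidden, C)
      if (is.null(V1)) V1 <- matrix(stats::rnorm(C * hidden, sd = 1 / sqrt(C)),
                                    C, hidden)
    })
  }
  V0 <- as.matrix(V0)
  V1 <- as.matrix(V1)
  if (!all(dim(V0) == c(hidden, C)) || !all(dim(V1) == c(C, hidden))) {
    stop("invalid input: V0 must be hidden x C and V1 C x hidden ",
         "(hidden = ceiling(C/r) = ", hidden, ")", call. = FALSE)
  }
  structure(list(C = as.integer(C), r = as.integer(r), hidden = hidden,
                 V0 = V0, V1 = V1, activation = activation),
            class = "attention_params")
}

#' Global average pooling
#'
#' Per-channel mean over all spatial positions.
#'
#' @param fmap a [feature_map()] (C x H x W array).
#' @return numeric C-vector.
#' @export
global_avg_pool <- function(fmap) {
  fmap <- feature_map(fmap)
  apply(fmap, 1L, mean)
}

#' Global max pooling
#'
#' Per-channel maximum over all spatial positions.
#'
#' @param fmap a [feature_map()] (C x H x W array).
#' @return numeric C-vector.
#' @export
global_max_pool <- function(fmap) {
  fmap <- feature_map(fmap)
  apply(fmap, 1L, max)
}

mlp_forward <- function(v, params) {
  h <- params$V0 %*% v
  h <- switch(params$activation,
              relu = pmax(h, 0),
              tanh = tanh(h),
              identity = h)
  drop(params$V1 %*% h)
}

#' Channel-attention weights
#'
#' Computes `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`: both pooled
#' descriptors pass through the same bottleneck MLP, the outputs are
#' combined by element-wise summation and squashed by the logistic
#' sigmoid, yielding one gating weight in (0, 1) per channel.
#'
#' @param fmap a [feature_map()] (C x H x W array).
#' @param params an [attention_params()] with matching channel count.
#' @return numeric C-vector strictly inside (0, 1).
#' @export
channel_attention <- function(fmap, params) {
  fmap <- feature_map(fmap)
  stopifnot(inherits(params, "attention_params"))
  if (dim(fmap)[1L] != params$C) {
    stop("invalid input: feature map has ", dim(fmap)[1L],
         " channels but params expect ", params$C, call. = FALSE)
  }
  pre <- mlp_forward(global_avg_pool(fmap), params) +
    mlp_forward(global_max_pool(fmap), params)
  stats::plogis(pre)
}

#' Recalibrate a feature map by channel weights
#'
#' Multiplies channel c of the map by `weights[c]`, broadcast over the
#' spatial grid; linear in the map for fixed weights.
#'
#' @param fmap a [feature_map()] (C x H x W array).
#' @param weights numeric C-vector (typically from [channel_attention()]).
#' @return a `feature_map` of the same shape.
#' @export
apply_channel_attention <- function(fmap, weights) {
  fmap <- feature_map(fmap)
  if (length(weights) != dim(fmap)[1L]) {
    stop("invalid input: weights length ", length(weights),
         " != channel count ", dim(fmap)[1L], call. = FALSE)
  }
  # arrays recycle along the first (channel) dimension
  feature_map(unclass(fmap) * as.numeric(weights))
}
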
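#' Model configuration for the sequence-to-expression CNN
#'
#' The architecture is a compact 1D CNN: convolution blocks (conv + ReLU +
#' max-pool), a flatten, dense hidden layers with ReLU and dropout, and a
#' single output unit. The default configuration has two conv blocks (128
#' filters of width 6 with pool 4, then 32 filters of width 9 with pool 4),
#' dense layers of 256 and 64 units with dropout 0.1, and a sigmoid output
#' so predictions live in (0, 1) like the GEx target.
#'
#' @param input_channels 1 (ATAC-only), 4 (DNA-only) or 5 (DNA+ATAC).
#' @param input_length window length L in bases.
#' @param conv_specs list of integer triples `c(n_filters, kernel_width,
#'   pool_width)`.
#' @param dense_sizes integer vector of hidden dense layer widths.
#' @param dropout dropout fraction applied after each hidden dense layer.
#' @param output_activation "sigmoid" or "linear".
#' @param global_pool when TRUE, average the last conv block's activations
#'   over positions (global mean pooling) instead of flattening — a
#'   position-invariant head that suits occurrence-count signals and trains
#'   with far fewer parameters.
#' @param batch_norm when TRUE, each conv block applies per-filter batch
#'   normalization before the ReLU (running statistics at inference), as in
#'   the reference architecture family.
#' @param head_init_scale multiplier on the output layer's initialization
#'   range; 0 starts the untrained network exactly at the constant
#'   predictor, so any input dependence of its output is learned, never
#'   inherited from random initialization.
#' @return an object of class `cnn_config`.
#' @export
model_config <- function(input_channels = 5L, input_length = 2000L,
                         conv_specs = list(c(128L, 6L, 4L), c(32L, 9L, 4L)),
                         dense_sizes = c(256L, 64L), dropout = 0.1,
                         output_activation = c("sigmoid", "linear"),
                         global_pool = FALSE, batch_norm = FALSE,
                         head_init_scale = 1) {
  output_activation <- match.arg(output_activation)
  stopifnot(input_channels %in% c(1L, 4L, 5L), input_length >= 1L,
            dropout >= 0, dropout < 1)
  cfg <- structure(list(input_channels = as.integer(input_channels),
                        input_length = as.integer(input_length),
                        conv_specs = lapply(conv_specs, as.integer),
                        dense_sizes = as.integer(dense_sizes),
                        dropout = dropout,
                        output_activation = output_activation,
                        global_pool = isTRUE(global_pool),
                        batch_norm = isTRUE(batch_norm),
                        head_init_scale = head_init_scale),
                   class = "cnn_config")
  layer_plan(cfg)  # validates shapes; errors on collapse below length 1
  cfg
}

#' Build a CNN with deterministic weight initialization
#'
#' Weights are drawn from the fan-in uniform scheme
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` under the given seed; the same seed
#' always yields bit-identical weights.
#'
#' @param config a [model_config()].
#' @param seed integer seed for initialization.
#' @return an object of class `gex_cnn`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  plan <- layer_plan(config)
  params <- init_params(plan, derive_seed(seed, "init"))
  structure(list(config = config, plan = plan, params = params,
                 buffers = init_buffers(plan), seed = seed),
            class = "gex_cnn")
}

#' Count trainable parameters of a model
#'
#' Adding one input channel to the first convolution adds exactly
#' `n_filters_1 * kernel_width_1` parameters, which is how channel-count
#' differences between ablated architectures are audited.
#'
#' @param model a `gex_cnn`.
#' @return integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) sum(lengths(p)), numeric(1)))
}

#' Predict GEx for a batch of samples
#'
#' Inference mode is deterministic: dropout is disabled.
#'
#' @param object a `gex_cnn`.
#' @param x a `gex_dataset`, an array (L, C, B), or a single L x C matrix.
#' @param batch_size maximum samples per forward pass.
#' @param ... unused.
#' @return a numeric vector of predictions (named by gene when `x` is a
#'   dataset); in (0, 1) for sigmoid output.
#' @export
predict.gex_cnn <- function(object, x, batch_size = 256L, ...) {
  nms <- NULL
  if (inherits(x, "gex_dataset")) {
    if (dim(x$x)[2] != object$config$input_channels)
      stop(sprintf("dataset has %d channels but model expects %d",
                   dim(x$x)[2], object$config$input_channels))
    nms <- x$gene_ids
    x <- x$x
  }
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (dim(x)[2] != object$config$input_channels)
    stop(sprintf("input has %d channels but model expects %d",
                 dim(x)[2], object$config$input_channels))
  B <- dim(x)[3]
  out <- numeric(B)
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    out[idx] <- nn_forward(object$params, object$plan,
                           x[, , idx, drop = FALSE],
                           buffers = object$buffers)$y
  }
  if (!is.null(nms)) names(out) <- nms
  out
}

#' Gradient of the model output with respect to its input
#'
#' Used by the attribution machinery (integrated gradients).
#'
#' @param model a `gex_cnn`.
#' @param x array (L, C, B) or a single L x C matrix.
#' @return an array of the same shape as `x` with d f / d x.
#' @export
input_gradients <- function(model, x) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  fw <- nn_forward(model$params, model$plan, x, buffers = model$buffers,
                   keep_cache = TRUE)
  bw <- nn_backward(model$params, model$plan, fw$cache,
                    rep(1, dim(x)[3]), need_dx = TRUE,
                    input_dim = dim(x)[1:2])
  if (was_mat) bw$dX[, , 1] else bw$dX
}

#' @export
print.gex_cnn <- function(x, ...) {
  cat(sprintf("<gex_cnn> %d input channels, L = %d, %d parameters\n",
              x$config$input_channels, x$config$input_length,
              count_parameters(x)))
  print(describe_model(x))
  invisible(x)
}

#' Layer table for a model or config
#'
#' @param x a `gex_cnn` or `cnn_config`.
#' @return a data.frame with one row per layer: type, output shape and
#'   parameter count.
#' @export
describe_model <- function(x) {
  cfg <- if (inherits(x, "gex_cnn")) x$config else x
  plan <- layer_plan(cfg)
  rows <- lapply(plan, function(ly) {
    if (ly$type == "conv")
      data.frame(type = if (isTRUE(ly$bn)) "conv+bn+relu+maxpool"
                        else "conv+relu+maxpool",
                 output = sprintf("%d x %d", ly$Q, ly$F),
                 params = ly$k * ly$C * ly$F + ly$F +
                   if (isTRUE(ly$bn)) 2L * ly$F else 0L)
    else if (ly$type == "gpool")
      data.frame(type = "global-mean-pool",
                 output = sprintf("%d", ly$F), params = 0)
    else
      data.frame(type = paste0("dense+", ly$act),
                 output = sprintf("%d", ly$n_out),
                 params = ly$n_in * ly$n_out + ly$n_out)
  })
  out <- do.call(rbind, rows)
  out$layer <- seq_len(nrow(out))
  out[, c("layer", "type", "output", "params")]
}
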
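# Internal neural-network engine: forward, backward and AdamW on top of the
# compiled conv/pool kernels. A batch is an array (L, C, B): position,
# channel, sample. Dense layers run on BLAS via %*%. Conv blocks optionally
# carry batch normalization (per-filter, over positions and samples), as in
# the reference architecture family; inference uses running statistics.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Build the layer plan (shapes) for a config; errors on impossible shapes.
layer_plan <- function(config) {
  L <- config$input_length
  C <- config$input_channels
  bn <- isTRUE(config$batch_norm)
  plan <- list()
  for (i in seq_along(config$conv_specs)) {
    spec <- config$conv_specs[[i]]
    f <- spec[1]; k <- spec[2]; w <- spec[3]
    P <- L - k + 1L
    if (P < 1L)
      stop(sprintf("conv layer %d: kernel width %d exceeds input length %d", i, k, L))
    Q <- P %/% w
    if (Q < 1L)
      stop(sprintf("conv layer %d: pool width %d collapses length %d below 1", i, w, P))
    plan[[length(plan) + 1L]] <- list(type = "conv", k = k, C = C, F = f,
                                      pool = w, P = P, Q = Q, bn = bn)
    L <- Q; C <- f
  }
  D <- L * C
  if (isTRUE(config$global_pool) && length(config$conv_specs) > 0L) {
    plan[[length(plan) + 1L]] <- list(type = "gpool", Q = L, F = C)
    D <- C
  }
  for (s in config$dense_sizes) {
    plan[[length(plan) + 1L]] <- list(type = "dense", n_in = D, n_out = s,
                                      act = "relu", dropout = config$dropout)
    D <- s
  }
  plan[[length(plan) + 1L]] <- list(type = "dense", n_in = D, n_out = 1L,
                                    act = config$output_activation, dropout = 0,
                                    init_scale = config$head_init_scale %||% 1)
  plan
}

init_params <- function(plan, seed) {
  with_seed(seed, {
    lapply(plan, function(ly) {
      if (ly$type == "gpool") {
        list(W = numeric(0), b = numeric(0))
      } else if (ly$type == "conv") {
        fan_in <- ly$k * ly$C
        s <- 1 / sqrt(fan_in)
        p <- list(W = array(runif(ly$k * ly$C * ly$F, -s, s),
                            dim = c(ly$k, ly$C, ly$F)),
                  b = runif(ly$F, -s, s))
        if (isTRUE(ly$bn)) {
          p$gamma <- rep(1, ly$F)
          p$beta <- rep(0, ly$F)
        }
        p
      } else {
        s <- (1 / sqrt(ly$n_in)) * (ly$init_scale %||% 1)
        list(W = matrix(runif(ly$n_in * ly$n_out, -s, s), ly$n_in, ly$n_out),
             b = runif(ly$n_out, -s, s))
      }
    })
  })
}

init_buffers <- function(plan) {
  lapply(plan, function(ly) {
    if (ly$type == "conv" && isTRUE(ly$bn))
      list(mean = rep(0, ly$F), var = rep(1, ly$F))
    else NULL
  })
}

# per-filter sums over the (position, sample) dimensions of a (P, F, B) array
per_filter_sum <- function(A) apply(A, 2, sum)

# Forward pass. X: array (L, C, B). Returns list(y, cache, buffers); cache
# holds per-layer intermediates for the backward pass (NULL unless
# keep_cache); buffers are the (possibly updated) batch-norm running stats.
nn_forward <- function(params, plan, X, buffers = NULL, training = FALSE,
                       keep_cache = FALSE, dropout_seed = NULL) {
  B <- dim(X)[3]
  if (is.null(buffers)) buffers <- init_buffers(plan)
  cache <- if (keep_cache) vector("list", length(plan)) else NULL
  H <- X
  flat_done <- FALSE
  drop_rng <- if (training && !is.null(dropout_seed)) dropout_seed else NULL
  for (i in seq_along(plan)) {
    ly <- plan[[i]]
    if (ly$type == "conv") {
      Z <- conv1d_fwd(H, params[[i]]$W, params[[i]]$b)
      bn_cc <- NULL
      if (isTRUE(ly$bn)) {
        if (training) {
          st <- bn_stats(Z)
          mu <- st$mean
          v <- st$var
          buffers[[i]]$mean <- (1 - BN_MOMENTUM) * buffers[[i]]$mean +
            BN_MOMENTUM * mu
          buffers[[i]]$var <- (1 - BN_MOMENTUM) * buffers[[i]]$var +
            BN_MOMENTUM * v
        } else {
          mu <- buffers[[i]]$mean
          v <- buffers[[i]]$var
        }
        scale <- 1 / sqrt(v + BN_EPS)
        ap <- bn_apply(Z, mu, scale, params[[i]]$gamma, params[[i]]$beta)
        Z <- ap$out
        bn_cc <- list(Zhat = ap$zhat, scale = scale, training = training)
      }
      A <- relu(Z)
      mp <- maxpool_fwd(A, ly$pool)
      if (keep_cache) cache[[i]] <- list(X = H, relu_mask = Z > 0,
                                         idx = mp$idx, P = ly$P, bn = bn_cc)
      H <- mp$out
    } else if (ly$type == "gpool") {
      H <- t(colMeans(H))  # (Q,F,B) -> B x F
      flat_done <- TRUE
      if (keep_cache) cache[[i]] <- list(Q = ly$Q)
    } else {
      if (!flat_done) {
        H <- t(matrix(H, nrow = prod(dim(H)[1:2]), ncol = B))  # B x D
        flat_done <- TRUE
      }
      Z <- H %*% params[[i]]$W
      Z <- sweep(Z, 2, params[[i]]$b, "+")
      A <- switch(ly$act,
                  relu = relu(Z),
                  sigmoid = 1 / (1 + exp(-Z)),
                  linear = Z)
      mask <- NULL
      if (training && ly$dropout > 0) {
        if (!is.null(drop_rng)) {
          mask <- with_seed(drop_rng + i, matrix(
            (runif(length(A)) >= ly$dropout) / (1 - ly$dropout),
            nrow(A), ncol(A)))
        } else {
          mask <- matrix((runif(length(A)) >= ly$dropout) / (1 - ly$dropout),
                         nrow(A), ncol(A))
        }
        A <- A * mask
      }
      if (keep_cache) cache[[i]] <- list(X = H, Z = Z, A = A, mask = mask, act = ly$act)
      H <- A
    }
  }
  list(y = as.numeric(H), cache = cache, buffers = buffers)
}

# Backward pass from d(loss)/d(output). Returns gradients shaped like params
# and, when need_dx, the gradient with respect to the input array (L, C, B);
# input_dim = c(L, C) is needed only when the first layer is dense.
nn_backward <- function(params, plan, cache, dy, need_dx = FALSE,
                        input_dim = NULL) {
  n <- length(plan)
  grads <- vector("list", n)
  dH <- matrix(dy, ncol = 1L)
  first_dense <- which(vapply(plan, function(l) l$type == "dense", logical(1)))[1]
  for (i in rev(seq_len(n))) {
    ly <- plan[[i]]
    cc <- cache[[i]]
    if (ly$type == "dense") {
      if (!is.null(cc$mask)) dH <- dH * cc$mask
      dZ <- switch(ly$act,
                   relu = dH * (cc$Z > 0),
                   sigmoid = {
                     sig <- 1 / (1 + exp(-cc$Z))
                     dH * sig * (1 - sig)
                   },
                   linear = dH)
      grads[[i]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
      dH <- tcrossprod(dZ, params[[i]]$W)  # B x n_in
      if (i == first_dense && i > 1L && plan[[i - 1L]]$type == "conv") {
        # unflatten to (Q, F, B) of the last conv block
        last_conv <- plan[[i - 1L]]
        dH <- array(t(dH), dim = c(last_conv$Q, last_conv$F, nrow(dH)))
      } else if (i == 1L && need_dx) {
        dH <- array(t(dH), dim = c(input_dim[1], input_dim[2], nrow(dH)))
      }
    } else if (ly$type == "gpool") {
      grads[[i]] <- list(W = numeric(0), b = numeric(0))
      B <- nrow(dH)
      dH <- array(rep(t(dH) / ly$Q, each = ly$Q), dim = c(ly$Q, ly$F, B))
    } else {
      dA <- maxpool_bwd(cc$idx, dH, cc$P)
      dZbn <- dA * cc$relu_mask
      g <- list(W = NULL, b = NULL)
      if (!is.null(cc$bn)) {
        bb <- bn_bwd(dZbn, cc$bn$Zhat, params[[i]]$gamma, cc$bn$scale,
                     isTRUE(cc$bn$training))
        g$gamma <- as.numeric(bb$dgamma)
        g$beta <- as.numeric(bb$dbeta)
        dZ <- bb$dZ
      } else {
        dZ <- dZbn
      }
      bw <- conv1d_bwd(cc$X, params[[i]]$W, dZ, need_dx || i > 1L)
      g$W <- bw$dW
      g$b <- bw$db
      grads[[i]] <- g
      if (i > 1L || need_dx) dH <- bw$dX
    }
  }
  list(grads = grads, dX = if (need_dx) dH else NULL)
}

tensor_names <- function(p) names(p)[vapply(p, length, integer(1)) > 0]

adamw_init <- function(params) {
  lapply(params, function(p) {
    st <- list()
    for (nm in tensor_names(p)) {
      st[[paste0("m_", nm)]] <- p[[nm]] * 0
      st[[paste0("v_", nm)]] <- p[[nm]] * 0
    }
    st
  })
}

adamw_step <- function(params, grads, state, t, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (i in seq_along(params)) {
    s <- state[[i]]
    for (nm in tensor_names(params[[i]])) {
      g <- grads[[i]][[nm]]
      s[[paste0("m_", nm)]] <- beta1 * s[[paste0("m_", nm)]] + (1 - beta1) * g
      s[[paste0("v_", nm)]] <- beta2 * s[[paste0("v_", nm)]] + (1 - beta2) * g^2
      # decoupled weight decay applies to weight matrices only
      wd <- if (nm == "W") weight_decay else 0
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * ((s[[paste0("m_", nm)]] / b1t) /
                (sqrt(s[[paste0("v_", nm)]] / b2t) + eps) +
              wd * params[[i]][[nm]])
    }
    state[[i]] <- s
  }
  list(params = params, state = state)
}
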
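#' Patch autoencoder architecture
#'
#' Describes the compact 2D convolutional autoencoder used for dual-modality
#' brain extraction. The encoder applies three convolutional layers (twelve
#' 5x5 kernels each, batch normalization, leaky rectifier with slope 0.1),
#' downsampling 16 -> 8 -> 4 -> 4 so the flattened feature vector has exactly
#' 192 entries; a fully connected 192 -> 192 bottleneck with dropout 0.25
#' follows, and the decoder mirrors the encoder with two transposed
#' convolutions (same structure) plus a final single-kernel transposed
#' convolution emitting a 16x16 patch of real-valued logits (no normalization,
#' no activation). At the default settings the model has 52,657 parameters:
#' 52,537 trainable and 120 non-trainable batch-norm running statistics.
#'
#' @param patch_size side of the square input patch, voxels.
#' @param in_channels input channels (T1 and T2).
#' @param n_kernels convolution kernels per hidden layer.
#' @param kernel_size convolution kernel side.
#' @param leak negative slope of the leaky rectifier.
#' @param dropout dropout rate after the dense bottleneck.
#' @param bn_eps,bn_momentum batch normalization constants (running statistics
#'   are updated as `momentum * running + (1 - momentum) * batch`).
#' @return An object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(patch_size = 16L, in_channels = 2L, n_kernels = 12L,
                             kernel_size = 5L, leak = 0.1, dropout = 0.25,
                             bn_eps = 1e-3, bn_momentum = 0.99) {
  spec <- list(patch_size = as.integer(patch_size),
               in_channels = as.integer(in_channels),
               n_kernels = as.integer(n_kernels),
               kernel_size = as.integer(kernel_size),
               leak = leak, dropout = dropout,
               bn_eps = bn_eps, bn_momentum = bn_momentum)
  # encoder strides (2, 2, 1): patch -> patch/2 -> patch/4 -> patch/4
  spec$bottleneck_hw <- spec$patch_size %/% 4L
  spec$bottleneck <- spec$bottleneck_hw^2 * spec$n_kernels
  structure(spec, class = "autoencoder_spec")
}

# "same"-style geometry: output size ceiling(n/s), asymmetric padding with the
# smaller pad before (parameter counts are independent of this choice)
conv_geom <- function(n_in, k, s) {
  n_out <- as.integer(ceiling(n_in / s))
  pad_total <- (n_out - 1L) * s + k - n_in
  list(n_out = n_out, pad = pad_total %/% 2L)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

new_conv <- function(n_in, cin, cout, k, stride) {
  g <- conv_geom(n_in, k, stride)
  list(type = "conv",
       W = glorot(c(k, k, cin, cout), k * k * cin, k * k * cout),
       b = numeric(cout), stride = stride, pad = g$pad,
       n_in = n_in, n_out = g$n_out)
}

# transposed convolution from n_in -> n_out expressed as the adjoint of a
# convolution n_out -> n_in; W is stored in the adjoint's layout
# (k, k, cout_tconv, cin_tconv)
new_tconv <- function(n_in, cin, cout, k, stride) {
  g <- conv_geom(n_in * stride, k, stride)
  n_out <- n_in * stride
  if (g$n_out != n_in) abort("transposed convolution geometry mismatch")
  list(type = "tconv",
       W = glorot(c(k, k, cout, cin), k * k * cin, k * k * cout),
       b = numeric(cout), stride = stride, pad = g$pad,
       n_in = n_in, n_out = n_out)
}

new_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

#' Build an untrained patch autoencoder
#'
#' Instantiates the layer sequence of [autoencoder_spec()] with Glorot-uniform
#' weights. The forward pass maps a batch of `in_channels` x 16 x 16 patches
#' to 16 x 16 logit patches.
#'
#' @param spec an [autoencoder_spec()].
#' @param seed optional integer seed for the weight initialisation.
#' @return An object of class `patch_autoencoder`.
#' @examples
#' m <- build_autoencoder(autoencoder_spec(), seed = 1)
#' count_parameters(m)
#' @export
build_autoencoder <- function(spec = autoencoder_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- spec$patch_size
  k <- spec$kernel_size
  nk <- spec$n_kernels
  bhw <- spec$bottleneck_hw
  nb <- spec$bottleneck
  if (bhw^2 * nk != nb) abort("flatten size does not match the bottleneck width")
  half <- conv_geom(p, k, 2L)$n_out
  layers <- list(
    new_conv(p, spec$in_channels, nk, k, 2L), new_bn(nk), list(type = "lrelu"),
    new_conv(half, nk, nk, k, 2L), new_bn(nk), list(type = "lrelu"),
    new_conv(bhw, nk, nk, k, 1L), new_bn(nk), list(type = "lrelu"),
    list(type = "flatten", in_dim = c(bhw, bhw, nk)),
    list(type = "dense",
         W = glorot(c(nb, nb), nb, nb), b = numeric(nb)),
    list(type = "dropout", rate = spec$dropout),
    list(type = "reshape", out_dim = c(bhw, bhw, nk)),
    new_tconv(bhw, nk, nk, k, 1L), new_bn(nk), list(type = "lrelu"),
    new_tconv(bhw, nk, nk, k, 2L), new_bn(nk), list(type = "lrelu"),
    new_tconv(half, nk, 1L, k, 2L)
  )
  structure(list(spec = spec, layers = layers), class = "patch_autoencoder")
}

#' Count model parameters
#'
#' Weights, biases and batch-norm scale/shift are trainable; batch-norm
#' running statistics are non-trainable.
#'
#' @param model a `patch_autoencoder`.
#' @return A named list with `total`, `trainable` and `non_trainable` counts.
#' @export
count_parameters <- function(model) {
  trainable <- 0L
  frozen <- 0L
  for (ly in model$layers) {
    if (ly$type %in% c("conv", "tconv", "dense")) {
      trainable <- trainable + length(ly$W) + length(ly$b)
    } else if (ly$type == "bn") {
      trainable <- trainable + length(ly$gamma) + length(ly$beta)
      frozen <- frozen + length(ly$rmean) + length(ly$rvar)
    }
  }
  list(total = trainable + frozen, trainable = trainable, non_trainable = frozen)
}

#' @export
print.patch_autoencoder <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<patch_autoencoder> %d layers, %d parameters (%d trainable, %d non-trainable)\n",
              length(x$layers), pc$total, pc$trainable, pc$non_trainable))
  invisible(x)
}

# forward / backward ----------------------------------------------------------
# Arrays are (H, W, C, N). Per-channel broadcasts exploit column-major
# recycling: a vector of length H*W*C recycles identically over N.

channel_broadcast <- function(v, hw) rep(v, each = hw)

channel_sums <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  s <- .colSums(m, d[1] * d[2], d[3] * d[4])
  dim(s) <- c(d[3], d[4])
  .rowSums(s, d[3], d[4])
}

add_channel_bias <- function(y, b) {
  d <- dim(y)
  y + channel_broadcast(b, d[1] * d[2])
}

net_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  layers <- model$layers
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      caches[[i]] <- list(x = x, xdim = dim(x))
      x <- .conv_fwd(x, ly$W, ly$b, ly$stride, ly$pad, ly$n_out, ly$n_out)
    } else if (ly$type == "tconv") {
      caches[[i]] <- list(x = x)
      N <- dim(x)[4]
      cout <- length(ly$b)
      y <- .conv_bwd_data(x, ly$W, ly$stride, ly$pad,
                          c(ly$n_out, ly$n_out, cout, N))
      x <- add_channel_bias(y, ly$b)
    } else if (ly$type == "bn") {
      d <- dim(x)
      hw <- d[1] * d[2]
      m <- hw * d[4]
      if (training) {
        mu <- channel_sums(x) / m
        xc <- x - channel_broadcast(mu, hw)
        v <- channel_sums(xc * xc) / m
        invstd <- 1 / sqrt(v + model$spec$bn_eps)
        xhat <- xc * channel_broadcast(invstd, hw)
        mom <- model$spec$bn_momentum
        model$layers[[i]]$rmean <- mom * ly$rmean + (1 - mom) * mu
        model$layers[[i]]$rvar <- mom * ly$rvar + (1 - mom) * v
        caches[[i]] <- list(xhat = xhat, invstd = invstd)
      } else {
        invstd <- 1 / sqrt(ly$rvar + model$spec$bn_eps)
        xhat <- (x - channel_broadcast(ly$rmean, hw)) *
          channel_broadcast(invstd, hw)
        caches[[i]] <- NULL
      }
      x <- xhat * channel_broadcast(ly$gamma, hw) +
        channel_broadcast(ly$beta, hw)
      dim(x) <- d
    } else if (ly$type == "lrelu") {
      pos <- x > 0
      caches[[i]] <- list(pos = pos)
      x <- x * pos + model$spec$leak * (x * !pos)
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(d = dim(x))
      dim(x) <- c(prod(dim(x)[1:3]), dim(x)[4])
    } else if (ly$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- ly$W %*% x + ly$b
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        keep <- array(runif(length(x)) >= ly$rate, dim(x))
        caches[[i]] <- list(keep = keep)
        x <- x * keep / (1 - ly$rate)
      }
    } else if (ly$type == "reshape") {
      N <- dim(x)[2]
      dim(x) <- c(ly$out_dim, N)
    }
  }
  list(out = x, caches = caches, model = model)
}

net_backward <- function(model, caches, dout) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  dx <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      cache <- caches[[i]]
      grads[[i]] <- list(W = .conv_bwd_w(cache$x, dx, dim(ly$W)[1], ly$stride, ly$pad),
                         b = channel_sums(dx))
      if (i > 1) {  # the input volume needs no gradient
        dx <- .conv_bwd_data(dx, ly$W, ly$stride, ly$pad, cache$xdim)
      }
    } else if (ly$type == "tconv") {
      cache <- caches[[i]]
      db <- channel_sums(dx)
      dW <- .conv_bwd_w(dx, cache$x, dim(ly$W)[1], ly$stride, ly$pad)
      grads[[i]] <- list(W = dW, b = db)
      dx <- .conv_fwd(dx, ly$W, numeric(dim(ly$W)[4]), ly$stride, ly$pad,
                      ly$n_in, ly$n_in)
    } else if (ly$type == "bn") {
      cache <- caches[[i]]
      d <- dim(dx)
      hw <- d[1] * d[2]
      m <- hw * d[4]
      dgamma <- channel_sums(dx * cache$xhat)
      dbeta <- channel_sums(dx)
      dxhat <- dx * channel_broadcast(ly$gamma, hw)
      s1 <- channel_sums(dxhat)
      s2 <- channel_sums(dxhat * cache$xhat)
      dx <- (dxhat - channel_broadcast(s1 / m, hw) -
               cache$xhat * channel_broadcast(s2 / m, hw)) *
        channel_broadcast(cache$invstd, hw)
      dim(dx) <- d
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (ly$type == "lrelu") {
      pos <- caches[[i]]$pos
      dx <- dx * pos + model$spec$leak * (dx * !pos)
    } else if (ly$type == "flatten") {
      dim(dx) <- caches[[i]]$d
    } else if (ly$type == "dense") {
      cache <- caches[[i]]
      grads[[i]] <- list(W = dx %*% t(cache$x), b = rowSums(dx))
      dx <- t(ly$W) %*% dx
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) {
        dx <- dx * caches[[i]]$keep / (1 - ly$rate)
      }
    } else if (ly$type == "reshape") {
      dim(dx) <- c(prod(dim(dx)[1:3]), dim(dx)[4])
    }
  }
  grads
}

# binary cross-entropy computed from logits, mean over all patch pixels
bce_with_logits <- function(z, t) {
  mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
}

bce_grad <- function(z, t) {
  (1 / (1 + exp(-z)) - t) / length(z)
}

# parameter flattening for the optimiser -------------------------------------

trainable_fields <- function(ly) {
  switch(ly$type,
         conv = c("W", "b"), tconv = c("W", "b"), dense = c("W", "b"),
         bn = c("gamma", "beta"), NULL)
}

get_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    for (f in trainable_fields(model$layers[[i]])) {
      out[[sprintf("%d.%s", i, f)]] <- model$layers[[i]][[f]]
    }
  }
  out
}

set_params <- function(model, flat) {
  pos <- 1L
  for (i in seq_along(model$layers)) {
    for (f in trainable_fields(model$layers[[i]])) {
      n <- length(model$layers[[i]][[f]])
      model$layers[[i]][[f]][] <- flat[pos:(pos + n - 1L)]
      pos <- pos + n
    }
  }
  model
}

flatten_grads <- function(model, grads) {
  out <- numeric(0)
  for (i in seq_along(model$layers)) {
    fields <- trainable_fields(model$layers[[i]])
    if (is.null(fields)) next
    for (f in fields) out <- c(out, as.vector(grads[[i]][[f]]))
  }
  out
}
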
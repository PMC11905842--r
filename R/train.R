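#' Training configuration
#'
#' Adam (beta1 = 0.9, beta2 = 0.999, amsgrad) on a binary cross-entropy loss
#' computed from logits, batch size 250, with a staged learning-rate schedule:
#' `epochs_per_rate` epochs are run at each value of `learning_rates` in turn.
#' The full-study settings are 25 epochs at each of 0.02, 0.01, 0.005, 0.002,
#' 0.001 (125 epochs) with 25,000 patches per scan per axis.
#'
#' @param learning_rates strictly decreasing vector of learning rates.
#' @param epochs_per_rate epochs run at each learning rate.
#' @param batch_size minibatch size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param amsgrad use the non-decreasing second-moment variant.
#' @param patches_per_scan_per_axis training patches sampled per annotated
#'   scan pair and per slice direction.
#' @param seed integer seed controlling sampling, initialisation, shuffling
#'   and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rates = c(0.02, 0.01, 0.005, 0.002, 0.001),
                         epochs_per_rate = 25L, batch_size = 250L,
                         beta1 = 0.9, beta2 = 0.999, amsgrad = TRUE,
                         patches_per_scan_per_axis = 25000L, seed = 1L) {
  if (any(diff(learning_rates) >= 0)) {
    abort("`learning_rates` must be strictly decreasing")
  }
  structure(list(learning_rates = learning_rates,
                 epochs_per_rate = as.integer(epochs_per_rate),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, amsgrad = amsgrad,
                 patches_per_scan_per_axis = as.integer(patches_per_scan_per_axis),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), vhat = numeric(n), t = 0L)
}

adam_step <- function(state, params, grad, lr, beta1, beta2, amsgrad, eps = 1e-7) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  v_use <- if (amsgrad) {
    state$vhat <- pmax(state$vhat, state$v)
    state$vhat
  } else {
    state$v
  }
  mhat <- state$m / (1 - beta1^state$t)
  vcorr <- v_use / (1 - beta2^state$t)
  list(state = state, params = params - lr * mhat / (sqrt(vcorr) + eps))
}

eval_loss <- function(model, inputs, targets, chunk = 2000L) {
  n <- dim(inputs)[4]
  total <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    z <- net_forward(model, inputs[, , , idx, drop = FALSE], training = FALSE)$out
    total <- total + bce_with_logits(z, targets[, , , idx, drop = FALSE]) * length(idx)
  }
  total / n
}

# Optimise one directional model on a patch set. Returns the model plus the
# loss (inference mode) before and after training.
train_autoencoder <- function(model, inputs, targets, config) {
  n <- dim(inputs)[4]
  if (n == 0) abort("cannot train on an empty patch set")
  if (length(dim(targets)) == 3) dim(targets) <- c(dim(targets)[1:2], 1L, n)
  flat <- unlist(get_params(model), use.names = FALSE)
  state <- adam_init(length(flat))
  set.seed(config$seed)
  loss_start <- eval_loss(model, inputs, targets)
  for (lr in config$learning_rates) {
    for (epoch in seq_len(config$epochs_per_rate)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- inputs[, , , idx, drop = FALSE]
        tb <- targets[, , , idx, drop = FALSE]
        fw <- net_forward(model, xb, training = TRUE)
        model <- fw$model  # batch-norm running statistics
        if (!all(is.finite(fw$out))) {
          abort("non-finite logits during training; aborting")
        }
        grads <- net_backward(model, fw$caches, bce_grad(fw$out, tb))
        g <- flatten_grads(model, grads)
        if (!all(is.finite(g))) abort("non-finite gradient during training; aborting")
        upd <- adam_step(state, unlist(get_params(model), use.names = FALSE), g,
                         lr, config$beta1, config$beta2, config$amsgrad)
        state <- upd$state
        model <- set_params(model, upd$params)
      }
    }
  }
  loss_end <- eval_loss(model, inputs, targets)
  list(model = model, loss_start = loss_start, loss_end = loss_end)
}

#' Train the three directional models
#'
#' Fits one patch autoencoder per slice direction (axial, sagittal, coronal)
#' under a shared architecture and training configuration. As a sanity
#' contract the training loss evaluated in inference mode must not increase;
#' a violation raises a warning.
#'
#' @param patch_sets named list with elements `axial`, `sagittal`, `coronal`,
#'   each a [sample_training_patches()] result.
#' @param config a [train_config()].
#' @param spec an [autoencoder_spec()].
#' @return An object of class `model_triplet`: the three trained models plus
#'   the intensity-normalisation rule applied to every input volume.
#' @export
train_triplet <- function(patch_sets, config = train_config(),
                          spec = autoencoder_spec()) {
  axes <- c("axial", "sagittal", "coronal")
  if (!all(axes %in% names(patch_sets))) {
    abort("`patch_sets` needs elements axial, sagittal and coronal")
  }
  models <- list()
  history <- list()
  for (i in seq_along(axes)) {
    ps <- patch_sets[[axes[i]]]
    if (dim(ps$inputs)[4] == 0) abort(sprintf("empty patch set for axis %s", axes[i]))
    model <- build_autoencoder(spec, seed = config$seed + i)
    cfg <- config
    cfg$seed <- config$seed + 100L * i
    fit <- train_autoencoder(model, ps$inputs, ps$targets, cfg)
    if (fit$loss_end > fit$loss_start) {
      warn(sprintf("training loss increased for axis %s (%.4g -> %.4g)",
                   axes[i], fit$loss_start, fit$loss_end))
    }
    models[[axes[i]]] <- fit$model
    history[[axes[i]]] <- c(start = fit$loss_start, end = fit$loss_end)
  }
  structure(list(models = models, spec = spec,
                 normalization = list(probs = c(0.01, 0.99)),
                 history = history),
            class = "model_triplet")
}

#' @export
print.model_triplet <- function(x, ...) {
  cat("<model_triplet> axial / sagittal / coronal patch autoencoders\n")
  for (ax in names(x$history)) {
    cat(sprintf("  %-8s loss %.4f -> %.4f\n", ax,
                x$history[[ax]]["start"], x$history[[ax]]["end"]))
  }
  invisible(x)
}

# Per-volume intensity normalisation: map the 1st/99th percentiles to [0, 1].
# Applied identically when sampling training patches and at inference.
normalize_intensity <- function(vol, probs = c(0.01, 0.99)) {
  q <- quantile(vol$values, probs, names = FALSE)
  if (q[2] <= q[1]) {
    vol$values <- vol$values - q[1]
  } else {
    vol$values <- (vol$values - q[1]) / (q[2] - q[1])
  }
  vol
}
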
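#' Training configuration
#'
#' The training protocol: two-class cross-entropy over softmax outputs,
#' Adam at an initial learning rate of 3e-4 divided by 10 at epoch 25, batch
#' size 16, 50 epochs.
#'
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param lr_initial Initial Adam learning rate.
#' @param lr_drop_factor Divisor applied at the drop epoch.
#' @param lr_drop_epoch First epoch (1-based) at which the reduced rate
#'   applies.
#' @param seed Seed for shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, epochs = 50L, lr_initial = 3e-4,
                         lr_drop_factor = 10, lr_drop_epoch = 25L,
                         seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 0, lr_initial > 0,
            lr_drop_factor > 0, lr_drop_epoch < max(epochs, lr_drop_epoch + 1L))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_initial = lr_initial,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch under the step schedule
#'
#' @param tc A [train_config()].
#' @param epoch Epoch number (1-based).
#' @return The learning rate in effect during that epoch.
#' @export
lr_schedule <- function(tc, epoch) {
  ifelse(epoch < tc$lr_drop_epoch, tc$lr_initial,
         tc$lr_initial / tc$lr_drop_factor)
}

zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

adam_step_tree <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      r <- adam_step_tree(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t,
                          beta1, beta2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
    list(p = p, m = m, v = v)
  }
}

#' Cross-entropy loss and logit gradient for 2-class softmax outputs
#' @noRd
xent_loss <- function(probs, labels) {
  n <- nrow(probs)
  p1 <- pmin(pmax(probs[, 2L], 1e-12), 1 - 1e-12)
  loss <- -mean(ifelse(labels == 1L, log(p1), log(1 - p1)))
  y <- cbind(1 - labels, labels)
  dlogits <- (probs - y) / n
  list(loss = loss, dlogits = dlogits)
}

#' Train a Sch-net model
#'
#' Minibatch Adam with the stepped learning-rate schedule and two-class
#' cross-entropy. Augmentation, when a policy is supplied, is applied to
#' training images only, with a fresh per-(epoch, sample) seed derived from
#' the training seed. With `epochs = 0` the model is returned unchanged
#' with an empty loss curve.
#'
#' @param model A `schnet_model` from [build_schnet()].
#' @param images List of `net_input_image` matrices.
#' @param labels Integer labels, 0 (control) or 1 (patient); both classes
#'   must be present.
#' @param tc A [train_config()].
#' @param augment_policy Optional [augmentation_policy()] applied to
#'   training batches.
#' @param verbose Print per-epoch loss.
#' @return List with the trained `model` and `loss_curve` (data frame of
#'   epoch, mean loss, training accuracy, learning rate).
#' @export
train_schnet <- function(model, images, labels, tc = train_config(),
                         augment_policy = NULL, verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L && tc$epochs > 0L) {
    stop("class-balance error: training data must contain both classes")
  }
  n <- length(images)
  stopifnot(length(labels) == n)
  if (tc$epochs == 0L) {
    return(list(model = model,
                loss_curve = data.frame(epoch = integer(), loss = numeric(),
                                        accuracy = numeric(), lr = numeric())))
  }
  opt_m <- zeros_like(model$params)
  opt_v <- zeros_like(model$params)
  step <- 0L
  curve <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_schedule(tc, epoch)
    ord <- with_seed(derive_seed(tc$seed, epoch), sample.int(n))
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      batch <- images[idx]
      if (!is.null(augment_policy) && augment_policy$enabled) {
        for (j in seq_along(batch)) {
          pol <- augment_policy
          pol$rng_seed <- derive_seed(tc$seed, epoch * 100003 + idx[j])
          batch[[j]] <- augment(batch[[j]], pol)
        }
      }
      x <- stack_images(batch)
      fw <- schnet_forward(model, x, train = TRUE, keep_cache = TRUE)
      model$state <- fw$state
      ls <- xent_loss(fw$probs, labels[idx])
      grads <- schnet_backward(model, fw$cache, ls$dlogits)
      step <- step + 1L
      upd <- adam_step_tree(model$params, grads, opt_m, opt_v, lr, step)
      model$params <- upd$p; opt_m <- upd$m; opt_v <- upd$v
      losses <- c(losses, ls$loss)
      correct <- correct + sum((fw$probs[, 2L] >= 0.5) == (labels[idx] == 1L))
    }
    curve[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                 accuracy = correct / n, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  lr %.2g",
                      epoch, mean(losses), correct / n, lr))
    }
  }
  list(model = model, loss_curve = do.call(rbind, curve))
}
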
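#' Combined Dice / cross-entropy segmentation loss
#'
#' The training loss is `L = -sum_s Dice_s + CE`, where for each class s
#' the smoothed Dice term is
#' `(2 * sum_x P_s(x) T_s(x) + eps) / (sum_x (P_s(x) + T_s(x)) + eps)`
#' and `CE = -sum_s sum_x T_s(x) log(max(P_s(x), eps))` is the categorical
#' cross-entropy. Lower is better; a perfect prediction with all classes
#' present approaches `-C`. The smoothing constant `eps` appears in both
#' numerator and denominator, so a class empty in both prediction and
#' truth contributes a perfect Dice term (-1 to the loss) and produces no
#' gradient — the standard convention that keeps absent classes from
#' destabilizing training. The log is clipped at `eps` for numerical
#' safety.
#'
#' @param probs a [ms_softmax()], or a `(nvox x C)` probability matrix.
#' @param truth a [ms_labels()], or a one-hot `(nvox x C)` matrix.
#' @param eps smoothing and clipping constant (default `1e-5`).
#' @return The scalar loss value.
#' @examples
#' t <- c(0, 0, 1, 1)
#' P <- cbind(1 - t, t)
#' dice_ce_loss(P, cbind(1 - t, t))  # perfect: close to -2
#' @export
dice_ce_loss <- function(probs, truth, eps = 1e-5) {
  pt <- loss_matrices(probs, truth)
  dice_ce_core(pt$P, pt$T, eps, grad = FALSE)$loss
}

loss_matrices <- function(probs, truth) {
  P <- if (inherits(probs, "ms_softmax")) {
    d <- dim(probs$data)
    matrix(probs$data, prod(d[1:3]), d[4])
  } else as.matrix(probs)
  C <- ncol(P)
  T_ <- if (inherits(truth, "ms_labels")) one_hot(truth, C) else as.matrix(truth)
  if (!all(dim(P) == dim(T_)))
    stop("probability and truth shapes do not match")
  rs <- rowSums(T_)
  if (max(abs(rs - 1)) > 1e-8 || any(T_ != 0 & T_ != 1))
    stop("truth must be one-hot (0/1 rows summing to 1)")
  list(P = P, T = T_)
}

# Loss and (optionally) its gradient w.r.t. the softmax probabilities.
dice_ce_core <- function(P, T_, eps, grad = TRUE) {
  A <- colSums(P * T_)                # per-class intersection
  B <- colSums(P) + colSums(T_)       # per-class mass
  dice <- (2 * A + eps) / (B + eps)
  Pc <- pmax(P, eps)
  ce <- -sum(T_ * log(Pc))
  loss <- -sum(dice) + ce
  if (!grad) return(list(loss = loss, dice = dice, ce = ce))
  # d(-dice_s)/dP_s(x) = -(2 T_s(x) (B_s+eps) - (2 A_s+eps)) / (B_s+eps)^2
  den <- (B + eps)^2
  gdice <- -(sweep(2 * T_, 2, B + eps, `*`) - matrix(2 * A + eps,
             nrow(P), ncol(P), byrow = TRUE)) / matrix(den, nrow(P),
             ncol(P), byrow = TRUE)
  gce <- -(T_ / Pc) * (P > eps)
  list(loss = loss, dice = dice, ce = ce, gP = gdice + gce, gce = gce)
}

# Gradient of the loss w.r.t. the pre-softmax logits. The Dice term goes
# through the softmax Jacobian (dL/dz_s = P_s * (g_s - sum_r g_r P_r));
# the cross-entropy term uses the exact softmax-CE identity dCE/dz = P - T,
# which — unlike differentiating the eps-clipped log — keeps gradient
# flowing to classes whose probability has collapsed below eps, so small
# structures cannot go permanently dead during training.
loss_grad_logits <- function(P, T_, eps) {
  g <- dice_ce_core(P, T_, eps, grad = TRUE)
  gd <- g$gP - g$gce  # Dice part only
  inner <- rowSums(gd * P)
  list(loss = g$loss, dlogits = P * (gd - inner) + (P - T_))
}

#' Random paired augmentation of a volume and its label map
#'
#' Draws one random geometric transform — translation, rotation and
#' isotropic crop-zoom about the volume center — and applies it to both
#' the image (cubic spline) and the label map (nearest neighbour), leaving
#' the grid shape unchanged. A zero-range control returns the pair
#' unchanged.
#'
#' @param image a [ms_volume()].
#' @param labels the paired [ms_labels()] (same grid).
#' @param control list with `max_translation_voxels` (default 5),
#'   `max_rotation_deg` (default 10) and `crop_fraction` (default 0.1).
#' @param seed integer seed making the draw reproducible.
#' @return A list with transformed `image` and `labels`.
#' @export
augment <- function(image, labels, control = augment_control(), seed = 1L) {
  stopifnot(identical(dim(image$data), dim(labels$data)))
  if (control$max_translation_voxels == 0 && control$max_rotation_deg == 0 &&
      control$crop_fraction == 0)
    return(list(image = image, labels = labels))
  with_seed(seed, {
    tra <- runif(3, -1, 1) * control$max_translation_voxels * image$spacing
    rot <- runif(3, -1, 1) * control$max_rotation_deg
    zoom <- if (control$crop_fraction > 0)
      1 / runif(1, 1 - control$crop_fraction, 1) else 1
  })
  center <- as.vector(image$affine %*% c((dim(image$data) - 1) / 2, 1))[1:3]
  t <- affine_from_params(translation = tra, rotation_deg = rot,
                          scale = rep(1 / zoom, 3), center = center)
  list(image = apply_transform(image, t, target_grid = image),
       labels = apply_transform(labels, t, target_grid = labels))
}

#' @rdname augment
#' @param max_translation_voxels,max_rotation_deg,crop_fraction ranges of
#'   the random transform draws.
#' @export
augment_control <- function(max_translation_voxels = 5,
                            max_rotation_deg = 10,
                            crop_fraction = 0.1) {
  list(max_translation_voxels = max_translation_voxels,
       max_rotation_deg = max_rotation_deg,
       crop_fraction = crop_fraction)
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs maximum number of epochs (default 400).
#' @param patience early-stopping patience: training stops once the
#'   validation loss has not improved for this many epochs (default 100;
#'   0 runs exactly one epoch). Must not exceed `max_epochs`.
#' @param batch_size gradient-accumulation batch size (default 1; volumes
#'   are large).
#' @param epsilon Dice smoothing / log clipping constant of the loss.
#' @param seed root seed governing weight initialization order,
#'   augmentation draws and data shuffling.
#' @param augment an [augment_control()] list, or `NULL` to disable
#'   augmentation.
#' @param normalize normalize input intensities to `[0, 100]` before
#'   training (percentiles 1/99)? Default `TRUE`.
#' @param min_val_dice optional early-success target: stop as soon as the
#'   validation average foreground Dice reaches this value (`NULL` to
#'   disable).
#' @param verbose print per-epoch progress?
#' @return A list of class `unet_control`.
#' @export
unet_control <- function(learning_rate = 0.001, max_epochs = 400L,
                         patience = 100L, batch_size = 1L,
                         epsilon = 1e-5, seed = 1L,
                         augment = augment_control(),
                         normalize = TRUE, min_val_dice = NULL,
                         verbose = FALSE) {
  if (patience > max_epochs) stop("patience must not exceed max_epochs")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 epsilon = epsilon, seed = as.integer(seed),
                 augment = augment, normalize = normalize,
                 min_val_dice = min_val_dice, verbose = verbose),
            class = "unet_control")
}

#' Fit a segmentation network
#'
#' Trains a [unet()] with the Adam optimizer on the combined
#' Dice/cross-entropy loss ([dice_ce_loss()]), applying random paired
#' augmentation to each training volume, monitoring the validation loss
#' after every epoch, and stopping early when it has not improved for
#' `patience` epochs. The returned model carries the weights of the
#' best-validation-loss epoch. The whole run is a pure function of the
#' control seed.
#'
#' @param object a [unet()].
#' @param train_pairs,val_pairs lists of `list(image =, labels =)` pairs
#'   (as produced by [phantom_dataset()]), all matching the network input
#'   shape.
#' @param control a [unet_control()].
#' @param ... unused.
#' @return An object of class `unet_fit` with elements `network` (best
#'   weights), `history` (per-epoch data.frame), `best_epoch` and
#'   `control`. Methods: `print`, `summary`, [predict.unet_fit()], `plot`
#'   (learning curves), [simulate.unet_fit()] (MC-dropout samples),
#'   `coef` (weight list).
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @export
fit.unet <- function(object, train_pairs, val_pairs, control = unet_control(),
                     ...) {
  net <- object
  if (length(train_pairs) < 1 || length(val_pairs) < 1)
    stop("need at least one training and one validation pair")
  shape <- net$config$input_shape
  C <- net$config$n_classes
  prep <- function(pair) {
    if (!identical(unname(dim(pair$image$data)), unname(shape)))
      stop("pair shape does not match network input shape")
    img <- if (control$normalize) normalize_intensity(pair$image) else pair$image
    list(image = img, labels = pair$labels,
         onehot = one_hot(pair$labels, C))
  }
  tr <- lapply(train_pairs, prep)
  va <- lapply(val_pairs, prep)

  # Adam state mirroring the trainable parameters
  pnames <- names(net$params)
  adam_m <- list(); adam_v <- list()
  for (nm in pnames) {
    p <- net$params[[nm]]
    adam_m[[nm]] <- if (!is.null(p$w)) list(w = p$w * 0, b = p$b * 0)
                    else list(gamma = p$gamma * 0, beta = p$beta * 0)
    adam_v[[nm]] <- adam_m[[nm]]
  }
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; step <- 0L
  lr <- control$learning_rate

  adam_update <- function(params, grads) {
    step <<- step + 1L
    ct <- lr * sqrt(1 - b2^step) / (1 - b1^step)
    for (nm in names(grads)) {
      for (f in names(grads[[nm]])) {
        g <- grads[[nm]][[f]]
        adam_m[[nm]][[f]] <<- b1 * adam_m[[nm]][[f]] + (1 - b1) * g
        adam_v[[nm]][[f]] <<- b2 * adam_v[[nm]][[f]] + (1 - b2) * g * g
        params[[nm]][[f]] <- params[[nm]][[f]] -
          ct * adam_m[[nm]][[f]] / (sqrt(adam_v[[nm]][[f]]) + adam_eps)
      }
    }
    params
  }

  add_grads <- function(a, b) {
    if (is.null(a)) return(b)
    for (nm in names(b)) for (f in names(b[[nm]]))
      a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
    a
  }
  scale_grads <- function(g, s) {
    for (nm in names(g)) for (f in names(g[[nm]]))
      g[[nm]][[f]] <- g[[nm]][[f]] * s
    g
  }

  validate <- function(net) {
    losses <- numeric(length(va)); dices <- numeric(length(va))
    for (i in seq_along(va)) {
      out <- unet_forward_core(net, as_input_matrix(va[[i]]$image))
      lg <- dice_ce_core(out$probs, va[[i]]$onehot, control$epsilon,
                         grad = FALSE)
      losses[i] <- lg$loss
      pred <- max.col(out$probs, ties.method = "first") - 1L
      truth <- as.vector(va[[i]]$labels$data)
      dices[i] <- mean_foreground_dice(pred, truth, C)
    }
    c(loss = mean(losses), dice = mean(dices))
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_dice = numeric())
  best_loss <- Inf; best_epoch <- 0L; best_params <- net$params
  set.seed(control$seed)

  for (epoch in seq_len(control$max_epochs)) {
    order_ <- sample.int(length(tr))
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (idx in order_) {
      pair <- tr[[idx]]
      if (!is.null(control$augment)) {
        aseed <- sample.int(.Machine$integer.max, 1)
        ag <- augment(pair$image, pair$labels, control$augment, seed = aseed)
        x <- as_input_matrix(ag$image)
        t_ <- one_hot(ag$labels, C)
      } else {
        x <- as_input_matrix(pair$image)
        t_ <- pair$onehot
      }
      out <- unet_forward_core(net, x, mode = "train", keep_cache = TRUE)
      net <- out$net
      lg <- loss_grad_logits(out$probs, t_, control$epsilon)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      ep_loss <- ep_loss + lg$loss
      grads <- unet_backward_core(net, out$cache, lg$dlogits)
      acc <- add_grads(acc, grads); acc_n <- acc_n + 1L
      if (acc_n >= control$batch_size) {
        if (acc_n > 1L) acc <- scale_grads(acc, 1 / acc_n)
        net$params <- adam_update(net$params, acc)
        acc <- NULL; acc_n <- 0L
      }
    }
    if (acc_n > 0L) {
      if (acc_n > 1L) acc <- scale_grads(acc, 1 / acc_n)
      net$params <- adam_update(net$params, acc)
    }
    vm <- validate(net)
    history[epoch, ] <- list(epoch, ep_loss / length(tr), vm[["loss"]],
                             vm[["dice"]])
    if (control$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val Dice %.4f",
                      epoch, ep_loss / length(tr), vm[["loss"]], vm[["dice"]]))
    if (vm[["loss"]] < best_loss) {
      best_loss <- vm[["loss"]]; best_epoch <- epoch
      best_params <- net$params
    }
    if (!is.null(control$min_val_dice) &&
        is.finite(vm[["dice"]]) && vm[["dice"]] >= control$min_val_dice) {
      if (vm[["loss"]] >= best_loss) {  # keep the epoch that met the target
        best_loss <- vm[["loss"]]; best_epoch <- epoch
        best_params <- net$params
      }
      break
    }
    if (epoch - best_epoch >= control$patience) break
  }

  net$params <- best_params
  structure(list(network = net, history = history, best_epoch = best_epoch,
                 best_val_loss = best_loss, control = control),
            class = "unet_fit")
}

# Mean Dice over the non-background classes present in prediction or
# truth (internal, used for the validation trace).
mean_foreground_dice <- function(pred, truth, C) {
  ds <- numeric(0)
  for (s in seq_len(C - 1)) {
    np <- sum(pred == s); nt <- sum(truth == s)
    if (np + nt == 0) next
    ds <- c(ds, 2 * sum(pred == s & truth == s) / (np + nt))
  }
  if (!length(ds)) return(NA_real_)
  mean(ds)
}

#' @export
print.unet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<unet_fit> %d epoch(s); best epoch %d (val loss %.4f, val Dice %.4f)\n",
              nrow(h), x$best_epoch, x$best_val_loss,
              h$val_dice[x$best_epoch]))
  print(x$network)
  invisible(x)
}

#' @export
summary.unet_fit <- function(object, ...) {
  h <- object$history
  cat("Training history (", nrow(h), " epochs):\n", sep = "")
  print(utils::tail(h, 5), row.names = FALSE)
  cat(sprintf("Best epoch %d: val loss %.5f, val Dice %.4f\n",
              object$best_epoch, object$best_val_loss,
              h$val_dice[object$best_epoch]))
  invisible(object)
}

#' Predict a segmentation from a fitted network
#'
#' @param object a `unet_fit`.
#' @param newdata a [ms_volume()] matching the network input shape.
#' @param type `"label"` for the argmax hard segmentation, `"prob"` for
#'   the softmax map.
#' @param stochastic keep dropout active (Monte-Carlo pass)?
#' @param seed dropout seed when `stochastic = TRUE`.
#' @param normalize normalize intensities to `[0, 100]` first (matching
#'   training; default `TRUE`).
#' @param ... unused.
#' @return A [ms_labels()] or [ms_softmax()].
#' @export
predict.unet_fit <- function(object, newdata, type = c("label", "prob"),
                             stochastic = FALSE, seed = NULL,
                             normalize = TRUE, ...) {
  type <- match.arg(type)
  v <- if (normalize) normalize_intensity(newdata) else newdata
  sm <- forward_unet(object$network, v, stochastic = stochastic, seed = seed)
  if (type == "prob") sm else hard_segmentation(sm)
}

#' Draw Monte-Carlo dropout samples from a fitted network
#'
#' `simulate` on a fitted segmentation model returns stochastic forward
#' passes (dropout active), i.e. the MC sample set used for uncertainty
#' quantification.
#'
#' @param object a `unet_fit`.
#' @param nsim number of MC samples.
#' @param seed integer seed from which per-sample dropout seeds are drawn.
#' @param newdata a [ms_volume()].
#' @param normalize normalize intensities first? Default `TRUE`.
#' @param ... unused.
#' @return A `ms_mcsamples` object (see [mc_predict()]).
#' @export
simulate.unet_fit <- function(object, nsim = 15, seed = 1L, newdata,
                              normalize = TRUE, ...) {
  mc_predict(object, newdata,
             config = inference_config(n_samples = nsim, seed = seed),
             normalize = normalize)
}

#' @export
coef.unet_fit <- function(object, ...) object$network$params

#' @export
plot.unet_fit <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), finite = TRUE)
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = rng, main = "Training history", ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", legend = c("train", "validation"), lty = c(1, 2),
         bty = "n")
  invisible(x)
}
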
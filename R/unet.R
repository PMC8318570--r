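#' Construct a 3D U-Net segmentation network
#'
#' Builds the encoder-decoder architecture with skip connections used for
#' volumetric anatomical segmentation: `depth` encoder blocks (each two
#' [conv -> batch-norm -> ReLU] operations, then channel-wise dropout,
#' then 2x max-pooling), a bottleneck block (two conv-BN-ReLU, *no*
#' dropout), `depth` decoder blocks (2x2x2/stride-2 transpose convolution
#' that halves the channels, concatenation with the matching encoder skip,
#' two conv-BN-ReLU, dropout), and a final 1x1x1 convolution to
#' `n_classes` channels followed by a voxelwise softmax. Convolutions use
#' "same" padding so the output grid equals the input grid. The number of
#' feature maps starts at `n_filters` and doubles after every encoder
#' block (halves in the decoder).
#'
#' Dropout is elementwise by default (each voxel-feature activation is
#' dropped independently), matching the plain dropout layer of the major
#' deep-learning frameworks; `dropout_type = "channel"` switches to
#' spatial (channel-wise) dropout, which zeroes whole feature maps. On
#' narrow networks channel dropout perturbs Monte-Carlo samples so
#' violently that entire structures vanish from individual samples, which
#' is why it is not the default.
#'
#' @param input_shape 3 integers, each divisible by `2^depth`.
#' @param n_classes number of output classes C including background
#'   (default 28).
#' @param depth number of pooling stages D (default 4).
#' @param n_filters feature maps after the first convolution, F (default
#'   32).
#' @param kernel convolution kernel size, default `c(3,3,3)` (must be
#'   cubic with odd size).
#' @param dropout dropout rate r in `[0, 1)` (default 0.2).
#' @param dropout_type `"element"` (default) or `"channel"` (spatial
#'   dropout).
#' @param seed integer seed for He-normal weight initialization.
#' @return An object of class `unet` with elements `config`, `plan`
#'   (channel widths and grid sizes per level) and `params`.
#' @examples
#' net <- unet(c(16, 16, 16), n_classes = 3, depth = 1, n_filters = 2)
#' net
#' @export
unet <- function(input_shape, n_classes = 28L, depth = 4L, n_filters = 32L,
                 kernel = c(3, 3, 3), dropout = 0.2,
                 dropout_type = c("element", "channel"), seed = 1L) {
  dropout_type <- match.arg(dropout_type)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape < 2))
    stop("input_shape must be 3 positive integers")
  depth <- as.integer(depth)
  if (any(input_shape %% 2L^depth != 0L))
    stop("each input dimension must be divisible by 2^depth = ", 2L^depth)
  if (n_filters < 1) stop("n_filters must be >= 1")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(kernel) != 3 || length(unique(kernel)) != 1 || kernel[1] %% 2 == 0)
    stop("kernel must be cubic with odd size, e.g. c(3,3,3)")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  k <- as.integer(kernel[1])

  f_enc <- n_filters * 2L^(seq_len(depth) - 1L)
  f_bott <- n_filters * 2L^depth
  dims <- lapply(0:depth, function(l) input_shape %/% 2L^l)
  plan <- list(encoder_channels = f_enc, bottleneck_channels = f_bott,
               decoder_channels = rev(f_enc), dims = dims, kernel = k)

  config <- list(input_shape = input_shape, n_classes = as.integer(n_classes),
                 depth = depth, n_filters = as.integer(n_filters),
                 kernel = c(k, k, k), dropout = dropout,
                 dropout_type = dropout_type, seed = as.integer(seed))

  he_conv <- function(cin, cout, kk = k) {
    list(w = matrix(rnorm(kk^3 * cin * cout, 0, sqrt(2 / (kk^3 * cin))),
                    kk^3 * cin, cout),
         b = numeric(cout), cin = cin, cout = cout)
  }
  new_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                             rmean = numeric(c), rvar = rep(1, c))
  he_tconv <- function(cin, cout) {
    list(w = matrix(rnorm(8 * cin * cout, 0, sqrt(2 / cin)), 8 * cin, cout),
         b = numeric(cout), cin = cin, cout = cout)
  }

  params <- list()
  with_seed(seed, {
    cin <- 1L
    for (i in seq_len(depth)) {
      f <- f_enc[i]
      params[[paste0("enc", i, "_conv1")]] <- he_conv(cin, f)
      params[[paste0("enc", i, "_bn1")]] <- new_bn(f)
      params[[paste0("enc", i, "_conv2")]] <- he_conv(f, f)
      params[[paste0("enc", i, "_bn2")]] <- new_bn(f)
      cin <- f
    }
    params[["bott_conv1"]] <- he_conv(cin, f_bott)
    params[["bott_bn1"]] <- new_bn(f_bott)
    params[["bott_conv2"]] <- he_conv(f_bott, f_bott)
    params[["bott_bn2"]] <- new_bn(f_bott)
    cin <- f_bott
    for (i in rev(seq_len(depth))) {
      f <- f_enc[i]
      params[[paste0("dec", i, "_tconv")]] <- he_tconv(cin, f)
      params[[paste0("dec", i, "_conv1")]] <- he_conv(2L * f, f)
      params[[paste0("dec", i, "_bn1")]] <- new_bn(f)
      params[[paste0("dec", i, "_conv2")]] <- he_conv(f, f)
      params[[paste0("dec", i, "_bn2")]] <- new_bn(f)
      cin <- f
    }
    params[["out_conv"]] <- list(
      w = matrix(rnorm(cin * n_classes, 0, sqrt(2 / cin)), cin, n_classes),
      b = numeric(n_classes), cin = cin, cout = as.integer(n_classes))
  })

  structure(list(config = config, plan = plan, params = params),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<unet> input %s, C=%d classes, D=%d, F=%d, kernel %dx%dx%d, dropout r=%.2f\n",
              paste(cfg$input_shape, collapse = "x"), cfg$n_classes,
              cfg$depth, cfg$n_filters, cfg$kernel[1], cfg$kernel[1],
              cfg$kernel[1], cfg$dropout))
  cat(sprintf("  encoder channels: %s | bottleneck: %d (no dropout)\n",
              paste(x$plan$encoder_channels, collapse = "/"),
              x$plan$bottleneck_channels))
  cat(sprintf("  trainable parameters: %s\n",
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a network
#'
#' Counts convolution/transpose-convolution weights and biases and
#' batch-norm scale/shift parameters (running statistics are not
#' trainable).
#'
#' @param net a [unet()] or `unet_fit`.
#' @return Integer count.
#' @export
n_params <- function(net) {
  if (inherits(net, "unet_fit")) net <- net$network
  sum(vapply(net$params, function(p) {
    if (!is.null(p$w)) length(p$w) + length(p$b)
    else length(p$gamma) + length(p$beta)
  }, numeric(1)))
}

bn_eps <- 1e-5
bn_momentum <- 0.9

bn_forward <- function(p, x, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + bn_eps)
    p$rmean <- bn_momentum * p$rmean + (1 - bn_momentum) * mu
    p$rvar <- bn_momentum * p$rvar + (1 - bn_momentum) * v
  } else {
    mu <- p$rmean
    invstd <- 1 / sqrt(p$rvar + bn_eps)
  }
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = y, xhat = xhat, invstd = invstd, p = p)
}

bn_backward <- function(p, cache, dy) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, p$gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, s1 / n, `-`) - sweep(cache$xhat, 2, s2 / n, `*`)
  dx <- sweep(dx, 2, cache$invstd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

drop_mask <- function(nchan, rate) {
  if (rate <= 0) return(rep(1, nchan))
  (runif(nchan) >= rate) / (1 - rate)
}

apply_dropout <- function(x, rate, type) {
  if (type == "channel") {
    m <- drop_mask(ncol(x), rate)
    list(y = sweep(x, 2, m, `*`), mask = m)
  } else {
    m <- matrix((runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
    list(y = x * m, mask = m)
  }
}

dropout_bwd <- function(dy, mask, type) {
  if (type == "channel") sweep(dy, 2, mask, `*`) else dy * mask
}

softmax_rows <- function(z) {
  rm <- z[, 1]
  nc <- ncol(z)
  if (nc > 1) for (j in 2:nc) rm <- pmax(rm, z[, j])
  e <- exp(z - rm)
  e / rowSums(e)
}

# Forward pass on the (nvox x 1) input matrix.
# mode: "infer" (deterministic), "mc" (dropout active, BN running stats),
# "train" (BN batch stats + running update, dropout active, caches kept).
# Dropout randomness comes from the current RNG state; callers seed it.
unet_forward_core <- function(net, x, mode = "infer", keep_cache = FALSE) {
  cfg <- net$config
  pl <- net$plan
  P <- net$params
  k <- pl$kernel
  D <- cfg$depth
  training <- mode == "train"
  use_dropout <- mode %in% c("train", "mc") && cfg$dropout > 0
  cache <- if (keep_cache) list() else NULL
  skips <- vector("list", D)

  cur <- x
  for (i in seq_len(D)) {
    dims <- pl$dims[[i]]
    for (j in 1:2) {
      cn <- paste0("enc", i, "_conv", j)
      bn <- paste0("enc", i, "_bn", j)
      cin <- cur
      y <- cpp_conv3d_forward(cin, P[[cn]]$w, P[[cn]]$b, dims, k)
      bf <- bn_forward(P[[bn]], y, training)
      P[[bn]] <- bf$p
      act <- bf$y * (bf$y > 0)
      if (keep_cache)
        cache[[cn]] <- list(x = cin, dims = dims, bn = bf[c("xhat", "invstd")],
                            relu = bf$y > 0)
      cur <- act
    }
    if (use_dropout) {
      dp <- apply_dropout(cur, cfg$dropout, cfg$dropout_type)
      cur <- dp$y
      if (keep_cache) cache[[paste0("enc", i, "_drop")]] <- dp$mask
    }
    skips[[i]] <- cur
    mp <- cpp_maxpool2_forward(cur, dims)
    if (keep_cache) cache[[paste0("enc", i, "_pool")]] <-
      list(idx = mp$idx, nvox_in = nrow(cur))
    cur <- mp$y
  }

  dims <- pl$dims[[D + 1]]
  for (j in 1:2) {
    cn <- paste0("bott_conv", j)
    bn <- paste0("bott_bn", j)
    cin <- cur
    y <- cpp_conv3d_forward(cin, P[[cn]]$w, P[[cn]]$b, dims, k)
    bf <- bn_forward(P[[bn]], y, training)
    P[[bn]] <- bf$p
    act <- bf$y * (bf$y > 0)
    if (keep_cache)
      cache[[cn]] <- list(x = cin, dims = dims, bn = bf[c("xhat", "invstd")],
                          relu = bf$y > 0)
    cur <- act
  }

  for (i in rev(seq_len(D))) {
    tn <- paste0("dec", i, "_tconv")
    dims_in <- pl$dims[[i + 1]]
    dims_out <- pl$dims[[i]]
    tin <- cur
    up <- cpp_tconv2_forward(tin, P[[tn]]$w, P[[tn]]$b, dims_in)
    if (keep_cache) cache[[tn]] <- list(x = tin, dims = dims_in)
    cur <- cbind(up, skips[[i]])
    if (keep_cache) cache[[paste0("dec", i, "_cat")]] <- ncol(up)
    for (j in 1:2) {
      cn <- paste0("dec", i, "_conv", j)
      bn <- paste0("dec", i, "_bn", j)
      cin <- cur
      y <- cpp_conv3d_forward(cin, P[[cn]]$w, P[[cn]]$b, dims_out, k)
      bf <- bn_forward(P[[bn]], y, training)
      P[[bn]] <- bf$p
      act <- bf$y * (bf$y > 0)
      if (keep_cache)
        cache[[cn]] <- list(x = cin, dims = dims_out,
                            bn = bf[c("xhat", "invstd")], relu = bf$y > 0)
      cur <- act
    }
    if (use_dropout) {
      dp <- apply_dropout(cur, cfg$dropout, cfg$dropout_type)
      cur <- dp$y
      if (keep_cache) cache[[paste0("dec", i, "_drop")]] <- dp$mask
    }
  }

  oc <- P[["out_conv"]]
  logits <- sweep(cur %*% oc$w, 2, oc$b, `+`)
  if (keep_cache) cache[["out_conv"]] <- list(x = cur)
  probs <- softmax_rows(logits)
  if (keep_cache) cache[["probs"]] <- probs

  net$params <- P  # running BN stats may have been updated
  list(probs = probs, cache = cache, net = net)
}

# Backward pass from the gradient of the loss w.r.t. the logits.
# Returns a list of gradients mirroring net$params (w/b/gamma/beta).
unet_backward_core <- function(net, cache, dlogits) {
  cfg <- net$config
  pl <- net$plan
  P <- net$params
  k <- pl$kernel
  D <- cfg$depth
  G <- list()

  oc <- P[["out_conv"]]
  xo <- cache[["out_conv"]]$x
  G[["out_conv"]] <- list(w = t(xo) %*% dlogits, b = colSums(dlogits))
  dcur <- dlogits %*% t(oc$w)

  dskips <- vector("list", D)
  for (i in seq_len(D)) {
    m <- cache[[paste0("dec", i, "_drop")]]
    if (!is.null(m)) dcur <- dropout_bwd(dcur, m, cfg$dropout_type)
    for (j in 2:1) {
      cn <- paste0("dec", i, "_conv", j)
      bn <- paste0("dec", i, "_bn", j)
      cc <- cache[[cn]]
      dy <- dcur * cc$relu
      bb <- bn_backward(P[[bn]], cc$bn, dy)
      G[[bn]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      cb <- cpp_conv3d_backward(cc$x, P[[cn]]$w, bb$dx, cc$dims, k)
      G[[cn]] <- list(w = cb$dw, b = cb$db)
      dcur <- cb$dx
    }
    ncat <- cache[[paste0("dec", i, "_cat")]]
    dup <- dcur[, seq_len(ncat), drop = FALSE]
    dskips[[i]] <- dcur[, -seq_len(ncat), drop = FALSE]
    tn <- paste0("dec", i, "_tconv")
    tc <- cache[[tn]]
    tb <- cpp_tconv2_backward(tc$x, P[[tn]]$w, dup, tc$dims)
    G[[tn]] <- list(w = tb$dw, b = tb$db)
    dcur <- tb$dx
  }

  for (j in 2:1) {
    cn <- paste0("bott_conv", j)
    bn <- paste0("bott_bn", j)
    cc <- cache[[cn]]
    dy <- dcur * cc$relu
    bb <- bn_backward(P[[bn]], cc$bn, dy)
    G[[bn]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    cb <- cpp_conv3d_backward(cc$x, P[[cn]]$w, bb$dx, cc$dims, k)
    G[[cn]] <- list(w = cb$dw, b = cb$db)
    dcur <- cb$dx
  }

  for (i in rev(seq_len(D))) {
    pc <- cache[[paste0("enc", i, "_pool")]]
    dcur <- cpp_maxpool2_backward(dcur, pc$idx, pc$nvox_in)
    dcur <- dcur + dskips[[i]]
    m <- cache[[paste0("enc", i, "_drop")]]
    if (!is.null(m)) dcur <- dropout_bwd(dcur, m, cfg$dropout_type)
    for (j in 2:1) {
      cn <- paste0("enc", i, "_conv", j)
      bn <- paste0("enc", i, "_bn", j)
      cc <- cache[[cn]]
      dy <- dcur * cc$relu
      bb <- bn_backward(P[[bn]], cc$bn, dy)
      G[[bn]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      cb <- cpp_conv3d_backward(cc$x, P[[cn]]$w, bb$dx, cc$dims, k)
      G[[cn]] <- list(w = cb$dw, b = cb$db)
      dcur <- cb$dx
    }
  }
  G
}

#' Run a forward pass of the network on a volume
#'
#' Produces the softmax quasi-probability map `P_s(x)` for each class.
#' With `stochastic = FALSE` the pass is fully deterministic (dropout off,
#' batch normalization in inference mode using running statistics). With
#' `stochastic = TRUE` dropout layers stay active at the configured rate
#' (batch norm still uses running statistics), and the output is a pure
#' function of `seed` — the mechanism behind Monte-Carlo dropout sampling.
#'
#' @param net a [unet()] or `unet_fit`.
#' @param volume a [ms_volume()] whose grid matches `input_shape`
#'   (intensities are expected on the trained scale, normally `[0, 100]`).
#' @param stochastic keep dropout active?
#' @param seed integer seed for the dropout masks (required when
#'   `stochastic = TRUE`).
#' @return A [ms_softmax()]; voxelwise class probabilities summing to 1.
#' @export
forward_unet <- function(net, volume, stochastic = FALSE, seed = NULL) {
  if (inherits(net, "unet_fit")) net <- net$network
  stopifnot(inherits(net, "unet"))
  x <- if (inherits(volume, "ms_volume")) volume else ms_volume(volume)
  if (!identical(unname(dim(x$data)), unname(net$config$input_shape)))
    stop("volume shape ", paste(dim(x$data), collapse = "x"),
         " does not match network input ",
         paste(net$config$input_shape, collapse = "x"))
  xm <- as_input_matrix(x)
  if (stochastic) {
    if (is.null(seed)) stop("stochastic forward passes require a seed")
    out <- with_seed(seed, unet_forward_core(net, xm, mode = "mc"))
  } else {
    out <- unet_forward_core(net, xm, mode = "infer")
  }
  ms_softmax(array(out$probs, c(dim(x$data), net$config$n_classes)),
             x$spacing, x$affine)
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a directory holding the weights in R's native
#' serialization (`weights.rds`) plus the network configuration as JSON
#' (`config.json`); the pair fully reconstructs the network.
#'
#' @param net a [unet()] or `unet_fit` (the underlying network is saved).
#' @param dir checkpoint directory (created if needed).
#' @return `save_unet` returns `dir` invisibly; `load_unet` returns a
#'   [unet()].
#' @export
save_unet <- function(net, dir) {
  if (inherits(net, "unet_fit")) net <- net$network
  stopifnot(inherits(net, "unet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(net$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(net$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_unet
#' @export
load_unet <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  net <- unet(input_shape = cfg$input_shape, n_classes = cfg$n_classes,
              depth = cfg$depth, n_filters = cfg$n_filters,
              kernel = cfg$kernel, dropout = cfg$dropout,
              dropout_type = cfg$dropout_type %||% "element",
              seed = cfg$seed)
  net$params <- readRDS(file.path(dir, "weights.rds"))
  net
}
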
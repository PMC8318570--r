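# Shared fixtures: small phantoms, tiny trained networks, and independent
# brute-force oracles used to cross-check the package implementations.

small_phantom <- function(grid = c(32, 32, 32), n_structures = 4,
                          geometry_seed = 3, wobble = 0.05) {
  phantom_spec(grid_shape = grid, n_structures = n_structures,
               geometry_seed = geometry_seed, wobble = wobble)
}

phantom_pair <- function(grid = c(32, 32, 32), n_structures = 4,
                         geometry_seed = 3, modality = "t1", seed = 11) {
  lab <- generate_label_map(small_phantom(grid, n_structures, geometry_seed))
  img <- render_modality(lab, modality_contrast(modality, n_structures),
                         seed = seed)
  list(image = img, labels = lab)
}

random_label_array <- function(d, n_labels, seed) {
  withr::with_seed(seed,
    array(sample(0:n_labels, prod(d), replace = TRUE), d))
}

# --- independent scalar oracles (pure R, no package internals) -----------

oracle_dice <- function(pred, truth, s) {
  a <- which(pred == s); b <- which(truth == s)
  if (length(a) + length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else FALSE,
      if (i < d[1]) mask[i + 1, j, k] else FALSE,
      if (j > 1) mask[i, j - 1, k] else FALSE,
      if (j < d[2]) mask[i, j + 1, k] else FALSE,
      if (k > 1) mask[i, j, k - 1] else FALSE,
      if (k < d[3]) mask[i, j, k + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_assd <- function(pred, truth, s, spacing = c(1, 1, 1)) {
  A <- oracle_surface(truth == s)
  B <- oracle_surface(pred == s)
  if (is.null(A) || is.null(B)) return(NA_real_)
  Amm <- sweep(A - 1, 2, spacing, `*`)
  Bmm <- sweep(B - 1, 2, spacing, `*`)
  d2 <- function(p, Q) min(sqrt(colSums((t(Q) - p)^2)))
  sumA <- sum(apply(Amm, 1, d2, Q = Bmm))
  sumB <- sum(apply(Bmm, 1, d2, Q = Amm))
  (sumA + sumB) / (nrow(A) + nrow(B))
}

# scalar re-implementation of the combined Dice/cross-entropy loss,
# written with explicit loops, independent of the vectorized one
oracle_dice_ce <- function(P, T_, eps) {
  C <- ncol(P)
  loss <- 0
  for (s in seq_len(C)) {
    num <- 0; den <- 0
    for (x in seq_len(nrow(P))) {
      num <- num + P[x, s] * T_[x, s]
      den <- den + P[x, s] + T_[x, s]
    }
    loss <- loss - (2 * num + eps) / (den + eps)
  }
  for (s in seq_len(C)) for (x in seq_len(nrow(P)))
    loss <- loss - T_[x, s] * log(max(P[x, s], eps))
  loss
}

# --- shared trained models (computed once per test run) ------------------

.fixture_env <- new.env(parent = emptyenv())

# A small network trained on 24^3 coarse-layout phantoms; reused by the
# inference/QC/CLI tests. Training problem sizes are chosen so the whole
# fixture builds in about a minute on one CPU.
# Training-set-size study at 24^3 (coarse layout): one model per
# N_train in {2, 8, 32}, all with identical hyperparameters, evaluated
# on the same 4 held-out phantoms. Returns fits and held-out Dice.
scaling_study <- function(seed = 9L) {
  key <- paste0("scaling_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- phantom_spec(grid_shape = c(24, 24, 24), n_structures = 3,
                       geometry_seed = 1,
                       structures = coarse_phantom_structures())
  contrast <- modality_contrast("t1", 3)
  heldout <- phantom_dataset(4, spec, contrast, seed = 500)
  runs <- lapply(c(2L, 8L, 32L), function(n) {
    train <- phantom_dataset(n, spec, contrast, seed = 1)
    net <- unet(c(24, 24, 24), n_classes = 4, depth = 2, n_filters = 8,
                seed = 4)
    ctrl <- unet_control(learning_rate = 0.003, max_epochs = 60,
                         patience = 60, seed = seed, augment = NULL,
                         min_val_dice = 0.95)
    fitted <- fit(net, train, heldout, ctrl)
    list(n_train = n, fit = fitted,
         dice = fitted$history$val_dice[fitted$best_epoch])
  })
  out <- list(runs = runs, spec = spec, contrast = contrast,
              heldout = heldout,
              dice = vapply(runs, `[[`, numeric(1), "dice"))
  .fixture_env[[key]] <- out
  out
}

trained_tiny_model <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  spec <- phantom_spec(grid_shape = c(24, 24, 24), n_structures = 3,
                       geometry_seed = 1,
                       structures = coarse_phantom_structures())
  contrast <- modality_contrast("t1", 3)
  train <- phantom_dataset(6, spec, contrast, seed = 1)
  val <- phantom_dataset(2, spec, contrast, seed = 101)
  net <- unet(c(24, 24, 24), n_classes = 4, depth = 2, n_filters = 8,
              seed = 4)
  ctrl <- unet_control(max_epochs = 25, patience = 25, seed = 9,
                       augment = NULL, min_val_dice = 0.9,
                       learning_rate = 0.003)
  fitted <- fit(net, train, val, ctrl)
  .fixture_env$tiny <- list(fit = fitted, spec = spec, contrast = contrast)
  .fixture_env$tiny
}
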
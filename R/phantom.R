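#' Specification of a synthetic multi-modal head phantom
#'
#' Defines the geometry of a synthetic 3D "head": a set of nested
#' ellipsoidal structures with sinusoidal boundary perturbation, sharing
#' one label map that is rendered into several modality-specific intensity
#' volumes. The default layout has 8 structures (cortex-like outer shell,
#' white-matter core, two ventricles, thalamus, putamen, hippocampus,
#' brainstem) and scales up to 27 by adding small deterministic blobs
#' inside the white matter. The phantom emulates the *statistical*
#' structure of real multi-modal head scans — shared anatomy, per-modality
#' contrast, noise, misalignment — not anatomical realism.
#'
#' @param grid_shape 3 positive integers (each >= 16), default `c(64,64,64)`.
#' @param voxel_spacing_mm 3 positive reals, default 1 mm isotropic.
#' @param n_structures number of non-background structures, 1..27.
#' @param geometry_seed integer; jitters structure centers/axes and the
#'   boundary-perturbation phases, so different seeds give different
#'   "subjects" with the same anatomy layout.
#' @param wobble relative amplitude of the sinusoidal boundary
#'   perturbation (0 disables it).
#' @param structures optional data.frame overriding the built-in layout;
#'   columns `name`, `cx,cy,cz` (center as grid fractions), `ax,ay,az`
#'   (semi-axes as grid fractions) and `parent` (label id, 0 = none).
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 32, 32), n_structures = 4)
#' lab <- generate_label_map(spec)
#' table(lab$data)
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing_mm = c(1, 1, 1),
                         n_structures = 8L,
                         geometry_seed = 1L,
                         wobble = 0.05,
                         structures = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 16))
    stop("grid_shape must be 3 integers, each >= 16")
  voxel_spacing_mm <- check_spacing(voxel_spacing_mm)
  n_structures <- as.integer(n_structures)
  if (n_structures < 1 || n_structures > 27)
    stop("n_structures must be in 1..27")
  if (is.null(structures))
    structures <- default_phantom_structures(n_structures)
  needed <- c("name", "cx", "cy", "cz", "ax", "ay", "az", "parent")
  if (!all(needed %in% names(structures)))
    stop("structures table needs columns: ", paste(needed, collapse = ", "))
  structures <- structures[seq_len(n_structures), ]
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = voxel_spacing_mm,
                 n_structures = n_structures,
                 geometry_seed = as.integer(geometry_seed),
                 wobble = wobble,
                 structures = structures),
            class = "phantom_spec")
}

# Built-in layout: centers and semi-axes as fractions of the grid; parent
# ids refer to earlier rows (structures are painted in id order, children
# overwrite parents and are clipped to the parent's pre-carving region).
default_phantom_structures <- function(n) {
  base <- data.frame(
    name  = c("cerebral_cortex", "white_matter", "ventricle_left",
              "ventricle_right", "thalamus", "putamen", "hippocampus",
              "brainstem"),
    cx = c(0.50, 0.50, 0.42, 0.58, 0.50, 0.36, 0.62, 0.50),
    cy = c(0.50, 0.50, 0.50, 0.50, 0.42, 0.45, 0.58, 0.55),
    cz = c(0.54, 0.56, 0.60, 0.60, 0.50, 0.50, 0.46, 0.20),
    ax = c(0.36, 0.27, 0.050, 0.050, 0.070, 0.050, 0.050, 0.065),
    ay = c(0.40, 0.31, 0.095, 0.095, 0.060, 0.070, 0.080, 0.065),
    az = c(0.34, 0.25, 0.070, 0.070, 0.050, 0.050, 0.050, 0.095),
    parent = c(0L, 1L, 2L, 2L, 2L, 2L, 1L, 0L),
    stringsAsFactors = FALSE)
  if (n <= nrow(base)) return(base[seq_len(n), ])
  # extra blobs on a spiral inside the white-matter ellipsoid
  k <- n - nrow(base)
  i <- seq_len(k)
  ang <- i * 2.399963  # golden angle
  rad <- 0.55 * sqrt(i / k)
  extra <- data.frame(
    name = default_structure_names(n)[seq.int(nrow(base) + 1, n)],
    cx = 0.50 + 0.27 * rad * cos(ang),
    cy = 0.50 + 0.31 * rad * sin(ang),
    cz = 0.56 + 0.12 * ((i %% 3) - 1),
    ax = 0.028, ay = 0.030, az = 0.026,
    parent = 2L,
    stringsAsFactors = FALSE)
  rbind(base, extra)
}

#' Coarse 3-structure layout for small grids
#'
#' The default 8-structure layout is designed for grids of 64^3 and
#' larger; below that, its smallest structures (the ventricles) shrink to
#' a few dozen voxels and stop being resolvable. This alternative layout
#' — cortex shell, white-matter core, one enlarged ventricle — keeps
#' every structure at a few hundred voxels on grids down to 24^3, which
#' is what capacity and learning experiments on small grids need.
#'
#' @return A structures data.frame for [phantom_spec()] (`n_structures`
#'   must be 3).
#' @export
coarse_phantom_structures <- function() {
  data.frame(
    name = c("cerebral_cortex", "white_matter", "ventricle"),
    cx = c(0.50, 0.50, 0.46),
    cy = c(0.50, 0.50, 0.50),
    cz = c(0.54, 0.56, 0.56),
    ax = c(0.36, 0.27, 0.12),
    ay = c(0.40, 0.31, 0.15),
    az = c(0.34, 0.25, 0.12),
    parent = c(0L, 1L, 2L),
    stringsAsFactors = FALSE)
}

#' Render the shared label map of a phantom
#'
#' Paints the structures of a [phantom_spec()] in label order onto the
#' voxel grid. Each structure is an ellipsoid whose boundary radius is
#' modulated sinusoidally in the two spherical angles (phases drawn from
#' `geometry_seed`); children are clipped to their parent's pre-carving
#' ellipsoid so declared nestings hold voxelwise. The result is a pure
#' function of the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return A [ms_labels()] containing exactly the labels
#'   `0..n_structures`, each nonempty.
#' @export
generate_label_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  st <- spec$structures
  with_seed(spec$geometry_seed, {
    jc <- matrix(runif(3 * nrow(st), -0.015, 0.015), ncol = 3)
    ja <- matrix(runif(3 * nrow(st), 0.93, 1.07), ncol = 3)
    ph <- matrix(runif(2 * nrow(st), 0, 2 * pi), ncol = 2)
    # keep the two biggest structures' jitter milder so nesting margins hold
    if (nrow(st) >= 2) ja[1:2, ] <- pmin(pmax(ja[1:2, ], 0.97), 1.03)
  })
  fx <- ((seq_len(d[1]) - 0.5) / d[1])
  fy <- ((seq_len(d[2]) - 0.5) / d[2])
  fz <- ((seq_len(d[3]) - 0.5) / d[3])
  X <- array(rep(fx, times = d[2] * d[3]), d)
  Y <- array(rep(rep(fy, each = d[1]), times = d[3]), d)
  Z <- array(rep(fz, each = d[1] * d[2]), d)

  lab <- array(0L, d)
  regions <- vector("list", nrow(st))  # pre-carving masks, for nesting
  for (s in seq_len(nrow(st))) {
    cen <- c(st$cx[s], st$cy[s], st$cz[s]) + jc[s, ]
    ax <- c(st$ax[s], st$ay[s], st$az[s]) * ja[s, ]
    if (st$parent[s] == 0L &&
        (any(cen - ax < 0) || any(cen + ax > 1)))
      stop("structure '", st$name[s], "' extends outside the grid")
    ux <- (X - cen[1]) / ax[1]
    uy <- (Y - cen[2]) / ax[2]
    uz <- (Z - cen[3]) / ax[3]
    q <- ux^2 + uy^2 + uz^2
    if (spec$wobble > 0) {
      r <- sqrt(pmax(q, 1e-12))
      theta <- atan2(uy, ux)
      psi <- acos(pmin(pmax(uz / r, -1), 1))
      mod <- 1 + spec$wobble * sin(3 * theta + ph[s, 1]) * sin(2 * psi + ph[s, 2])
      mask <- q < mod^2
    } else mask <- q < 1
    if (st$parent[s] > 0L) {
      p <- st$parent[s]
      if (p >= s) stop("parent id must precede child id")
      mask <- mask & regions[[p]]
    }
    regions[[s]] <- mask
    lab[mask] <- s
  }
  counts <- tabulate(lab + 1L, nbins = nrow(st) + 1L)
  if (any(counts == 0))
    stop("empty label(s) after painting: ",
         paste(which(counts == 0) - 1L, collapse = ", "),
         " (structure hidden by later siblings or too small for the grid)")
  ml <- ms_labels(lab, spec$voxel_spacing_mm,
                  scheme = label_scheme(st$name))
  attr(ml, "regions") <- NULL
  ml
}

#' Per-modality intensity contrast tables
#'
#' A `modality_contrast` assigns a mean intensity to every label of a
#' phantom, plus a Gaussian noise level and an optional smooth
#' multiplicative bias field. The default tables encode the key
#' radiological ordering: T1-like contrast separates the gray-matter-like
#' shell from the white-matter core by well over 4 noise SDs, while the
#' CT-like table separates them by less than one noise SD (soft-tissue
#' contrast on CT is poor), with FLAIR/DWI in between.
#'
#' @param modality one of `"t1"`, `"flair"`, `"dwi"`, `"ct"`.
#' @param n_structures number of non-background labels covered.
#' @param means optional numeric vector of length `n_structures + 1`
#'   (background first) overriding the default table.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param bias_amplitude relative amplitude of the low-order polynomial
#'   bias field (0 disables it).
#' @return An object of class `modality_contrast`.
#' @export
modality_contrast <- function(modality = c("t1", "flair", "dwi", "ct"),
                              n_structures = 8L,
                              means = NULL,
                              noise_sigma = 5,
                              bias_amplitude = 0) {
  modality <- match.arg(modality)
  if (noise_sigma < 0 || bias_amplitude < 0)
    stop("noise_sigma and bias_amplitude must be >= 0")
  if (is.null(means)) means <- default_contrast_means(modality, n_structures)
  means <- as.numeric(means)
  if (length(means) != n_structures + 1)
    stop("means must cover background + ", n_structures, " structures")
  structure(list(modality = modality, means = means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 n_structures = as.integer(n_structures)),
            class = "modality_contrast")
}

default_contrast_means <- function(modality, n) {
  # background, cortex(GM-like), white matter, ventricles x2, thalamus,
  # putamen, hippocampus, brainstem
  base <- switch(modality,
    t1    = c(2, 60, 90, 22, 22, 70, 66, 64, 78),
    flair = c(2, 64, 44, 12, 12, 54, 58, 68, 48),
    dwi   = c(2, 56, 44, 18, 18, 60, 62, 58, 50),
    ct    = c(1, 33, 36, 10, 10, 35, 37, 34, 38))
  if (n + 1 <= length(base)) return(base[seq_len(n + 1)])
  k <- n + 1 - length(base)
  gm <- base[2]; wm <- base[3]
  i <- seq_len(k)
  # deterministic extras between the GM and WM means
  extra <- gm + (wm - gm) * ((i * 7) %% 11 + 1) / 12
  c(base, extra)
}

#' Render a label map into a modality-specific intensity volume
#'
#' Intensity = structure mean (from the contrast table) times a smooth
#' multiplicative bias field, plus i.i.d. Gaussian noise; a pure function
#' of `(labels, contrast, seed)`.
#'
#' @param labels a [ms_labels()] from [generate_label_map()].
#' @param contrast a [modality_contrast()] covering every label present.
#' @param seed integer controlling the noise (and bias) realization.
#' @return A [ms_volume()] on the label map's grid.
#' @export
render_modality <- function(labels, contrast, seed = 1L) {
  stopifnot(inherits(labels, "ms_labels"), inherits(contrast, "modality_contrast"))
  present <- sort(unique(as.vector(labels$data)))
  if (any(present > contrast$n_structures))
    stop("contrast table does not cover label(s): ",
         paste(setdiff(present, 0:contrast$n_structures), collapse = ", "))
  d <- dim(labels$data)
  vol <- array(contrast$means[labels$data + 1L], d)
  with_seed(seed, {
    if (contrast$bias_amplitude > 0) {
      co <- runif(9, -1, 1)
      fx <- seq(-1, 1, length.out = d[1])
      fy <- seq(-1, 1, length.out = d[2])
      fz <- seq(-1, 1, length.out = d[3])
      X <- array(rep(fx, times = d[2] * d[3]), d)
      Y <- array(rep(rep(fy, each = d[1]), times = d[3]), d)
      Z <- array(rep(fz, each = d[1] * d[2]), d)
      poly <- co[1] * X + co[2] * Y + co[3] * Z + co[4] * X * Y +
        co[5] * X * Z + co[6] * Y * Z + co[7] * (X^2 - 1 / 3) +
        co[8] * (Y^2 - 1 / 3) + co[9] * (Z^2 - 1 / 3)
      poly <- poly / max(abs(poly))
      vol <- vol * (1 + contrast$bias_amplitude * poly)
    }
    if (contrast$noise_sigma > 0)
      vol <- vol + array(rnorm(prod(d), 0, contrast$noise_sigma), d)
  })
  ms_volume(vol, labels$spacing, labels$affine)
}

#' Apply a random rigid misalignment to a volume
#'
#' Draws a rotation (per axis, uniform in `[-max_rotation_deg,
#' max_rotation_deg]`) and translation (per axis, uniform in
#' `[-max_translation_mm, max_translation_mm]`) about the volume center,
#' resamples the volume through the transform, and returns both the moved
#' volume and the ground-truth transform — enabling registration-recovery
#' round trips. With both bounds zero the input is returned unchanged with
#' an exact identity transform.
#'
#' The returned transform `t` maps the coordinates of the *misaligned*
#' frame to the original frame (`misaligned(x) = original(t x)`), i.e.
#' registering the misaligned volume back onto the original should recover
#' `invert(t)`; equivalently `compose(t, t_estimated)` is close to the
#' identity.
#'
#' @param volume a [ms_volume()] or [ms_labels()].
#' @param max_rotation_deg,max_translation_mm non-negative bounds.
#' @param seed integer RNG seed.
#' @return A list with elements `volume` and `transform` (an `ms_affine`).
#' @export
misalign <- function(volume, max_rotation_deg = 5, max_translation_mm = 4,
                     seed = 1L) {
  if (max_rotation_deg < 0 || max_translation_mm < 0)
    stop("perturbation bounds must be >= 0")
  if (max_rotation_deg == 0 && max_translation_mm == 0)
    return(list(volume = volume, transform = affine_transform(diag(4))))
  with_seed(seed, {
    rot <- runif(3, -max_rotation_deg, max_rotation_deg)
    tra <- runif(3, -max_translation_mm, max_translation_mm)
  })
  center <- as.vector(volume$affine %*% c((dim(volume$data) - 1) / 2, 1))[1:3]
  t <- affine_from_params(translation = tra, rotation_deg = rot,
                          center = center)
  moved <- apply_transform(volume, t, target_grid = volume)
  list(volume = moved, transform = t)
}

#' Add extra Gaussian noise to an existing rendering
#'
#' Creates graded out-of-distribution inputs (emulating corrupted scans or
#' acquisition artifacts) for quality-control experiments. `sigma = 0`
#' returns the input unchanged.
#'
#' @param volume a [ms_volume()].
#' @param extra_noise_sigma Gaussian noise SD added on top, >= 0.
#' @param seed integer RNG seed.
#' @return A [ms_volume()].
#' @export
degrade <- function(volume, extra_noise_sigma, seed = 1L) {
  stopifnot(inherits(volume, "ms_volume"))
  if (extra_noise_sigma < 0) stop("extra_noise_sigma must be >= 0")
  if (extra_noise_sigma == 0) return(volume)
  with_seed(seed, {
    volume$data <- volume$data +
      array(rnorm(length(volume$data), 0, extra_noise_sigma),
            dim(volume$data))
  })
  volume
}

#' Generate a set of paired (image, label) phantoms
#'
#' Convenience generator for training/evaluation experiments: each pair
#' shares one label map (rendered from a per-subject geometry seed) and
#' the image is its modality rendering. The label map returned with each
#' pair is exactly the one used for rendering.
#'
#' @param n number of phantom pairs.
#' @param spec a [phantom_spec()] template; its `geometry_seed` is offset
#'   per subject.
#' @param contrast a [modality_contrast()].
#' @param seed base seed for geometry and noise.
#' @return A list of `n` lists with elements `image` ([ms_volume()]) and
#'   `labels` ([ms_labels()]).
#' @export
phantom_dataset <- function(n, spec, contrast, seed = 1L) {
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$geometry_seed <- spec$geometry_seed + 1000L * (seed - 1L) + i
    lab <- generate_label_map(sp)
    img <- render_modality(lab, contrast, seed = sp$geometry_seed + 500000L)
    list(image = img, labels = lab)
  })
}

#' Write a phantom pair as NIfTI files
#'
#' Files are named `<id>_<modality>.nii.gz` and `<id>_labels.nii.gz`, with
#' spacing encoded in the header.
#'
#' @param pair a list with `image` and `labels` (as from
#'   [phantom_dataset()]).
#' @param dir output directory (created if needed).
#' @param id subject identifier used as the filename stem.
#' @param modality modality tag for the image filename.
#' @return Character vector of the two paths, invisibly.
#' @export
write_phantom_pair <- function(pair, dir, id, modality) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, sprintf("%s_%s.nii.gz", id, modality))
  p2 <- file.path(dir, sprintf("%s_labels.nii.gz", id))
  write_nifti(pair$image, p1)
  write_nifti(pair$labels, p2)
  invisible(c(p1, p2))
}
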
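#' Affine transforms between world coordinate frames
#'
#' An `ms_affine` wraps a 4x4 matrix with last row `(0,0,0,1)` mapping
#' reference world coordinates (mm) to moving world coordinates (mm), the
#' convention used by coregistration: resampling the moving image through
#' the transform aligns it onto the reference grid.
#'
#' `affine_from_params()` builds a transform from 12 interpretable
#' parameters applied about a center point: translation (mm), rotation
#' (degrees, applied as Rz Ry Rx), anisotropic scale, and shears.
#'
#' @param matrix a 4x4 matrix with bottom row `(0,0,0,1)`.
#' @return An object of class `ms_affine`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4))) stop("affine must be 4x4")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row must be (0,0,0,1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("singular transform")
  structure(list(matrix = matrix), class = "ms_affine")
}

#' @rdname affine_transform
#' @param translation,rotation_deg,scale,shear numeric length-3 parameter
#'   vectors (shear order: xy, xz, yz).
#' @param center rotation/scaling center in world mm.
#' @export
affine_from_params <- function(translation = c(0, 0, 0),
                               rotation_deg = c(0, 0, 0),
                               scale = c(1, 1, 1),
                               shear = c(0, 0, 0),
                               center = c(0, 0, 0)) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(scale)
  H <- diag(3); H[1, 2] <- shear[1]; H[1, 3] <- shear[2]; H[2, 3] <- shear[3]
  A <- Rz %*% Ry %*% Rx %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- translation + center - A %*% center
  affine_transform(m)
}

#' @export
print.ms_affine <- function(x, ...) {
  cat("<ms_affine> reference world -> moving world (mm)\n")
  print(round(x$matrix, 6))
  if (isTRUE(attr(x, "identity_fallback")))
    cat("  [warning: registration failed to improve over identity]\n")
  invisible(x)
}

#' Invert or compose affine transforms
#'
#' @param t,a,b `ms_affine` objects.
#' @return An `ms_affine`. `compose(a, b)` applies `b` first, then `a`
#'   (matrix product `a %*% b`).
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "ms_affine"))
  affine_transform(solve(t$matrix))
}

#' @rdname invert
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "ms_affine"), inherits(b, "ms_affine"))
  affine_transform(a$matrix %*% b$matrix)
}

is_identity_affine <- function(t, tol = 1e-12) {
  max(abs(t$matrix - diag(4))) <= tol
}

#' Resample an object through an affine transform
#'
#' Samples `obj` (the moving image) on the grid of `target_grid`: the value
#' at output voxel `i` is taken from the moving image at world position
#' `T %*% world(i)`. Volumes are interpolated with cubic splines, label
#' maps with nearest-neighbour sampling; voxels mapping outside the moving
#' field of view are filled with 0 (background).
#'
#' @param obj a [ms_volume()] or [ms_labels()] (the moving image).
#' @param t an [affine_transform()] mapping target (reference) world
#'   coordinates to moving world coordinates.
#' @param target_grid a `ms_volume`/`ms_labels` or a list with elements
#'   `dim`, `spacing`, `affine` defining the output grid; defaults to the
#'   grid of `obj`.
#' @param mode `"spline"`, `"linear"` or `"nearest"`; defaults by class.
#' @return Object of the same class as `obj` on the target grid.
#' @export
apply_transform <- function(obj, t, target_grid = NULL,
                            mode = if (inherits(obj, "ms_labels")) "nearest" else "spline") {
  stopifnot(inherits(t, "ms_affine"))
  mode <- match.arg(mode, c("spline", "nearest", "linear"))
  if (inherits(obj, "ms_labels") && mode != "nearest")
    stop("label maps must be transformed with nearest-neighbour sampling")
  g <- if (is.null(target_grid)) grid_of(obj)
       else if (inherits(target_grid, c("ms_volume", "ms_labels")))
         grid_of(target_grid)
       else target_grid
  if (is_identity_affine(t) && identical(unname(g$dim), unname(dim(obj$data))) &&
      max(abs(g$affine - obj$affine)) < 1e-12)
    return(obj)  # exact no-op
  # output voxel -> target world -> moving world -> moving voxel
  M <- solve(obj$affine) %*% t$matrix %*% g$affine
  imode <- c(nearest = 0L, linear = 1L, spline = 3L)[[mode]]
  out <- cpp_resample_affine(as.vector(as.numeric(obj$data)), dim(obj$data),
                             M, as.integer(g$dim), imode)
  arr <- array(out, g$dim)
  if (inherits(obj, "ms_labels"))
    ms_labels(round(arr), g$spacing, g$affine, scheme = obj$scheme)
  else ms_volume(arr, g$spacing, g$affine)
}

#' Serialize an affine transform
#'
#' The matrix is written as a 4-line row-major text file; a JSON sidecar
#' (`<path>.json`) records grid metadata when supplied.
#'
#' @param t an `ms_affine`.
#' @param path output path for the matrix text file.
#' @param meta optional list stored in the JSON sidecar.
#' @return `path` invisibly (`write_transform`); an `ms_affine`
#'   (`read_transform`).
#' @export
write_transform <- function(t, path, meta = NULL) {
  stopifnot(inherits(t, "ms_affine"))
  lines <- apply(t$matrix, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(lines, path)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- do.call(rbind, lapply(readLines(path), function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  affine_transform(m)
}
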
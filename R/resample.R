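#' Percentile-clipped intensity normalization to [0, 100]
#'
#' Clips intensities to the `low_pct`/`high_pct` percentiles and maps the
#' clipped range linearly so that the lower clip lands on 0 and the upper
#' clip on 100 — the intensity interval the segmentation network is trained
#' on. Percentile clipping (rather than raw min-max) keeps single hot
#' voxels from compressing the brain's dynamic range. A constant volume
#' maps to all zeros.
#'
#' @param v a [ms_volume()].
#' @param low_pct,high_pct clip percentiles in `[0, 100]`, defaults 1 and 99;
#'   use `0` and `100` for exact min-max scaling.
#' @return A `ms_volume` with values in `[0, 100]`.
#' @examples
#' v <- ms_volume(array(c(10, 20, 30), c(3, 1, 1)))
#' range(normalize_intensity(v, 0, 100)$data)
#' @export
normalize_intensity <- function(v, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(v, "ms_volume"))
  if (high_pct <= low_pct) stop("high_pct must exceed low_pct")
  q <- quantile(v$data, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    v$data[] <- 0
    return(v)
  }
  x <- pmin(pmax(v$data, q[1]), q[2])
  v$data <- (x - q[1]) / (q[2] - q[1]) * 100
  v
}

#' Resample a volume or label map to a new grid shape
#'
#' Changes the voxel grid to `target_shape` while preserving the physical
#' extent: spacing is rescaled by `dim/target_shape` and the world affine
#' is updated accordingly (voxel centers stay aligned). Volumes use cubic
#' spline (Catmull-Rom) interpolation; label maps use nearest-neighbour
#' sampling, which never introduces label values absent from the input.
#'
#' @param obj a [ms_volume()] or [ms_labels()].
#' @param target_shape integer vector of 3 positive grid dimensions.
#' @param mode `"spline"` (volumes only) or `"nearest"`; defaults by class.
#' @return Object of the same class on the new grid.
#' @export
resample <- function(obj, target_shape,
                     mode = if (inherits(obj, "ms_labels")) "nearest" else "spline") {
  mode <- match.arg(mode, c("spline", "nearest", "linear"))
  if (inherits(obj, "ms_labels") && mode != "nearest")
    stop("label maps must be resampled with nearest-neighbour sampling")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3 || any(target_shape < 1))
    stop("target_shape must be 3 positive integers")
  d <- dim(obj$data)
  scale <- d / target_shape
  # output voxel i -> input voxel coordinate (i + 0.5) * scale - 0.5
  M <- diag(c(scale, 1))
  M[1:3, 4] <- 0.5 * scale - 0.5
  imode <- c(nearest = 0L, linear = 1L, spline = 3L)[[mode]]
  out <- cpp_resample_affine(as.vector(as.numeric(obj$data)), d, M,
                             target_shape, imode)
  arr <- array(out, target_shape)
  new_affine <- obj$affine %*% M
  new_spacing <- obj$spacing * scale
  if (inherits(obj, "ms_labels"))
    ms_labels(round(arr), new_spacing, new_affine, scheme = obj$scheme)
  else ms_volume(arr, new_spacing, new_affine)
}
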
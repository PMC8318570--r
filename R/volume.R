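#' Spatial data containers
#'
#' A `ms_volume` is a 3D scalar field with voxel spacing (mm) and a 4x4
#' world affine mapping 0-based voxel indices to world coordinates in mm.
#' A `ms_labels` is the integer-valued counterpart holding a segmentation
#' map over labels `0..C-1` (0 = background). A `ms_softmax` holds per-class
#' probability fields as a 4D array with the class along the last axis.
#'
#' @param data numeric 3D array (`ms_volume`), integer-valued 3D array
#'   (`ms_labels`), or 4D array with class as the trailing axis
#'   (`ms_softmax`).
#' @param spacing voxel spacing in mm, length 3, strictly positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling
#'   by `spacing` with the origin at voxel (0,0,0).
#' @param scheme optional [label_scheme()] attached to a label map.
#' @return An object of class `ms_volume`, `ms_labels` or `ms_softmax`.
#' @examples
#' v <- ms_volume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 1, 2))
#' dim(v$data)
#' @export
ms_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- check_grid_array(data, 3L)
  spacing <- check_spacing(spacing)
  affine <- check_affine(affine %||% spacing_affine(spacing))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "ms_volume")
}

#' @rdname ms_volume
#' @export
ms_labels <- function(data, spacing = c(1, 1, 1), affine = NULL,
                      scheme = NULL) {
  data <- check_grid_array(data, 3L)
  if (any(data != round(data)) || any(data < 0))
    stop("label data must be non-negative integers")
  storage.mode(data) <- "integer"
  if (!is.null(scheme)) {
    bad <- setdiff(unique(as.vector(data)), scheme$id)
    if (length(bad))
      stop("label value(s) ", paste(bad, collapse = ", "),
           " not in the label scheme (C = ", nrow(scheme), ")")
  }
  spacing <- check_spacing(spacing)
  affine <- check_affine(affine %||% spacing_affine(spacing))
  structure(list(data = data, spacing = spacing, affine = affine,
                 scheme = scheme),
            class = "ms_labels")
}

#' @rdname ms_volume
#' @export
ms_softmax <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- check_grid_array(data, 4L)
  spacing <- check_spacing(spacing)
  affine <- check_affine(affine %||% spacing_affine(spacing))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "ms_softmax")
}

check_grid_array <- function(data, ndim) {
  if (is.null(dim(data)) && ndim == 3L) stop("data must be an array")
  if (length(dim(data)) == 4L && ndim == 3L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])  # 4D with singleton trailing dim
  if (length(dim(data)) != ndim)
    stop("data must be a ", ndim, "-dimensional array")
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  spacing
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  affine
}

spacing_affine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

grid_of <- function(obj) {
  list(dim = dim(obj$data)[1:3], spacing = obj$spacing, affine = obj$affine)
}

voxel_volume_mm3 <- function(obj) prod(obj$spacing)

#' @export
print.ms_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ms_volume> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ms_labels <- function(x, ...) {
  d <- dim(x$data)
  labs <- sort(unique(as.vector(x$data)))
  cat(sprintf("<ms_labels> %d x %d x %d voxels, spacing %s mm, labels {%s}\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              paste(labs, collapse = ",")))
  invisible(x)
}

#' @export
print.ms_softmax <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ms_softmax> %d x %d x %d voxels, %d classes\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Label schemes
#'
#' An ordered table of `(id, name)` pairs describing the segmentation
#' classes. Label 0 is always background and ids are consecutive `0..C-1`.
#' The default scheme has 28 classes (27 anatomical structures plus
#' background), the standard subcortical/cortical label set size for
#' whole-brain anatomical segmentation.
#'
#' @param names character vector of structure names, background excluded;
#'   or a single integer giving the number of non-background structures.
#' @return data.frame with columns `id` and `name`, class `ms_scheme`.
#' @examples
#' label_scheme(3)
#' @export
label_scheme <- function(names = 27L) {
  if (is.numeric(names) && length(names) == 1) {
    n <- as.integer(names)
    if (n < 1) stop("need at least one structure")
    names <- default_structure_names(n)
  }
  df <- data.frame(id = 0:length(names),
                   name = c("background", names),
                   stringsAsFactors = FALSE)
  class(df) <- c("ms_scheme", "data.frame")
  df
}

default_structure_names <- function(n) {
  base <- c("cerebral_cortex", "white_matter", "ventricle_left",
            "ventricle_right", "thalamus", "putamen", "hippocampus",
            "brainstem", "pallidum", "caudate", "amygdala", "cerebellum",
            "accumbens", "insula", "corpus_callosum", "fornix",
            "internal_capsule", "choroid_plexus", "third_ventricle",
            "fourth_ventricle", "midbrain", "pons", "medulla",
            "optic_chiasm", "septum", "pineal", "pituitary")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("structure_", seq.int(length(base) + 1, n)))
}

n_classes_of <- function(scheme) nrow(scheme)

#' One-hot encoding of a label map
#'
#' Expands a label map into per-class indicator columns `T_s(x)`, one row
#' per voxel (column-major voxel order), one column per class. Every row
#' sums to exactly 1.
#'
#' @param labels a [ms_labels()] object or integer array/vector.
#' @param n_classes total number of classes C including background.
#' @return numeric matrix with `prod(dim)` rows and `n_classes` columns.
#' @export
one_hot <- function(labels, n_classes) {
  v <- if (inherits(labels, "ms_labels")) as.vector(labels$data)
       else as.vector(labels)
  if (any(v < 0 | v >= n_classes))
    stop("labels outside 0..", n_classes - 1)
  m <- matrix(0, length(v), n_classes)
  m[cbind(seq_along(v), v + 1L)] <- 1
  m
}

# Flatten a volume to the (nvox x channels) matrix layout the network uses.
as_input_matrix <- function(v) {
  matrix(as.vector(v$data), ncol = 1L)
}
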
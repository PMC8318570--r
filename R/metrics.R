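#' Per-structure Dice overlap
#'
#' `D_s = 2 |S_s intersect T_s| / (|S_s| + |T_s|)` between the predicted
#' and ground-truth masks of structure `s`. When the structure is empty in
#' both maps the score is defined as 1 (documented convention).
#'
#' @param pred,truth [ms_labels()] on the same grid (or integer arrays).
#' @param s label id of the structure.
#' @return Dice score in `[0, 1]`.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
#' b <- array(0L, c(4, 4, 4)); b[2:3, 1, 1] <- 1L
#' dice_score(a, b, 1)  # overlap 1 of sizes 2+2 -> 0.5
#' @export
dice_score <- function(pred, truth, s) {
  p <- label_array(pred); t_ <- label_array(truth)
  if (!identical(dim(p), dim(t_))) stop("grids do not match")
  np <- sum(p == s); nt <- sum(t_ == s)
  if (np + nt == 0) return(1)
  2 * sum(p == s & t_ == s) / (np + nt)
}

label_array <- function(x) {
  if (inherits(x, "ms_labels")) x$data
  else if (is.array(x)) x
  else stop("expected a label map or array")
}

#' Average and volume-weighted Dice over all structures
#'
#' `average_dice` is the arithmetic mean of the per-structure Dice scores
#' over the non-background structures of the scheme (background is never
#' included). `weighted_dice` weights each structure's Dice by its volume
#' in the *predicted* mask, `D_V = (1/V) sum_s V_s D_s` with
#' `V = sum_s V_s`; it returns `NA` when the prediction contains no
#' foreground at all.
#'
#' @param pred,truth [ms_labels()] on the same grid.
#' @param scheme a [label_scheme()]; defaults to the scheme attached to
#'   `truth` or, failing that, the labels present in either map.
#' @return A single Dice value.
#' @export
average_dice <- function(pred, truth, scheme = NULL) {
  ids <- foreground_ids(pred, truth, scheme)
  mean(vapply(ids, function(s) dice_score(pred, truth, s), numeric(1)))
}

#' @rdname average_dice
#' @export
weighted_dice <- function(pred, truth, scheme = NULL) {
  ids <- foreground_ids(pred, truth, scheme)
  p <- label_array(pred)
  vs <- vapply(ids, function(s) sum(p == s), numeric(1))
  if (sum(vs) == 0) return(NA_real_)
  ds <- vapply(ids, function(s) dice_score(pred, truth, s), numeric(1))
  sum(vs * ds) / sum(vs)
}

foreground_ids <- function(pred, truth, scheme) {
  if (is.null(scheme) && inherits(truth, "ms_labels") &&
      !is.null(truth$scheme))
    scheme <- truth$scheme
  if (!is.null(scheme)) return(setdiff(scheme$id, 0L))
  ids <- sort(unique(c(as.vector(label_array(pred)),
                       as.vector(label_array(truth)))))
  setdiff(ids, 0L)
}

#' Extract the surface voxels of a binary mask
#'
#' A surface voxel is a mask voxel with at least one non-mask 6-neighbour;
#' voxels on the grid boundary count the outside as non-mask. Distances
#' are later measured between voxel centers in mm.
#'
#' @param mask logical 3D array (or 0/1 integer array).
#' @param spacing voxel spacing in mm (length 3).
#' @return A matrix of surface voxel center coordinates in mm (possibly
#'   with zero rows), with attribute `voxels` holding the 1-based voxel
#'   indices.
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1)) {
  mask <- mask != 0
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be 3D")
  interior <- array(TRUE, d)
  shift_and <- function(m, axis, dir) {
    # neighbour presence along one direction, FALSE at the grid border
    out <- array(FALSE, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (dir > 0) { idx_dst[[axis]] <- seq_len(d[axis] - 1)
                   idx_src[[axis]] <- 2:d[axis] }
    else         { idx_dst[[axis]] <- 2:d[axis]
                   idx_src[[axis]] <- seq_len(d[axis] - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_and(mask, axis, dir)
  surf <- mask & !interior
  idx <- which(surf, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, `*`)
  storage.mode(coords) <- "double"
  attr(coords, "voxels") <- idx
  coords
}

#' Average symmetric surface distance (mm)
#'
#' `ASSD(A, B) = (sum_{a in A} D_B(a) + sum_{b in B} D_A(b)) / (|A| + |B|)`
#' where A and B are the surface voxel sets of the ground-truth and
#' predicted masks of structure `s`, and `D_B(a)` is the minimal Euclidean
#' distance (in mm, using the anisotropic voxel spacing) from `a` to
#' surface B. Returns `NA` (a flagged missing value) when either mask is
#' empty.
#'
#' @param pred,truth [ms_labels()] or integer arrays on the same grid.
#' @param s label id of the structure.
#' @param spacing voxel spacing in mm; defaults to the spacing attached
#'   to `truth` (or 1 mm isotropic).
#' @return The ASSD in mm, or `NA_real_`.
#' @export
assd <- function(pred, truth, s, spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (inherits(truth, "ms_labels")) truth$spacing else c(1, 1, 1)
  p <- label_array(pred); t_ <- label_array(truth)
  if (!identical(dim(p), dim(t_))) stop("grids do not match")
  A <- extract_surface(t_ == s, spacing)
  B <- extract_surface(p == s, spacing)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  r <- cpp_min_dist_sums(A, B)
  (r$sum_a_to_b + r$sum_b_to_a) / (r$n_a + r$n_b)
}

#' Full evaluation of a predicted segmentation
#'
#' Computes, for every non-background structure of the scheme: the Dice
#' score, the ASSD in mm, and the structure volume in the predicted mask
#' (mm^3); plus the aggregates average Dice, volume-weighted Dice and mean
#' ASSD (averaged over structures with a defined ASSD, with the exclusion
#' count reported).
#'
#' @param pred,truth [ms_labels()] on the same grid.
#' @param scheme a [label_scheme()] (defaults as in [average_dice()]).
#' @param spacing voxel spacing in mm (defaults to `truth`'s spacing).
#' @return A list of class `ms_metrics` with elements `per_structure`
#'   (data.frame: id, name, dice, assd_mm, volume_mm3), `average_dice`,
#'   `weighted_dice`, `mean_assd_mm`, `n_assd_excluded`,
#'   `total_volume_mm3`.
#' @export
evaluate_segmentation <- function(pred, truth, scheme = NULL,
                                  spacing = NULL) {
  if (is.null(scheme) && inherits(truth, "ms_labels") &&
      !is.null(truth$scheme))
    scheme <- truth$scheme
  if (is.null(scheme)) {
    ids <- foreground_ids(pred, truth, NULL)
    scheme <- label_scheme(max(c(ids, 0L)))
  }
  if (is.null(spacing))
    spacing <- if (inherits(truth, "ms_labels")) truth$spacing else c(1, 1, 1)
  ids <- setdiff(scheme$id, 0L)
  p <- label_array(pred)
  voxvol <- prod(spacing)
  per <- data.frame(
    id = ids,
    name = scheme$name[match(ids, scheme$id)],
    dice = vapply(ids, function(s) dice_score(pred, truth, s), numeric(1)),
    assd_mm = vapply(ids, function(s) assd(pred, truth, s, spacing),
                     numeric(1)),
    volume_mm3 = vapply(ids, function(s) sum(p == s) * voxvol, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(
    per_structure = per,
    average_dice = mean(per$dice),
    weighted_dice = weighted_dice(pred, truth, scheme),
    mean_assd_mm = if (all(is.na(per$assd_mm))) NA_real_
                   else mean(per$assd_mm, na.rm = TRUE),
    n_assd_excluded = sum(is.na(per$assd_mm)),
    total_volume_mm3 = sum(per$volume_mm3)),
    class = "ms_metrics")
}

#' @export
print.ms_metrics <- function(x, ...) {
  cat(sprintf("<ms_metrics> average Dice %.4f | weighted Dice %s | mean ASSD %s mm\n",
              x$average_dice,
              ifelse(is.na(x$weighted_dice), "NA",
                     sprintf("%.4f", x$weighted_dice)),
              ifelse(is.na(x$mean_assd_mm), "NA",
                     sprintf("%.3f", x$mean_assd_mm))))
  print(x$per_structure, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Keys follow `dice.<name>`, `assd_mm.<name>`, `volumes_mm3.<name>` plus
#' the aggregates; the round trip through JSON is lossless.
#'
#' @param report a `ms_metrics` from [evaluate_segmentation()].
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
metrics_to_json <- function(report, path = NULL) {
  per <- report$per_structure
  obj <- list(
    dice = as.list(stats::setNames(per$dice, per$name)),
    assd_mm = as.list(stats::setNames(per$assd_mm, per$name)),
    volumes_mm3 = as.list(stats::setNames(per$volume_mm3, per$name)),
    average_dice = report$average_dice,
    weighted_dice = report$weighted_dice,
    mean_assd_mm = report$mean_assd_mm,
    n_assd_excluded = report$n_assd_excluded,
    total_volume_mm3 = report$total_volume_mm3)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            na = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
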
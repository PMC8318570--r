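#' Read a NIfTI file as a volume, label map or softmax map
#'
#' Loads values, voxel spacing and the world affine from a NIfTI-1 file
#' (`.nii` / `.nii.gz`). 3D images (or 4D with a singleton trailing
#' dimension) load as [ms_volume()] or, with `as = "labels"`, as
#' [ms_labels()]; genuinely 4D images load as [ms_softmax()] with the class
#' along the 4th axis.
#'
#' @param path path to a NIfTI file.
#' @param as `"volume"`, `"labels"` or `"softmax"`.
#' @param scheme optional [label_scheme()]; label values outside the scheme
#'   are an error.
#' @return A `ms_volume`, `ms_labels` or `ms_softmax` object.
#' @seealso [write_nifti()]
#' @export
read_nifti <- function(path, as = c("volume", "labels", "softmax"),
                       scheme = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (as == "softmax") {
    if (length(d) != 4) stop("softmax maps must be 4D NIfTI, got ",
                             length(d), "D")
  } else {
    if (length(d) == 4 && d[4] == 1) { img <- img[, , , 1]; d <- dim(img) }
    if (length(d) != 3) stop("expected a 3D image, got ", length(d), "D")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4, 4))
  data <- as.array(img)
  attributes(data) <- list(dim = d)
  switch(as,
    volume = ms_volume(data, spacing, affine),
    labels = ms_labels(data, spacing, affine, scheme = scheme),
    softmax = ms_softmax(data, spacing, affine))
}

#' Write a volume, label map or softmax map to NIfTI
#'
#' Spacing is stored in `pixdim` and the world affine in the sform (code 2).
#' Label maps are written with an unsigned integer datatype; softmax maps
#' are written as 4D float images with the class along the 4th axis.
#'
#' @param obj a `ms_volume`, `ms_labels` or `ms_softmax`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(obj, path) {
  UseMethod("write_nifti")
}

ms_write_nifti <- function(data, spacing, affine, path, datatype) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @export
write_nifti.ms_volume <- function(obj, path) {
  ms_write_nifti(obj$data, obj$spacing, obj$affine, path, "double")
}

#' @export
write_nifti.ms_labels <- function(obj, path) {
  dt <- if (max(obj$data) < 256) "uint8" else "uint16"
  ms_write_nifti(obj$data, obj$spacing, obj$affine, path, dt)
}

#' @export
write_nifti.ms_softmax <- function(obj, path) {
  ms_write_nifti(obj$data, obj$spacing, obj$affine, path, "double")
}

#' Read or write a label scheme as a 2-column TSV
#'
#' The on-disk format is tab-separated `id` and `name` columns with a
#' header row, ids consecutive from 0 (background).
#'
#' @param path file path.
#' @param scheme a [label_scheme()] data.frame.
#' @return `read_label_scheme` returns the scheme; `write_label_scheme`
#'   returns `path` invisibly.
#' @export
read_label_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(df)))
    stop("scheme TSV must have 'id' and 'name' columns")
  df <- df[order(df$id), c("id", "name")]
  if (!identical(as.integer(df$id), seq_len(nrow(df)) - 1L))
    stop("scheme ids must be consecutive 0..C-1")
  class(df) <- c("ms_scheme", "data.frame")
  df
}

#' @rdname read_label_scheme
#' @export
write_label_scheme <- function(scheme, path) {
  utils::write.table(scheme[, c("id", "name")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
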
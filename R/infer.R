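#' Inference configuration
#'
#' Bundles the Monte-Carlo dropout settings and the modality-specific
#' quality-control threshold. The default thresholds on the aggregate
#' coefficient of variation are 1.0% for T1-weighted input and 2.5% for
#' FLAIR/DWI/CT; they were calibrated on clinical data and should be
#' re-tuned for other input distributions. Default network input shapes
#' per modality are 128^3 (t1, flair), 160x160x32 (dwi) and 96x128x96
#' (ct), all configurable.
#'
#' @param modality one of `"t1"`, `"flair"`, `"dwi"`, `"ct"`.
#' @param n_samples number of MC samples N (default 15).
#' @param seed integer seed from which the per-sample dropout seeds are
#'   derived.
#' @param cv_threshold QC threshold on the aggregate CV; default by
#'   modality as above.
#' @param input_shape expected network input grid; default by modality.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(modality = c("t1", "flair", "dwi", "ct"),
                             n_samples = 15L, seed = 1L,
                             cv_threshold = NULL, input_shape = NULL) {
  modality <- match.arg(modality)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (is.null(cv_threshold))
    cv_threshold <- if (modality == "t1") 0.010 else 0.025
  if (cv_threshold <= 0) stop("cv_threshold must be > 0")
  if (is.null(input_shape))
    input_shape <- switch(modality,
                          t1 = c(128L, 128L, 128L),
                          flair = c(128L, 128L, 128L),
                          dwi = c(160L, 160L, 32L),
                          ct = c(96L, 128L, 96L))
  structure(list(modality = modality, n_samples = n_samples,
                 seed = as.integer(seed), cv_threshold = cv_threshold,
                 input_shape = as.integer(input_shape)),
            class = "inference_config")
}

#' Hard segmentation by voxelwise argmax
#'
#' `S(x) = argmax_s P_s(x)`; exact ties break toward the lowest label id.
#'
#' @param probs a [ms_softmax()] (or `(nvox x C)` matrix with attribute-free
#'   grid, in which case grid metadata defaults to 1 mm).
#' @param scheme optional [label_scheme()] attached to the result.
#' @return A [ms_labels()].
#' @export
hard_segmentation <- function(probs, scheme = NULL) {
  stopifnot(inherits(probs, "ms_softmax"))
  d <- dim(probs$data)
  m <- matrix(probs$data, prod(d[1:3]), d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  ms_labels(array(lab, d[1:3]), probs$spacing, probs$affine, scheme = scheme)
}

#' Monte-Carlo dropout sampling
#'
#' Runs `n_samples` stochastic forward passes (dropout active, batch norm
#' in inference mode) with per-sample dropout seeds drawn reproducibly
#' from `config$seed`. With dropout rate 0 all samples equal the
#' deterministic forward pass.
#'
#' @param net a [unet()] or `unet_fit`.
#' @param volume a [ms_volume()] matching the network input shape.
#' @param config an [inference_config()].
#' @param normalize normalize intensities to `[0, 100]` first? Default
#'   `TRUE`.
#' @return A `ms_mcsamples` object: list with `samples` (list of
#'   `(nvox x C)` probability matrices), `grid`, `n_classes`.
#' @export
mc_predict <- function(net, volume, config = inference_config(),
                       normalize = TRUE) {
  if (inherits(net, "unet_fit")) net <- net$network
  v <- if (normalize) normalize_intensity(volume) else volume
  if (!identical(unname(dim(v$data)), unname(net$config$input_shape)))
    stop("volume shape does not match network input shape")
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, config$n_samples))
  xm <- as_input_matrix(v)
  samples <- lapply(seeds, function(s) {
    if (net$config$dropout > 0)
      with_seed(s, unet_forward_core(net, xm, mode = "mc"))$probs
    else unet_forward_core(net, xm, mode = "infer")$probs
  })
  structure(list(samples = samples, grid = grid_of(v),
                 n_classes = net$config$n_classes,
                 seeds = seeds),
            class = "ms_mcsamples")
}

#' @export
print.ms_mcsamples <- function(x, ...) {
  cat(sprintf("<ms_mcsamples> N = %d samples, %s grid, %d classes\n",
              length(x$samples), paste(x$grid$dim, collapse = "x"),
              x$n_classes))
  invisible(x)
}

#' Aggregate MC samples into the final segmentation
#'
#' Sums the softmax outputs of all samples and applies the argmax:
#' `S(x) = argmax_s sum_i P_s^i(x)`, with ties toward the lowest label.
#' For a single sample this reduces exactly to [hard_segmentation()].
#'
#' @param samples a `ms_mcsamples` from [mc_predict()].
#' @param scheme optional [label_scheme()] for the result.
#' @return A [ms_labels()].
#' @export
aggregate_mc <- function(samples, scheme = NULL) {
  stopifnot(inherits(samples, "ms_mcsamples"))
  if (!length(samples$samples)) stop("empty sample set")
  acc <- Reduce(`+`, samples$samples)
  lab <- max.col(acc, ties.method = "first") - 1L
  ms_labels(array(lab, samples$grid$dim), samples$grid$spacing,
            samples$grid$affine, scheme = scheme)
}

#' Coefficient-of-variation quality report from MC samples
#'
#' For each structure s, the volumes of its hard segmentation across the
#' N MC samples give a mean `mu_s` (mm^3) and sample standard deviation
#' `sigma_s` (N-1 denominator); `CV_s = sigma_s / mu_s`. The aggregate CV
#' is the arithmetic mean of `CV_s` over the non-background structures
#' that appear in at least one sample (structures absent everywhere have
#' `CV_s = 0` by convention and are excluded from the mean's
#' denominator). The segmentation is flagged when `CV > threshold`.
#'
#' @param samples a `ms_mcsamples`.
#' @param scheme a [label_scheme()] defining the structures.
#' @param spacing voxel spacing in mm (defaults to the sample grid's).
#' @param threshold QC threshold on the aggregate CV (default 0.025).
#' @return A list of class `qc_report`: `per_structure` (data.frame: id,
#'   name, mean_volume_mm3, sd_volume_mm3, cv), `cv`, `threshold`,
#'   `flagged`, `n_samples`.
#' @export
volume_cv <- function(samples, scheme, spacing = NULL, threshold = 0.025) {
  stopifnot(inherits(samples, "ms_mcsamples"))
  if (is.null(spacing)) spacing <- samples$grid$spacing
  N <- length(samples$samples)
  if (N < 2)
    warning("CV from a single MC sample is identically zero")
  C <- samples$n_classes
  ids <- setdiff(scheme$id, 0L)
  voxvol <- prod(spacing)
  vols <- vapply(samples$samples, function(P) {
    lab <- max.col(P, ties.method = "first") - 1L
    tabulate(lab, nbins = C - 1L) * voxvol  # counts for labels 1..C-1
  }, numeric(C - 1L))
  vols <- matrix(vols, nrow = C - 1L)  # structures x samples
  mu <- rowMeans(vols)
  sigma <- if (N >= 2) apply(vols, 1, sd) else rep(0, C - 1L)
  cv_s <- ifelse(mu > 0, sigma / mu, 0)
  keep <- ids[ids <= C - 1L]
  present <- mu[keep] > 0
  cv <- if (any(present)) mean(cv_s[keep][present]) else 0
  structure(list(
    per_structure = data.frame(
      id = keep,
      name = scheme$name[match(keep, scheme$id)],
      mean_volume_mm3 = mu[keep],
      sd_volume_mm3 = sigma[keep],
      cv = cv_s[keep],
      stringsAsFactors = FALSE),
    cv = cv, threshold = threshold, flagged = cv > threshold,
    n_samples = N),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> aggregate CV = %.4f (threshold %.4f) -> %s [N = %d]\n",
              x$cv, x$threshold,
              if (x$flagged) "FLAGGED" else "ok", x$n_samples))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `qc_report`.
#' @param path optional output path.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
qc_to_json <- function(report, path = NULL) {
  obj <- list(cv_per_structure =
                as.list(stats::setNames(report$per_structure$cv,
                                        report$per_structure$name)),
              cv = report$cv, threshold = report$threshold,
              flagged = report$flagged, n_samples = report$n_samples)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full segmentation pipeline with uncertainty gating
#'
#' Orchestrates the complete workflow on a native-grid scan: affine
#' coregistration to the reference volume, resampling of the registered
#' scan to the network input grid (cubic spline), intensity normalization
#' to `[0, 100]`, N stochastic forward passes, softmax-sum aggregation,
#' the coefficient-of-variation QC gate, and back-projection of the final
#' mask to the scan's native grid with the inverse transform and
#' nearest-neighbour resampling — so the returned mask's grid and affine
#' exactly match the input scan.
#'
#' @param scan a [ms_volume()] or path to a NIfTI file.
#' @param net a `unet_fit` or [unet()] with trained weights.
#' @param reference the reference [ms_volume()] defining the registration
#'   frame, or `NULL` to skip registration (scan assumed aligned).
#' @param config an [inference_config()].
#' @param scheme optional [label_scheme()] for the outputs.
#' @param register run the affine registration step? Defaults to `TRUE`
#'   when a reference is supplied.
#' @return A list of class `ms_segmentation`: `labels` (mask on the
#'   native grid), `qc` (a `qc_report`; inspect `qc$flagged`),
#'   `transform` (the estimated `ms_affine`), `labels_netgrid`.
#' @export
segment_volume <- function(scan, net, reference = NULL,
                           config = inference_config(), scheme = NULL,
                           register = !is.null(reference)) {
  if (is.character(scan)) scan <- read_nifti(scan)
  stopifnot(inherits(scan, "ms_volume"))
  if (inherits(net, "unet_fit")) net <- net$network
  shape <- net$config$input_shape
  if (is.null(scheme)) scheme <- label_scheme(net$config$n_classes - 1L)

  t <- affine_transform(diag(4))
  work <- scan
  if (register) {
    if (is.null(reference)) stop("registration requires a reference volume")
    t <- estimate_affine(scan, reference)
    work <- apply_transform(scan, t, target_grid = reference, mode = "spline")
  } else if (!is.null(reference)) {
    work <- apply_transform(scan, t, target_grid = reference, mode = "spline")
  }
  if (!identical(unname(dim(work$data)), unname(shape)))
    work <- resample(work, shape, mode = "spline")
  work <- normalize_intensity(work)

  mc <- mc_predict(net, work, config, normalize = FALSE)
  agg <- aggregate_mc(mc, scheme = scheme)
  qc <- volume_cv(mc, scheme, spacing = work$spacing,
                  threshold = config$cv_threshold)
  if (qc$flagged)
    warning(sprintf("segmentation flagged by QC: CV = %.4f > %.4f",
                    qc$cv, qc$threshold))

  native <- apply_transform(agg, invert(t), target_grid = scan,
                            mode = "nearest")
  structure(list(labels = native, qc = qc, transform = t,
                 labels_netgrid = agg),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  print(x$labels)
  print(x$qc)
  invisible(x)
}
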
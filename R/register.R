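#' Affine coregistration of a scan to a reference volume
#'
#' Estimates the affine transform aligning `moving` onto the grid of
#' `reference` by maximizing normalized mutual information (NMI) between
#' the reference and the transformed moving image. NMI is computed from a
#' 32x32 joint intensity histogram, which makes the objective usable
#' across modalities (e.g. registering a CT to a T1-weighted reference).
#' Optimization is a deterministic multi-resolution scheme: a Nelder-Mead
#' search over the rigid parameters at each pyramid level from coarse to
#' fine, followed (for `dof > 6`) by a full search over scales and shears
#' at the finest level. Initialization is always the identity.
#'
#' The returned transform maps reference world coordinates to moving world
#' coordinates, so `apply_transform(moving, t, reference)` resamples the
#' moving image onto the reference grid in alignment with it. If the final
#' objective fails to improve on the identity transform, the identity is
#' returned with attribute `identity_fallback = TRUE` and a warning.
#'
#' @param moving,reference [ms_volume()] objects; both must be non-constant.
#' @param levels number of resolution levels (downsampling factors
#'   `2^(levels-1), ..., 2, 1`), reduced automatically on small grids.
#' @param dof degrees of freedom: 6 (rigid), 9 (+scales) or 12 (+shears).
#' @param seed reserved for stochastic objective subsampling; the default
#'   objective uses every voxel and is fully deterministic.
#' @param bins joint histogram size per axis.
#' @param maxit Nelder-Mead iteration budget per level.
#' @return An [affine_transform()] with attributes `objective` (final NMI),
#'   `objective_trace` (best NMI per level, evaluated at the finest level)
#'   and `identity_fallback`.
#' @export
estimate_affine <- function(moving, reference, levels = 3, dof = 12,
                            seed = 1L, bins = 32, maxit = 400) {
  stopifnot(inherits(moving, "ms_volume"), inherits(reference, "ms_volume"))
  if (diff(range(moving$data)) == 0 || diff(range(reference$data)) == 0)
    stop("registration requires non-constant volumes")
  dof <- match.arg(as.character(dof), c("6", "9", "12"))
  dof <- as.integer(dof)
  ref <- normalize_intensity(reference, 1, 99)
  mov <- normalize_intensity(moving, 1, 99)
  center <- as.vector(ref$affine %*% c((dim(ref$data) - 1) / 2, 1))[1:3]

  par_to_affine <- function(p) {
    affine_from_params(translation = p[1:3], rotation_deg = p[4:6],
                       scale = exp(p[7:9]), shear = p[10:12],
                       center = center)
  }
  nmi_at <- function(p, refL, movL) {
    t <- par_to_affine(p)
    M <- solve(movL$affine) %*% t$matrix %*% refL$affine
    cpp_nmi(as.vector(refL$data), dim(refL$data),
            as.vector(movL$data), dim(movL$data),
            M, bins, 0, 100, 0, 100)
  }

  # resolution pyramid: drop factors that would shrink any axis below 8
  factors <- 2^((levels:1) - 1)
  factors <- factors[pmin(min(dim(ref$data)), min(dim(mov$data))) / factors >= 8]
  if (!length(factors)) factors <- 1
  pyramid <- lapply(factors, function(f) {
    if (f == 1) list(ref = ref, mov = mov)
    else list(ref = resample(ref, pmax(4L, as.integer(round(dim(ref$data) / f))),
                             mode = "linear"),
              mov = resample(mov, pmax(4L, as.integer(round(dim(mov$data) / f))),
                             mode = "linear"))
  })

  p <- rep(0, 12)
  pscale <- c(rep(1, 3), rep(0.5, 3), rep(0.02, 3), rep(0.02, 3))
  trace <- numeric(0)
  finest <- pyramid[[length(pyramid)]]
  for (li in seq_along(pyramid)) {
    lev <- pyramid[[li]]
    free <- 1:6
    obj <- function(q) { pp <- p; pp[free] <- q; -nmi_at(pp, lev$ref, lev$mov) }
    fit <- optim(p[free], obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8,
                                parscale = pscale[free]))
    p[free] <- fit$par
    if (dof > 6 && li == length(pyramid)) {
      free <- seq_len(dof)
      fit <- optim(p[free], obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-8,
                                  parscale = pscale[free]))
      p[free] <- fit$par
    }
    trace <- c(trace, nmi_at(p, finest$ref, finest$mov))
  }

  final_obj <- nmi_at(p, finest$ref, finest$mov)
  ident_obj <- nmi_at(rep(0, 12), finest$ref, finest$mov)
  if (final_obj < ident_obj) {
    warning("registration failed to improve over identity; returning identity")
    t <- affine_transform(diag(4))
    attr(t, "identity_fallback") <- TRUE
    attr(t, "objective") <- ident_obj
    attr(t, "objective_trace") <- trace
    return(t)
  }
  t <- par_to_affine(p)
  attr(t, "identity_fallback") <- FALSE
  attr(t, "objective") <- final_obj
  attr(t, "objective_trace") <- trace
  attr(t, "params") <- p
  t
}
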
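# Pixel-wise slope fitting, perfusion maps, hemodynamic-response maps, and
# the flow-rate/slope correlation analysis.

#' Pixel-wise linear fit of signal versus recovery delay
#'
#' Ordinary least squares of each pixel's time course against the TOF
#' delays, with an intercept by default (the in vivo delay triplets do not
#' start at zero and saturation is never perfect, so a through-origin fit is
#' unsafe; it is available via `through_origin = TRUE`). No per-pixel
#' weighting is applied — with three points there is nothing to estimate
#' weights from. The slope standard error is computed from the residual
#' variance (`n - 2` degrees of freedom) and carried along as a quality
#' layer.
#'
#' @param images 3-D array (x, y, dynamic) of SNR maps or magnitude images,
#'   or a `tof_recon` object (its SNR stack is used when present, otherwise
#'   the magnitude stack).
#' @param tof_delays Delays in seconds, one per dynamic (taken from the
#'   `tof_recon` object when omitted).
#' @param mask Optional logical matrix; pixels outside the mask get `NA` in
#'   every output layer.
#' @param through_origin Fit without intercept? Default `FALSE`.
#' @return An object of class `slope_map`: list with matrices `slope`
#'   (signal units per second), `intercept`, `r_squared` (`NA` where the
#'   pixel time course is constant), `se` (slope standard error; `NA` when
#'   `n <= 2`), plus `n_points`, `tof_delays`, `mask`.
#' @export
fit_slope_map <- function(images, tof_delays = NULL, mask = NULL,
                          through_origin = FALSE) {
  if (inherits(images, "tof_recon")) {
    if (is.null(tof_delays)) tof_delays <- images$tof_delays
    images <- if (!is.null(images$snr)) images$snr else images$images
  }
  stopifnot(is.array(images), length(dim(images)) == 3)
  nd <- dim(images)[3]
  if (nd < 2) stop("need at least 2 dynamics to fit a slope", call. = FALSE)
  tau <- check_tau(tof_delays)
  if (length(tau) != nd)
    stop("`tof_delays` must match the number of dynamics", call. = FALSE)
  if (max(tau) - min(tau) <= 0)
    stop("delays must not all be equal", call. = FALSE)
  dims <- dim(images)[1:2]
  Y <- matrix(images, prod(dims), nd)  # pixels x dynamics

  if (through_origin) {
    stt <- sum(tau^2)
    slope <- as.vector(Y %*% tau) / stt
    fitted <- outer(slope, tau)
    intercept <- rep(0, length(slope))
    sst <- rowSums(Y^2)
  } else {
    tc <- tau - mean(tau)
    stt <- sum(tc^2)
    ybar <- rowMeans(Y)
    slope <- as.vector(Y %*% tc) / stt
    intercept <- ybar - slope * mean(tau)
    fitted <- outer(slope, tau) + intercept
    sst <- rowSums((Y - ybar)^2)
  }
  sse <- rowSums((Y - fitted)^2)
  r2 <- ifelse(sst > 0, pmax(0, 1 - sse / sst), NA_real_)
  dof <- nd - 2L
  se <- if (dof > 0) sqrt(pmax(sse, 0) / dof / stt) else rep(NA_real_, length(slope))

  shape <- function(v) { m <- matrix(v, dims[1], dims[2]); if (!is.null(mask)) m[!mask] <- NA; m }
  if (!is.null(mask)) stopifnot(is.logical(mask), all(dim(mask) == dims))
  structure(list(slope = shape(slope), intercept = shape(intercept),
                 r_squared = shape(r2), se = shape(se),
                 n_points = nd, tof_delays = tau, mask = mask),
            class = "slope_map")
}

#' @export
print.slope_map <- function(x, ...) {
  cat("<slope_map> ", paste(dim(x$slope), collapse = " x "),
      " pixels, ", x$n_points, " dynamics (tau = ",
      paste(x$tof_delays, collapse = ", "), " s)\n", sep = "")
  cat("  slope range:", paste(signif(range(x$slope, na.rm = TRUE), 4),
                              collapse = " .. "), "per s\n")
  invisible(x)
}

#' Default fitting mask from an SNR stack
#'
#' Pixels whose maximum SNR across the dynamics exceeds a threshold. The
#' source protocol states no masking rule; this conventional rule (default
#' threshold 3) excludes noise-only background from fitting.
#'
#' @param snr_stack 3-D SNR array (x, y, dynamic) or a `tof_recon` object.
#' @param threshold SNR threshold, default 3.
#' @return Logical matrix.
#' @export
default_fit_mask <- function(snr_stack, threshold = 3) {
  if (inherits(snr_stack, "tof_recon")) {
    if (is.null(snr_stack$snr))
      stop("tof_recon has no SNR stack; reconstruct with a noise region",
           call. = FALSE)
    snr_stack <- snr_stack$snr
  }
  apply(snr_stack, c(1, 2), max) > threshold
}

#' Convert a slope map to a perfusion map
#'
#' Applies [slope_to_perfusion()] pixel-wise: `f_sum = 60 * slope /
#' s_arterial`, in mL blood per mL tissue per minute. Negative slopes pass
#' through unclipped (clipping would bias subsequent map subtraction); they
#' are flagged in the `negative` quality layer.
#'
#' @param slopes A [fit_slope_map()] result.
#' @param calibration A [calibration_params()] object.
#' @return An object of class `perfusion_map`: list with `f_sum` (matrix,
#'   mL/mL/min), `negative` (logical quality layer), `calibration`, and the
#'   source `slope_map`.
#' @export
make_perfusion_map <- function(slopes, calibration) {
  stopifnot(inherits(slopes, "slope_map"),
            inherits(calibration, "calibration_params"))
  f <- slope_to_perfusion(slopes$slope, calibration)
  structure(list(f_sum = f, negative = !is.na(f) & f < 0,
                 calibration = calibration, slopes = slopes),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  cat("<perfusion_map> ", paste(dim(x$f_sum), collapse = " x "),
      " pixels, mL/mL/min; s_arterial = ",
      signif(x$calibration$s_arterial, 5), "\n", sep = "")
  invisible(x)
}

#' Hemodynamic-response map
#'
#' Task-minus-baseline difference of two slope maps acquired with the same
#' delay design: `delta = task$slope - baseline$slope`. The operation is
#' antisymmetric: swapping the arguments negates the map. Where either
#' input is `NA` (outside its mask), the difference is `NA`.
#'
#' @param task,baseline [fit_slope_map()] results of identical shape.
#' @return An object of class `hdr_map`: list with `delta_slope` (matrix,
#'   signal units per second) and `se` (propagated slope standard error,
#'   `sqrt(se_task^2 + se_base^2)`, where available).
#' @export
hdr_map <- function(task, baseline) {
  stopifnot(inherits(task, "slope_map"), inherits(baseline, "slope_map"))
  if (!all(dim(task$slope) == dim(baseline$slope)))
    stop("task and baseline maps have different shapes", call. = FALSE)
  if (!isTRUE(all.equal(task$tof_delays, baseline$tof_delays)))
    warning("task and baseline were fitted on different delay designs",
            call. = FALSE)
  se <- sqrt(task$se^2 + baseline$se^2)
  structure(list(delta_slope = task$slope - baseline$slope, se = se,
                 tof_delays = task$tof_delays),
            class = "hdr_map")
}

#' Threshold an HDR map for display
#'
#' Marks pixels whose |delta slope| exceeds `z` times a noise scale. This
#' display utility is a convenience addition, not part of the source
#' acquisition protocol (which applies no multiple-comparison control to
#' the xenon maps). By default the noise scale is the median absolute
#' deviation of the in-mask delta values, which is robust to a minority of
#' truly activated pixels.
#'
#' Deviations are measured from the in-mask median rather than from zero:
#' the SNR normalization of two separately acquired series (two
#' breath-holds) carries an independent noise-sd estimate each, so the
#' whole difference map can be offset by a few percent of the slope scale;
#' median centering removes that common mode while a minority of truly
#' activated pixels leaves the median and the MAD nearly untouched.
#'
#' @param hdr An [hdr_map()] result.
#' @param z Threshold multiple, default 2.
#' @param sigma Noise scale; default `mad` of the finite delta values
#'   (median-centered).
#' @return Logical matrix (`NA` pixels are `FALSE`).
#' @export
threshold_hdr <- function(hdr, z = 2, sigma = NULL) {
  stopifnot(inherits(hdr, "hdr_map"))
  d <- hdr$delta_slope
  ctr <- stats::median(d[is.finite(d)])
  if (is.null(sigma)) sigma <- stats::mad(d[is.finite(d)])
  out <- abs(d - ctr) > z * sigma
  out[!is.finite(d)] <- FALSE
  out
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical nonempty masks, 0 for
#' disjoint ones, `NaN` when both are empty.
#'
#' @param a,b Logical matrices of equal dimensions.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Mean map value per phantom compartment
#'
#' @param map Numeric matrix (e.g. `perfusion_map$f_sum` or a slope layer).
#' @param masks Named list of logical masks (see [phantom_masks()]).
#' @return Named numeric vector of in-mask means (`NA` values dropped).
#' @export
compartment_means <- function(map, masks) {
  vapply(masks, function(m) mean(map[m], na.rm = TRUE), numeric(1))
}

#' Correlation between flow rate and TOF recovery slope
#'
#' Fits each recovery curve's slope by least squares on the quasilinear
#' window (default 200-700 ms, inclusive) and returns the Pearson
#' correlation between the flow rates and the fitted slopes, mirroring the
#' in vitro flow-phantom analysis.
#'
#' @param flows Flow rates, mL/min; at least 3.
#' @param curves List of [uptake_curve()] objects, one per flow rate.
#' @param window Fit window in seconds, default `c(0.2, 0.7)`.
#' @return An object of class `flow_correlation`: list with `r` (Pearson
#'   correlation), `p_value` (two-sided, from [stats::cor.test()]),
#'   `slopes`, `flows`, `window`.
#' @export
flow_slope_correlation <- function(flows, curves, window = c(0.2, 0.7)) {
  if (length(flows) < 3)
    stop("need at least 3 flow rates", call. = FALSE)
  if (length(curves) != length(flows))
    stop("`curves` must have one curve per flow rate", call. = FALSE)
  slopes <- vapply(curves, function(cv) {
    stopifnot(inherits(cv, "uptake_curve"))
    sel <- cv$tau >= window[1] - 1e-9 & cv$tau <= window[2] + 1e-9
    if (sum(sel) < 2)
      stop("fit window contains fewer than 2 curve points", call. = FALSE)
    stats::cov(cv$tau[sel], cv$signal[sel]) / stats::var(cv$tau[sel])
  }, numeric(1))
  if (stats::sd(slopes) == 0 || stats::sd(flows) == 0)
    stop("degenerate (zero-variance) slopes or flows", call. = FALSE)
  ct <- stats::cor.test(flows, slopes)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 slopes = slopes, flows = flows, window = window),
            class = "flow_correlation")
}

#' @export
print.flow_correlation <- function(x, ...) {
  cat("<flow_correlation> r =", signif(x$r, 4),
      " (p =", signif(x$p_value, 3), ") over window [",
      x$window[1], ",", x$window[2], "] s\n")
  cat("  flows (mL/min):", paste(x$flows, collapse = ", "), "\n")
  cat("  slopes (1/s):  ", paste(signif(x$slopes, 4), collapse = ", "), "\n")
  invisible(x)
}
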
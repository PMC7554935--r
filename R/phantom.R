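# Synthetic-data engine: tube flow phantom, digital brain phantom, and the
# forward gradient-echo k-space acquisition model.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Tube flow phantom specification
#'
#' Geometry and signal model of a saline tube fed by a syringe pump at a
#' constant volumetric flow rate, imaged with the TOF sequence. After the
#' saturation pulse, fresh xenon-laden saline refills the coil-sensitive
#' tube length; the signal is proportional to the refilled fraction of the
#' sensitive volume.
#'
#' @param flow_rate Volumetric flow rate Q, mL/min (> 0).
#' @param tube_id Inner tube diameter, mm. Default 3.175.
#' @param sensitive_length Coil-sensitive tube length, mm. Default 20, a
#'   declared simulator geometry (not a printed value) chosen so that the
#'   simulated curves show a quasilinear rise to ~0.7 s, a nonlinear
#'   transition, and earlier saturation at faster flow within a 2 s delay
#'   range.
#' @param profile Velocity profile: `"laminar"` (parabolic Poiseuille,
#'   default) or `"plug"` (uniform).
#' @param s_max Plateau signal when the sensitive volume is fully
#'   replenished (arbitrary units).
#' @param noise_sd Additive Gaussian noise sd on each sampled point
#'   (same units as `s_max`). Default `0.02 * s_max`.
#' @return An object of class `flow_phantom_spec`.
#' @export
flow_phantom_spec <- function(flow_rate, tube_id = 3.175,
                              sensitive_length = 20,
                              profile = c("laminar", "plug"),
                              s_max = 1, noise_sd = 0.02 * s_max) {
  profile <- match.arg(profile)
  vals <- c(flow_rate, tube_id, sensitive_length, s_max, noise_sd)
  if (any(!is.finite(vals)))
    stop("flow phantom parameters must be finite", call. = FALSE)
  if (flow_rate <= 0 || tube_id <= 0 || sensitive_length <= 0)
    stop("flow_rate, tube_id and sensitive_length must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(flow_rate = flow_rate, tube_id = tube_id,
                 sensitive_length = sensitive_length, profile = profile,
                 s_max = s_max, noise_sd = noise_sd),
            class = "flow_phantom_spec")
}

#' Sensitive volume of a flow phantom (mL)
#' @param spec A [flow_phantom_spec()].
#' @return Volume `pi * (tube_id/2)^2 * sensitive_length` in mL.
#' @export
flow_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "flow_phantom_spec"))
  pi * (spec$tube_id / 2)^2 * spec$sensitive_length / 1000
}

#' Replenished fraction of the sensitive volume at delay tau
#'
#' Plug flow refills the sensitive length as a sharp front:
#' `min(Q*tau/V, 1)` with Q in mL/s. Laminar (Poiseuille) flow has velocity
#' `v(r) = 2*vbar*(1 - (r/R)^2)`; spins beyond the sensitive length no
#' longer contribute, giving the closed form
#' `u/2` for `u <= 1` and `1 - 1/(2u)` for `u > 1`, where
#' `u = 2*vbar*tau/L` is the transit fraction of the fastest (axial) spins.
#' Both profiles give the same early-time linear rise `Q*tau/V` and the same
#' plateau; they differ in the transition.
#'
#' @param spec A [flow_phantom_spec()].
#' @param tau Recovery delays, seconds.
#' @return Fraction in \[0, 1\] at each `tau`.
#' @export
flow_fill_fraction <- function(spec, tau) {
  tau <- check_tau(tau)
  V <- flow_phantom_volume(spec)            # mL
  q <- spec$flow_rate / 60                  # mL/s
  if (spec$profile == "plug") {
    pmin(q * tau / V, 1)
  } else {
    # u = 2*vbar*tau/L = 2*(Q*tau/V): fastest-spin transit fraction
    u <- 2 * q * tau / V
    ifelse(u <= 1, u / 2, 1 - 1 / (2 * pmax(u, 1)))
  }
}

#' Simulate a TOF recovery curve from a flow phantom
#'
#' Evaluates `s_max * flow_fill_fraction()` on a delay grid and adds
#' independent Gaussian noise. The default grid reproduces the in vitro
#' protocol: 20 delays from 200 ms to 2000 ms in 100 ms steps.
#'
#' @param spec A [flow_phantom_spec()].
#' @param tau_grid Delays in seconds, strictly increasing.
#' @param seed Optional integer RNG seed (local to this call).
#' @return An [uptake_curve()].
#' @export
simulate_flow_curve <- function(spec, tau_grid = seq(0.2, 2.0, by = 0.1),
                                seed = NULL) {
  if (length(tau_grid) == 0) stop("`tau_grid` must be nonempty", call. = FALSE)
  s <- spec$s_max * flow_fill_fraction(spec, tau_grid)
  if (spec$noise_sd > 0)
    s <- s + with_local_seed(seed, stats::rnorm(length(s), 0, spec$noise_sd))
  uptake_curve(tau_grid, s)
}

# ---- digital brain phantom -------------------------------------------------

ellipse_mask <- function(grid, center, semi_axes) {
  x <- matrix(seq_len(grid[1]) - 1, grid[1], grid[2])
  y <- matrix(seq_len(grid[2]) - 1, grid[1], grid[2], byrow = TRUE)
  ((x - center[1]) / semi_axes[1])^2 + ((y - center[2]) / semi_axes[2])^2 <= 1
}

#' Elliptical tissue compartment of a digital phantom
#'
#' Geometry (an ellipse, optionally with an elliptical hole) plus the
#' kinetic parameters of one tissue compartment. Coordinates are 0-based
#' pixel indices on the acquisition grid; `center` and `semi_axes` are in
#' pixels.
#'
#' @param label Compartment name (e.g. `"gray"`).
#' @param center Ellipse center, 0-based pixel coordinates (length 2).
#' @param semi_axes Ellipse semi-axes in pixels (length 2).
#' @param params A [kinetics_params()] object.
#' @param hole Optional inner ellipse excluded from the compartment:
#'   list with `center` and `semi_axes`.
#' @return An object of class `phantom_compartment`.
#' @export
phantom_compartment <- function(label, center, semi_axes, params,
                                hole = NULL) {
  stopifnot(inherits(params, "kinetics_params"),
            length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0", call. = FALSE)
  structure(list(label = label, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), params = params,
                 hole = hole),
            class = "phantom_compartment")
}

compartment_mask <- function(comp, grid, scale = 1, erode_px = 0) {
  m <- ellipse_mask(grid, comp$center * scale + (scale - 1) / 2,
                    pmax(comp$semi_axes * scale - erode_px, 0.5))
  if (!is.null(comp$hole)) {
    h <- ellipse_mask(grid, comp$hole$center * scale + (scale - 1) / 2,
                      comp$hole$semi_axes * scale + erode_px)
    m <- m & !h
  }
  m
}

#' Digital brain phantom specification
#'
#' A two-compartment head phantom on the acquisition grid: a white-matter
#' inner ellipse surrounded by a gray-matter elliptical shell, in a
#' zero-perfusion background. Defaults place the head well inside a 20 x 20
#' grid over a 250 x 250 mm field of view so that the image corners stay
#' signal-free for noise estimation.
#'
#' @param grid Acquisition matrix, length 2. Default `c(20, 20)`.
#' @param fov Field of view in mm, length 2. Default `c(250, 250)`.
#' @param compartments List of [phantom_compartment()] objects with mutually
#'   disjoint masks. Defaults to the gray-shell / white-core head.
#' @return An object of class `brain_phantom_spec`.
#' @export
brain_phantom_spec <- function(grid = c(20, 20), fov = c(250, 250),
                               compartments = NULL) {
  grid <- as.integer(rep_len(grid, 2))
  fov <- as.numeric(rep_len(fov, 2))
  if (any(grid < 4) || any(fov <= 0))
    stop("invalid grid or field of view", call. = FALSE)
  if (is.null(compartments)) {
    ctr <- (grid - 1) / 2
    inner <- list(center = ctr, semi_axes = c(3.2, 4.0) * grid / 20)
    compartments <- list(
      phantom_compartment("gray", ctr, c(6.5, 7.5) * grid / 20,
                          kinetics_preset("gray"), hole = inner),
      phantom_compartment("white", inner$center, inner$semi_axes,
                          kinetics_preset("white")))
  }
  if (length(compartments) == 0)
    stop("at least one compartment is required", call. = FALSE)
  spec <- structure(list(grid = grid, fov = fov,
                         compartments = compartments),
                    class = "brain_phantom_spec")
  cover <- Reduce(`+`, lapply(compartments, compartment_mask, grid = grid))
  if (any(cover > 1))
    stop("compartment masks overlap", call. = FALSE)
  if (!any(cover > 0))
    stop("compartment masks lie outside the grid", call. = FALSE)
  spec
}

#' Rasterize a phantom to a ground-truth perfusion image
#'
#' @param spec A [brain_phantom_spec()].
#' @return A list of class `brain_phantom` with `f_map` (matrix of summed
#'   compartment perfusion, mL/mL/min; background 0), `masks` (named list of
#'   logical compartment masks), and `spec`.
#' @export
make_brain_phantom <- function(spec) {
  stopifnot(inherits(spec, "brain_phantom_spec"))
  masks <- lapply(spec$compartments, compartment_mask_resolved,
                  grid = spec$grid)
  cover <- Reduce(`+`, masks)
  if (any(cover > 1)) stop("compartment masks overlap", call. = FALSE)
  names(masks) <- vapply(spec$compartments, `[[`, "", "label")
  f_map <- matrix(0, spec$grid[1], spec$grid[2])
  for (i in seq_along(masks))
    f_map[masks[[i]]] <- sum(spec$compartments[[i]]$params$f)
  structure(list(f_map = f_map, masks = masks, spec = spec),
            class = "brain_phantom")
}

#' Add an activated region to a phantom
#'
#' Splits every compartment intersecting an elliptical "activation blob"
#' into an unchanged part and an activated part whose perfusion is scaled by
#' `1 + frac`, emulating a stimulus-driven local blood-flow increase. The
#' resulting spec stays disjoint by construction.
#'
#' @param spec A [brain_phantom_spec()].
#' @param center Blob center, 0-based pixels on the acquisition grid.
#' @param semi_axes Blob semi-axes in pixels.
#' @param frac Fractional perfusion increase inside the blob (default 0.2).
#' @return A new `brain_phantom_spec`; the blob geometry is recorded in
#'   `attr(, "activation")`.
#' @export
add_activation <- function(spec, center = NULL, semi_axes = NULL,
                           frac = 0.2) {
  stopifnot(inherits(spec, "brain_phantom_spec"))
  if (is.null(center)) center <- (spec$grid - 1) / 2 + c(0, 5) * spec$grid / 20
  if (is.null(semi_axes)) semi_axes <- c(2.2, 2.2) * spec$grid / 20
  blob <- ellipse_mask(spec$grid, center, semi_axes)
  comps <- list()
  for (comp in spec$compartments) {
    m <- compartment_mask(comp, spec$grid)
    if (!any(m & blob)) { comps <- c(comps, list(comp)); next }
    p <- comp$params
    boosted <- kinetics_params(f = p$f * (1 + frac), lam = p$lam,
                               t1_blood = p$t1_blood,
                               t1_tissue = p$t1_tissue,
                               transit_delay = p$transit_delay,
                               m_a0 = p$m_a0)
    comps <- c(comps,
               list(structure(utils::modifyList(unclass(comp),
                      list(raw_mask = m & !blob)),
                      class = "phantom_compartment"),
                    structure(list(label = paste0(comp$label, "_active"),
                                   center = comp$center,
                                   semi_axes = comp$semi_axes,
                                   params = boosted, hole = comp$hole,
                                   raw_mask = m & blob),
                              class = "phantom_compartment")))
  }
  out <- structure(list(grid = spec$grid, fov = spec$fov,
                        compartments = comps),
                   class = "brain_phantom_spec")
  attr(out, "activation") <- list(center = center, semi_axes = semi_axes,
                                  frac = frac)
  out
}

# raw_mask (explicit pixel set) takes precedence over ellipse geometry; used
# by add_activation() to keep split compartments disjoint.
compartment_mask_resolved <- function(comp, grid) {
  if (!is.null(comp$raw_mask)) comp$raw_mask else compartment_mask(comp, grid)
}

#' Compartment masks on an arbitrary (e.g. reconstruction) grid
#'
#' Re-rasterizes the phantom's elliptical compartments on a `dims` grid over
#' the same field of view. A positive `erode_px` shrinks every ellipse (and
#' grows every hole) by that many target-grid pixels, eroding the
#' partial-volume edge before compartment means are computed on
#' reconstructed maps.
#'
#' @param spec A [brain_phantom_spec()].
#' @param dims Target grid, length 2 (default the spec's own grid).
#' @param erode_px Edge erosion in target-grid pixels; default 0.
#' @return Named list of logical masks.
#' @export
phantom_masks <- function(spec, dims = spec$grid, erode_px = 0) {
  stopifnot(inherits(spec, "brain_phantom_spec"))
  dims <- as.integer(rep_len(dims, 2))
  scale <- dims[1] / spec$grid[1]
  masks <- lapply(spec$compartments, function(comp) {
    if (!is.null(comp$raw_mask) && all(dims == spec$grid) && erode_px == 0)
      return(comp$raw_mask)
    compartment_mask(comp, dims, scale = scale, erode_px = erode_px)
  })
  names(masks) <- vapply(spec$compartments, `[[`, "", "label")
  masks
}

#' Activation blob mask on an arbitrary grid
#' @inheritParams phantom_masks
#' @return Logical mask of the activated region, or an error if the spec
#'   carries no activation.
#' @export
activation_mask <- function(spec, dims = spec$grid) {
  act <- attr(spec, "activation")
  if (is.null(act)) stop("spec carries no activation", call. = FALSE)
  dims <- as.integer(rep_len(dims, 2))
  scale <- dims[1] / spec$grid[1]
  ellipse_mask(dims, act$center * scale + (scale - 1) / 2,
               act$semi_axes * scale)
}

# ---- forward acquisition ---------------------------------------------------

#' Acquisition parameters for a dynamic TOF scan
#'
#' @param tof_delays Recovery delays in seconds, strictly increasing, >= 0.
#'   Default: the axial in vivo triplet `c(2.5, 6.7, 7.1)`.
#' @param flip_angle Readout excitation flip angle in degrees, in (0, 90\].
#'   Default 20.
#' @param matrix Acquisition matrix (phase-encode lines x readout samples).
#'   Default `c(20, 20)`.
#' @param zero_pad_to Reconstruction matrix after zero-padding; each
#'   dimension >= `matrix`. Default `c(32, 32)`.
#' @param noise_sd Complex Gaussian noise sd per k-space sample and
#'   component (arbitrary units). Default 0 (noiseless).
#' @param phase_order Phase-encode acquisition order: `"linear"`
#'   (bottom-to-top, default) or `"centric"` (center-out).
#' @param seed Integer RNG seed for the noise; `NULL` leaves the global RNG
#'   untouched and unused draws nondeterministic.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tof_delays = c(2.5, 6.7, 7.1),
                               flip_angle = 20, matrix = c(20, 20),
                               zero_pad_to = c(32, 32), noise_sd = 0,
                               phase_order = c("linear", "centric"),
                               seed = NULL) {
  phase_order <- match.arg(phase_order)
  tof_delays <- check_tau(tof_delays)
  if (length(tof_delays) > 1 && any(diff(tof_delays) <= 0))
    stop("`tof_delays` must be strictly increasing", call. = FALSE)
  if (!is.finite(flip_angle) || flip_angle <= 0 || flip_angle > 90)
    stop("`flip_angle` must be in (0, 90] degrees", call. = FALSE)
  matrix <- as.integer(rep_len(matrix, 2))
  zero_pad_to <- as.integer(rep_len(zero_pad_to, 2))
  if (any(zero_pad_to < matrix))
    stop("`zero_pad_to` must be >= `matrix`", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(tof_delays = tof_delays, flip_angle = flip_angle,
                 matrix = matrix, zero_pad_to = zero_pad_to,
                 noise_sd = noise_sd, phase_order = phase_order,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "acquisition_params")
}

#' Hyperpolarized depletion weights per phase-encode line
#'
#' The hyperpolarized magnetization is consumed, not recovered: the j-th
#' excitation of a dynamic tips `sin(alpha)` of the remaining longitudinal
#' magnetization into the transverse plane and leaves `cos(alpha)`, so the
#' j-th acquired line carries amplitude `sin(alpha) * cos(alpha)^(j-1)`.
#' The returned vector is ordered by k-space row (DC-centered grid):
#' `"linear"` ordering acquires rows bottom-to-top, `"centric"` acquires the
#' DC row first and alternates outward.
#'
#' @param flip_angle Flip angle in degrees.
#' @param n_lines Number of phase-encode lines.
#' @param phase_order `"linear"` or `"centric"`.
#' @return Numeric vector of length `n_lines`: amplitude weight of each
#'   k-space row.
#' @export
gre_line_weights <- function(flip_angle, n_lines,
                             phase_order = c("linear", "centric")) {
  phase_order <- match.arg(phase_order)
  a <- flip_angle * pi / 180
  w_acq <- sin(a) * cos(a)^(seq_len(n_lines) - 1)
  if (phase_order == "linear") return(w_acq)
  dc <- floor(n_lines / 2) + 1
  ord <- order(abs(seq_len(n_lines) - dc),
               -(seq_len(n_lines) - dc))  # DC first, tie -> lower row first
  w <- numeric(n_lines)
  w[ord] <- w_acq
  w
}

uptake_image <- function(spec, tau) {
  img <- matrix(0, spec$grid[1], spec$grid[2])
  for (comp in spec$compartments) {
    m <- compartment_mask_resolved(comp, spec$grid)
    if (any(m)) img[m] <- img[m] + analytic_uptake(comp$params, tau)
  }
  img
}

#' Simulate a dynamic TOF k-space series from a digital phantom
#'
#' For each recovery delay, evaluates the noiseless per-pixel uptake signal
#' from the phantom's kinetic compartments, applies the forward unitary 2-D
#' DFT, weights each phase-encode line (k-space row) by the flip-angle
#' depletion factor of its acquisition order, and adds seeded complex
#' Gaussian noise. The saturation pulse resets the magnetization between
#' dynamics, so depletion weighting restarts in every dynamic; the available
#' magnetization at dynamic i is the kinetics value at its delay.
#'
#' @param spec A [brain_phantom_spec()].
#' @param acq An [acquisition_params()] object; `acq$matrix` must equal the
#'   phantom grid.
#' @return An object of class `tof_series`: list with `kspace` (complex
#'   array, rows x cols x dynamics), `tof_delays`, `acq`, `spec`, `truth`
#'   (the `brain_phantom` ground truth).
#' @export
simulate_tof_series <- function(spec, acq) {
  stopifnot(inherits(spec, "brain_phantom_spec"),
            inherits(acq, "acquisition_params"))
  if (!all(acq$matrix == spec$grid))
    stop("acquisition matrix must match the phantom grid", call. = FALSE)
  nd <- length(acq$tof_delays)
  w <- gre_line_weights(acq$flip_angle, acq$matrix[1], acq$phase_order)
  ks <- array(as.complex(0), c(acq$matrix, nd))
  noise <- if (acq$noise_sd > 0) {
    n <- prod(acq$matrix) * nd
    with_local_seed(acq$seed,
      complex(real = stats::rnorm(n, 0, acq$noise_sd),
              imaginary = stats::rnorm(n, 0, acq$noise_sd)))
  } else rep(as.complex(0), prod(acq$matrix) * nd)
  dim(noise) <- c(acq$matrix, nd)
  for (i in seq_len(nd)) {
    img <- uptake_image(spec, acq$tof_delays[i])
    ks[, , i] <- forward_dft2(img) * w + noise[, , i]
  }
  structure(list(kspace = ks, tof_delays = acq$tof_delays, acq = acq,
                 spec = spec, truth = make_brain_phantom(spec)),
            class = "tof_series")
}

#' Expected image-domain gain of the acquisition and reconstruction chain
#'
#' A pixel of noiseless magnetization `m` appears in the zero-padded
#' magnitude reconstruction with amplitude approximately `m * gain`, where
#' `gain = w_dc * sqrt(prod(matrix) / prod(zero_pad_to))`: `w_dc` is the
#' depletion weight of the DC phase-encode line and the square root is the
#' amplitude change of the unitary DFT pair under zero-padding.
#'
#' @param acq An [acquisition_params()] object.
#' @return Scalar gain.
#' @export
acquisition_gain <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  w <- gre_line_weights(acq$flip_angle, acq$matrix[1], acq$phase_order)
  w_dc <- w[floor(acq$matrix[1] / 2) + 1]
  w_dc * sqrt(prod(acq$matrix) / prod(acq$zero_pad_to))
}

#' Arterial reference SNR for simulated data
#'
#' Computes the calibration scalar `s_arterial` — the SNR a voxel fully
#' occupied by fresh arterial blood would have — from the known simulation
#' gains: arterial magnetization `m_a0` times [acquisition_gain()], divided
#' by the measured background noise sd of the reconstructed magnitude
#' images. With real data this constant must be measured or assumed; with
#' simulated data it is known exactly.
#'
#' @param acq An [acquisition_params()] object.
#' @param m_a0 Arterial magnetization scale used in the simulation.
#' @param sigma_hat Background noise sd of the reconstructed magnitude
#'   images (e.g. `tof_recon$sigma_hat`); use 1 for magnitude-domain
#'   (non-SNR) fitting.
#' @return A [calibration_params()] object.
#' @export
arterial_reference <- function(acq, m_a0 = 100, sigma_hat = 1) {
  calibration_params(m_a0 * acquisition_gain(acq) / sigma_hat)
}

#' Choose the k-space noise sd that yields a target image SNR
#'
#' Runs a noiseless simulation, measures the mean brain-region intensity of
#' the reconstructed dynamics, and returns the k-space complex noise sd for
#' which the mean image SNR (mean brain intensity over the uncorrected
#' magnitude background noise sd) equals `target_snr`. The background noise
#' sd of the reconstruction is `noise_sd * sqrt(prod(matrix)/prod(pad)) *
#' sqrt(2 - pi/2)` (Rayleigh magnitude background).
#'
#' @param spec A [brain_phantom_spec()].
#' @param acq An [acquisition_params()] object (its `noise_sd` is ignored).
#' @param target_snr Desired mean image SNR across dynamics. Default 10.
#' @return k-space noise sd (scalar).
#' @export
noise_for_target_snr <- function(spec, acq, target_snr = 10) {
  acq0 <- acq; acq0$noise_sd <- 0
  series <- simulate_tof_series(spec, acq0)
  rec <- reconstruct_series(series, noise_region = NULL)
  brain <- Reduce(`|`, phantom_masks(spec, dims = acq$zero_pad_to))
  mean_sig <- mean(vapply(seq_len(dim(rec$images)[3]),
                          function(i) mean(rec$images[, , i][brain]),
                          numeric(1)))
  pad_gain <- sqrt(prod(acq$matrix) / prod(acq$zero_pad_to))
  mean_sig / (target_snr * pad_gain * RAYLEIGH_STD_FACTOR)
}
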
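# One-compartment tracer-kinetic model of dissolved hyperpolarized 129Xe
# wash-in after a saturation pulse, plus RF/physics utilities.

#' Gyromagnetic ratio of xenon-129 (MHz/T)
#'
#' Reduced gyromagnetic ratio \eqn{\bar\gamma = \gamma/2\pi} of the
#' \eqn{^{129}}Xe nucleus, in MHz per tesla. The value is negative in sign
#' conventions that track precession direction; only the magnitude matters
#' for frequency calculations, so the magnitude is stored.
#'
#' @export
GYROMAG_XE129 <- 11.777

#' Gyromagnetic ratio of the proton (MHz/T)
#' @rdname GYROMAG_XE129
#' @export
GYROMAG_H1 <- 42.576

#' Tissue kinetic parameters for dissolved-xenon wash-in
#'
#' Bundles the physiological parameters of the one-compartment uptake model.
#' A voxel may contain several tissue compartments: `f`, `lam` and
#' `t1_tissue` may be vectors (one entry per compartment, recycled to a
#' common length), in which case the modeled voxel signal is the sum of
#' independent one-compartment solutions and fitted slopes estimate the sum
#' of the compartment perfusions.
#'
#' @param f Perfusion of each tissue compartment, in mL blood per mL tissue
#'   per minute. Must be >= 0.
#' @param lam Blood-tissue partition coefficient \eqn{\lambda} of dissolved
#'   xenon (dimensionless, > 0), per compartment.
#' @param t1_blood Longitudinal relaxation time of dissolved 129Xe in
#'   arterial blood, seconds (> 0). Shared by all compartments.
#' @param t1_tissue Longitudinal relaxation time of dissolved 129Xe in
#'   tissue, seconds (> 0), per compartment.
#' @param transit_delay Lung-to-voxel arterial transit time, seconds (>= 0).
#' @param m_a0 Arterial magnetization scale on arrival at the voxel
#'   (arbitrary units, >= 0).
#'
#' @return An object of class `kinetics_params`.
#' @seealso [analytic_uptake()], [linearized_uptake()], [kinetics_preset()]
#' @export
#' @examples
#' p <- kinetics_params(f = 0.55, lam = 0.9, t1_blood = 8, t1_tissue = 16)
#' analytic_uptake(p, tau = c(0, 1, 2))
kinetics_params <- function(f, lam = 0.9, t1_blood = 8, t1_tissue = 16,
                            transit_delay = 0, m_a0 = 100) {
  nc <- max(length(f), length(lam), length(t1_tissue))
  f <- rep_len(as.numeric(f), nc)
  lam <- rep_len(as.numeric(lam), nc)
  t1_tissue <- rep_len(as.numeric(t1_tissue), nc)
  t1_blood <- as.numeric(t1_blood)[1]
  transit_delay <- as.numeric(transit_delay)[1]
  m_a0 <- as.numeric(m_a0)[1]
  vals <- c(f, lam, t1_blood, t1_tissue, transit_delay, m_a0)
  if (any(!is.finite(vals)))
    stop("kinetics parameters must be finite", call. = FALSE)
  if (any(f < 0)) stop("perfusion `f` must be >= 0", call. = FALSE)
  if (any(lam <= 0)) stop("partition coefficient `lam` must be > 0", call. = FALSE)
  if (t1_blood <= 0 || any(t1_tissue <= 0))
    stop("relaxation times must be > 0", call. = FALSE)
  if (transit_delay < 0) stop("`transit_delay` must be >= 0", call. = FALSE)
  if (m_a0 < 0) stop("`m_a0` must be >= 0", call. = FALSE)
  structure(list(f = f, lam = lam, t1_blood = t1_blood,
                 t1_tissue = t1_tissue, transit_delay = transit_delay,
                 m_a0 = m_a0),
            class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("<kinetics_params> ", length(x$f), " compartment(s)\n", sep = "")
  cat("  f  =", paste(signif(x$f, 4), collapse = ", "),
      "mL/mL/min  (sum", signif(sum(x$f), 4), ")\n")
  cat("  lambda =", paste(signif(x$lam, 4), collapse = ", "),
      " T1 blood =", x$t1_blood, "s  T1 tissue =",
      paste(signif(x$t1_tissue, 4), collapse = ", "), "s\n")
  cat("  transit delay =", x$transit_delay, "s  m_a0 =", x$m_a0, "\n")
  invisible(x)
}

#' Literature-derived kinetic presets
#'
#' Named parameter sets for gray and white matter. These are conventional
#' literature values for cerebral perfusion and dissolved-xenon relaxation
#' (gray matter ~0.55 and white matter ~0.22 mL/mL/min, partition
#' coefficient 0.9, T1 of dissolved xenon ~8 s in blood, ~16 s in tissue);
#' they are defaults for simulation, not measured constants.
#'
#' @param name One of `"gray"`, `"white"`.
#' @param ... Overrides passed on to [kinetics_params()].
#' @return A `kinetics_params` object.
#' @export
kinetics_preset <- function(name = c("gray", "white"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    gray  = list(f = 0.55, lam = 0.9, t1_blood = 8, t1_tissue = 16),
    white = list(f = 0.22, lam = 0.9, t1_blood = 8, t1_tissue = 16))
  args <- utils::modifyList(defaults, list(...))
  do.call(kinetics_params, args)
}

#' Calibration between SNR slope and perfusion
#'
#' The fitted TOF slope (SNR per second) is proportional to the summed
#' perfusion of the voxel. The proportionality constant is the SNR that a
#' voxel completely replaced by fresh arterial xenon-laden blood would
#' produce, `s_arterial`; perfusion in mL/mL/min is then
#' `60 * slope / s_arterial`. The factor 60 converts the seconds-based
#' recovery-delay axis to the minutes-based perfusion unit.
#'
#' @param s_arterial SNR of a voxel fully occupied by fresh arterial blood
#'   (dimensionless, > 0). For simulated data it can be computed with
#'   [arterial_reference()].
#' @param time_unit_factor Seconds per minute; fixed at 60 and exposed only
#'   for documentation of the unit conversion.
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(s_arterial, time_unit_factor = 60) {
  s_arterial <- as.numeric(s_arterial)[1]
  if (!is.finite(s_arterial) || s_arterial <= 0)
    stop("`s_arterial` must be a finite positive number", call. = FALSE)
  structure(list(s_arterial = s_arterial,
                 time_unit_factor = time_unit_factor),
            class = "calibration_params")
}

#' TOF recovery curve
#'
#' A set of recovery delays and the signal measured at each delay, e.g. the
#' SNR of a flow-phantom image series as a function of the TOF delay.
#'
#' @param tau Recovery delays in seconds; strictly increasing, >= 0.
#' @param signal Signal (magnetization or SNR, arbitrary units) at each delay.
#' @return An object of class `uptake_curve` (also a data frame with columns
#'   `tau` and `signal`).
#' @export
uptake_curve <- function(tau, signal) {
  tau <- as.numeric(tau); signal <- as.numeric(signal)
  if (length(tau) != length(signal))
    stop("`tau` and `signal` must have equal length", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  if (length(tau) > 1 && any(diff(tau) <= 0))
    stop("`tau` must be strictly increasing", call. = FALSE)
  structure(data.frame(tau = tau, signal = signal),
            class = c("uptake_curve", "data.frame"))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)))
    stop("`tau` must be finite numeric", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be >= 0 (seconds)", call. = FALSE)
  as.numeric(tau)
}

# Threshold below which the uptake solution switches to its removable-
# singularity limit form (|k - 1/T1b| in s^-1).
.SINGULARITY_TOL <- 1e-10

#' Analytic one-compartment uptake signal
#'
#' Longitudinal magnetization of dissolved 129Xe in a voxel at time `tau`
#' after a saturation pulse. Fresh hyperpolarized xenon arrives with the
#' arterial inflow at rate `f` (converted internally to s^-1 as `f/60`),
#' decays in blood with time constant `t1_blood`, and, once in the voxel, is
#' cleared by venous outflow (`f/60/lam`) and tissue relaxation
#' (`1/t1_tissue`). The solution of
#' \deqn{dM/dt = (f/60)\, m_{a0}\, e^{-t/T_{1b}} - k M,\qquad
#'       k = (f/60)/\lambda + 1/T_{1t}}
#' with \eqn{M(0)=0} is
#' \deqn{M(\tau') = (f/60)\, m_{a0}\,
#'       \frac{e^{-\tau'/T_{1b}} - e^{-k\tau'}}{k - 1/T_{1b}}}
#' where \eqn{\tau' = \max(\tau - transit\_delay, 0)}. At the removable
#' singularity \eqn{k = 1/T_{1b}} the limit form
#' \eqn{(f/60) m_{a0} \tau' e^{-\tau'/T_{1b}}} is used. Multi-compartment
#' parameter sets return the sum of the per-compartment solutions.
#'
#' @param p A [kinetics_params()] object.
#' @param tau Recovery delay(s), seconds, >= 0.
#' @return Magnetization at each `tau` (arbitrary units, >= 0).
#' @seealso [linearized_uptake()] for the short-time linear approximation.
#' @export
analytic_uptake <- function(p, tau) {
  stopifnot(inherits(p, "kinetics_params"))
  tau <- check_tau(tau)
  tp <- pmax(tau - p$transit_delay, 0)
  a <- 1 / p$t1_blood
  total <- numeric(length(tau))
  for (c in seq_along(p$f)) {
    A <- (p$f[c] / 60) * p$m_a0
    k <- (p$f[c] / 60) / p$lam[c] + 1 / p$t1_tissue[c]
    if (abs(k - a) < .SINGULARITY_TOL) {
      total <- total + A * tp * exp(-a * tp)
    } else {
      total <- total + A * (exp(-a * tp) - exp(-k * tp)) / (k - a)
    }
  }
  total
}

#' Linearized short-time uptake signal
#'
#' Short-time approximation of [analytic_uptake()]: when relaxation in blood
#' dominates the polarization decay and the clearance rate
#' \eqn{f/(60\lambda) + 1/T_{1t}} is small, the signal grows linearly,
#' \deqn{M_{lin}(\tau) = \frac{\sum f}{60}\, m_{a0}\, \tau',}
#' so the fitted slope of signal versus delay is directly proportional to
#' the summed perfusion of the voxel. The approximation overestimates the
#' analytic signal (spins only lose polarization relative to the linear
#' influx), with relative error growing with `tau`.
#'
#' @inheritParams analytic_uptake
#' @return Linearized magnetization at each `tau`.
#' @export
linearized_uptake <- function(p, tau) {
  stopifnot(inherits(p, "kinetics_params"))
  tau <- check_tau(tau)
  (sum(p$f) / 60) * p$m_a0 * pmax(tau - p$transit_delay, 0)
}

#' Convert a TOF SNR slope to perfusion
#'
#' In the linear regime the slope of SNR versus recovery delay equals
#' `(sum(f)/60) * s_arterial`, where `s_arterial` is the SNR of a voxel
#' fully occupied by fresh arterial blood. Inverting,
#' \deqn{F = 60\,\mathrm{slope}/s_{arterial}}
#' gives perfusion in mL blood per mL tissue per minute.
#'
#' @param slope Fitted slope(s), SNR per second. May be a vector or matrix;
#'   negative values pass through unchanged (they are meaningful as fit
#'   noise and must not be clipped before map subtraction).
#' @param c A [calibration_params()] object.
#' @return Perfusion in mL/mL/min, same shape as `slope`.
#' @export
slope_to_perfusion <- function(slope, c) {
  stopifnot(inherits(c, "calibration_params"))
  c$time_unit_factor * slope / c$s_arterial
}

#' Inverse of [slope_to_perfusion()]
#' @inheritParams slope_to_perfusion
#' @param f Perfusion in mL/mL/min.
#' @return Slope in SNR per second.
#' @export
perfusion_to_slope <- function(f, c) {
  stopifnot(inherits(c, "calibration_params"))
  f * c$s_arterial / c$time_unit_factor
}

#' Bandwidth of a rectangular RF pulse
#'
#' For a rectangular (block) pulse the excitation bandwidth is the
#' reciprocal of the pulse duration: a 0.5 ms block pulse covers 2 kHz.
#'
#' @param duration Pulse duration in seconds (> 0).
#' @return Bandwidth in Hz.
#' @export
#' @examples
#' pulse_bandwidth(0.5e-3)  # 2000 Hz
pulse_bandwidth <- function(duration) {
  duration <- as.numeric(duration)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("`duration` must be > 0 seconds", call. = FALSE)
  1 / duration
}

#' Express a bandwidth in ppm of the carrier frequency
#'
#' @param bandwidth_hz Bandwidth in Hz.
#' @param carrier_mhz Carrier (Larmor) frequency in MHz.
#' @return Bandwidth in parts per million of the carrier.
#' @export
#' @examples
#' bandwidth_ppm(2000, larmor_frequency(3))  # ~56.6 ppm for 129Xe at 3 T
bandwidth_ppm <- function(bandwidth_hz, carrier_mhz) {
  if (any(carrier_mhz <= 0)) stop("`carrier_mhz` must be > 0", call. = FALSE)
  bandwidth_hz / carrier_mhz
}

#' Larmor frequency
#'
#' `f0 = gyromag * b0`, with the reduced gyromagnetic ratio in MHz/T.
#' Defaults to xenon-129 (11.777 MHz/T), giving 35.33 MHz at 3 T.
#'
#' @param b0 Static field strength in tesla (>= 0).
#' @param gyromag Reduced gyromagnetic ratio in MHz/T; see [GYROMAG_XE129].
#' @return Frequency in MHz.
#' @export
#' @examples
#' larmor_frequency(3)               # 35.33 MHz for 129Xe
#' larmor_frequency(3, GYROMAG_H1)   # 127.7 MHz for protons
larmor_frequency <- function(b0, gyromag = GYROMAG_XE129) {
  b0 <- as.numeric(b0)
  if (any(!is.finite(b0)) || any(b0 < 0))
    stop("`b0` must be >= 0 tesla", call. = FALSE)
  gyromag * b0
}

#' TOF recovery-delay presets
#'
#' Delay triplets used by the different in vivo protocols (axial and
#' sagittal perfusion mapping, visual and motor stimulation) plus a short
#' `"linear"` triplet lying inside the quasilinear regime of the uptake
#' curve, used for quantitative recovery simulations. The in vivo protocols
#' report slightly different triplets in different places; all variants are
#' shipped and none is canonical.
#'
#' @param name One of `"axial"`, `"sagittal"`, `"visual"`, `"motor"`,
#'   `"linear"`.
#' @return Numeric vector of three delays in seconds.
#' @export
tof_delay_preset <- function(name = c("axial", "sagittal", "visual",
                                      "motor", "linear")) {
  name <- match.arg(name)
  switch(name,
    axial    = c(2.5, 6.7, 7.1),
    sagittal = c(1.0, 6.5, 7.1),
    visual   = c(1.0, 6.5, 8.0),
    motor    = c(2.5, 6.8, 7.1),
    linear   = c(0.1, 0.2, 0.3))
}
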
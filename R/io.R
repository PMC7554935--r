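# NIfTI and sidecar round-tripping, configuration, axis conventions.
#
# Interchange format: NIfTI-1 volumes (x, y, dynamic) written as float64 so
# round trips are bit-exact, with a JSON sidecar named <stem>.json that
# carries the recovery delays, the seed and the acquisition parameters.
# Axis convention: the first array index runs left -> right, the second
# posterior -> anterior (anatomical view).

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a simulated TOF series to NIfTI plus a JSON sidecar
#'
#' The complex k-space stack is stored natively (NIfTI complex datatype);
#' the sidecar records the TOF delays, seed and acquisition parameters
#' needed to reconstruct and fit the series.
#'
#' @param series A `tof_series` object from [simulate_tof_series()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, a list with the image and sidecar paths.
#' @export
write_tof_series <- function(series, path) {
  stopifnot(inherits(series, "tof_series"))
  img <- RNifti::asNifti(series$kspace)
  img$descrip <- "xetof kspace series; units=a.u."
  RNifti::writeNifti(img, path)
  acq <- series$acq
  sidecar <- list(kind = "kspace", tof_delays = acq$tof_delays,
                  seed = acq$seed, flip_angle = acq$flip_angle,
                  matrix = acq$matrix, zero_pad_to = acq$zero_pad_to,
                  noise_sd = acq$noise_sd, phase_order = acq$phase_order,
                  package_version = as.character(utils::packageVersion("xetof")))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(image = path, sidecar = sidecar_path(path)))
}

#' Read a TOF series written by [write_tof_series()]
#'
#' @param path Path to the `.nii` file; the sidecar `<stem>.json` must be
#'   alongside it.
#' @return A `tof_series` object (with `spec` and `truth` set to `NULL` for
#'   externally supplied data).
#' @export
read_tof_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing sidecar (", side, "): recovery delays unknown",
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$tof_delays))
    stop("sidecar lacks `tof_delays`", call. = FALSE)
  arr <- tryCatch(
    suppressWarnings(as.array(RNifti::readNifti(path))),
    error = function(e) stop("cannot read NIfTI volume ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(dim(arr)) != 3)
    stop("expected a 3-D (x, y, dynamic) volume", call. = FALSE)
  if (dim(arr)[3] != length(meta$tof_delays))
    stop("number of dynamics does not match sidecar delays", call. = FALSE)
  acq <- acquisition_params(
    tof_delays = meta$tof_delays,
    flip_angle = meta$flip_angle %||% 20,
    matrix = dim(arr)[1:2],
    zero_pad_to = meta$zero_pad_to %||% c(32, 32),
    noise_sd = meta$noise_sd %||% 0,
    phase_order = meta$phase_order %||% "linear",
    seed = meta$seed)
  structure(list(kspace = arr, tof_delays = acq$tof_delays, acq = acq,
                 spec = NULL, truth = NULL),
            class = "tof_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 2-D parametric map as NIfTI
#'
#' @param map Numeric matrix (slope, perfusion or HDR layer).
#' @param path Output `.nii` path.
#' @param units Unit string recorded in the NIfTI `descrip` header field.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, units = "a.u.") {
  img <- RNifti::asNifti(as.matrix(map), datatype = "double")
  img$descrip <- paste0("units=", units)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parametric map written by [write_map()]
#' @param path `.nii` path.
#' @return Numeric matrix with attribute `units`.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  m <- as.array(img)
  dim(m) <- utils::head(dim(m), 2)
  units <- sub("^units=", "", RNifti::niftiHeader(img)$descrip)
  attr(m, "units") <- units
  m
}

#' Flip a radiological-view image to anatomical view
#'
#' Reverses the left-right (first) axis. Applied to every slice of a 3-D
#' stack. Applying it twice is the identity.
#'
#' @param img Matrix or 3-D array.
#' @return Flipped array of the same shape.
#' @export
radiological_to_anatomical <- function(img) {
  if (length(dim(img)) == 2) img[rev(seq_len(nrow(img))), , drop = FALSE]
  else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
}

# ---- configuration ---------------------------------------------------------

CONFIG_SCHEMA <- list(
  phantom = c("grid", "fov", "gray_f", "white_f", "activation_frac",
              "activation"),
  acquisition = c("tof_delays", "flip_angle", "matrix", "zero_pad_to",
                  "noise_sd", "phase_order", "seed", "target_snr",
                  "delay_preset"),
  kinetics = c("f", "lambda", "t1_blood_s", "t1_tissue_s",
               "transit_delay_s", "m_a0", "s_arterial"),
  calibration = c("s_arterial"),
  flow = c("flow_rates", "tube_id", "sensitive_length", "profile",
           "s_max", "noise_sd", "tau_start", "tau_end", "tau_step",
           "window"),
  regions = c("noise", "roi"),
  mask = c("snr_threshold"),
  seed = NULL, output = NULL)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  x
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON mappings with sections `phantom`,
#' `acquisition`, `kinetics`, `calibration`, `flow`, `regions`, `mask`,
#' and scalar `seed`. Unknown keys anywhere are rejected before any
#' computation. All sections are optional; defaults reproduce the in vivo
#' axial protocol (20 x 20 matrix, flip angle 20 degrees, delays
#' 2.5/6.7/7.1 s, zero-padding to 32 x 32).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a list already
#'   in memory.
#' @return Validated configuration list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg, names(CONFIG_SCHEMA), "top level")
  for (sec in names(CONFIG_SCHEMA)) {
    if (!is.null(cfg[[sec]]) && !is.null(CONFIG_SCHEMA[[sec]]))
      check_keys(cfg[[sec]], CONFIG_SCHEMA[[sec]], sec)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Build kinetics parameters from a config section
#'
#' Honors the documented config keys `f`, `lambda`, `t1_blood_s`,
#' `t1_tissue_s`, `transit_delay_s`, `m_a0` (and ignores `s_arterial`,
#' which belongs to calibration).
#'
#' @param cfg Named list (the `kinetics` config section).
#' @return A [kinetics_params()] object.
#' @export
kinetics_from_config <- function(cfg) {
  cfg <- check_keys(cfg, CONFIG_SCHEMA$kinetics, "kinetics")
  kinetics_params(
    f = cfg$f %||% 0.55,
    lam = cfg$lambda %||% 0.9,
    t1_blood = cfg$t1_blood_s %||% 8,
    t1_tissue = cfg$t1_tissue_s %||% 16,
    transit_delay = cfg$transit_delay_s %||% 0,
    m_a0 = cfg$m_a0 %||% 100)
}

acquisition_from_config <- function(cfg, seed = NULL) {
  cfg <- if (is.null(cfg)) list() else cfg
  delays <- cfg$tof_delays %||%
    tof_delay_preset(cfg$delay_preset %||% "axial")
  acquisition_params(
    tof_delays = delays,
    flip_angle = cfg$flip_angle %||% 20,
    matrix = cfg$matrix %||% c(20, 20),
    zero_pad_to = cfg$zero_pad_to %||% c(32, 32),
    noise_sd = cfg$noise_sd %||% 0,
    phase_order = cfg$phase_order %||% "linear",
    seed = seed %||% cfg$seed)
}

phantom_from_config <- function(cfg) {
  cfg <- if (is.null(cfg)) list() else cfg
  grid <- cfg$grid %||% c(20, 20)
  fov <- cfg$fov %||% c(250, 250)
  gray_f <- cfg$gray_f %||% 0.55
  white_f <- cfg$white_f %||% 0.22
  grid <- as.integer(rep_len(grid, 2))
  ctr <- (grid - 1) / 2
  inner <- list(center = ctr, semi_axes = c(3.2, 4.0) * grid / 20)
  spec <- brain_phantom_spec(grid, fov, list(
    phantom_compartment("gray", ctr, c(6.5, 7.5) * grid / 20,
                        kinetics_preset("gray", f = gray_f), hole = inner),
    phantom_compartment("white", inner$center, inner$semi_axes,
                        kinetics_preset("white", f = white_f))))
  if (isTRUE(cfg$activation) || !is.null(cfg$activation_frac))
    spec <- add_activation(spec, frac = cfg$activation_frac %||% 0.2)
  spec
}
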
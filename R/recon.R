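# k-space handling and magnitude reconstruction.
#
# Conventions, declared once and pinned by tests:
#   * k-space grids are stored DC-centered: the DC sample sits at 0-based
#     index floor(N/2) along each axis (R index floor(N/2)+1).
#   * The DFT is unitary (1/sqrt(N) per transform), so Parseval holds as
#     sum(|image|^2) == sum(|kspace|^2).
#   * Zero-padding inserts zeros symmetrically around the centered spectrum,
#     with any odd extra row/column on the high-frequency side.

fftshift_idx <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2)))

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

#' Unitary centered 2-D discrete Fourier transform
#'
#' `forward_dft2()` maps an image to a DC-centered k-space grid;
#' `inverse_dft2()` maps a DC-centered k-space grid back to a complex image.
#' Both are unitary (scaled by `1/sqrt(N)`), so energy is preserved.
#'
#' @param x A numeric or complex matrix.
#' @return A complex matrix of the same dimensions.
#' @keywords internal
forward_dft2 <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname forward_dft2
#' @keywords internal
inverse_dft2 <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Zero-pad a k-space grid to a larger matrix
#'
#' Embeds a DC-centered k-space grid in a larger all-zero grid so that the
#' DC samples coincide (0-based index `floor(N/2)` on each axis). All
#' original samples are preserved unchanged; the added samples are exactly
#' zero. Reconstruction of the padded grid yields a sinc-interpolated image
#' on a finer pixel grid over the same field of view.
#'
#' @param k Complex (or numeric) matrix of k-space samples, DC-centered.
#' @param target Integer vector of length 2: output dimensions, each >= the
#'   corresponding input dimension.
#' @return Complex matrix with `dim == target`.
#' @seealso [crop_kspace()], [reconstruct_magnitude()]
#' @export
zero_pad_kspace <- function(k, target = c(32, 32)) {
  k <- as.matrix(k)
  target <- as.integer(rep_len(target, 2))
  if (any(target < dim(k)))
    stop("`target` must be >= input dimensions", call. = FALSE)
  out <- matrix(as.complex(0), target[1], target[2])
  off <- floor(target / 2) - floor(dim(k) / 2)
  out[off[1] + seq_len(nrow(k)), off[2] + seq_len(ncol(k))] <- k
  out
}

#' Crop a k-space grid back to a smaller centered matrix
#'
#' Exact inverse of [zero_pad_kspace()]: extracts the centered `target`
#' block, so `crop_kspace(zero_pad_kspace(k, n), dim(k))` is the identity.
#'
#' @param k Complex matrix, DC-centered.
#' @param target Output dimensions, each <= the input dimension.
#' @return Complex matrix with `dim == target`.
#' @export
crop_kspace <- function(k, target) {
  k <- as.matrix(k)
  target <- as.integer(rep_len(target, 2))
  if (any(target > dim(k)))
    stop("`target` must be <= input dimensions", call. = FALSE)
  off <- floor(dim(k) / 2) - floor(target / 2)
  k[off[1] + seq_len(target[1]), off[2] + seq_len(target[2]), drop = FALSE]
}

#' Reconstruct a magnitude image from k-space
#'
#' Applies the centered unitary inverse 2-D DFT and takes the modulus.
#' Under the unitary normalization Parseval's identity holds:
#' `sum(image^2) == sum(Mod(k)^2)`.
#'
#' @param k Complex matrix of k-space samples, DC-centered.
#' @return Nonnegative numeric matrix of the same dimensions.
#' @export
reconstruct_magnitude <- function(k) {
  k <- as.matrix(k)
  if (any(!is.finite(Re(k))) || any(!is.finite(Im(k))))
    stop("k-space contains non-finite values", call. = FALSE)
  Mod(inverse_dft2(k))
}

#' Rectangular pixel region
#'
#' Half-open rectangle in 0-based image coordinates: pixels with first index
#' in `[x0, x1)` and second index in `[y0, y1)`. The first index is the row
#' (matrix) index. A string form `"x0:x1,y0:y1"` is accepted by
#' [parse_region()].
#'
#' @param x0,x1,y0,y1 Integer bounds, `0 <= x0 < x1`, `0 <= y0 < y1`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(x0, x1, y0, y1) {
  v <- as.integer(c(x0, x1, y0, y1))
  if (any(is.na(v)) || v[1] < 0 || v[3] < 0 || v[2] <= v[1] || v[4] <= v[3])
    stop("invalid region bounds (need 0 <= x0 < x1, 0 <= y0 < y1)",
         call. = FALSE)
  structure(list(x0 = v[1], x1 = v[2], y0 = v[3], y1 = v[4]),
            class = "region_spec")
}

#' @rdname region_spec
#' @param text Region as `"x0:x1,y0:y1"`.
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^(\\d+):(\\d+),(\\d+):(\\d+)$", text))[[1]]
  if (length(m) != 5)
    stop("region must be of the form 'x0:x1,y0:y1'", call. = FALSE)
  region_spec(m[2], m[3], m[4], m[5])
}

region_values <- function(img, region) {
  if (inherits(region, "region_spec")) {
    if (region$x1 > nrow(img) || region$y1 > ncol(img))
      stop("region exceeds image bounds", call. = FALSE)
    img[(region$x0 + 1):region$x1, (region$y0 + 1):region$y1]
  } else if (is.logical(region)) {
    if (!identical(dim(region), dim(img)))
      stop("mask region must match image dimensions", call. = FALSE)
    if (!any(region)) stop("empty mask region", call. = FALSE)
    img[region]
  } else stop("region must be a region_spec or a logical mask", call. = FALSE)
}

region_overlaps <- function(a, b, dim) {
  ma <- matrix(FALSE, dim[1], dim[2]); mb <- ma
  if (inherits(a, "region_spec")) ma[(a$x0 + 1):a$x1, (a$y0 + 1):a$y1] <- TRUE else ma <- a
  if (inherits(b, "region_spec")) mb[(b$x0 + 1):b$x1, (b$y0 + 1):b$y1] <- TRUE else mb <- b
  any(ma & mb)
}

# Mean of a Rayleigh-to-Gaussian std correction: the std of the magnitude of
# complex Gaussian noise (per-component sd sigma) is sigma*sqrt(2 - pi/2).
RAYLEIGH_STD_FACTOR <- sqrt(2 - pi / 2)

#' Noise standard deviation of a background region
#'
#' Standard deviation of the magnitude pixels in a noise-only region. By
#' default no Rayleigh correction is applied (the plain standard deviation
#' of the magnitude data is used); set `rayleigh_correct = TRUE` to divide
#' by `sqrt(2 - pi/2)` and recover the per-component complex noise sd.
#'
#' @param img Magnitude image (nonnegative matrix).
#' @param region A [region_spec()] or logical mask of background pixels.
#' @param rayleigh_correct Apply the Rayleigh bias factor? Default `FALSE`.
#' @return Estimated noise standard deviation (scalar, > 0).
#' @export
noise_sigma <- function(img, region, rayleigh_correct = FALSE) {
  s <- stats::sd(region_values(img, region))
  if (rayleigh_correct) s <- s / RAYLEIGH_STD_FACTOR
  s
}

#' Pixel-wise SNR map
#'
#' Divides each pixel of a magnitude image by the standard deviation of a
#' background noise region. The map is invariant under global intensity
#' scaling of the image.
#'
#' @inheritParams noise_sigma
#' @param min_sigma Relative floor: a noise sd below
#'   `min_sigma * max(img)` raises a degenerate-noise error instead of
#'   propagating near-infinite values.
#' @return SNR map, same dimensions as `img`.
#' @export
snr_map <- function(img, region, rayleigh_correct = FALSE,
                    min_sigma = 1e-12) {
  sigma <- noise_sigma(img, region, rayleigh_correct)
  if (!is.finite(sigma) || sigma <= min_sigma * max(abs(img), 1))
    stop("degenerate noise region: standard deviation is zero or near zero",
         call. = FALSE)
  img / sigma
}

#' Scalar image SNR
#'
#' Ratio of the mean pixel intensity in a signal region of interest to the
#' standard deviation of a background region.
#'
#' @param img Magnitude image.
#' @param roi Signal region ([region_spec()] or logical mask).
#' @param background Background noise region, disjoint from `roi`.
#' @inheritParams snr_map
#' @return Scalar SNR.
#' @export
image_snr <- function(img, roi, background, rayleigh_correct = FALSE,
                      min_sigma = 1e-12) {
  if (region_overlaps(roi, background, dim(img)))
    warning("ROI and background regions overlap", call. = FALSE)
  sigma <- noise_sigma(img, background, rayleigh_correct)
  if (!is.finite(sigma) || sigma <= min_sigma * max(abs(img), 1))
    stop("degenerate background region: standard deviation is zero",
         call. = FALSE)
  mean(region_values(img, roi)) / sigma
}

#' Reconstruct a simulated TOF k-space series to images and SNR maps
#'
#' Runs the image-processing chain on a [simulate_tof_series()] result:
#' zero-pads each dynamic's k-space to the reconstruction matrix, applies
#' the inverse DFT, takes magnitudes, and (if a noise region is given)
#' divides by the background noise standard deviation pooled across
#' dynamics to form SNR maps.
#'
#' @param series A `tof_series` object (k-space stack plus delays).
#' @param noise_region Background [region_spec()] in reconstructed-image
#'   coordinates, or `NULL` to skip SNR mapping. The default `"edge"`
#'   uses the first three image rows across the full width — background for
#'   any phantom whose object keeps a margin from the field-of-view edge —
#'   which gives the noise-sd estimate enough samples that the SNR
#'   normalization is stable across repeated acquisitions.
#' @param rayleigh_correct Passed to [noise_sigma()].
#' @return A list of class `tof_recon` with elements `images` (3-D array,
#'   x by y by dynamic), `snr` (same shape, or `NULL`), `sigma_hat`
#'   (pooled background noise sd), `tof_delays`, and `zero_pad_to`.
#' @export
reconstruct_series <- function(series, noise_region = "edge",
                               rayleigh_correct = FALSE) {
  stopifnot(inherits(series, "tof_series"))
  target <- series$acq$zero_pad_to
  if (identical(noise_region, "edge"))
    noise_region <- region_spec(0, 3, 0, target[2])
  nd <- length(series$tof_delays)
  images <- array(0, c(target, nd))
  for (i in seq_len(nd)) {
    images[, , i] <- reconstruct_magnitude(
      zero_pad_kspace(series$kspace[, , i], target))
  }
  snr <- NULL; sigma <- NA_real_
  if (!is.null(noise_region)) {
    sig_i <- vapply(seq_len(nd), function(i)
      noise_sigma(images[, , i], noise_region, rayleigh_correct), numeric(1))
    sigma <- sqrt(mean(sig_i^2))  # pooled across dynamics
    if (sigma <= 1e-12 * max(images, 1))
      stop("degenerate noise region in reconstructed series", call. = FALSE)
    snr <- images / sigma
  }
  structure(list(images = images, snr = snr, sigma_hat = sigma,
                 tof_delays = series$tof_delays, zero_pad_to = target,
                 noise_region = noise_region, acq = series$acq),
            class = "tof_recon")
}
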
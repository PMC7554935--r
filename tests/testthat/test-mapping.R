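make_linear_stack <- function(a, b, tau, dims = c(6, 6)) {
  arr <- array(0, c(dims, length(tau)))
  for (i in seq_along(tau)) arr[, , i] <- a * tau[i] + b
  arr
}

test_that("pixel-wise fit recovers exact linear data to machine precision", {
  tau <- c(2.5, 6.7, 7.1)
  withr::with_seed(41, { a <- matrix(rnorm(36), 6, 6); b <- matrix(rnorm(36), 6, 6) })
  arr <- array(0, c(6, 6, 3))
  for (i in 1:3) arr[, , i] <- a * tau[i] + b
  sm <- fit_slope_map(arr, tau)
  expect_equal(sm$slope, a, tolerance = 1e-12)
  expect_equal(sm$intercept, b, tolerance = 1e-12)
  expect_true(all(abs(sm$r_squared - 1) < 1e-12))
  # property: any 3 distinct delays
  withr::with_seed(42, {
    for (rep in 1:10) {
      tau_r <- sort(runif(3, 0, 10) + c(0, 1, 2))
      arr_r <- make_linear_stack(a, b, tau_r)
      sm_r <- fit_slope_map(arr_r, tau_r)
      expect_equal(sm_r$slope, a, tolerance = 1e-10)
      expect_equal(sm_r$intercept, b, tolerance = 1e-10)
    }
  })
})

test_that("constant pixels give zero slope and undefined R-squared", {
  arr <- array(5, c(4, 4, 3))
  sm <- fit_slope_map(arr, c(1, 2, 3))
  expect_true(all(sm$slope == 0))
  expect_true(all(is.na(sm$r_squared)))
})

test_that("degenerate fit inputs raise errors", {
  arr <- array(1, c(4, 4, 1))
  expect_error(fit_slope_map(arr, 1), "at least 2")
  arr2 <- array(1, c(4, 4, 3))
  expect_error(fit_slope_map(arr2, c(2, 2, 2)), "increasing|equal")
})

test_that("through-origin option and masking behave as documented", {
  tau <- c(1, 2, 4)
  arr <- make_linear_stack(matrix(2, 3, 3), matrix(0, 3, 3), tau, c(3, 3))
  sm <- fit_slope_map(arr, tau, through_origin = TRUE)
  expect_equal(sm$slope, matrix(2, 3, 3), tolerance = 1e-12)
  expect_true(all(sm$intercept == 0))
  mask <- matrix(rep(c(TRUE, FALSE), length.out = 9), 3, 3)
  sm2 <- fit_slope_map(arr, tau, mask = mask)
  expect_true(all(is.na(sm2$slope[!mask])))
  expect_true(all(is.finite(sm2$slope[mask])))
})

test_that("noiseless simulated series reproduces the kinetic slope scale", {
  # compartment-mean fitted slope must equal (sum f / 60) * s_arterial,
  # with s_arterial the arterial amplitude under the acquisition gain
  spec <- brain_phantom_spec()
  acq <- acquisition_params(tof_delays = tof_delay_preset("linear"),
                            flip_angle = 20, noise_sd = 0)
  rec <- reconstruct_series(simulate_tof_series(spec, acq),
                            noise_region = NULL)
  sm <- fit_slope_map(rec$images, rec$tof_delays)
  cal <- arterial_reference(acq, m_a0 = 100, sigma_hat = 1)
  masks <- phantom_masks(spec, dims = c(32, 32), erode_px = 1.5)
  means <- compartment_means(sm$slope, masks)
  expected <- c(gray = 0.55, white = 0.22) / 60 * cal$s_arterial
  expect_equal(means, expected, tolerance = 0.02)
})

test_that("perfusion map is the calibrated rescaling of the slope map", {
  tau <- c(1, 2, 3)
  arr <- make_linear_stack(matrix(0.5, 4, 4), matrix(1, 4, 4), tau, c(4, 4))
  sm <- fit_slope_map(arr, tau)
  pm <- make_perfusion_map(sm, calibration_params(60))
  expect_equal(pm$f_sum, matrix(0.5, 4, 4), tolerance = 1e-12)
  expect_false(any(pm$negative))
  # zero slope -> zero perfusion
  sm0 <- fit_slope_map(array(3, c(4, 4, 3)), tau)
  expect_true(all(make_perfusion_map(sm0, calibration_params(60))$f_sum == 0))
  # scaling s_arterial by c scales the map by 1/c, exactly
  pm2 <- make_perfusion_map(sm, calibration_params(120))
  expect_equal(pm2$f_sum, pm$f_sum / 2)
  # negative slopes pass through but are flagged
  smn <- fit_slope_map(make_linear_stack(matrix(-0.2, 4, 4),
                                         matrix(5, 4, 4), tau, c(4, 4)), tau)
  pmn <- make_perfusion_map(smn, calibration_params(60))
  expect_true(all(pmn$f_sum < 0))
  expect_true(all(pmn$negative))
})

test_that("HDR subtraction is exact and antisymmetric", {
  tau <- c(1, 2, 3)
  withr::with_seed(43, {
    a1 <- matrix(rnorm(16), 4, 4); a2 <- matrix(rnorm(16), 4, 4)
  })
  s1 <- fit_slope_map(make_linear_stack(a1, a1 * 0, tau, c(4, 4)), tau)
  s2 <- fit_slope_map(make_linear_stack(a2, a2 * 0, tau, c(4, 4)), tau)
  expect_true(all(hdr_map(s1, s1)$delta_slope == 0))
  expect_identical(hdr_map(s1, s2)$delta_slope, -hdr_map(s2, s1)$delta_slope)
  expect_equal(hdr_map(s1, s2)$delta_slope, a1 - a2, tolerance = 1e-12)
  s3 <- fit_slope_map(array(1, c(5, 5, 3)), tau)
  expect_error(hdr_map(s1, s3), "different shapes")
})

test_that("HDR of two noise realizations stays within propagated error", {
  # same phantom simulated twice with independent noise: the gray-matter
  # mean of the difference map should be within 3 standard errors of zero
  # in at least 95% of seeds. Fits are done on the magnitude images: the
  # residual-based slope SE models the pixel noise, not the common-mode
  # normalization term an SNR division would add (that term is why
  # threshold_hdr() centers on the median).
  spec <- brain_phantom_spec()
  acq0 <- acquisition_params(tof_delays = tof_delay_preset("linear"))
  nsd <- noise_for_target_snr(spec, acq0, 10)
  gm <- phantom_masks(spec, dims = c(32, 32), erode_px = 1.5)$gray
  ok <- vapply(1:100, function(s) {
    mk <- function(seed) {
      acq <- acquisition_params(tof_delays = tof_delay_preset("linear"),
                                noise_sd = nsd, seed = seed)
      rec <- reconstruct_series(simulate_tof_series(spec, acq),
                                noise_region = NULL)
      fit_slope_map(rec$images, rec$tof_delays)
    }
    h <- hdr_map(mk(2 * s), mk(2 * s + 1))
    dmean <- mean(h$delta_slope[gm])
    se <- sqrt(sum(h$se[gm]^2)) / sum(gm)
    abs(dmean) < 3 * se
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("thresholded HDR localizes a simulated activation blob", {
  base <- brain_phantom_spec()
  act <- add_activation(base, frac = 0.2)
  acq0 <- acquisition_params(tof_delays = tof_delay_preset("linear"))
  nsd <- noise_for_target_snr(base, acq0, 60)  # powered detection setting
  brain <- Reduce(`|`, phantom_masks(base, dims = c(32, 32)))
  truth <- activation_mask(act, dims = c(32, 32)) & brain
  for (s in 1:3) {
    sim <- function(spc, seed) {
      acq <- acquisition_params(tof_delays = tof_delay_preset("linear"),
                                noise_sd = nsd, seed = seed)
      reconstruct_series(simulate_tof_series(spc, acq))
    }
    rb <- sim(base, s); rt <- sim(act, s + 500)
    mask <- default_fit_mask(rb) & default_fit_mask(rt)
    h <- hdr_map(fit_slope_map(rt, mask = mask),
                 fit_slope_map(rb, mask = mask))
    pred <- threshold_hdr(h, z = 2) & h$delta_slope > 0
    expect_gt(dice_coefficient(pred, truth), 0.5)
  }
})

test_that("dice coefficient matches its definition", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  expect_equal(dice_coefficient(a, b), 2 * 1 / (2 + 2))
})

test_that("flow-slope correlation is exact for proportional slopes", {
  flows <- c(5, 6, 7, 10)
  curves <- lapply(flows, function(q)
    simulate_flow_curve(flow_phantom_spec(q, profile = "plug",
                                          noise_sd = 0)))
  res <- flow_slope_correlation(flows, curves)
  expect_equal(res$r, 1.0)
  # negating the slopes (e.g. a decreasing signal convention) flips the sign
  neg <- lapply(curves, function(cv) uptake_curve(cv$tau, -cv$signal))
  expect_equal(flow_slope_correlation(flows, neg)$r, -1.0)
  # reversing the flow labels against the same curves anti-correlates
  expect_lt(flow_slope_correlation(rev(flows), curves)$r, -0.85)
})

test_that("correlation rejects degenerate designs", {
  flows <- c(5, 6)
  cv <- simulate_flow_curve(flow_phantom_spec(5, noise_sd = 0))
  expect_error(flow_slope_correlation(flows, list(cv, cv)), "at least 3")
  flat <- uptake_curve(seq(0.2, 2, by = 0.1), rep(1, 19))
  expect_error(flow_slope_correlation(c(5, 6, 7), list(flat, flat, flat)),
               "degenerate")
})

test_that("noisy flow simulation preserves a strong flow-slope correlation", {
  flows <- c(5, 6, 7, 10)
  stats <- vapply(1:15, function(s) {
    curves <- lapply(seq_along(flows), function(i)
      simulate_flow_curve(flow_phantom_spec(flows[i]), seed = 100 * s + i))
    res <- flow_slope_correlation(flows, curves)
    c(res$r, res$p_value)
  }, numeric(2))
  expect_gt(median(stats[1, ]), 0.9)
  expect_lt(median(stats[2, ]), 0.05)
})
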
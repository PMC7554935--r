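# geometry helper used in several places: sensitive length giving V = 0.5 mL
length_for_half_ml <- 500 / (pi * (3.175 / 2)^2)

test_that("flow phantom spec validates and exposes its volume", {
  expect_error(flow_phantom_spec(0), "> 0")
  expect_error(flow_phantom_spec(5, tube_id = -1), "> 0")
  expect_error(flow_phantom_spec(5, noise_sd = -0.1), ">= 0")
  spec <- flow_phantom_spec(5, sensitive_length = length_for_half_ml)
  expect_equal(flow_phantom_volume(spec), 0.5)
})

test_that("plug-flow curve is the closed-form front fill", {
  spec <- flow_phantom_spec(5, sensitive_length = length_for_half_ml,
                            profile = "plug", s_max = 1, noise_sd = 0)
  # Q = 5 mL/min = 1/12 mL/s, V = 0.5 mL, tau = 0.7 s
  expect_equal(flow_fill_fraction(spec, 0.7), (5 / 60) * 0.7 / 0.5)
  expect_equal(flow_fill_fraction(spec, 0.7), 0.11667, tolerance = 1e-4)
  # plateau at and beyond the fill time V/Q
  fill_t <- 0.5 / (5 / 60)
  expect_equal(flow_fill_fraction(spec, c(fill_t, fill_t + 1, 99)),
               c(1, 1, 1))
  # noiseless curve starts at zero and is nondecreasing
  cv <- simulate_flow_curve(spec, tau_grid = seq(0, 10, by = 0.25))
  expect_equal(cv$signal[1], 0)
  expect_true(all(diff(cv$signal) >= 0))
})

test_that("laminar curve matches the radial quadrature oracle", {
  for (q in c(5, 10)) for (tau in c(0.3, 0.7, 1.5, 3)) {
    spec <- flow_phantom_spec(q, sensitive_length = length_for_half_ml,
                              profile = "laminar", noise_sd = 0)
    ref <- laminar_quadrature(q, 3.175, length_for_half_ml, tau)
    expect_equal(flow_fill_fraction(spec, tau), ref, tolerance = 1e-3)
  }
})

test_that("laminar and plug profiles agree early and share the plateau", {
  plug <- flow_phantom_spec(6, profile = "plug", noise_sd = 0)
  lam <- flow_phantom_spec(6, profile = "laminar", noise_sd = 0)
  tau <- seq(0.05, 30, by = 0.05)
  fp <- flow_fill_fraction(plug, tau); fl <- flow_fill_fraction(lam, tau)
  expect_true(all(fl <= fp + 1e-12))          # front fill is the upper envelope
  early <- tau <= 0.5 * flow_phantom_volume(plug) / (6 / 60)
  expect_equal(fl[early], fp[early])          # identical before the fastest
                                              # spins exit (u <= 1)
  expect_equal(max(fp), 1)                    # plug fills completely
  expect_gt(flow_fill_fraction(lam, 200), 0.995)  # laminar tail ~ 1 - 1/(2u)
})

test_that("plug slope over the quasilinear window is Q*s_max/(60V) exactly", {
  flows <- c(5, 6, 7, 10)
  curves <- lapply(flows, function(q)
    simulate_flow_curve(flow_phantom_spec(q, profile = "plug", noise_sd = 0)))
  res <- flow_slope_correlation(flows, curves, window = c(0.2, 0.7))
  V <- flow_phantom_volume(flow_phantom_spec(5, profile = "plug"))
  expect_equal(res$slopes, flows / (60 * V))
  expect_equal(res$r, 1.0)
})

test_that("flow-curve noise is seeded and reproducible", {
  spec <- flow_phantom_spec(7)
  a <- simulate_flow_curve(spec, seed = 3)
  b <- simulate_flow_curve(spec, seed = 3)
  d <- simulate_flow_curve(spec, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$signal, d$signal))
})

test_that("brain phantom rasterizes compartment perfusion exactly", {
  ph <- make_brain_phantom(brain_phantom_spec())
  expect_equal(sort(unique(as.vector(ph$f_map))), c(0, 0.22, 0.55))
  expect_false(any(ph$masks$gray & ph$masks$white))
  expect_equal(ph$f_map[1, 1], 0)  # background corner
  # a single compartment covering the whole grid gives a constant image
  allspec <- brain_phantom_spec(compartments = list(
    phantom_compartment("all", c(9.5, 9.5), c(100, 100),
                        kinetics_preset("gray"))))
  expect_true(all(make_brain_phantom(allspec)$f_map == 0.55))
})

test_that("overlapping compartments are rejected", {
  ctr <- c(9.5, 9.5)
  expect_error(brain_phantom_spec(compartments = list(
    phantom_compartment("a", ctr, c(5, 5), kinetics_preset("gray")),
    phantom_compartment("b", ctr, c(3, 3), kinetics_preset("white")))),
    "overlap")
})

test_that("acquisition parameters validate their invariants", {
  expect_error(acquisition_params(tof_delays = c(2, 1, 3)), "increasing")
  expect_error(acquisition_params(flip_angle = 0), "flip_angle")
  expect_error(acquisition_params(flip_angle = 95), "flip_angle")
  expect_error(acquisition_params(zero_pad_to = c(10, 10)), "zero_pad_to")
  expect_error(acquisition_params(noise_sd = -1), "noise_sd")
})

test_that("depletion weights implement sin(a)cos(a)^(j-1) per excitation", {
  w90 <- gre_line_weights(90, 20, "linear")
  expect_equal(w90[1], 1)               # first line: full consumption
  expect_equal(w90[2], 0)               # nothing left for the second
  a <- 20 * pi / 180
  w20 <- gre_line_weights(20, 20, "linear")
  expect_equal(w20[10], sin(a) * cos(a)^9)
  expect_equal(w20, sin(a) * cos(a)^(0:19))
  # centric ordering spends the freshest magnetization on the DC line
  wc <- gre_line_weights(20, 20, "centric")
  expect_equal(wc[11], sin(a))          # DC row (0-based index 10)
  expect_equal(which.max(wc), 11)
  expect_equal(sort(wc, decreasing = TRUE), sort(w20, decreasing = TRUE))
})

test_that("simulated series is deterministic under a fixed seed", {
  spec <- brain_phantom_spec()
  acq <- acquisition_params(tof_delays = c(0.5, 1, 2), noise_sd = 0.01,
                            seed = 99)
  s1 <- simulate_tof_series(spec, acq)
  s2 <- simulate_tof_series(spec, acq)
  expect_identical(s1$kspace, s2$kspace)
  acq$seed <- 100L
  expect_false(identical(simulate_tof_series(spec, acq)$kspace, s1$kspace))
})

test_that("zero perfusion and zero noise give an all-zero k-space", {
  spec <- brain_phantom_spec(compartments = list(
    phantom_compartment("dead", c(9.5, 9.5), c(6, 6),
                        kinetics_params(f = 0))))
  ser <- simulate_tof_series(spec, acquisition_params(noise_sd = 0))
  expect_true(all(Mod(ser$kspace) == 0))
})

test_that("noiseless low-flip reconstruction is proportional to the ideal image", {
  spec <- brain_phantom_spec()
  acq <- acquisition_params(tof_delays = c(0.1, 0.2, 0.3), flip_angle = 1,
                            noise_sd = 0, zero_pad_to = c(20, 20))
  rec <- reconstruct_series(simulate_tof_series(spec, acq),
                            noise_region = NULL)
  ideal <- analytic_uptake(kinetics_preset("gray"), 0.3)
  ph <- make_brain_phantom(spec)
  ratio <- rec$images[, , 3][ph$masks$gray] / ideal
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.01)
  expect_equal(mean(ratio), acquisition_gain(acq), tolerance = 1e-3)
})

test_that("activation splits keep masks disjoint and scale perfusion by 1+frac", {
  base <- brain_phantom_spec()
  act <- add_activation(base, frac = 0.2)
  ph_b <- make_brain_phantom(base); ph_a <- make_brain_phantom(act)
  blob <- activation_mask(act)
  expect_equal(ph_a$f_map[!blob], ph_b$f_map[!blob])
  inside <- blob & ph_b$f_map > 0
  expect_equal(ph_a$f_map[inside], 1.2 * ph_b$f_map[inside])
  cover <- Reduce(`+`, ph_a$masks)
  expect_true(all(cover <= 1))
})

test_that("noise calibration hits the target mean image SNR", {
  spec <- brain_phantom_spec()
  acq <- acquisition_params(tof_delays = tof_delay_preset("axial"))
  nsd <- noise_for_target_snr(spec, acq, target_snr = 10)
  brain <- Reduce(`|`, phantom_masks(spec, dims = c(32, 32)))
  snrs <- vapply(1:6, function(s) {
    acq_s <- acquisition_params(tof_delays = tof_delay_preset("axial"),
                                noise_sd = nsd, seed = s)
    rec <- reconstruct_series(simulate_tof_series(spec, acq_s))
    mean(vapply(1:3, function(i)
      image_snr(rec$images[, , i], brain, rec$noise_region), numeric(1)))
  }, numeric(1))
  # the in vivo regime: mean perfusion-weighted map SNR around 10
  expect_true(all(snrs > 9 & snrs < 12))
})
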
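# Independent numerical oracles, deliberately implemented with different
# algorithms than the package code they check.

# 4th-order Runge-Kutta integration of the uptake ODE
#   dM/dt = (f/60) * m_a0 * exp(-t/T1b) - k * M,  k = (f/60)/lam + 1/T1t,
# vectorized over parameter draws (each argument a vector).
rk4_uptake <- function(f, lam, t1_blood, t1_tissue, m_a0, tau, dt = 1e-3) {
  a <- 1 / t1_blood
  k <- (f / 60) / lam + 1 / t1_tissue
  A <- (f / 60) * m_a0
  n <- max(length(f), length(tau))
  M <- numeric(n)
  tmax <- max(tau)
  steps <- ceiling(tmax / dt)
  rhs <- function(t, M) A * exp(-a * t) - k * M
  t <- 0
  done <- rep(FALSE, n)
  out <- numeric(n)
  for (i in seq_len(steps)) {
    hit <- !done & tau <= t + dt / 2
    out[hit] <- M[hit]; done[done | hit] <- TRUE
    k1 <- rhs(t, M)
    k2 <- rhs(t + dt / 2, M + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, M + dt / 2 * k2)
    k4 <- rhs(t + dt, M + dt * k3)
    M <- M + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  out[!done] <- M[!done]
  out
}

# Trapezoid quadrature of the laminar fill fraction:
#   (1/(pi R^2 L)) * int_0^R min(v(r) tau, L) 2 pi r dr,
#   v(r) = 2 vbar (1 - (r/R)^2), vbar = Q/(pi R^2).
laminar_quadrature <- function(flow_ml_min, tube_id_mm, length_mm, tau_s,
                               n = 1e4) {
  R <- tube_id_mm / 2
  Q <- flow_ml_min * 1000 / 60                 # mm^3/s
  vbar <- Q / (pi * R^2)                       # mm/s
  r <- seq(0, R, length.out = n + 1)
  v <- 2 * vbar * (1 - (r / R)^2)
  integrand <- pmin(v * tau_s, length_mm) * 2 * pi * r
  int <- sum((integrand[-1] + integrand[-(n + 1)]) / 2) * (R / n)
  int / (pi * R^2 * length_mm)
}

# Naive O(N^2 M^2) evaluation of the trigonometric interpolant defined by a
# DC-centered k-space grid at arbitrary (possibly fractional) 0-based image
# coordinates, under the package's unitary DFT convention.
direct_dft_eval <- function(kspace, x, y) {
  n <- dim(kspace)
  kx <- seq_len(n[1]) - 1 - floor(n[1] / 2)
  ky <- seq_len(n[2]) - 1 - floor(n[2] / 2)
  # image coordinates are measured relative to the centered origin
  cx <- x - floor(n[1] / 2)
  cy <- y - floor(n[2] / 2)
  out <- matrix(0 + 0i, length(x), length(y))
  for (ix in seq_along(x)) for (iy in seq_along(y)) {
    ph <- exp(2i * pi * (outer(kx * cx[ix] / n[1], ky * cy[iy] / n[2], `+`)))
    out[ix, iy] <- sum(kspace * ph) / sqrt(prod(n))
  }
  out
}
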
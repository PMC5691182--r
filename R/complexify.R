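# Complexified dynamics: extending real blow-up ODEs/PDEs to complex
# dependent variables regularizes collapse — a minuscule imaginary part
# steers the orbit around infinity and back.

#' Planar vector field of the complexified power ODE
#'
#' Real/imaginary decomposition of `dz/dt = z^power` for `z = x + iy`:
#' for power 2, `dx/dt = x^2 - y^2`, `dy/dt = 2xy`; for power 3,
#' `dx/dt = x^3 - 3xy^2`, `dy/dt = 3x^2 y - y^3`. The real axis is an
#' invariant subspace carrying the original collapsing dynamics.
#'
#' @param x,y Real and imaginary parts of the state.
#' @param power 2 or 3.
#' @return Numeric vector `c(dx/dt, dy/dt)`.
#' @export
complex_rhs <- function(x, y, power = 2) {
  if (!(power %in% c(2, 3))) stop("unsupported power: ", power)
  z <- complex(real = x, imaginary = y)^power
  c(Re(z), Im(z))
}

#' Closed-form orbit of the complexified quadratic ODE
#'
#' Exact solution of `dz/dt = z^2` from `z(0) = x0 + i y0` (obtained from
#' `1/z = 1/z(0) - t`), written out in real coordinates. With `y0 = 0` it
#' reduces to the real collapse path `x = x0/(1 - x0 t)`, continued through
#' infinity; any nonzero `y0` turns the orbit into a circle through the
#' origin and collapse is avoided.
#'
#' @param x0,y0 Initial real and imaginary parts (not both zero).
#' @param t Time(s).
#' @return Data frame with columns `t`, `x`, `y`.
#' @export
orbit_closed_form <- function(x0, y0, t) {
  if (x0 == 0 && y0 == 0) stop("initial condition must be nonzero")
  m <- x0^2 + y0^2
  den <- (x0 - t * m)^2 + y0^2
  data.frame(t = t,
             x = (x0 * m - t * m^2) / den,
             y = y0 * m / den)
}

#' Conserved quantity of the complexified quadratic dynamics
#'
#' `E = (x^2 + y^2) / y` is invariant along orbits of `dz/dt = z^2`; the
#' level sets are the circles `x^2 + (y - R)^2 = R^2` with `R = E/2`.
#' As `y0 -> 0`, `|E| -> Inf` and the circles flatten onto the real axis,
#' retrieving the collapsing real dynamics as a limiting case.
#'
#' @param x,y State coordinates (`y != 0`).
#' @return `E` (same length as `x`).
#' @export
invariant_E <- function(x, y) {
  if (any(y == 0)) stop("E is undefined on the real axis (y = 0)")
  (x^2 + y^2) / y
}

#' Circle radius of a complexified quadratic orbit
#' @param x0,y0 Initial condition (`y0 != 0`).
#' @return `R` with `R^2 = (x0^2 + y0^2)^2 / (4 y0^2)`.
#' @export
orbit_radius <- function(x0, y0) {
  if (y0 == 0) stop("real-axis orbits have infinite radius")
  (x0^2 + y0^2) / (2 * abs(y0))
}

#' Integrate a complexified power ODE as a real planar system
#'
#' @param x0,y0 Initial condition.
#' @param t_out Output times.
#' @param power 2 or 3.
#' @param rtol,atol Solver tolerances.
#' @return Data frame `t, x, y` (plus `E` for power 2).
#' @export
integrate_complex_orbit <- function(x0, y0, t_out, power = 2,
                                    rtol = 1e-11, atol = 1e-12) {
  fun <- function(t, s, p) list(complex_rhs(s[1], s[2], power))
  out <- deSolve::lsoda(c(x0, y0), t_out, fun, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 1e5)
  df <- data.frame(t = out[, 1], x = out[, 2], y = out[, 3])
  if (power == 2 && y0 != 0) df$E <- invariant_E(df$x, df$y)
  df
}

#' Transit time along a radius-R arc between infinities
#'
#' Time for the complexified dynamics to move along a radial contour of
#' radius `R`: `T = integral over C of dz / z^power`, taken over the
#' quarter circle from the real to the imaginary axis for power 3, and the
#' semicircle from the positive to the negative real axis for power 2.
#' The products `T R^2` (power 3) and `T R` (power 2) are constant, so the
#' transit time between infinities vanishes as `R -> Inf`.
#'
#' @param R Contour radius.
#' @param power 2 or 3.
#' @return Real part of the numerically evaluated contour integral.
#' @export
transit_time <- function(R, power = 3) {
  if (!(power %in% c(2, 3))) stop("unsupported power: ", power)
  phi_max <- if (power == 3) pi / 2 else pi
  integrand <- function(phi) {
    z <- R * exp(1i * phi)
    1i * z / z^power
  }
  re <- stats::integrate(function(p) Re(integrand(p)), 0, phi_max,
                         rel.tol = 1e-12, abs.tol = 1e-14)$value
  re
}

# --- spectral utilities (even, pi-periodic fields on [0, pi]) -------------

# Collocation nodes x_j = j*pi/N, j = 0..N. Fields satisfying Neumann
# conditions extend evenly to a smooth 2pi-periodic function, so Fourier
# differentiation of the even extension is spectrally accurate.
cosine_grid <- function(N) seq(0, pi, length.out = N + 1L)

even_extend <- function(u) c(u, rev(u[2:(length(u) - 1L)]))

spectral_deriv <- function(u, order) {
  n1 <- length(u)            # N + 1 samples on [0, pi]
  M <- 2L * (n1 - 1L)        # extended length
  ue <- even_extend(u)
  k <- c(0:(M / 2), (-M / 2 + 1):(-1))   # wavenumbers for period 2*pi
  uh <- stats::fft(ue)
  if (order == 1) {
    uh <- uh * (1i * k)
    uh[M / 2 + 1] <- 0       # Nyquist mode has no well-defined odd derivative
  } else {
    uh <- uh * (1i * k)^order
  }
  Re(stats::fft(uh, inverse = TRUE) / M)[seq_len(n1)]
}

#' Evolve the complexified level-set PDE
#'
#' Method-of-lines integration of the real/imaginary pair obtained from the
#' focusing equation `w_t = w_xx - (2/w) w_x^2 + w + r w^2` under
#' `w = a + ib`:
#' `a_t = a_xx - 2a (a_x^2 - b_x^2)/(a^2+b^2) - 4b a_x b_x/(a^2+b^2) + a + r(a^2 - b^2)`,
#' `b_t = b_xx + 2b (a_x^2 - b_x^2)/(a^2+b^2) - 4a a_x b_x/(a^2+b^2) + b + 2 r a b`,
#' with Neumann conditions on `[0, pi]`. A small imaginary seed makes the
#' solution turn around instead of collapsing, re-emerging on the other
#' side with its imaginary part practically extinguished.
#'
#' Spatial derivatives are evaluated by Fourier-cosine spectral collocation
#' (the fields are even and analytic, so the spatial error is negligible
#' against the time-integration tolerance); see the methods vignette.
#'
#' @param a0,b0 Initial profiles sampled on the uniform grid `seq(0, pi, length.out = N + 1)` with `N + 1`
#'   points (`a0^2 + b0^2 > 0` everywhere).
#' @param r Level-set offset of the underlying equation.
#' @param t_grid Output times (starting at 0).
#' @param rtol,atol Time-integration tolerances.
#' @return A list of class `complex_field` with `x`, `t`, and matrices `a`,
#'   `b` (rows = times). Fails with a division-singular error if
#'   `a^2 + b^2` reaches zero at a node (the solution passed through w = 0).
#' @export
complex_pde_evolve <- function(a0, b0, r, t_grid, rtol = 1e-9, atol = 1e-11) {
  stopifnot(length(a0) == length(b0))
  if (any(a0^2 + b0^2 <= 0)) stop("a^2 + b^2 must be positive initially")
  n1 <- length(a0)
  fun <- function(t, s, p) {
    a <- s[seq_len(n1)]; b <- s[n1 + seq_len(n1)]
    m2 <- a^2 + b^2
    if (any(m2 < 1e-28))
      stop("division singular: a^2 + b^2 reached zero (solution passed through w = 0)")
    ax <- spectral_deriv(a, 1); bx <- spectral_deriv(b, 1)
    axx <- spectral_deriv(a, 2); bxx <- spectral_deriv(b, 2)
    q <- (ax^2 - bx^2) / m2
    cr <- ax * bx / m2
    list(c(axx - 2 * a * q - 4 * b * cr + a + r * (a^2 - b^2),
           bxx + 2 * b * q - 4 * a * cr + b + 2 * r * a * b))
  }
  out <- deSolve::ode(c(a0, b0), t_grid, fun, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol, maxsteps = 1e6)
  structure(list(x = cosine_grid(n1 - 1L), t = out[, 1],
                 a = out[, 1 + seq_len(n1), drop = FALSE],
                 b = out[, 1 + n1 + seq_len(n1), drop = FALSE], r = r),
            class = "complex_field")
}

#' Analytic solution of the complexified level-set PDE
#'
#' The good variable `v = c + id` obeys the linear complex equation
#' `v_t = v_xx - v - r`, solvable exactly by cosine-eigenfunction expansion
#' on `[0, pi]`; the bad field follows from `w = 1/v`, i.e.
#' `a = c/(c^2 + d^2)`, `b = -d/(c^2 + d^2)`. This reconstruction is the
#' independent oracle for [complex_pde_evolve()].
#'
#' @param c0,d0 Initial profiles of the good variable on the same uniform grid as [complex_pde_evolve()].
#' @param r Constant forcing level.
#' @param t Evaluation time (scalar).
#' @return List with vectors `a`, `b`, `c`, `d` at time `t`. Requesting a
#'   point where `c^2 + d^2 = 0` is a singular-evaluation error.
#' @export
complex_pde_oracle <- function(c0, d0, r, t) {
  n1 <- length(c0)
  ct <- heat_decay_modes(c0 + r, t) - r
  dt_ <- heat_decay_modes(d0, t)
  m2 <- ct^2 + dt_^2
  if (any(m2 == 0)) stop("singular evaluation: c^2 + d^2 = 0 at a grid point")
  list(a = ct / m2, b = -dt_ / m2, c = ct, d = dt_)
}

# exact solution of phi_t = phi_xx - phi with Neumann BC via DCT modes
heat_decay_modes <- function(phi0, t) {
  n1 <- length(phi0)
  M <- 2L * (n1 - 1L)
  ph <- stats::fft(even_extend(phi0))
  k <- c(0:(M / 2), (-M / 2 + 1):(-1))
  ph <- ph * exp(-(1 + k^2) * t)
  Re(stats::fft(ph, inverse = TRUE) / M)[seq_len(n1)]
}

#' Reconstruct the bad complex field from the good one (and back)
#'
#' `w = a + ib = 1/v = 1/(c + id)` gives `a = c/(c^2+d^2)`,
#' `b = -d/(c^2+d^2)`; the map is an involution up to sign bookkeeping, so
#' the same formula inverts it.
#'
#' @param c,d Real and imaginary parts of the field to invert.
#' @return List with components `a` and `b`.
#' @export
reciprocal_field <- function(c, d) {
  m2 <- c^2 + d^2
  if (any(m2 == 0)) stop("singular evaluation: field vanishes at a grid point")
  list(a = c / m2, b = -d / m2)
}
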
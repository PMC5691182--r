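# Compactification maps: blow-up orbits sent to bounded coordinates so that
# infinity becomes a regular point (circle), level set (sphere) or pole
# (Riemann sphere).

#' Circle compactification for power-law blow-up
#'
#' Maps an orbit diverging like `x ~ (t* - t)^(-a)` to the unit circle via
#' `X = ((t*-t)^a - x) / ((t*-t)^a + x)`, `Y = 2 / ((t*-t)^a + x)`.
#' With `a = 1` this is the compactification of the quadratic blow-up; the
#' squared variant (`x` replaced by `x^2`, `a = 1`) handles the cubic case
#' whose transformed variable would otherwise leave the real axis.
#'
#' @param x State value(s) (use `x^2` yourself for the squared variant).
#' @param t Time(s).
#' @param t_star Blow-up time.
#' @param a Self-similarity power (default 1).
#' @return A data frame with columns `t`, `X`, `Y` on the unit circle and
#'   `theta = atan2(Y, X)` in `(-pi, pi]`.
#' @export
circle_map_power <- function(x, t, t_star, a = 1) {
  den <- (t_star - t)^a + x
  if (any(den == 0)) stop("map singular: (t*-t)^a + x vanishes")
  X <- ((t_star - t)^a - x) / den
  Y <- 2 / den
  data.frame(t = t, X = X, Y = Y, theta = atan2(Y, X))
}

#' Circle compactification for exponential (linear-ODE) dynamics
#'
#' For `dx/dt = +/- x` with solution `x = exp(+/-(t - t*))` the circle
#' variables reduce to `X = tanh(-/+(t - t*))`, `Y = sech(t - t*)`: the
#' orbit is a realization of `tanh^2 + sech^2 = 1`, putting the
#' infinite-time limits on the same footing as all other points.
#'
#' @param x State value(s).
#' @param t Time(s).
#' @param t_star Reference time at which `x = 1`.
#' @param sign +1 for growth (`dx/dt = x`), -1 for decay.
#' @return Data frame `t, X, Y, theta`.
#' @export
circle_map_linear <- function(x, t, t_star, sign = 1) {
  den <- exp(sign * (t_star - t)) + x
  if (any(den <= 0)) stop("map singular: nonpositive denominator")
  X <- (exp(sign * (t_star - t)) - x) / den
  Y <- 2 / den
  data.frame(t = t, X = X, Y = Y, theta = atan2(Y, X))
}

#' Circle compactification for the asymptotically self-similar example
#'
#' Same construction as [circle_map_power()] with `a = 1` but with
#' `t* - t` replaced by `(exp(2(t*-t)) - 1)/2`, which is exact for
#' `dx/dt = 2x + x^2`: near `t*` it Taylor-reduces to the power map, far
#' from `t*` the exponential (linear-term) contribution dominates.
#'
#' @inheritParams circle_map_power
#' @return Data frame `t, X, Y, theta`.
#' @export
circle_map_asymptotic <- function(x, t, t_star) {
  surrogate <- expm1(2 * (t_star - t)) / 2
  den <- surrogate + x
  if (any(den == 0)) stop("map singular: surrogate + x vanishes")
  X <- (surrogate - x) / den
  Y <- 2 / den
  data.frame(t = t, X = X, Y = Y, theta = atan2(Y, X))
}

#' Sphere compactification of a self-similar PDE profile
#'
#' For a self-similar profile `u = f(xi) / (t*-t)^r_exp` with `|f| <= 1`
#' (pre-normalize by `max |f|`), builds the unit-sphere coordinates whose
#' squares sum to one:
#' `X' = g * ((t*-t)^r - u) / ((t*-t)^r + u)`, `Y' = g * 2 sqrt(|f|) /
#' ((t*-t)^r + u)`, `Z' = f`, with `g^2 = 1 - f^2`. Infinity becomes a
#' regular level set crossed by the dynamics on the sphere.
#'
#' @param u Profile values.
#' @param t Time (scalar).
#' @param t_star Blow-up time.
#' @param r_exp Amplitude self-similarity power.
#' @param f Normalized profile values (same length as `u`), `|f| <= 1`.
#' @return Data frame with columns `Xp`, `Yp`, `Zp` on the unit sphere.
#' @export
pde_compactify <- function(u, t, t_star, r_exp, f) {
  if (length(f) != length(u)) stop("u and f must have equal length")
  if (any(abs(f) > 1 + 1e-12))
    stop("|f| > 1: normalize the profile by max|f| first")
  f <- pmin(1, pmax(-1, f))
  g <- sqrt(1 - f^2)
  pw <- (t_star - t)^r_exp
  den <- pw + u
  if (any(den == 0)) stop("map singular: (t*-t)^r + u vanishes")
  Xp <- g * (pw - u) / den
  Yp <- g * 2 * sqrt(abs(f)) / den
  Zp <- f
  data.frame(Xp = Xp, Yp = Yp, Zp = Zp)
}

#' Inverse stereographic projection onto the Riemann sphere
#'
#' Maps a point of the complex plane `(x, y)` to the unit sphere:
#' `X = 2x / (x^2+y^2+1)`, `Y = 2y / (x^2+y^2+1)`,
#' `Z = (x^2+y^2-1) / (x^2+y^2+1)`. All points with `x^2 + y^2 -> Inf` are
#' identified with the north pole `(0, 0, 1)`; the real axis maps to a
#' great circle.
#'
#' @param x,y Real and imaginary parts (vectors).
#' @return Data frame with columns `X`, `Y`, `Z`.
#' @export
riemann_project <- function(x, y) {
  den <- x^2 + y^2 + 1
  data.frame(X = 2 * x / den, Y = 2 * y / den, Z = (x^2 + y^2 - 1) / den)
}

#' Invert the Riemann-sphere projection
#'
#' Standard stereographic projection from the north pole back to the plane;
#' exact inverse of [riemann_project()] away from `Z = 1`.
#' @param X,Y,Z Sphere coordinates.
#' @return Data frame with columns `x`, `y`.
#' @export
riemann_unproject <- function(X, Y, Z) {
  data.frame(x = X / (1 - Z), y = Y / (1 - Z))
}
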
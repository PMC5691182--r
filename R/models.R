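# Catalog of worked blow-up examples, each paired with its closed-form
# oracle where one exists, plus a fixture generator for estimator tests.

#' Look up a worked example model
#'
#' Returns a fully parameterized catalog entry: the [ode_problem()] (or PDE
#' configuration), a closed-form oracle `oracle(t)` where available, and a
#' `collapse_time(x0)` map.
#'
#' @param name One of `"power_p2"` (`dx/dt = x^2`), `"power_p3"`
#'   (`dx/dt = x^3`), `"power_general"` (`dx/dt = x^p`, integer `p` in 2..4),
#'   `"linear_plus"`/`"linear_minus"` (`dx/dt = +/- x`), `"asymptotic_quad"`
#'   (`dx/dt = 2x + x^2`, asymptotically self-similar), `"qif_1d"`
#'   (quadratic integrate-and-fire `dv/dt = I + v^2`), `"qif_2d"` (2D
#'   quadratic IF, both variables blow up), `"quartic_2d"` (quartic IF,
#'   only the voltage blows up), `"heat_level_set"` (the level-set PDE
#'   test case).
#' @param x0 Initial state used to pin the oracle/collapse time (scalar
#'   models; default 1).
#' @param p Power for `"power_general"` (integer 2, 3 or 4; fractional
#'   powers are rejected because uniqueness of the continuation is not
#'   guaranteed for non-integer powers).
#' @param I,b Model constants for the integrate-and-fire entries.
#'
#' @return A list of class `model_entry` with elements `name`, `problem`,
#'   `oracle` (function of `t`, or `NULL`), `collapse_time` (function of the
#'   initial state, or `NULL`) and `reference` (plain-language tag).
#' @examples
#' m <- get_model("power_p2")
#' m$collapse_time(1)        # t* = 1/x(0) = 1
#' m$oracle(2)               # continuation: -1
#' @export
get_model <- function(name, x0 = 1, p = NULL, I = 1, b = 1) {
  entry <- switch(
    name,
    power_p2 = power_model(2, x0),
    power_p3 = power_model(3, x0),
    power_general = {
      if (is.null(p)) stop("power_general requires p")
      if (abs(p - round(p)) > 1e-12 || !(round(p) %in% 2:4))
        stop("only integer powers p in {2, 3, 4} are registered; fractional ",
             "powers raise uniqueness issues for the continuation and are rejected")
      power_model(round(p), x0)
    },
    linear_plus = linear_model(+1, x0),
    linear_minus = linear_model(-1, x0),
    asymptotic_quad = asymptotic_quad_model(x0),
    qif_1d = qif1_model(x0, I),
    qif_2d = list(
      name = "qif_2d",
      problem = ode_problem(function(x, pm) c(pm$I + x[1]^2 - x[2],
                                              pm$b * x[1] - x[2]),
                            dim = 2, params = list(I = I, b = b),
                            known_power = 2, blowing = 1L, name = "qif_2d"),
      oracle = NULL, collapse_time = NULL,
      reference = "2D quadratic integrate-and-fire (simultaneous blow-up)"),
    quartic_2d = list(
      name = "quartic_2d",
      problem = ode_problem(function(x, pm) c(pm$I + x[1]^4 + 2 * x[1] - x[2],
                                              pm$b * x[1] - x[2]),
                            dim = 2, params = list(I = I, b = b),
                            known_power = 4, blowing = 1L, name = "quartic_2d"),
      oracle = NULL, collapse_time = NULL,
      reference = "2D quartic integrate-and-fire (voltage-only blow-up)"),
    heat_level_set = heat_level_set_model(),
    stop("unknown model: ", name)
  )
  class(entry) <- "model_entry"
  entry
}

power_model <- function(p, x0) {
  stopifnot(x0 > 0)
  t_star <- x0^(1 - p) / (p - 1)
  oracle <- function(t) {
    s <- t_star - t
    if (p == 2) return(1 / s)
    # p = 3 (and general odd p): continuation leaves the real axis; the
    # +i-infinity reentry branch is the default
    if (is.complex(s) || s > 0) return(as.complex(((p - 1) * s)^(1 / (1 - p))))
    if (s == 0) stop("oracle is singular at t = t*")
    if (p == 3) return(complex(real = 0, imaginary = 1 / sqrt(2 * (t - t_star))))
    stop("real continuation undefined for p = ", p, " past t*")
  }
  list(name = paste0("power_p", p),
       problem = ode_problem(function(x, pm) x^p, params = list(p = p),
                             known_power = p, name = paste0("power_p", p)),
       oracle = function(t) {
         if (!is.complex(t) && t == t_star) stop("oracle is singular at t = t*")
         oracle(t)
       },
       collapse_time = function(x0) x0^(1 - p) / (p - 1),
       reference = paste0("pure power-law blow-up, p = ", p))
}

linear_model <- function(sgn, x0) {
  stopifnot(x0 > 0)
  t_star <- -sgn * log(x0)   # so that x(t) = exp(sgn * (t - t*))
  list(name = if (sgn > 0) "linear_plus" else "linear_minus",
       problem = ode_problem(function(x, pm) pm$sgn * x, params = list(sgn = sgn),
                             name = "linear"),
       oracle = function(t) exp(sgn * (t - t_star)),
       collapse_time = NULL, t_star = t_star,
       reference = "linear growth/decay (exponential, infinite-time)")
}

asymptotic_quad_model <- function(x0) {
  stopifnot(x0 > 0)
  t_star <- -0.5 * log(x0 / (x0 + 2))
  list(name = "asymptotic_quad",
       problem = ode_problem(function(x, pm) 2 * x + x^2, known_power = 2,
                             name = "asymptotic_quad"),
       oracle = function(t) {
         if (is.complex(t))
           return(2 * exp(2 * (t - t_star)) / (1 - exp(2 * (t - t_star))))
         if (t == t_star) stop("oracle is singular at t = t*")
         # 1 - e^{2(t-t*)} via expm1 to avoid cancellation near t*
         2 * exp(2 * (t - t_star)) / (-expm1(2 * (t - t_star)))
       },
       collapse_time = function(x0) -0.5 * log(x0 / (x0 + 2)),
       reference = "asymptotically self-similar blow-up with an offending linear term")
}

qif1_model <- function(x0, I) {
  cc <- atan(x0 / sqrt(I)) / sqrt(I)
  t_star <- (pi / 2) / sqrt(I) - cc
  list(name = "qif_1d",
       problem = ode_problem(function(x, pm) pm$I + x^2, params = list(I = I),
                             known_power = 2, name = "qif_1d"),
       oracle = function(t) {
         if (!is.complex(t) && abs(cos(sqrt(I) * (cc + t))) < 1e-300)
           stop("oracle is singular at a collapse time")
         sqrt(I) * tan(sqrt(I) * (cc + t))
       },
       collapse_time = function(x0) (pi / 2 - atan(x0 / sqrt(I))) / sqrt(I),
       t_star = t_star,
       reference = "quadratic integrate-and-fire neuron (periodic blow-up)")
}

heat_level_set_model <- function(a = 0.4, cc = 1.5, r = 1) {
  u_fun <- function(x, t) a * exp(-5 * t) * cos(2 * x) + cc * exp(-t)
  first_touch <- function() {
    stats::uniroot(function(t) cc * exp(-t) - a * exp(-5 * t) - r,
                   c(0, 10), tol = 1e-14)$root
  }
  list(name = "heat_level_set",
       problem = list(kind = "pde", a = a, c = cc, r = r,
                      domain = c(0, pi),
                      u0 = function(x) a * cos(2 * x) + cc),
       oracle = u_fun,
       collapse_time = function(...) first_touch(),
       reference = "linear heat-decay equation observed through the 1/(u - r) level-set lens")
}

#' @export
print.model_entry <- function(x, ...) {
  cat("<model_entry '", x$name, "'> ", x$reference, "\n", sep = "")
  invisible(x)
}

#' List the registered models
#' @return Character vector of catalog names accepted by [get_model()].
#' @export
list_models <- function() {
  c("power_p2", "power_p3", "power_general", "linear_plus", "linear_minus",
    "asymptotic_quad", "qif_1d", "qif_2d", "quartic_2d", "heat_level_set")
}

#' Evaluate a model's closed-form oracle
#'
#' @param entry A `model_entry` from [get_model()].
#' @param t Time (scalar or vector). Evaluation exactly at a collapse time
#'   is a singular-evaluation error.
#' @return State value(s); complex past a crossing whose continuation leaves
#'   the real axis.
#' @export
oracle_eval <- function(entry, t) {
  if (is.null(entry$oracle)) stop("model '", entry$name, "' has no closed-form oracle")
  if (length(t) > 1) return(sapply(t, function(tt) entry$oracle(tt)))
  entry$oracle(t)
}

#' Sample a fixture trajectory from a model oracle
#'
#' Draws `(t, x, dx/dt)` samples from the closed form, with optional
#' multiplicative lognormal noise (applied independently to states and
#' derivatives) for exercising the exponent estimator.
#'
#' @param entry A `model_entry` with an oracle.
#' @param t_grid Times to sample; must not cross the collapse time.
#' @param noise_level Standard deviation of the log-noise (0 = exact).
#' @param seed Integer seed used when `noise_level > 0`.
#' @return A list of class `blowup_fixture` with `times`, `states`,
#'   `derivatives`, `noise_level`, `seed`.
#' @export
make_fixture <- function(entry, t_grid, noise_level = 0, seed = 1L) {
  ts <- entry$t_star %||% environment(entry$oracle)$t_star
  if (!is.null(ts) && !is.null(entry$collapse_time)) {
    if (any(t_grid == ts)) stop("t_grid touches the collapse time")
    if (min(t_grid) < ts && max(t_grid) > ts)
      stop("t_grid crosses the collapse time t* = ", signif(ts, 8))
  }
  states <- vapply(t_grid, function(tt) Re(entry$oracle(tt)), numeric(1))
  derivs <- vapply(states, function(x) entry$problem$rhs(x, entry$problem$params)[1],
                   numeric(1))
  if (noise_level > 0) {
    set.seed(seed)
    states <- states * exp(stats::rnorm(length(states), 0, noise_level))
    derivs <- derivs * exp(stats::rnorm(length(derivs), 0, noise_level))
  }
  structure(list(times = t_grid, states = states, derivatives = derivs,
                 noise_level = noise_level, seed = seed),
            class = "blowup_fixture")
}

# --- small power-series (Laurent) utilities -------------------------------

# reciprocal of a power series q (q[1] = constant term, must be nonzero)
series_recip <- function(q, n) {
  r <- numeric(n)
  r[1] <- 1 / q[1]
  for (k in seq_len(n - 1)) {
    acc <- 0
    for (j in seq_len(k)) if (j + 1 <= length(q)) acc <- acc + q[j + 1] * r[k - j + 1]
    r[k + 1] <- -acc / q[1]
  }
  r
}

#' Laurent coefficients of the asymptotically self-similar solution
#'
#' Expands the closed-form solution of `dx/dt = 2x + x^2` about its blow-up
#' time in powers of `s = t* - t`, by exact series arithmetic (series
#' reciprocal of `e^{2s} - 1`). The leading terms are
#' `1/s - 1 + s/3 - s^3/45 + ...`, exhibiting the offending lower-order
#' contributions explicitly.
#'
#' @param order Highest power of `s` to return.
#' @return Named numeric vector of coefficients for `s^-1, s^0, ..., s^order`.
#' @examples
#' asymptotic_quad_series(3)[["s^3"]] * 45   # = -1
#' @export
asymptotic_quad_series <- function(order = 3) {
  n <- order + 2L
  # e^{2s} - 1 = s * q(s),  q_k = 2^{k+1} / (k+1)!
  q <- 2^(seq_len(n)) / factorial(seq_len(n))
  r <- series_recip(q, n)
  coefs <- 2 * r
  names(coefs) <- paste0("s^", seq_len(n) - 2L)
  names(coefs)[1] <- "s^-1"
  coefs
}
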
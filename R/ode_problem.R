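#' Define an autonomous ODE problem
#'
#' Container for a (possibly vector-valued, possibly complex) autonomous
#' right-hand side `dx/dt = f(x)` together with the metadata the blow-up
#' machinery needs: which component is expected to diverge and, optionally,
#' a known nonlinearity power `p` (so that near blow-up `f(x) ~ x^p` in the
#' diverging component).
#'
#' @param rhs Function `rhs(x, params)` returning the derivative, same length
#'   as `x`. Must be evaluable at any finite state; for continuation through
#'   complex reentry branches it should also accept complex `x` (all
#'   polynomial right-hand sides do).
#' @param dim Positive integer, number of state components.
#' @param params Named list of real constants (e.g. `I`, `b`).
#' @param known_power Optional hint for the blow-up power `p > 1`. When given
#'   it is used to validate the fitted exponent, never to replace detection.
#' @param blowing Index (or indices) of the component(s) expected to blow up.
#'   Defaults to component 1.
#' @param name Optional identifier.
#'
#' @return An object of class `ode_problem`.
#' @examples
#' pr <- ode_problem(function(x, p) x^2, name = "quadratic")
#' pr$rhs(3, pr$params)
#' @export
ode_problem <- function(rhs, dim = 1L, params = list(), known_power = NULL,
                        blowing = 1L, name = NULL) {
  stopifnot(is.function(rhs), dim >= 1)
  if (!is.null(known_power) && known_power <= 1)
    stop("known_power must be > 1 (p <= 1 does not blow up in finite time)")
  structure(
    list(rhs = rhs, dim = as.integer(dim), params = params,
         known_power = known_power, blowing = as.integer(blowing),
         name = name),
    class = "ode_problem"
  )
}

#' @export
print.ode_problem <- function(x, ...) {
  cat("<ode_problem", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "dim =", x$dim, ">\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  }
  cat("  blowing component(s):", paste(x$blowing, collapse = ", "), "\n")
  invisible(x)
}

# Sign-preserving real power: the odd-root convention used for fractional
# exponents whose inverse branch is real, e.g. spow(-8, 1/3) = -2.
spow <- function(x, e) sign(x) * abs(x)^e

# Largest |x| at which x^p is still comfortably inside double range; states
# beyond this are clipped before evaluating chain-rule expressions.  The
# subdominant terms dropped by clipping are relatively O(clip^-1) and hence
# far below machine precision.
power_clip <- function(p) 10^(250 / max(p, 1))

#' Switching policy for blow-up continuation
#'
#' Thresholds and fit settings controlling when the integrator leaves the
#' original ("bad") equation for the transformed ("good") one and back.
#'
#' @param switch_high Magnitude of the diverging component that triggers the
#'   bad-to-good switch (and errors out the good regime if re-approached).
#' @param switch_low How far past zero the good variable must travel before
#'   reverting to the bad equation ("safely crossed").
#' @param exponent_window Maximum number of trailing samples fed to the
#'   power-law fit.
#' @param min_fit_r2 Minimum R-squared of the log-log fit of `|dx/dt|` vs
#'   `|x|` for the growth to be accepted as asymptotically self-similar.
#' @param rtol,atol Solver tolerances for both regimes.
#'
#' @return A list of class `switch_policy`.
#' @export
switch_policy <- function(switch_high = 100, switch_low = 0.01,
                          exponent_window = 50L, min_fit_r2 = 0.999,
                          rtol = 1e-8, atol = 1e-8) {
  stopifnot(switch_high > 1, switch_low > 0)
  structure(list(switch_high = switch_high, switch_low = switch_low,
                 exponent_window = as.integer(exponent_window),
                 min_fit_r2 = min_fit_r2, rtol = rtol, atol = atol),
            class = "switch_policy")
}
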
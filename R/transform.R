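#' Singular transformation between bad and good variables
#'
#' Constructs the invertible map `y = (x - level)^exponent` (power kind) or
#' `y = integral from x to Inf of 1/f(s) ds` (integral kind) that sends a
#' variable blowing up to infinity to a "good" variable that merely crosses
#' zero. The branch policy decides how the state re-enters when the inverse
#' is multivalued past the crossing (even transform exponent): along the
#' positive or negative imaginary axis, or an error for `real_continuation`.
#'
#' @param kind `"power"` or `"integral"`.
#' @param exponent Transform exponent (for power kind, `1 - p`; negative).
#' @param level Real offset subtracted before transforming (0 for pure ODEs;
#'   the level-set value `r` in the PDE setting).
#' @param branch One of `"real_continuation"`, `"plus_i"`, `"minus_i"`.
#' @param sign Direction of divergence (+1 or -1) of the bad variable before
#'   the crossing; fixes the real pre-crossing inverse branch.
#' @param f For the integral kind, the scalar right-hand side `f(x)`.
#'
#' @return An object of class `singular_transform` with elements `forward`
#'   and `inverse` (functions) plus the construction metadata.
#' @examples
#' tr <- singular_transform(exponent = -1)   # p = 2: y = 1/x
#' tr$forward(100); tr$inverse(0.01)
#' @export
singular_transform <- function(kind = c("power", "integral"), exponent = -1,
                               level = 0,
                               branch = c("real_continuation", "plus_i", "minus_i"),
                               sign = 1, f = NULL) {
  kind <- match.arg(kind)
  branch <- match.arg(branch)
  if (kind == "power") {
    if (exponent >= 0) stop("power transform exponent must be negative (1 - p with p > 1)")
    inv_e <- 1 / exponent
    even_exp <- abs(exponent - round(exponent)) < 1e-12 &&
      round(exponent) %% 2 == 0
    forward <- function(x) (x - level)^exponent
    inverse <- function(y) {
      if (is.complex(y)) stop("good variable must be real")
      if (!even_exp) return(level + spow(y, inv_e))
      # even exponent (odd p): pre-crossing branch is fixed by `sign`,
      # post-crossing (y < 0) the inverse leaves the real axis
      if (y > 0) return(level + sign * abs(y)^inv_e)
      if (y == 0) return(if (branch == "real_continuation") Inf else
        switch(branch, plus_i = complex(real = 0, imaginary = Inf),
               minus_i = complex(real = 0, imaginary = -Inf)))
      if (branch == "real_continuation")
        stop("phase loss: inverse of an even-exponent transform is not real past ",
             "the crossing; choose branch 'plus_i' or 'minus_i'")
      im <- abs(y)^inv_e
      level + switch(branch, plus_i = complex(real = 0, imaginary = im),
                     minus_i = complex(real = 0, imaginary = -im))
    }
  } else {
    if (is.null(f)) stop("integral transform requires the right-hand side f")
    forward <- function(x) {
      val <- tryCatch(
        stats::integrate(function(s) 1 / f(s), lower = x, upper = Inf,
                         rel.tol = 1e-12, abs.tol = 1e-14)$value,
        error = function(e) stop("transform undefined: tail of 1/f is not integrable (",
                                 conditionMessage(e), ")", call. = FALSE))
      if (!is.finite(val)) stop("transform undefined: tail of 1/f is not integrable")
      val
    }
    inverse <- function(y) {
      # forward is decreasing in x; expand a bracket by decades so that
      # the quadrature is never asked to start arbitrarily close to level
      g <- function(x) forward(x) - y
      lo <- level + 1; hi <- level + 1
      while (g(lo) <= 0 && lo - level > 1e-6) lo <- level + (lo - level) / 10
      while (g(hi) >= 0 && hi - level < 1e12) hi <- level + (hi - level) * 10
      stats::uniroot(g, lower = lo, upper = hi, tol = 1e-14)$root
    }
    exponent <- NA_real_
  }
  structure(list(kind = kind, exponent = exponent, level = level,
                 branch = branch, sign = sign,
                 forward = forward, inverse = inverse),
            class = "singular_transform")
}

#' Build the singular transform and good equation from a detection
#'
#' Turns a [detect_blowup()] record into the matching power transform
#' `y = x^(1 - p_hat)` together with the transformed "good" system produced
#' by the exact chain rule from the full right-hand side (not only the
#' dominant term), so that asymptotically self-similar cases are integrated
#' exactly in the good variable.
#'
#' @param detection A `blowup_detection`.
#' @param problem The [ode_problem()] being integrated.
#' @param branch Branch policy for reentry when the inverse is multivalued.
#'
#' @return A list with `transform` (the [singular_transform()]) and
#'   `good_problem` (an [ode_problem()] in the transformed variables; see
#'   [transform_subsystem()]).
#' @examples
#' pr <- ode_problem(function(x, p) x^2)
#' det <- structure(list(p_hat = 2, alpha = -1, t_switch = 0.99,
#'                       x_switch = 100, sign = 1, fit_r2 = 1),
#'                  class = "blowup_detection")
#' bt <- build_transform(det, pr)
#' bt$good_problem$rhs(0.01, pr$params)   # dy/dt = -1
#' @export
build_transform <- function(detection, problem,
                            branch = c("real_continuation", "plus_i", "minus_i")) {
  branch <- match.arg(branch)
  if (detection$p_hat <= 1) stop("detection power must exceed 1")
  exponent <- 1 - detection$p_hat
  comp <- problem$blowing[1]
  good <- transform_subsystem(problem, comp, exponent,
                              sign = detection$sign, branch = branch)
  list(transform = good$subsystem$transform, good_problem = good)
}

#' Transform one blowing component of a system
#'
#' Replaces component `component` of the system by its singularly transformed
#' variable `y = x^exponent` (chain rule applied to the full right-hand
#' side); the remaining components are untouched. This is the construction
#' used for models where a single variable blows up while the others stay
#' bounded, e.g. the quartic integrate-and-fire model with `y = 1/v^3`.
#'
#' @param problem An [ode_problem()].
#' @param component Index of the component to transform.
#' @param exponent Transform exponent (negative; `1 - p`). `exponent = 1`
#'   returns the problem unchanged.
#' @param sign,branch Passed to [singular_transform()].
#'
#' @return An [ode_problem()] in the mixed variables, with a `$subsystem`
#'   field recording `component`, `exponent` and the transform. Evaluating
#'   its `rhs` near the crossing is safe: the inverse image of the good
#'   variable is magnitude-clipped so that dominant-balance terms are exact
#'   to machine precision while no intermediate overflows.
#' @export
transform_subsystem <- function(problem, component, exponent, sign = 1,
                                branch = "real_continuation") {
  if (identical(exponent, 1) || identical(exponent, 1L)) return(problem)
  p <- 1 - exponent
  tr <- singular_transform("power", exponent = exponent, sign = sign,
                           branch = branch)
  clip <- power_clip(p)
  rhs_orig <- problem$rhs
  comp <- as.integer(component)
  good_rhs <- function(state, params) {
    y <- state[comp]
    x <- tr$inverse(y)
    m <- Mod(x)
    if (!is.finite(m) || m > clip) {
      dir <- if (is.finite(m) && m > 0) x / m else {
        if (is.complex(x)) {
          complex(real = 0, imaginary = base::sign(Im(x)))
        } else tr$sign
      }
      x <- dir * clip
    }
    full <- state
    if (is.complex(x) && !is.complex(full)) full <- as.complex(full)
    full[comp] <- x
    f <- rhs_orig(full, params)
    dy <- (1 - p) * x^(-p) * f[comp]
    out <- f
    out[comp] <- dy
    if (is.complex(out)) {
      if (max(abs(Im(out))) > 1e-8 * max(1, max(abs(Re(out)))))
        stop("transformed right-hand side is not real; component ", comp,
             " cannot be continued on this branch")
      out <- Re(out)
    }
    out
  }
  res <- ode_problem(good_rhs, dim = problem$dim, params = problem$params,
                     blowing = comp,
                     name = paste0(problem$name %||% "system", "_good"))
  res$subsystem <- list(component = comp, exponent = exponent, transform = tr)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polar decomposition of a two-component system with simultaneous blow-up
#'
#' For planar systems where both variables blow up together (e.g. the 2D
#' quadratic integrate-and-fire model), rewrites the dynamics of
#' `v = rho*sin(theta)`, `u = rho*cos(theta)` in `(rho, theta)`, capturing
#' the concurrent blow-up through `rho` alone; the singular transform
#' `rho -> 1/rho` then applies to a single component.
#'
#' @param problem A 2D [ode_problem()] with state ordered `(v, u)`.
#'
#' @return An [ode_problem()] in `(rho, theta)` (exact chain rule applied to
#'   the original right-hand side), with helper closures `$to_polar(vu)` and
#'   `$from_polar(rt)` attached. Evaluation at `rho = 0` is an error (the
#'   angular equation carries a `1/rho` term).
#' @examples
#' qif2 <- get_model("qif_2d")$problem
#' pp <- polar_decompose(qif2)
#' pp$rhs(c(1, pi / 2), pp$params)
#' @export
polar_decompose <- function(problem) {
  if (problem$dim != 2) stop("polar decomposition requires a 2D system")
  rhs_orig <- problem$rhs
  rhs_polar <- function(state, params) {
    rho <- state[1]; th <- state[2]
    if (rho == 0) stop("polar right-hand side is singular at rho = 0")
    vu <- c(rho * sin(th), rho * cos(th))
    f <- rhs_orig(vu, params)
    c(sin(th) * f[1] + cos(th) * f[2],
      (cos(th) * f[1] - sin(th) * f[2]) / rho)
  }
  res <- ode_problem(rhs_polar, dim = 2, params = problem$params,
                     blowing = 1L,
                     name = paste0(problem$name %||% "system", "_polar"))
  res$to_polar <- function(vu) c(sqrt(sum(vu^2)), atan2(vu[1], vu[2]))
  res$from_polar <- function(rt) c(rt[1] * sin(rt[2]), rt[1] * cos(rt[2]))
  res
}

#' Diagnose whether non-transformed companions stayed regular at a crossing
#'
#' After a single-component singular transform, the remaining components
#' must have integrable dynamics through the crossing: their derivatives
#' may diverge no faster than `|y|^{-q}` with `q < 1` as the good variable
#' `y` approaches zero. Fitting `log |d(companion)/dt|` against `log |y|`
#' over the good-regime samples flags a contract violation (for instance,
#' transforming only the voltage of the 2D quadratic integrate-and-fire
#' model, where the adaptation variable blows up too, gives slope -1).
#'
#' @param traj A `blowup_trajectory` containing at least one good segment.
#' @param slope_limit Divergence exponent at which a companion is declared
#'   non-integrable (default -0.9).
#' @return List with `ok` (logical) and `slopes` (one per companion).
#' @export
check_bounded_companions <- function(traj, slope_limit = -0.9) {
  segs <- Filter(function(s) s$regime == "good", traj$segments)
  if (!length(segs)) stop("trajectory has no good segment to diagnose")
  seg <- segs[[1]]
  d <- ncol(seg$state)
  others <- setdiff(seq_len(d), seg$comp)
  if (!length(others)) return(list(ok = TRUE, slopes = numeric(0)))
  y <- Re(seg$state[, seg$comp])
  keep <- which(abs(y) > 1e-9)
  if (length(keep) < 5) stop("too few good-regime samples for the diagnostic")
  # exact companion derivatives: evaluate the original right-hand side at
  # the inverse-mapped states
  f_oth <- t(vapply(keep, function(i) {
    st <- Re(seg$state[i, ])
    st[seg$comp] <- Re(seg$transform$inverse(y[i]))
    traj$problem$rhs(st, traj$problem$params)[others]
  }, numeric(length(others))))
  ym <- abs(y[keep])
  slopes <- vapply(seq_along(others), function(j) {
    fj <- abs(f_oth[, j])
    ok <- fj > 1e-12
    if (sum(ok) < 5) return(0)
    unname(stats::lsfit(log(ym[ok]), log(fj[ok]))$coefficients[2])
  }, numeric(1))
  list(ok = all(slopes > slope_limit), slopes = slopes)
}
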
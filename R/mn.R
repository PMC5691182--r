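# MN-dynamics (co-exploding frame) scaling calculus: map the scaling powers
# of the spatial operator (a) and the nonlinearity (s) to the blow-up
# exponents of amplitude and width, and fit those exponents empirically
# from buffered PDE runs.

#' Predicted self-similar scaling exponents
#'
#' In the co-exploding frame `u = A(tau) f(xi)`, `xi = x / L(tau)`, matching
#' the scalings of the spatial operator (`1/L^a`) and the nonlinearity
#' (`A^{s-1}`) forces `A ~ L^{-a/(s-1)}`; demanding a stationary profile
#' then gives `A ~ (t*-t)^{1/(1-s)}` and `L ~ (t*-t)^{1/a}`. For the
#' focusing level-set PDE the dominant balance has `s = 2`, `a = 2`, hence
#' amplitude exponent -1, width exponent 1/2 and `A ~ 1/L^2`.
#'
#' @param a Spatial-operator scaling power (> 0).
#' @param s Nonlinearity power (> 1).
#' @return List of class `mn_scaling` with `a`, `s`, `amp_exponent`
#'   (`1/(1-s)`), `width_exponent` (`1/a`) and `amp_width_exponent`
#'   (`a/(s-1)`, the `k` in `A ~ L^-k`).
#' @examples
#' predict_scalings(2, 2)$amp_width_exponent   # A ~ 1/L^2
#' @export
predict_scalings <- function(a, s) {
  if (s <= 1) stop("s <= 1: no finite-time blow-up scaling")
  if (a <= 0) stop("a must be positive")
  structure(list(a = a, s = s,
                 amp_exponent = 1 / (1 - s),
                 width_exponent = 1 / a,
                 amp_width_exponent = a / (s - 1)),
            class = "mn_scaling")
}

#' @export
print.mn_scaling <- function(x, ...) {
  cat(sprintf("<mn_scaling a = %g, s = %g>  A ~ (t*-t)^%g,  L ~ (t*-t)^%g,  A ~ L^-%g\n",
              x$a, x$s, x$amp_exponent, x$width_exponent,
              x$amp_width_exponent))
  invisible(x)
}

# full width at half maximum of the tip from a mixed-representation state;
# interpolates the crossings of 1/|w| through 2/A on either side of the tip
profile_fwhm <- function(x, vals, kinds) {
  cm <- compose_mag(vals, kinds)
  itip <- which.max(cm$mag)
  A <- cm$mag[itip]
  lev <- 2 / A                       # |w| = A/2  <=>  1/|w| = 2/A
  q <- cm$inv
  n <- length(q)
  right <- NA_real_; left <- NA_real_
  for (j in seq.int(itip, n - 1L)) {
    if (q[j] <= lev && q[j + 1] > lev) {
      right <- x[j] + (lev - q[j]) / (q[j + 1] - q[j]) * (x[j + 1] - x[j])
      break
    }
  }
  for (j in seq.int(itip, 2L)) {
    if (q[j] <= lev && q[j - 1] > lev) {
      left <- x[j] - (lev - q[j]) / (q[j - 1] - q[j]) * (x[j] - x[j - 1])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("fit error: tip half-maximum not bracketed (tip at the boundary?)")
  list(A = A, L = right - left, x_tip = x[itip])
}

#' Fit amplitude and width scaling exponents from PDE snapshots
#'
#' Measures `A = max|w|` and `L` = full width at half maximum of `|w|`
#' around the tip on each snapshot of the late pre-touch window, then fits
#' least-squares slopes of `log A` and `log L` against `log(t* - t)` and of
#' `log A` against `log L`.
#'
#' @param run A `pde_run` from [run_full()], or a list of snapshots
#'   (each `list(t, vals, kinds)`).
#' @param t_star_estimate Collapse-time estimate (defaults to the run's
#'   first-touch time).
#' @param A_range Snapshots are used while `A` lies in this window.
#' @return List with `amp_exp_fit`, `width_exp_fit`, `k_fit`
#'   (`A ~ L^-k_fit`), and the measured `t`, `A`, `L` series.
#' @export
fit_amplitude_width <- function(run, t_star_estimate = NULL,
                                A_range = c(1e2, 1e4)) {
  snaps <- if (inherits(run, "pde_run")) run$snapshots else run
  if (is.null(t_star_estimate) && inherits(run, "pde_run"))
    t_star_estimate <- run$t_first_touch
  x <- if (inherits(run, "pde_run")) run$config$grid$x else
    seq(0, pi, length.out = length(snaps[[1]]$vals))
  meas <- lapply(snaps, function(s) {
    fw <- tryCatch(profile_fwhm(x, s$vals, s$kinds), error = function(e) NULL)
    if (is.null(fw)) return(NULL)
    c(t = s$t, A = fw$A, L = fw$L)
  })
  meas <- do.call(rbind, meas[!vapply(meas, is.null, logical(1))])
  sel <- meas[, "A"] >= A_range[1] & meas[, "A"] <= A_range[2]
  if (!is.null(t_star_estimate))
    sel <- sel & meas[, "t"] < t_star_estimate
  meas <- meas[sel, , drop = FALSE]
  if (nrow(meas) < 8)
    stop("fit error: fewer than 8 snapshots in the pre-touch window")
  k_fit <- -unname(stats::lsfit(log(meas[, "L"]),
                                log(meas[, "A"]))$coefficients[2])
  amp_exp_fit <- NA_real_; width_exp_fit <- NA_real_
  if (!is.null(t_star_estimate) && is.finite(t_star_estimate)) {
    lt <- log(t_star_estimate - meas[, "t"])
    amp_exp_fit <- unname(stats::lsfit(lt, log(meas[, "A"]))$coefficients[2])
    width_exp_fit <- unname(stats::lsfit(lt, log(meas[, "L"]))$coefficients[2])
  }
  list(amp_exp_fit = amp_exp_fit, width_exp_fit = width_exp_fit,
       k_fit = k_fit, t = meas[, "t"], A = meas[, "A"], L = meas[, "L"])
}
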
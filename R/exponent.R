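#' Estimate the blow-up nonlinearity power from trajectory samples
#'
#' Fits the power-law relation between the observed growth rate and the state,
#' `|dx/dt| ~ |x|^p`, by least squares on log-log scale over a trailing
#' window. Near a self-similar blow-up `x ~ (t*-t)^{1/(1-p)}` this recovers
#' the nonlinearity power `p`.
#'
#' @param x Numeric vector of states (one diverging component).
#' @param dxdt Numeric vector of matching time derivatives.
#' @param window Number of trailing samples used for the fit (default: all).
#'
#' @return A list with `p_hat` (fitted power), `fit_r2` (R-squared of the
#'   log-log fit) and `n` (samples used).
#'
#' @details The window must look like a self-similar approach to infinity:
#'   at least 5 samples, `|x|` strictly increasing, all of one sign, and all
#'   derivatives nonzero of one sign. Otherwise the samples are rejected with
#'   error "not in self-similar regime".
#' @examples
#' x <- 1 / (1 - seq(0.9, 0.99, by = 0.01))   # x' = x^2 along x = 1/(1-t)
#' estimate_exponent(x, x^2)$p_hat
#' @export
estimate_exponent <- function(x, dxdt, window = length(x)) {
  if (length(x) != length(dxdt)) stop("x and dxdt must have equal length")
  if (length(x) < 5) stop("need at least 5 samples for the exponent fit")
  window <- min(window, length(x))
  idx <- seq.int(length(x) - window + 1L, length(x))
  xs <- x[idx]; ds <- dxdt[idx]
  if (length(xs) < 5) stop("need at least 5 samples for the exponent fit")
  if (any(xs == 0) || any(sign(xs) != sign(xs[1])))
    stop("not in self-similar regime: window mixes signs or touches zero")
  if (any(diff(abs(xs)) <= 0))
    stop("not in self-similar regime: |x| is not strictly increasing")
  if (any(ds == 0) || any(sign(ds) != sign(ds[1])))
    stop("not in self-similar regime: derivative vanishes or changes sign")
  lx <- log(abs(xs)); ly <- log(abs(ds))
  fit <- stats::lsfit(lx, ly)
  p_hat <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  list(p_hat = p_hat, fit_r2 = r2, n = length(xs))
}

# Snap a fitted power to the nearest integer when within `tol`; the worked
# models all have integer powers and snapping yields exact good equations.
snap_power <- function(p_hat, tol = 0.05) {
  p_int <- round(p_hat)
  if (abs(p_hat - p_int) <= tol && p_int >= 2) p_int else p_hat
}

#' Detect asymptotically self-similar blow-up in a trajectory tail
#'
#' Inspects the most recent samples of the diverging component and returns a
#' detection record once (i) the magnitude has reached `policy$switch_high`
#' and (ii) the growth passes the power-law self-similarity fit. Called
#' internally by [integrate_crossing()] at the moment the threshold is hit;
#' usable standalone on recorded samples.
#'
#' @param t Times of the trailing samples.
#' @param x States of the diverging component at those times.
#' @param dxdt Matching derivatives.
#' @param policy A [switch_policy()].
#'
#' @return `NULL` if the threshold has not been reached; otherwise a
#'   `blowup_detection` list with `p_hat`, `alpha = 1/(1-p_hat)`, `t_switch`,
#'   `x_switch`, `sign` and `fit_r2`. If the threshold is reached but the fit
#'   is rejected, integration must not guess: an error
#'   "growth not asymptotically self-similar" is thrown.
#' @export
detect_blowup <- function(t, x, dxdt, policy = switch_policy()) {
  n <- length(x)
  if (abs(x[n]) < policy$switch_high) return(NULL)
  # Fit over the trailing contiguous run of samples already in the asymptotic
  # range (|x| >= switch_high / 3); fall back to the last 5 samples if too few.
  ok <- abs(x) >= policy$switch_high / 3
  last_bad <- if (any(!ok)) max(which(!ok)) else 0L
  sel <- seq.int(last_bad + 1L, n)
  if (length(sel) < 5) sel <- seq.int(max(1L, n - 4L), n)
  sel <- utils::tail(sel, policy$exponent_window)
  est <- tryCatch(estimate_exponent(x[sel], dxdt[sel]),
                  error = function(e)
                    stop("growth not asymptotically self-similar: ",
                         conditionMessage(e), call. = FALSE))
  if (est$fit_r2 < policy$min_fit_r2 || est$p_hat < 1.1)
    stop("growth not asymptotically self-similar: p_hat = ",
         signif(est$p_hat, 4), ", r2 = ", signif(est$fit_r2, 6), call. = FALSE)
  p_hat <- snap_power(est$p_hat)
  structure(list(p_hat = p_hat, alpha = 1 / (1 - p_hat),
                 t_switch = t[n], x_switch = x[n],
                 sign = sign(Re(x[n])), fit_r2 = est$fit_r2,
                 p_raw = est$p_hat),
            class = "blowup_detection")
}

#' @export
print.blowup_detection <- function(x, ...) {
  cat(sprintf(
    "<blowup_detection> p_hat = %.4g (alpha = %.4g), t_switch = %.6g, sign = %+d, r2 = %.6f\n",
    x$p_hat, x$alpha, x$t_switch, x$sign, x$fit_r2))
  invisible(x)
}
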
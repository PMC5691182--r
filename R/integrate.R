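# Regime-switching integration through blow-up: solve the bad equation while
# monitoring growth, switch to the transformed good equation once self-similar
# approach to infinity is detected, cross zero there, and revert.

# deSolve wrapper for a possibly complex autonomous system stored as a real
# vector (Re parts then Im parts when complex).
wrap_rhs <- function(problem, complex_state) {
  d <- problem$dim
  if (!complex_state) {
    function(t, y, parms) list(problem$rhs(y, problem$params))
  } else {
    function(t, y, parms) {
      z <- complex(real = y[seq_len(d)], imaginary = y[d + seq_len(d)])
      f <- problem$rhs(z, problem$params)
      list(c(Re(f), Im(f)))
    }
  }
}

state_pack <- function(x, complex_state) {
  if (complex_state) c(Re(x), Im(x)) else as.numeric(x)
}
state_unpack <- function(y, d, complex_state) {
  if (complex_state) complex(real = y[seq_len(d)], imaginary = y[d + seq_len(d)])
  else y
}

seg_times <- function(t0, t1, dt_out) {
  ts <- seq(t0, t1, by = dt_out)
  if (utils::tail(ts, 1) < t1) ts <- c(ts, t1)
  ts
}

run_lsodar <- function(state, t0, t1, fun, rootfun, dt_out, rtol, atol) {
  times <- seg_times(t0, t1, dt_out)
  if (length(times) < 2) times <- c(t0, t1)
  out <- deSolve::lsodar(y = state, times = times, func = fun,
                         rootfunc = rootfun, rtol = rtol, atol = atol,
                         maxsteps = 1e5)
  troot <- attr(out, "troot")
  list(t = out[, 1], y = out[, -1, drop = FALSE],
       root = !is.null(troot) && length(troot) > 0 && is.finite(troot[1]),
       troot = if (!is.null(troot) && length(troot)) troot[1] else NA_real_,
       iroot = attr(out, "indroot"))
}

#' Integrate an ODE through infinity by regime switching
#'
#' Implements the four-step continuation protocol: (1) integrate the original
#' ("bad") equation, monitoring growth of the diverging component; (2) when
#' its magnitude reaches `policy$switch_high`, fit the power law
#' `|dx/dt| ~ |x|^p` and accept the blow-up as asymptotically self-similar
#' only if the fit is good (otherwise integration halts rather than
#' guessing); (3) switch by continuity to the good equation for
#' `y = x^(1-p)` and run it until zero is safely crossed
#' (`|y| >= policy$switch_low` on the far side); (4) transform back and march
#' the bad equation on. The loop repeats for arbitrarily many crossings
#' (periodic blow-up, as in integrate-and-fire models, is supported).
#'
#' @param problem An [ode_problem()].
#' @param x0 Initial state (finite; real).
#' @param t_span Length-2 numeric, the time interval to cover.
#' @param policy A [switch_policy()].
#' @param branch Reentry branch policy when the inverse transform is
#'   multivalued (odd blow-up powers): `"real_continuation"` (error in the
#'   multivalued case), `"plus_i"`, or `"minus_i"`.
#' @param n_out Approximate number of output samples across `t_span`.
#'
#' @return A `blowup_trajectory`: ordered segments of `(t, state)` samples
#'   with regime annotations (`"bad"`/`"good"`), the transform used in each
#'   good segment, and an event table (switches, infinity crossings with
#'   their blow-up-time estimates, fitted powers).
#' @examples
#' pr <- ode_problem(function(x, p) x^2)
#' tr <- integrate_crossing(pr, 1, c(0, 2))
#' final_state(tr)              # continuation gives x(2) = -1
#' crossing_times(tr)           # blow-up at t* = 1
#' @export
integrate_crossing <- function(problem, x0, t_span, policy = switch_policy(),
                               branch = c("real_continuation", "plus_i", "minus_i"),
                               n_out = 2000) {
  branch <- match.arg(branch)
  stopifnot(length(t_span) == 2, all(is.finite(t_span)), all(is.finite(x0)))
  d <- problem$dim
  comp <- problem$blowing[1]
  dt_out <- diff(t_span) / n_out
  segments <- list()
  events <- list()
  t_cur <- t_span[1]
  state <- x0
  complex_state <- FALSE
  regime <- "bad"
  good_ctx <- NULL  # transform + good problem while in good regime
  guard_lo <- NULL
  seg_id <- 0L

  add_event <- function(time, type, ...) {
    events[[length(events) + 1L]] <<- c(list(time = time, type = type), list(...))
  }
  check_finite <- function(state) {
    if (any(!is.finite(Re(state))) ||
        (is.complex(state) && any(!is.finite(Im(state)))))
      stop("integration produced a non-finite state: a component other ",
           "than the transformed one may be diverging at the crossing")
    state
  }

  while (t_cur < t_span[2] - 1e-14) {
    seg_id <- seg_id + 1L
    if (regime == "bad") {
      fun <- wrap_rhs(problem, complex_state)
      magfun <- function(y) {
        x <- state_unpack(y, d, complex_state)
        Mod(x[comp])
      }
      # cool-down: if we start at/above threshold (just reentered), wait for
      # the magnitude to recede before re-arming the blow-up root
      if (magfun(state_pack(state, complex_state)) >= 0.6 * policy$switch_high) {
        res0 <- run_lsodar(state_pack(state, complex_state), t_cur, t_span[2], fun,
                           function(t, y, parms) magfun(y) - 0.5 * policy$switch_high,
                           dt_out, policy$rtol, policy$atol)
        segments[[seg_id]] <- make_segment(res0, d, complex_state, "bad", NULL, comp)
        t_cur <- utils::tail(res0$t, 1)
        state <- check_finite(state_unpack(res0$y[nrow(res0$y), ], d, complex_state))
        if (!res0$root || t_cur >= t_span[2] - 1e-14) break
        seg_id <- seg_id + 1L
      }
      res <- run_lsodar(state_pack(state, complex_state), t_cur, t_span[2], fun,
                        function(t, y, parms) magfun(y) - policy$switch_high,
                        dt_out, policy$rtol, policy$atol)
      segments[[seg_id]] <- make_segment(res, d, complex_state, "bad", NULL, comp)
      t_cur <- utils::tail(res$t, 1)
      state <- check_finite(state_unpack(res$y[nrow(res$y), ], d, complex_state))
      if (!res$root) break  # bounded dynamics or t_end reached
      if (complex_state)
        stop("blow-up continuation of complex states is not supported")
      # detection on the trailing samples of this segment
      xb <- segments[[seg_id]]$state[, comp]
      db <- vapply(seq_along(res$t),
                   function(i) problem$rhs(res$y[i, ], problem$params)[comp],
                   numeric(1))
      det <- detect_blowup(res$t, Re(xb), db, policy)
      if (is.null(det)) stop("internal: threshold root without detection")
      bt <- build_transform(det, problem, branch = branch)
      add_event(det$t_switch, "switch_bad_to_good", p_hat = det$p_hat,
                alpha = det$alpha, fit_r2 = det$fit_r2, sign = det$sign,
                value = det$x_switch)
      good_ctx <- bt
      state[comp] <- bt$transform$forward(state[comp])
      regime <- "good"
    } else {
      gp <- good_ctx$good_problem
      tr <- good_ctx$transform
      fun <- wrap_rhs(gp, FALSE)
      y0 <- state[comp]
      s0 <- sign(y0)
      # single stage: run until zero is safely crossed (|y| = switch_low on
      # the far side), guarding against the good equation itself diverging
      # (cf. the quadratic IF good equation, which shares the blow-up
      # structure). The solver is not stopped at y = 0 itself: for coupled
      # systems the crossing instant is a delicate point of the transformed
      # companion equations, and t* is recovered from the dense output's
      # linear zero crossing instead.
      others <- setdiff(seq_len(d), comp)
      base_others <- state[others]
      rootg <- function(t, y, parms) {
        g <- c(y[comp] + s0 * policy$switch_low,
               abs(y[comp]) - policy$switch_high)
        if (length(others))
          g <- c(g, max(abs(y[others] - base_others)) - policy$switch_high)
        g
      }
      record_crossings <- function(res) {
        yv <- res$y[, comp]
        chg <- which(yv[-1] * yv[-length(yv)] < 0)
        for (j in chg) {
          tstar <- res$t[j] - yv[j] * (res$t[j + 1] - res$t[j]) /
            (yv[j + 1] - yv[j])
          add_event(tstar, "infinity_crossing", t_star = tstar,
                    p_hat = 1 - tr$exponent, alpha = 1 / tr$exponent,
                    sign = s0)
        }
      }
      # the crossing passage is short; resolve it on a fine grid sized by
      # the entry speed of the good variable, then fall back to the
      # trajectory-wide grid if zero has not been crossed in that horizon
      f0 <- abs(fun(t_cur, as.numeric(state), NULL)[[1]][comp])
      horizon <- 4 * (abs(y0) + policy$switch_low) / max(f0, 1e-8)
      t_fine <- min(t_span[2], t_cur + horizon)
      res <- run_lsodar(as.numeric(state), t_cur, t_fine, fun, rootg,
                        max(horizon / 400, 1e-12), policy$rtol, policy$atol)
      segments[[seg_id]] <- make_segment(res, d, FALSE, "good", tr, comp)
      t_cur <- utils::tail(res$t, 1)
      state <- check_finite(res$y[nrow(res$y), ])
      record_crossings(res)
      if (!res$root && t_cur < t_span[2] - 1e-14) {
        seg_id <- seg_id + 1L
        res <- run_lsodar(as.numeric(state), t_cur, t_span[2], fun, rootg,
                          dt_out, policy$rtol, policy$atol)
        segments[[seg_id]] <- make_segment(res, d, FALSE, "good", tr, comp)
        t_cur <- utils::tail(res$t, 1)
        state <- check_finite(res$y[nrow(res$y), ])
        record_crossings(res)
      }
      if (!res$root) break
      if (abs(state[comp]) >= policy$switch_high * (1 - 1e-9))
        stop("good equation diverging (|y| reached switch_high) before ",
             "recrossing; nested transforms are not supported")
      if (length(others) &&
          max(abs(state[others] - base_others)) >=
            policy$switch_high * (1 - 1e-9))
        stop("non-transformed component diverging during the crossing: ",
             "the transformed component was not the only one blowing up")
      # reentry
      xc <- tr$inverse(state[comp])
      if (is.complex(xc) && Im(xc) != 0) {
        complex_state <- TRUE
        state <- as.complex(state)
      }
      state[comp] <- xc
      add_event(t_cur, "switch_good_to_bad", value = xc, sign = s0)
      regime <- "bad"
      good_ctx <- NULL
    }
  }

  ev <- if (length(events)) {
    do.call(rbind, lapply(events, function(e) {
      data.frame(time = e$time, type = e$type,
                 t_star = if (!is.null(e$t_star)) e$t_star else NA_real_,
                 p_hat = if (!is.null(e$p_hat)) e$p_hat else NA_real_,
                 alpha = if (!is.null(e$alpha)) e$alpha else NA_real_,
                 fit_r2 = if (!is.null(e$fit_r2)) e$fit_r2 else NA_real_,
                 sign = if (!is.null(e$sign)) e$sign else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(time = numeric(), type = character(), t_star = numeric(),
               p_hat = numeric(), alpha = numeric(), fit_r2 = numeric(),
               sign = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(segments = segments, events = ev, problem = problem,
                 policy = policy, branch = branch,
                 complex_flag = complex_state),
            class = "blowup_trajectory")
}

make_segment <- function(res, d, complex_state, regime, transform, comp) {
  st <- if (complex_state) {
    matrix(complex(real = res$y[, seq_len(d)], imaginary = res$y[, d + seq_len(d)]),
           ncol = d)
  } else res$y[, seq_len(d), drop = FALSE]
  list(t = res$t, state = st, regime = regime, transform = transform,
       comp = comp)
}

#' @export
print.blowup_trajectory <- function(x, ...) {
  ns <- length(x$segments)
  tr <- range(unlist(lapply(x$segments, function(s) range(s$t))))
  ncross <- sum(x$events$type == "infinity_crossing")
  cat(sprintf("<blowup_trajectory> %d segment(s), t in [%g, %g], %d infinity crossing(s)%s\n",
              ns, tr[1], tr[2], ncross,
              if (x$complex_flag) ", complex continuation" else ""))
  if (ncross > 0)
    cat("  t* estimates:", paste(signif(crossing_times(x), 8), collapse = ", "), "\n")
  invisible(x)
}

#' Times at which the trajectory crossed infinity
#'
#' @param traj A `blowup_trajectory`.
#' @return Numeric vector of blow-up times, estimated from the zero crossings
#'   of the good variable (dense-output roots).
#' @export
crossing_times <- function(traj) {
  traj$events$t_star[traj$events$type == "infinity_crossing"]
}

#' Final state of a trajectory in the original variables
#'
#' @param traj A `blowup_trajectory`.
#' @return The state at the last computed time; if the trajectory ended in
#'   the good regime, the recorded transform is inverted first.
#' @export
final_state <- function(traj) {
  seg <- traj$segments[[length(traj$segments)]]
  st <- seg$state[nrow(seg$state), ]
  if (seg$regime == "good") st[seg$comp] <- seg$transform$inverse(st[seg$comp])
  unname(st)
}

#' Flatten a trajectory to a data frame
#'
#' One row per stored sample with the segment's own variables (the good
#' variable inside good segments), plus `regime` and `segment` columns.
#' Complex components are split into `.re`/`.im` columns.
#'
#' @param x A `blowup_trajectory`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @export
as.data.frame.blowup_trajectory <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  d <- x$problem$dim
  rows <- lapply(seq_along(x$segments), function(i) {
    s <- x$segments[[i]]
    df <- data.frame(t = s$t)
    for (j in seq_len(d)) {
      v <- s$state[, j]
      if (is.complex(v)) {
        df[[paste0("x", j, ".re")]] <- Re(v)
        df[[paste0("x", j, ".im")]] <- Im(v)
      } else {
        df[[paste0("x", j)]] <- v
      }
    }
    df$regime <- s$regime
    df$segment <- i
    df
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (m in setdiff(nm, names(df))) df[[m]] <- if (m == "regime") "" else 0
    df[nm]
  })
  do.call(rbind, rows)
}

#' Reconstruct the original (bad) variable along a trajectory
#'
#' Inverts the recorded transform on good segments so the full path of the
#' diverging component is available (it passes through `Inf` at crossings).
#' Post-crossing samples on a multivalued branch come back complex.
#'
#' @param traj A `blowup_trajectory`.
#' @return A data frame with columns `t` and `x.re`, `x.im` for the blowing
#'   component.
#' @export
original_component <- function(traj) {
  out <- lapply(traj$segments, function(s) {
    v <- s$state[, s$comp]
    if (s$regime == "good") {
      v <- vapply(v, function(y) {
        z <- s$transform$inverse(y)
        as.complex(z)
      }, complex(1))
    }
    data.frame(t = s$t, x.re = Re(v), x.im = Im(as.complex(v)))
  })
  do.call(rbind, out)
}
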
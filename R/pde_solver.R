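# Adaptive domain-decomposition solver that integrates the focusing
# ("bad") PDE  w_t = w_xx - (2/w) w_x^2 + w + r w^2  through infinity by
# solving the linear ("good") PDE  v_t = v_xx - v - r  for v = 1/w inside
# adaptively tracked singular buffer regions, glued to the regular domain
# by an explicit-interface / implicit-interior scheme.

#' Uniform 1D grid on `[0, pi]` with Neumann ends
#'
#' @param N Number of nodes (>= 51).
#' @return List of class `grid1d` with `N`, `x`, `h`.
#' @export
grid1d <- function(N) {
  N <- as.integer(N)
  if (N < 51) stop("N must be at least 51")
  structure(list(N = N, x = seq(0, pi, length.out = N), h = pi / (N - 1)),
            class = "grid1d")
}

#' Buffer management policy
#'
#' @param W_max Magnitude of `w` at which a node is considered to be
#'   approaching infinity and must be handled inside a buffer (default 1e4).
#' @param margin Nodes added on each side of the `|w| >= W_max` span when a
#'   buffer is (re)drawn; also the hysteresis unit for splitting.
#' @param era_len Steps between partition re-evaluations (one
#'   "computational era").
#' @param exponent_check Minimum R-squared for the on-the-fly power-law
#'   growth fit that must pass before the first buffer is declared.
#' @return List of class `buffer_policy`.
#' @export
buffer_policy <- function(W_max = 1e4, margin = 5L, era_len = 10L,
                          exponent_check = 0.99) {
  stopifnot(W_max >= 100, margin >= 1)
  structure(list(W_max = W_max, margin = as.integer(margin),
                 era_len = as.integer(era_len),
                 exponent_check = exponent_check),
            class = "buffer_policy")
}

# second-order central differences with mirrored (Neumann) ghost nodes
fd_neighbors <- function(u) {
  n <- length(u)
  list(l = c(u[2], u[seq_len(n - 1)]), r = c(u[2:n], u[n - 1]))
}

#' Right-hand side of the bad (focusing) PDE
#'
#' `w_t = w_xx - (2/w) w_x^2 + w + r w^2`, discretized with second-order
#' central differences and mirrored ghost nodes at the Neumann ends. The
#' singular combination `w_xx - (2/w) w_x^2` is evaluated in its
#' algebraically identical gradient-free form `-w^2 (1/w)_xx`, whose
#' truncation error stays proportional to the smooth reciprocal field even
#' across the steep collapsing front (see the methods vignette).
#'
#' @param w Nodal values (nonzero).
#' @param grid A [grid1d()].
#' @param r Level-set offset.
#' @return Nodal time derivatives.
#' @export
bad_rhs <- function(w, grid, r) {
  if (any(w == 0))
    stop("division error: w = 0 at a node (this span belongs in a buffer's ",
         "complement, handled in v)")
  v <- 1 / w
  nb <- fd_neighbors(v)
  -w^2 * (nb$r - 2 * v + nb$l) / grid$h^2 + w + r * w^2
}

#' Right-hand side of the good (transformed) PDE
#'
#' `v_t = v_xx - v - r`: linear, with the same discretization and Neumann
#' handling as [bad_rhs()].
#'
#' @param v Nodal values.
#' @param grid A [grid1d()].
#' @param r Level-set offset.
#' @return Nodal time derivatives.
#' @export
good_rhs <- function(v, grid, r) {
  nb <- fd_neighbors(v)
  (nb$r - 2 * v + nb$l) / grid$h^2 - v - r
}

# nodal magnitude of w: regular nodes store w, buffer nodes store v = 1/w
node_mag <- function(vals, kinds) {
  m <- abs(vals)
  b <- kinds == 1L
  m[b] <- 1 / abs(vals[b])
  m
}

# contiguous runs of TRUE as a two-column matrix (lo, hi)
true_runs <- function(flag) {
  r <- rle(flag)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  cbind(lo, hi)[r$values, , drop = FALSE]
}

#' Re-evaluate the regular/buffer partition
#'
#' Nodes where `|w| >= W_max` (expanded by `margin` on each side) become
#' buffer nodes. Before the first buffer is declared, the growth of
#' `max|w|` must pass the power-law self-similarity check (log-log fit of
#' `d(max w)/dt` against `max w`); the detected exponent is reported as
#' `alpha = 1/(1 - p_hat)`. A single buffer splits into two (the 5-region
#' topology) once an interior span of at least `2*margin` nodes has receded
#' below `W_max`.
#'
#' @param vals Nodal values in their per-region representation.
#' @param kinds Integer vector (0 = regular node, 1 = buffer node).
#' @param history Data frame with columns `t`, `A` (per-step `max|w|`),
#'   used for the pre-buffer growth fit.
#' @param policy A [buffer_policy()].
#' @param grid A [grid1d()].
#' @return List with `kinds` (new), `detection` (`NULL` or the growth-fit
#'   record the first time a buffer is created), `changed` (logical).
#' @export
detect_and_partition <- function(vals, kinds, history, policy, grid) {
  N <- grid$N
  mag <- node_mag(vals, kinds)
  core <- mag >= policy$W_max
  detection <- NULL
  if (!any(core)) {
    if (any(kinds == 1L)) {
      # buffers never fully dissolve in the supported scenario; keep them
      return(list(kinds = kinds, detection = NULL, changed = FALSE))
    }
    return(list(kinds = integer(N), detection = NULL, changed = FALSE))
  }
  if (!any(kinds == 1L)) {
    detection <- growth_power_fit(history, policy)
    if (detection$fit_r2 < policy$exponent_check || detection$p_hat <= 1)
      stop("not self-similar: tip growth failed the power-law check (p_hat = ",
           signif(detection$p_hat, 4), ", r2 = ",
           signif(detection$fit_r2, 4), ")")
  }
  runs <- true_runs(core)
  # hysteresis: merge core runs separated by fewer than 2*margin nodes
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[i, 1] - last[2] - 1L < 2L * policy$margin) {
        last[2] <- runs[i, 2]
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }
  if (nrow(runs) > 2)
    stop("unsupported scenario: more than two infinity crossings")
  new_kinds <- integer(N)
  for (i in seq_len(nrow(runs))) {
    lo <- runs[i, 1] - policy$margin
    hi <- runs[i, 2] + policy$margin
    if (lo <= 1L || hi >= N)
      stop("unsupported topology: buffer reached the domain boundary")
    new_kinds[lo:hi] <- 1L
  }
  list(kinds = new_kinds, detection = detection,
       changed = !identical(new_kinds, kinds))
}

# on-the-fly exponent from d(max w)/dt vs max w on log-log scale
growth_power_fit <- function(history, policy) {
  sel <- which(history$A >= policy$W_max / 100 & history$A <= policy$W_max)
  if (length(sel) < 5)
    stop("not self-similar: too few growth samples for the power-law check")
  t <- history$t[sel]; A <- history$A[sel]
  n <- length(A)
  dA <- (A[3:n] - A[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  Amid <- A[2:(n - 1)]
  ok <- dA > 0 & Amid > 0
  if (sum(ok) < 5) stop("not self-similar: growth is not monotone")
  fit <- stats::lsfit(log(Amid[ok]), log(dA[ok]))
  p_hat <- unname(fit$coefficients[2])
  ss <- sum(fit$residuals^2)
  st <- sum((log(dA[ok]) - mean(log(dA[ok])))^2)
  r2 <- if (st == 0) 1 else 1 - ss / st
  list(p_hat = p_hat, alpha = 1 / (1 - p_hat), fit_r2 = r2,
       n = sum(ok), A_range = range(Amid[ok]))
}

# --- implicit interior steps ---------------------------------------------

# one backward-Euler step for a bad-region span vals[lo..hi];
# dirichlet: list(left = value or NULL (Neumann), right = ...)
implicit_bad_step <- function(w, dt, h, r, dirichlet, tol = 1e-11,
                              maxit = 30L) {
  n <- length(w)
  w_old <- w
  wn <- w
  left_neu <- is.null(dirichlet$left)
  right_neu <- is.null(dirichlet$right)
  if (n == 1L) {
    # single interior node between two interfaces: scalar Newton
    if (left_neu || right_neu) stop("degenerate single-node region")
    vl <- 1 / dirichlet$left; vr <- 1 / dirichlet$right
    for (it in seq_len(maxit)) {
      B <- (vr - 2 / wn + vl) / h^2
      f <- -wn^2 * B + wn + r * wn^2
      res <- wn - w_old - dt * f
      dfd <- -2 * wn * B - 2 / h^2 + 1 + 2 * r * wn
      delta <- res / (1 - dt * dfd)
      wn <- wn - delta
      if (abs(delta) <= tol * max(1, abs(wn))) return(wn)
    }
    stop("implicit solve non-convergence in bad region")
  }
  for (it in seq_len(maxit)) {
    vn <- 1 / wn
    vl <- c(if (left_neu) vn[2] else 1 / dirichlet$left, vn[seq_len(n - 1)])
    vr <- c(vn[2:n], if (right_neu) vn[n - 1] else 1 / dirichlet$right)
    B <- (vr - 2 * vn + vl) / h^2
    f <- -wn^2 * B + wn + r * wn^2
    res <- wn - w_old - dt * f
    dfd <- -2 * wn * B - 2 / h^2 + 1 + 2 * r * wn
    wl2 <- c(1, wn[seq_len(n - 1)]^2)            # w_{j-1}^2 (pad unused)
    wr2 <- c(wn[2:n]^2, 1)                       # w_{j+1}^2 (pad unused)
    dfl <- wn^2 / (h^2 * wl2)                    # d f_j / d w_{j-1}
    dfu <- wn^2 / (h^2 * wr2)                    # d f_j / d w_{j+1}
    if (left_neu) dfu[1] <- 2 * wn[1]^2 / (h^2 * wn[2]^2)
    if (right_neu) dfl[n] <- 2 * wn[n]^2 / (h^2 * wn[n - 1]^2)
    dg <- 1 - dt * dfd
    dl <- -dt * dfl[2:n]
    du <- -dt * dfu[seq_len(n - 1)]
    delta <- thomas_solve(dl, dg, du, res)
    wn <- wn - delta
    if (max(abs(delta)) <= tol * max(1, max(abs(wn)))) return(wn)
  }
  stop("implicit solve non-convergence in bad region")
}

# one backward-Euler step for a good-region span (linear solve)
implicit_good_step <- function(v, dt, h, r, dirichlet) {
  n <- length(v)
  if (n == 1L) {
    if (is.null(dirichlet$left) || is.null(dirichlet$right))
      stop("degenerate single-node region")
    rhs1 <- v - dt * r + dt / h^2 * (dirichlet$left + dirichlet$right)
    return(rhs1 / (1 + dt * (2 / h^2 + 1)))
  }
  rhs <- v - dt * r
  dg <- rep(1 + dt * (2 / h^2 + 1), n)
  dl <- rep(-dt / h^2, max(0L, n - 1L))
  du <- dl
  if (is.null(dirichlet$left)) du[1] <- -2 * dt / h^2   # mirrored ghost
  else rhs[1] <- rhs[1] + dt / h^2 * dirichlet$left
  if (is.null(dirichlet$right)) dl[n - 1] <- -2 * dt / h^2
  else rhs[n] <- rhs[n] + dt / h^2 * dirichlet$right
  thomas_solve(dl, dg, du, rhs)
}

# explicit forward-Euler update of the two nodes flanking every internal
# interface, each in its own representation with converted neighbor values
interface_step <- function(vals, kinds, dt, h, r) {
  N <- length(vals)
  bnd <- which(diff(kinds) != 0L)       # interface between bnd and bnd+1
  if (!length(bnd)) return(vals)
  nodes <- sort(unique(c(bnd, bnd + 1L)))
  newv <- vals
  # neighbor value in the good (v) representation
  as_v <- function(j) if (kinds[j] == 1L) vals[j] else 1 / vals[j]
  for (i in nodes) {
    uc <- vals[i]
    vl <- as_v(i - 1L); vr <- as_v(i + 1L)
    f <- if (kinds[i] == 0L) {
      -uc^2 * (vr - 2 / uc + vl) / h^2 + uc + r * uc^2
    } else {
      (vr - 2 * uc + vl) / h^2 - uc - r
    }
    newv[i] <- uc + dt * f
  }
  newv
}

# advance one time step under a frozen partition:
# explicit interfaces first, then implicit interiors with the fresh
# interface values as Dirichlet data
step_once <- function(vals, kinds, dt, grid, r) {
  h <- grid$h
  N <- grid$N
  if (all(kinds == 0L)) {
    return(implicit_bad_step(vals, dt, h, r, list(left = NULL, right = NULL)))
  }
  vals1 <- interface_step(vals, kinds, dt, h, r)
  runs <- region_runs(kinds)
  out <- vals1
  for (i in seq_len(nrow(runs))) {
    lo <- runs[i, 1]; hi <- runs[i, 2]; kind <- kinds[lo]
    ilo <- if (lo == 1L) 1L else lo + 1L      # interior span (interface
    ihi <- if (hi == N) N else hi - 1L        # nodes already advanced)
    if (ilo > ihi) next
    dir <- list(left = if (lo == 1L) NULL else vals1[ilo - 1L],
                right = if (hi == N) NULL else vals1[ihi + 1L])
    seg <- vals[ilo:ihi]
    out[ilo:ihi] <- if (kind == 0L)
      implicit_bad_step(seg, dt, h, r, dir)
    else implicit_good_step(seg, dt, h, r, dir)
  }
  out
}

region_runs <- function(kinds) {
  r <- rle(kinds)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  cbind(lo, hi, kind = r$values)
}

#' Advance one computational era
#'
#' Runs `policy$era_len` time steps under the current partition (explicit
#' forward-Euler at the interface nodes providing the interior Dirichlet
#' data, backward-Euler inside each region), then re-evaluates the
#' partition and converts representations nodewise (`v = 1/w`) on any node
#' that changed kind.
#'
#' @param state List with `t`, `vals`, `kinds`.
#' @param dt Time step (must satisfy `dt <= h^2/4` for the explicit
#'   interface step).
#' @param grid A [grid1d()].
#' @param r Level-set offset.
#' @param policy A [buffer_policy()].
#' @param history Data frame `t`, `A` of per-step `max|w|` (updated and
#'   returned).
#' @return List with the advanced `state`, updated `history`, and
#'   `detection` (non-NULL the era a first buffer is created).
#' @export
step_era <- function(state, dt, grid, r, policy, history) {
  vals <- state$vals; kinds <- state$kinds; t <- state$t
  hrows <- vector("list", policy$era_len)
  for (s in seq_len(policy$era_len)) {
    vals <- step_once(vals, kinds, dt, grid, r)
    t <- t + dt
    hrows[[s]] <- c(t, max(node_mag(vals, kinds)))
    # end the era early if a regular node has crossed W_max: the focusing
    # growth is so fast there that waiting for the era boundary would let
    # the tip outrun the implicit solver
    if (any(abs(vals[kinds == 0L]) >= policy$W_max)) {
      hrows <- hrows[seq_len(s)]
      break
    }
  }
  hmat <- do.call(rbind, hrows)
  history <- rbind(history, data.frame(t = hmat[, 1], A = hmat[, 2]))
  part <- detect_and_partition(vals, kinds, history, policy, grid)
  if (part$changed) {
    flip <- part$kinds != kinds
    vals[flip] <- 1 / vals[flip]
    kinds <- part$kinds
  }
  list(state = list(t = t, vals = vals, kinds = kinds),
       history = history, detection = part$detection)
}

#' Locate the infinity crossings inside the buffers
#'
#' Zero crossings of the good variable `v` inside buffer regions, located
#' by linear interpolation. At most two crossings are supported (the
#' generic 1D scenario: one touch opening into a left- and a
#' right-propagating crossing).
#'
#' @param state List with `t`, `vals`, `kinds`.
#' @param grid A [grid1d()].
#' @return A one-row data frame `t, x_left, x_right` (`NA` where absent),
#'   or `NULL` if there are no buffers.
#' @export
track_crossings <- function(state, grid) {
  runs <- region_runs(state$kinds)
  runs <- runs[runs[, 3] == 1L, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  xs <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    idx <- runs[i, 1]:runs[i, 2]
    v <- state$vals[idx]
    sgn <- sign(v)
    ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (j in ch) {
      x1 <- grid$x[idx[j]]; x2 <- grid$x[idx[j + 1]]
      v1 <- v[j]; v2 <- v[j + 1]
      xs <- c(xs, x1 - v1 * (x2 - x1) / (v2 - v1))
    }
    zero <- which(v == 0)
    xs <- c(xs, grid$x[idx[zero]])
  }
  if (length(xs) > 2) stop("unsupported scenario: more than two crossings")
  if (!length(xs)) return(data.frame(t = state$t, x_left = NA_real_,
                                     x_right = NA_real_))
  data.frame(t = state$t, x_left = min(xs),
             x_right = if (length(xs) == 2) max(xs) else NA_real_)
}

#' Quadratic fit of the collapsing tip
#'
#' Least-squares fit `v ~ c0 + c2 (x - x0)^2` over a window around the tip:
#' near collapse the good field behaves like a rising parabola cutting
#' through zero, so `c2 > 0` and the root of `c0(t)` estimates the first
#' touch time.
#'
#' @param x Node coordinates.
#' @param v Good-variable values at those nodes.
#' @param x0 Tip abscissa.
#' @param halfwidth Window half-width (same units as `x`).
#' @return List with `c0`, `c2`.
#' @export
parabola_tip_check <- function(x, v, x0, halfwidth) {
  sel <- abs(x - x0) <= halfwidth
  if (sum(sel) < 3) stop("tip window too narrow for a parabola fit")
  X <- (x[sel] - x0)^2
  fit <- stats::lsfit(X, v[sel])
  c0 <- unname(fit$coefficients[1]); c2 <- unname(fit$coefficients[2])
  c2_floor <- 1e-10 * max(1, max(abs(v[sel]))) / halfwidth^2
  if (!is.finite(c2) || c2 <= c2_floor)
    stop("non-parabolic tip: fitted curvature is not positive")
  list(c0 = c0, c2 = c2)
}

#' Track the tip parabola over time and estimate the touch time
#'
#' Applies [parabola_tip_check()] to a sequence of profiles and estimates
#' the zero-crossing time of `c0(t)` by a linear fit.
#'
#' @param t Times.
#' @param V Matrix of good-variable profiles (rows = times).
#' @param x Node coordinates.
#' @param x0 Tip abscissa.
#' @param halfwidth Window half-width.
#' @return List with `c0` (vector), `c2` (mean curvature), `t_star_fit`.
#' @export
parabola_tip_track <- function(t, V, x, x0, halfwidth) {
  fits <- lapply(seq_along(t), function(i)
    parabola_tip_check(x, V[i, ], x0, halfwidth))
  c0 <- vapply(fits, `[[`, numeric(1), "c0")
  c2 <- mean(vapply(fits, `[[`, numeric(1), "c2"))
  lf <- stats::lsfit(t, c0)
  t_star <- -unname(lf$coefficients[1]) / unname(lf$coefficients[2])
  list(c0 = c0, c2 = c2, t_star_fit = t_star)
}

#' Configuration for a full buffered PDE run
#'
#' @param N Grid nodes; `dt` must satisfy `dt <= h^2/4` (explicit interface
#'   step stability), enforced here.
#' @param dt Time step.
#' @param t_end Final time.
#' @param a,c Initial-data parameters: `u(x, 0) = a cos(2x) + c`.
#' @param r Level set whose crossing is continued (`w = 1/(u - r)`).
#' @param policy A [buffer_policy()].
#' @param snap_every Store a snapshot every this many eras (snapshots are
#'   always stored while `max|w|` is inside the detection window
#'   `[50, 2 W_max]`).
#' @return Validated list of class `pde_config`.
#' @export
pde_config <- function(N = 401L, dt = 1e-5, t_end = 0.35, a = 0.4, c = 1.5,
                       r = 1, policy = buffer_policy(), snap_every = 50L) {
  g <- grid1d(N)
  if (dt > g$h^2 / 4)
    stop("dt = ", dt, " violates the interface stability bound h^2/4 = ",
         signif(g$h^2 / 4, 4))
  structure(list(N = as.integer(N), dt = dt, t_end = t_end, a = a, c = c,
                 r = r, policy = policy, snap_every = as.integer(snap_every),
                 grid = g),
            class = "pde_config")
}

#' Closed-form reference solution of the level-set example
#'
#' The underlying linear field is `u(x,t) = a e^{-5t} cos(2x) + c e^{-t}`;
#' the bad field is `w = 1/(u - r)`. Used only by oracle tests, never by
#' the solver.
#'
#' @param x,t Evaluation points.
#' @param a,c,r Model parameters.
#' @return List with `u` and `w`.
#' @export
pde_oracle <- function(x, t, a = 0.4, c = 1.5, r = 1) {
  u <- a * exp(-5 * t) * cos(2 * x) + c * exp(-t)
  list(u = u, w = 1 / (u - r))
}

# compose per-node |w| magnitude and 1/|w| from a mixed-representation state
compose_mag <- function(vals, kinds) {
  mag <- abs(vals)
  b <- kinds == 1L
  mag[b] <- 1 / abs(vals[b])
  inv <- abs(vals)
  inv[!b] <- 1 / abs(vals[!b])
  list(mag = mag, inv = inv)
}

#' Run the buffered PDE solver end to end
#'
#' Starts from `w(x, 0) = 1/(u(x,0) - r)` on a single regular region and
#' advances era by era: growth of the tip is monitored, the first buffer is
#' opened once `|w|` reaches `W_max` and the power-law check passes, the
#' zero crossing of `v = 1/w` is tracked, and the buffer splits around the
#' two separating crossings (five-region topology) once the interior has
#' receded from infinity.
#'
#' @param config A [pde_config()].
#' @return List of class `pde_run` with `config`, `detection` (`p_hat`,
#'   `alpha`, `fit_r2`), `history` (per-step `t`, `A = max|w|`), `locus`
#'   (crossing abscissae per era), `snapshots` (list of `t`, `vals`,
#'   `kinds`), `topology` (era-wise region counts), `t_first_touch`,
#'   `tip` (parabola-fit track) and the final `state`.
#' @export
run_full <- function(config) {
  g <- config$grid
  pol <- config$policy
  r <- config$r
  state <- list(t = 0,
                vals = 1 / (config$a * cos(2 * g$x) + config$c - r),
                kinds = integer(g$N))
  history <- data.frame(t = numeric(), A = numeric())
  detection <- NULL
  locus <- list(); snaps <- list(); topo <- list(); tip_rows <- list()
  t_first_touch <- NA_real_
  n_era <- ceiling(config$t_end / (config$dt * pol$era_len))
  for (era in seq_len(n_era)) {
    res <- step_era(state, config$dt, g, r, pol, history)
    state <- res$state; history <- res$history
    if (!is.null(res$detection)) detection <- res$detection
    A_now <- utils::tail(history$A, 1)
    cr <- track_crossings(state, g)
    if (!is.null(cr)) {
      locus[[length(locus) + 1L]] <- cr
      if (is.na(t_first_touch) && !is.na(cr$x_left)) t_first_touch <- cr$t
    }
    in_window <- A_now >= 50 && A_now <= 2 * pol$W_max
    if (in_window || era %% config$snap_every == 0L) {
      snaps[[length(snaps) + 1L]] <-
        list(t = state$t, vals = state$vals, kinds = state$kinds)
    }
    runs_now <- region_runs(state$kinds)
    if (sum(runs_now[, 3] == 1L) == 1L) {
      bruns <- runs_now[runs_now[, 3] == 1L, , drop = FALSE]
      idx <- bruns[1, 1]:bruns[1, 2]
      imin <- idx[which.min(abs(state$vals[idx]))]
      fit <- tryCatch(
        parabola_tip_check(g$x[idx], state$vals[idx], g$x[imin], 8 * g$h),
        error = function(e) NULL)
      if (!is.null(fit))
        tip_rows[[length(tip_rows) + 1L]] <- c(state$t, fit$c0, fit$c2)
    }
    topo[[era]] <- c(state$t, nrow(region_runs(state$kinds)))
  }
  tip <- NULL
  if (length(tip_rows) >= 3) {
    tm <- do.call(rbind, tip_rows)
    lf <- stats::lsfit(tm[, 1], tm[, 2])
    tip <- list(t = tm[, 1], c0 = tm[, 2], c2 = mean(tm[, 3]),
                t_star_fit = -unname(lf$coefficients[1]) /
                  unname(lf$coefficients[2]))
  }
  tp <- do.call(rbind, topo)
  structure(list(config = config, detection = detection, history = history,
                 locus = if (length(locus)) do.call(rbind, locus) else NULL,
                 snapshots = snaps,
                 topology = data.frame(t = tp[, 1], regions = tp[, 2]),
                 t_first_touch = t_first_touch, tip = tip, state = state),
            class = "pde_run")
}

#' @export
print.pde_run <- function(x, ...) {
  cat("<pde_run> N =", x$config$N, ", dt =", x$config$dt,
      ", t_end =", x$config$t_end, "\n")
  if (!is.null(x$detection))
    cat(sprintf("  detected growth power p_hat = %.4f (alpha = %.4f, r2 = %.5f)\n",
                x$detection$p_hat, x$detection$alpha, x$detection$fit_r2))
  cat("  region topology reached:", max(x$topology$regions), "\n")
  if (!is.na(x$t_first_touch))
    cat("  first infinity touch near t =", signif(x$t_first_touch, 6), "\n")
  invisible(x)
}

#' Integrate the linear heat-decay equation by method of lines
#'
#' Solves `u_t = u_xx - u` (the good equation with zero offset) with
#' Neumann conditions on `[0, pi]`, second-order central differences and
#' an adaptive stiff integrator. Used to verify mode-decay rates
#' independently of the buffered solver.
#'
#' @param u0 Initial nodal values, or a function of `x`.
#' @param t_out Output times.
#' @param N Grid nodes.
#' @param r Constant offset (`u_t = u_xx - u - r`).
#' @param rtol,atol Integrator tolerances.
#' @return List with `x`, `t`, and matrix `u` (rows = times).
#' @export
integrate_linear_pde <- function(u0, t_out, N = 401L, r = 0,
                                 rtol = 1e-10, atol = 1e-12) {
  g <- grid1d(N)
  u0v <- if (is.function(u0)) u0(g$x) else u0
  stopifnot(length(u0v) == N)
  fun <- function(t, u, p) list(good_rhs(u, g, r))
  out <- deSolve::ode.1D(u0v, t_out, fun, parms = NULL, nspec = 1L,
                         method = "lsoda", rtol = rtol, atol = atol)
  list(x = g$x, t = out[, 1], u = out[, -1, drop = FALSE])
}

#' Cosine-mode amplitude of a Neumann profile
#'
#' Trapezoid-rule projection `(2/pi) * integral of u(x) cos(k x) dx` on
#' `[0, pi]` (`1/pi` for `k = 0`).
#'
#' @param u Nodal values on a uniform grid spanning `[0, pi]`.
#' @param x Node coordinates.
#' @param k Mode number.
#' @return Scalar amplitude.
#' @export
cos_mode_amplitude <- function(u, x, k) {
  w <- rep(1, length(x)); w[c(1, length(x))] <- 0.5
  h <- x[2] - x[1]
  val <- sum(w * u * cos(k * x)) * h
  if (k == 0) val / pi else 2 * val / pi
}
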
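# Buffered domain-decomposition PDE solver (small grids; the full-resolution
# run lives in the acceptance tests).

small_cfg <- function(t_end = 0.35, N = 101, dt = 1e-4, W_max = 1e3,
                      margin = 3L) {
  pde_config(N = N, dt = dt, t_end = t_end,
             policy = buffer_policy(W_max = W_max, margin = margin))
}

test_that("grid and config invariants are enforced", {
  g <- grid1d(101)
  expect_equal(g$h, pi / 100)
  expect_error(grid1d(41), "at least 51")
  expect_error(pde_config(N = 101, dt = 1e-2), "stability bound")
  expect_error(buffer_policy(W_max = 10), "W_max")
})

test_that("bad PDE right-hand side is the exact transform of the linear flow", {
  # uniform state: spatial terms vanish, the ODE w + r w^2 remains
  g <- grid1d(256 + 1)
  expect_equal(bad_rhs(rep(7, g$N), g, 2), rep(7 + 2 * 49, g$N))
  expect_error(bad_rhs(c(rep(1, 100), 0, rep(1, g$N - 101)), g, 1),
               "division error")
  # identity check with spectrally accurate derivatives: for w = 1/(u - 1)
  # with u the two-mode linear solution, w_t = -u_t w^2 must equal
  # w_xx - (2/w) w_x^2 + w + r w^2
  u <- 0.4 * cos(2 * g$x) + 1.5
  w <- 1 / (u - 1)
  ut <- -2 * cos(2 * g$x) - 1.5            # u_xx - u at t = 0
  wx <- spectral_d(w, 1); wxx <- spectral_d(w, 2)
  resid <- (wxx - (2 / w) * wx^2 + w + w^2) - (-ut * w^2)
  expect_lt(max(abs(resid)), 1e-6)
  # the finite-difference operator agrees to its truncation order
  g4 <- grid1d(401)
  u4 <- 0.4 * cos(2 * g4$x) + 1.5
  w4 <- 1 / (u4 - 1)
  ut4 <- -2 * cos(2 * g4$x) - 1.5
  expect_lt(max(abs(bad_rhs(w4, g4, 1) - (-ut4 * w4^2)) / (1 + abs(ut4 * w4^2))),
            5e-3)
})

test_that("good PDE right-hand side is linear with the expected fixed points", {
  g <- grid1d(101)
  expect_equal(good_rhs(rep(0, g$N), g, 1.3), rep(-1.3, g$N))
  expect_equal(good_rhs(rep(-1.3, g$N), g, 1.3), rep(0, g$N))
  # v = u - 1 gives residual at the truncation level of the scheme
  v <- 0.4 * cos(2 * g$x) + 0.5
  ut <- -2 * cos(2 * g$x) - 1.5
  expect_lt(max(abs(good_rhs(v, g, 1) - ut)), 1e-3)
})

test_that("partition detection opens a centered buffer after the power-law check", {
  g <- grid1d(101)
  pol <- buffer_policy(W_max = 1e3, margin = 3L)
  # pre-touch oracle history of max|w| passes the check with alpha ~ -1
  th <- seq(0.30, 0.3315, by = 1e-4)
  hist <- data.frame(t = th,
                     A = 1 / abs(1.5 * exp(-th) - 0.4 * exp(-5 * th) - 1))
  w <- pde_oracle(g$x, 0.3315)$w
  part <- detect_and_partition(w, integer(g$N), hist, pol, g)
  expect_false(is.null(part$detection))
  expect_lt(abs(part$detection$alpha + 1), 0.05)
  runs <- blowthrough:::region_runs(part$kinds)
  expect_identical(nrow(runs), 3L)
  buf <- runs[runs[, 3] == 1L, , drop = FALSE]
  expect_equal(mean(g$x[buf[1, 1:2]]), pi / 2, tolerance = 0.05)
  # initial data: single regular region
  part0 <- detect_and_partition(pde_oracle(g$x, 0)$w, integer(g$N),
                                hist[1:6, ], pol, g)
  expect_true(all(part0$kinds == 0L))
  # non-power-law growth is refused
  lin <- data.frame(t = th, A = 10 + 3e4 * (th - 0.3))
  expect_error(detect_and_partition(w, integer(g$N), lin, pol, g),
               "not self-similar")
  # buffer touching the boundary is unsupported
  wb <- rep(1, g$N); wb[1:5] <- 2e3
  expect_error(detect_and_partition(wb, integer(g$N), hist, pol, g),
               "domain boundary")
})

test_that("pre-collapse solution tracks the oracle and refines at first order", {
  run1 <- run_full(small_cfg(t_end = 0.2, N = 101, dt = 1.2e-4))
  g1 <- run1$config$grid
  err1 <- max(abs(run1$state$vals - pde_oracle(g1$x, run1$state$t)$w) /
                abs(pde_oracle(g1$x, run1$state$t)$w))
  expect_lt(err1, 5e-3)
  run2 <- run_full(small_cfg(t_end = 0.2, N = 201, dt = 6e-5))
  g2 <- run2$config$grid
  err2 <- max(abs(run2$state$vals - pde_oracle(g2$x, run2$state$t)$w) /
                abs(pde_oracle(g2$x, run2$state$t)$w))
  expect_gt(err1 / err2, 1.8)
})

test_that("full run crosses infinity through the 1 -> 3 -> 5 region sequence", {
  run <- run_full(small_cfg())
  expect_identical(rle(run$topology$regions)$values, c(1, 3, 5))
  # first touch agrees with the root of min_x u(x, t) = 1
  t_touch <- stats::uniroot(function(t) 1.5 * exp(-t) - 0.4 * exp(-5 * t) - 1,
                            c(0.2, 0.4), tol = 1e-12)$root
  expect_lt(abs(run$t_first_touch - t_touch),
            5 * run$config$dt * run$config$policy$era_len)
  # detected exponent ~ -1
  expect_lt(abs(run$detection$alpha + 1), 0.2)
  # solution and locus stay symmetric about pi/2
  w <- run$state$vals
  expect_lt(max(abs(w - rev(w))) / max(abs(w)), 1e-8)
  locus <- utils::tail(run$locus[!is.na(run$locus$x_right), ], 1)
  expect_lt(abs((locus$x_left + locus$x_right) / 2 - pi / 2), 1e-8)
  # crossing abscissae match the oracle level set to 2h
  xc <- stats::uniroot(function(x) pde_oracle(x, locus$t)$u - 1,
                       c(1e-3, pi / 2), tol = 1e-12)$root
  expect_lt(abs(locus$x_left - xc), 2 * run$config$grid$h)
  # crossings separate monotonically
  both <- run$locus[!is.na(run$locus$x_right), ]
  expect_true(all(diff(both$x_right - both$x_left) > -1e-12))
  # no stored value ever exceeds 10 * W_max
  expect_lt(max(abs(run$state$vals)), 10 * run$config$policy$W_max)
  # the inner regular region carries w returning from minus infinity
  runs <- blowthrough:::region_runs(run$state$kinds)
  inner <- runs[runs[, 3] == 0L, , drop = FALSE]
  expect_identical(nrow(inner), 3L)
  mid <- inner[2, 1]:inner[2, 2]
  expect_true(all(run$state$vals[mid] < 0))
  expect_gt(max(abs(run$state$vals[mid])), 100)
})

test_that("interface conversions preserve v * w = 1 at partition changes", {
  run <- run_full(small_cfg(t_end = 0.33))
  st <- run$state
  # the two representations composed at any node satisfy v * w = 1
  w_all <- ifelse(st$kinds == 1L, 1 / st$vals, st$vals)
  v_all <- ifelse(st$kinds == 1L, st$vals, 1 / st$vals)
  expect_lt(max(abs(v_all * w_all - 1)), 1e-12)
  # and the composed field is consistent across interfaces relative to
  # the oracle there
  g <- run$config$grid
  orc <- pde_oracle(g$x, st$t)
  edges <- which(diff(st$kinds) != 0L)
  for (i in edges) {
    for (j in c(i, i + 1L)) {
      wj <- if (st$kinds[j] == 1L) 1 / st$vals[j] else st$vals[j]
      expect_lt(abs(wj - orc$w[j]) / abs(orc$w[j]), 0.2)
    }
  }
})

test_that("tip behaves as a rising parabola crossing zero", {
  # idealized shifting parabola: v = x^2 + (0.1 - 0.1 t)
  x <- seq(-1, 1, length.out = 81)
  ts <- seq(0, 0.6, by = 0.1)
  V <- t(vapply(ts, function(tt) x^2 + (0.1 - 0.1 * tt), numeric(81)))
  fit <- parabola_tip_track(ts, V, x, 0, halfwidth = 0.5)
  expect_equal(fit$c2, 1, tolerance = 1e-10)
  expect_equal(fit$c0, 0.1 - 0.1 * ts, tolerance = 1e-10)
  expect_equal(fit$t_star_fit, 1, tolerance = 1e-10)
  # a flat profile is not a parabolic tip
  expect_error(parabola_tip_check(x, rep(1, 81), 0, 0.5), "non-parabolic")
  # on the real run the fitted touch time agrees with the observed one
  run <- run_full(small_cfg())
  expect_false(is.null(run$tip))
  expect_lt(abs(run$tip$t_star_fit - run$t_first_touch), 5e-3)
})

test_that("crossing tracker reports at most two interpolated crossings", {
  g <- grid1d(101)
  # construct a buffered state from the oracle shortly after touch
  tt <- 0.34
  orc <- pde_oracle(g$x, tt)
  kinds <- as.integer(abs(orc$w) >= 1e3)
  # widen by margin like the solver does
  idx <- which(kinds == 1L)
  kinds[max(1, min(idx) - 3):min(g$N, max(idx) + 3)] <- 1L
  vals <- ifelse(kinds == 1L, orc$u - 1, orc$w)
  cr <- track_crossings(list(t = tt, vals = vals, kinds = kinds), g)
  expect_identical(nrow(cr), 1L)
  xl <- stats::uniroot(function(x) pde_oracle(x, tt)$u - 1, c(1, pi / 2),
                       tol = 1e-12)$root
  expect_lt(abs(cr$x_left - xl), g$h)
  expect_lt(abs((cr$x_left + cr$x_right) / 2 - pi / 2), 1e-10)
})
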
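# Regime-switching integration through blow-up.

test_that("quadratic blow-up is continued through infinity along the closed form", {
  pr <- get_model("power_p2")
  traj <- integrate_crossing(pr$problem, 1, c(0, 2))
  expect_equal(crossing_times(traj), 1, tolerance = 1e-6)
  expect_equal(final_state(traj), -1, tolerance = 1e-6)
  # oracle equivalence at all sampled times with |x| <= switch_high
  for (seg in traj$segments) {
    if (seg$regime != "bad") next
    x <- Re(seg$state[, 1])
    keep <- abs(x) <= 100 & abs(seg$t - 1) > 1e-6
    ora <- vapply(seg$t[keep], function(tt) Re(pr$oracle(tt)), numeric(1))
    expect_lt(max(abs(x[keep] - ora) / pmax(1, abs(ora))), 1e-6)
  }
})

test_that("the good variable of the quadratic model is exactly linear", {
  pr <- get_model("power_p2")
  traj <- integrate_crossing(pr$problem, 1, c(0, 2))
  good <- traj$segments[[which(vapply(traj$segments, `[[`, "", "regime") == "good")[1]]]
  fit <- stats::lsfit(good$t, good$state[, 1])
  expect_lt(abs(unname(fit$coefficients[2]) + 1), 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # strictly decreasing
  expect_true(all(diff(good$state[, 1]) < 0))
})

test_that("state continuity holds under the recorded transform at every switch", {
  mq <- get_model("qif_1d")
  traj <- integrate_crossing(mq$problem, 1, c(0, 10))
  segs <- traj$segments
  for (k in seq_len(length(segs) - 1)) {
    a <- segs[[k]]; b <- segs[[k + 1]]
    xa <- a$state[nrow(a$state), a$comp]
    xb <- b$state[1, b$comp]
    if (a$regime == "bad" && b$regime == "good") {
      y <- b$transform$forward(xa)
      expect_lt(abs(y - xb), 1e-8 * max(1, abs(xb)))
    } else if (a$regime == "good" && b$regime == "bad") {
      x <- a$transform$inverse(Re(xa))
      expect_lt(Mod(x - xb), 1e-8 * max(1, Mod(xb)))
    }
    expect_lt(a$t[length(a$t)], b$t[1] + 1e-12)
  }
})

test_that("periodic blow-up of the quadratic IF model has period pi", {
  mq <- get_model("qif_1d")
  traj <- integrate_crossing(mq$problem, 1, c(0, 10))
  ct <- crossing_times(traj)
  expect_gte(length(ct), 3)
  expect_equal(ct[1], pi / 4, tolerance = 1e-6)
  expect_lt(max(abs(diff(ct) - pi)), 1e-4)
  # matches tan(pi/4 + t) on both sides of the first crossing
  for (seg in traj$segments[1:3]) {
    if (seg$regime != "bad") next
    x <- Re(seg$state[, 1])
    keep <- abs(x) <= 100
    ora <- tan(pi / 4 + seg$t[keep])
    expect_lt(max(abs(x[keep] - ora) / pmax(1, abs(ora))), 5e-6)
  }
})

test_that("cubic blow-up re-enters along the chosen imaginary branch", {
  m3 <- get_model("power_p3")
  traj <- integrate_crossing(m3$problem, 1, c(0, 1), branch = "plus_i")
  expect_true(traj$complex_flag)
  expect_equal(crossing_times(traj), 0.5, tolerance = 1e-6)
  last <- traj$segments[[length(traj$segments)]]
  expect_true(is.complex(last$state))
  xs <- last$state[, 1]
  expect_lt(max(abs(Re(xs))), 1e-8)
  expect_true(all(Im(xs[-1]) > 0))
  # x(t) = i / sqrt(2 (t - t*)) after the crossing
  keep <- last$t > 0.51
  ora <- 1 / sqrt(2 * (last$t[keep] - 0.5))
  expect_lt(max(abs(Im(xs[keep]) - ora) / ora), 1e-4)
  # the minus_i branch mirrors it
  trm <- integrate_crossing(m3$problem, 1, c(0, 1), branch = "minus_i")
  lastm <- trm$segments[[length(trm$segments)]]
  expect_true(all(Im(lastm$state[-1, 1]) < 0))
  # real continuation is a phase-loss error
  expect_error(integrate_crossing(m3$problem, 1, c(0, 1)), "phase loss")
})

test_that("bounded dynamics never trigger a detection", {
  md <- get_model("linear_minus")
  traj <- integrate_crossing(md$problem, 1, c(0, 5))
  expect_identical(nrow(traj$events), 0L)
  expect_identical(length(traj$segments), 1L)
  # a fixed point stays put
  pr <- ode_problem(function(x, p) x^2)
  tr0 <- integrate_crossing(pr, 0, c(0, 1))
  expect_identical(nrow(tr0$events), 0L)
  expect_equal(final_state(tr0), 0)
})

test_that("asymptotically self-similar blow-up converges to the transformed steady state", {
  ma <- get_model("asymptotic_quad")
  traj <- integrate_crossing(ma$problem, 1, c(0, 10))
  expect_equal(crossing_times(traj), 0.5 * log(3), tolerance = 1e-5)
  expect_equal(1 / final_state(traj), -0.5, tolerance = 1e-6)
})

test_that("threshold reached without self-similar growth halts integration", {
  mg <- get_model("linear_plus")
  expect_error(integrate_crossing(mg$problem, 1, c(0, 8)),
               "not asymptotically self-similar")
})

test_that("quartic IF model crosses infinity with bounded adaptation variable", {
  m4 <- get_model("quartic_2d")
  traj <- integrate_crossing(m4$problem, c(1, 0.1), c(0, 1))
  expect_gte(length(crossing_times(traj)), 1)
  det <- traj$events[traj$events$type == "switch_bad_to_good", ]
  expect_equal(det$p_hat[1], 4)
  u_all <- unlist(lapply(traj$segments, function(s) Re(s$state[, 2])))
  expect_lt(max(abs(u_all)), 5)
  # voltage re-emerges from minus infinity through the good variable
  oc <- original_component(traj)
  expect_lt(min(oc$x.re), -5)
  post <- traj$segments[[length(traj$segments)]]
  expect_true(any(Re(post$state[, 1]) < -4))
  # the companion-divergence diagnostic accepts this model
  expect_true(check_bounded_companions(traj)$ok)
})

test_that("2D quadratic IF crosses infinity after polar decomposition", {
  pp <- polar_decompose(get_model("qif_2d")$problem)
  traj <- integrate_crossing(pp, pp$to_polar(c(1, 0.1)), c(0, 1.5))
  expect_gte(length(crossing_times(traj)), 1)
  # the voltage v = rho sin(theta) visits both infinities around t*
  vu <- do.call(rbind, lapply(traj$segments, function(s) {
    if (s$regime != "bad") return(NULL)
    t(apply(Re(s$state), 1, pp$from_polar))
  }))
  expect_gt(max(vu[, 1]), 90)
  expect_lt(min(vu[, 1]), -40)
})

test_that("trajectories flatten to tidy data frames", {
  pr <- get_model("power_p2")
  traj <- integrate_crossing(pr$problem, 1, c(0, 2))
  df <- as.data.frame(traj)
  expect_true(all(c("t", "x1", "regime", "segment") %in% names(df)))
  expect_true(all(diff(df$t) >= 0))
  oc <- original_component(traj)
  expect_equal(names(oc), c("t", "x.re", "x.im"))
  expect_equal(utils::tail(oc$x.re, 1), -1, tolerance = 1e-6)
})
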
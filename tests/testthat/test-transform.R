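# Singular transformations, transformed subsystems, polar decomposition.

test_that("power transforms invert exactly away from the level", {
  for (p in c(2, 3, 4)) {
    tr <- singular_transform("power", exponent = 1 - p)
    for (x in c(0.5, 3, 47, 1e3)) {
      expect_lt(abs(tr$inverse(tr$forward(x)) - x), 1e-12 * abs(x))
    }
  }
  # odd inverse exponent also covers negative states
  tr2 <- singular_transform("power", exponent = -1)
  for (x in c(-250, -1.5)) {
    expect_lt(abs(tr2$inverse(tr2$forward(x)) - x), 1e-12 * abs(x))
  }
  expect_equal(singular_transform(exponent = -1, level = 2)$forward(102), 0.01)
})

test_that("chain rule produces the exact good equations of the worked models", {
  det2 <- structure(list(p_hat = 2, alpha = -1, t_switch = 0, x_switch = 100,
                         sign = 1, fit_r2 = 1), class = "blowup_detection")
  # pure quadratic: dy/dt = -1 everywhere, including the crossing itself
  g <- build_transform(det2, ode_problem(function(x, p) x^2))$good_problem
  for (y in c(0.01, 0, -0.01)) expect_equal(g$rhs(y, list()), -1)
  # quadratic integrate-and-fire: dy/dt = -1 - I y^2
  gq <- build_transform(det2, get_model("qif_1d", I = 1.7)$problem)$good_problem
  for (y in c(0.02, 0, -0.02)) {
    expect_equal(gq$rhs(y, list(I = 1.7)), -1 - 1.7 * y^2, tolerance = 1e-12)
  }
  # asymptotically self-similar case: dy/dt = -2y - 1 (full rhs, not just
  # the dominant term)
  ga <- build_transform(det2, get_model("asymptotic_quad")$problem)$good_problem
  for (y in c(0.05, 0, -0.05)) {
    expect_equal(ga$rhs(y, list()), -2 * y - 1, tolerance = 1e-12)
  }
  # cubic: y = 1/x^2 travels at dy/dt = -2
  det3 <- structure(list(p_hat = 3, alpha = -0.5, t_switch = 0,
                         x_switch = 100, sign = 1, fit_r2 = 1),
                    class = "blowup_detection")
  g3 <- build_transform(det3, ode_problem(function(x, p) x^3),
                        branch = "plus_i")$good_problem
  expect_equal(g3$rhs(1e-4, list()), -2, tolerance = 1e-10)
  expect_equal(g3$rhs(0, list()), -2, tolerance = 1e-10)
})

test_that("integral transform reduces any scalar blow-up to dy/dt = -1", {
  f <- function(s) s^2
  tr <- singular_transform("integral", f = f)
  expect_equal(tr$forward(10), 0.1, tolerance = 1e-9)
  expect_equal(tr$inverse(tr$forward(25)), 25, tolerance = 1e-6)
  # dy/dt = -f(x)/f(x) = -1: forward derivative times rhs
  x <- 50
  dydx <- (tr$forward(x + 1e-4) - tr$forward(x - 1e-4)) / 2e-4
  expect_equal(dydx * f(x), -1, tolerance = 1e-6)
  # non-integrable tail must be refused
  expect_error(singular_transform("integral", f = identity)$forward(10),
               "transform undefined")
})

test_that("branch policy governs reentry through the multivalued inverse", {
  tr <- singular_transform("power", exponent = -2, branch = "plus_i")
  expect_equal(tr$inverse(-0.01), complex(real = 0, imaginary = 10))
  trm <- singular_transform("power", exponent = -2, branch = "minus_i")
  expect_equal(trm$inverse(-0.01), complex(real = 0, imaginary = -10))
  trr <- singular_transform("power", exponent = -2)
  expect_error(trr$inverse(-0.01), "phase loss")
  # pre-crossing real branch follows the divergence sign
  trneg <- singular_transform("power", exponent = -2, sign = -1)
  expect_equal(trneg$inverse(1e-4), -100)
})

test_that("transforming one component leaves the others untouched", {
  quartic <- get_model("quartic_2d")$problem
  good <- transform_subsystem(quartic, 1, -3)
  # at the crossing (y = 0) the transformed voltage equation gives -3 and
  # the adaptation variable keeps its own dynamics
  st <- c(0, 0.25)
  f <- good$rhs(st, quartic$params)
  expect_equal(f[1], -3, tolerance = 1e-12)
  # identity exponent returns the problem unchanged
  expect_identical(transform_subsystem(quartic, 1, 1), quartic)
})

test_that("transformed subsystem matches hand-derived chain rule", {
  # quartic IF with y = 1/v^3: dy/dt = -3[(I-u) sign(y)|y|^{4/3} + 1 + 2y],
  # du/dt = b y^{-1/3} - u
  quartic <- get_model("quartic_2d")$problem
  good <- transform_subsystem(quartic, 1, -3)
  pm <- quartic$params
  for (y in c(0.2, 0.01, -0.01, -0.2)) {
    u <- 0.3
    f <- good$rhs(c(y, u), pm)
    v <- blowthrough:::spow(y, -1 / 3)
    expect_equal(f[1], -3 * v^(-4) * (pm$I + v^4 + 2 * v - u),
                 tolerance = 1e-10)
    expect_equal(f[2], pm$b * v - u, tolerance = 1e-12)
  }
})

test_that("polar decomposition is the exact chain rule in (rho, theta)", {
  qif2 <- get_model("qif_2d")$problem
  pp <- polar_decompose(qif2)
  # worked value: at (rho, theta) = (1, pi/2), I = 1:
  # drho/dt = 1*1 - 0 + 1 = 2, dtheta/dt = 0 - 1 + 0 + 0 = -1
  f <- pp$rhs(c(1, pi / 2), pp$params)
  expect_equal(f, c(2, -1), tolerance = 1e-12)
  # agrees with the printed (rho, theta) system for b = 1 on a grid
  rhs55 <- function(rho, th, I) {
    c(rho^2 * sin(th)^3 - rho * cos(th)^2 + I * sin(th),
      sign(rho) * rho * sin(th)^2 * cos(th) - 1 + cos(th) * sin(th) +
        I / rho * cos(th))
  }
  for (rt in list(c(1, pi / 2), c(2, 0.3), c(0.5, 2.2), c(10, 1.4))) {
    expect_equal(pp$rhs(rt, pp$params), rhs55(rt[1], rt[2], 1),
                 tolerance = 1e-12)
  }
  # polar round trip
  vu <- c(1, 0.1)
  rt <- pp$to_polar(vu)
  expect_equal(rt, c(sqrt(1.01), atan2(1, 0.1)), tolerance = 1e-12)
  expect_equal(pp$from_polar(rt), vu, tolerance = 1e-12)
  # the angular equation carries I/rho: evaluation at rho = 0 must fail
  expect_error(pp$rhs(c(0, 1), pp$params), "rho = 0")
  expect_error(polar_decompose(ode_problem(function(x, p) x^2)), "2D")
})

test_that("transforming a bounded component is caught by the divergence guard", {
  # in the 2D quadratic model both components blow up; transforming only
  # the voltage makes the adaptation variable's dynamics non-integrable at
  # the crossing (du/dt ~ 1/y), which the diagnostic flags
  qif2 <- get_model("qif_2d")$problem
  traj <- tryCatch(integrate_crossing(qif2, c(1, 0.1), c(0, 1)),
                   error = function(e) e)
  if (inherits(traj, "error")) {
    expect_match(conditionMessage(traj), "diverging|non-finite")
  } else {
    diag <- check_bounded_companions(traj)
    expect_false(diag$ok)
    expect_lt(diag$slopes[1], -0.9)
  }
  # the legitimate single-blow-up model passes the same diagnostic
  m4 <- get_model("quartic_2d")
  tr4 <- integrate_crossing(m4$problem, c(1, 0.1), c(0, 1))
  d4 <- check_bounded_companions(tr4)
  expect_true(d4$ok)
  expect_gt(d4$slopes[1], -0.6)
})
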
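test_that("piecewise-linear evaluation interpolates and extends as constant", {
  f <- piecewise_linear(c(0, 1), c(2, 4))
  expect_equal(plf_eval(f, 0.5), 3)
  expect_equal(plf_eval(f, c(0, 1)), c(2, 4))   # breakpoints keep their values
  expect_equal(plf_eval(f, 7), 4)               # constant beyond the end
  expect_equal(plf_eval(f, -1), 2)
  g <- plf_const(0.1)
  expect_equal(plf_eval(g, 0.7), 0.1)
  h <- piecewise_linear(c(0, 1, 2), c(1, 3, 3))
  expect_equal(plf_eval(h, 1.5), 3)
  # midpoint of any segment is the mean of its endpoint values
  set.seed(42)
  for (i in 1:20) {
    x <- sort(runif(4, 0, 5)); y <- runif(4, 0, 2)
    f <- piecewise_linear(x, y)
    mids <- (x[-1] + x[-4]) / 2
    expect_equal(plf_eval(f, mids), (y[-1] + y[-4]) / 2)
  }
  expect_error(piecewise_linear(c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(piecewise_linear(c(0, 1), c(-1, 0)), "nonnegative")
})

test_that("scaled population size converts to individuals via nu = Ne * tau", {
  expect_equal(pop_size_in_individuals(0.1, 1e-6), 1e5)
  expect_equal(pop_size_in_individuals(0.1, 1e-3), 100)
  expect_equal(pop_size_in_individuals(0.37, 1), 0.37)  # time in generations
  expect_error(pop_size_in_individuals(0.1, 0), "tau")
})

test_that("rational decomposition reproduces the quotient pointwise", {
  d <- rational_decompose(1, 0, 1, 0, 1, 0)
  expect_equal(unlist(d), c(c0 = 1, c1 = 0, c2 = 0, quad = 0))
  d <- rational_decompose(0, 1, 0, 1, 0, 1)   # t * t / t = t
  expect_equal(unlist(d), c(c0 = 0, c1 = 1, c2 = 0, quad = 0))
  expect_error(rational_decompose(1, 1, 1, 1, 0, 0), "degenerate")
  set.seed(7)
  for (i in 1:100) {
    co <- runif(6, -2, 2)
    if (abs(co[5]) < 0.1) co[5] <- 0.5        # keep the pole away from [0,1]
    if (co[5] + co[6] < 0.2) co[6] <- 0.2 - co[5] + abs(co[6])
    d <- rational_decompose(co[1], co[2], co[3], co[4], co[5], co[6])
    t <- seq(0, 1, length.out = 100)
    lhs <- (co[1] + co[2] * t) * (co[3] + co[4] * t) / (co[5] + co[6] * t)
    rhs <- d$c0 + d$c1 * t + d$quad * t^2 + if (co[6] != 0)
      d$c2 / (co[5] + co[6] * t) else 0
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("hazard integrals match closed forms and numerical quadrature", {
  # constant nu = 2, one lineage pair on [0, 1]: 1/nu * dt = 0.5
  expect_equal(integrate_hazard(hazard(den = plf_const(2)), 0, 1), 0.5)
  # constant migration m = 0.1, nu_b = 2, nu_a = 1 over [0, 2]: 0.1*2/1*2
  hm <- hazard(num1 = plf_const(0.1), num2 = plf_const(2), den = plf_const(1))
  expect_equal(integrate_hazard(hm, 0, 2), 0.4)
  # linear denominator: int_0^1 1/(1+t) dt = log 2
  hl <- hazard(den = piecewise_linear(c(0, 1), c(1, 2)))
  expect_equal(integrate_hazard(hl, 0, 1), log(2))
  # additivity over abutting intervals and monotonicity
  expect_equal(integrate_hazard(hl, 0, 0.4) + integrate_hazard(hl, 0.4, 1),
               integrate_hazard(hl, 0, 1))
  # randomized comparison against adaptive quadrature
  set.seed(99)
  for (i in 1:25) {
    n1 <- piecewise_linear(sort(runif(3, 0, 3)), runif(3, 0, 2))
    n2 <- piecewise_linear(sort(runif(2, 0, 3)), runif(2, 0.1, 2))
    de <- piecewise_linear(sort(runif(3, 0, 3)), runif(3, 0.2, 3))
    h <- hazard(num1 = n1, num2 = n2, den = de)
    f <- function(t) plf_eval(n1, t) * plf_eval(n2, t) / plf_eval(de, t)
    a <- runif(1, 0, 1); b <- a + runif(1, 0.5, 3)
    # quadrature piecewise between breakpoints, where f is smooth
    cuts <- sort(unique(c(a, b, Filter(function(x) x > a && x < b,
                                       c(n1$x, n2$x, de$x)))))
    num <- sum(vapply(seq_len(length(cuts) - 1L), function(k)
      stats::integrate(f, cuts[k], cuts[k + 1L], rel.tol = 1e-11)$value, 0))
    expect_equal(integrate_hazard(h, a, b), num, tolerance = 1e-8)
  }
  # nu hitting zero on an occupied stretch is an error
  expect_error(hazard(den = piecewise_linear(c(0, 1), c(1, 0))), "singular")
})

test_that("waiting-time solving inverts the cumulative hazard", {
  # exponential inverse CDF for a constant rate
  h <- hazard(den = plf_const(2))           # rate 1/2
  u <- 1 - exp(-0.25)
  expect_equal(solve_waiting_time(h, 0, u), 0.5)
  expect_equal(solve_waiting_time(h, 3, u), 3.5)     # shift invariance
  # step hazard: zero on [0,1), rate 1 after; target 0.5 -> t = 1.5
  hs <- hazard(den = plf_const(1), window = c(1, Inf))
  expect_equal(solve_waiting_time(hs, 0, 1 - exp(-0.5)), 1.5)
  # u = 0 maps to the infimum time with positive hazard
  expect_equal(solve_waiting_time(h, 0.3, 0), 0.3)
  expect_equal(solve_waiting_time(hs, 0, 0), 1)
  # horizon censors to infinity
  expect_identical(solve_waiting_time(h, 0, 1 - exp(-10), horizon = 1), Inf)
  # zero scale (impossible event) is censored immediately
  expect_identical(solve_waiting_time(h, 0, 0.5, scale = 0), Inf)
  # monotone nondecreasing in u
  us <- seq(0.05, 0.95, by = 0.05)
  ts <- vapply(us, function(u) solve_waiting_time(h, 0, u), 0)
  expect_true(all(diff(ts) > 0))
})

test_that("round trip: integrate then invert recovers the time", {
  set.seed(11)
  for (i in 1:40) {
    h <- random_hazard()
    t0 <- runif(1, 0, 1)
    t1 <- t0 + runif(1, 0.1, 3)
    if (t1 <= h$lo || t1 >= h$hi) next       # identity holds inside the window
    I <- integrate_hazard(h, t0, t1)
    if (I <= 0 || I > 8) next
    t <- solve_waiting_time(h, t0, 1 - exp(-I))
    expect_equal(t, t1, tolerance = 1e-9)
  }
})

test_that("constant-rate waiting times are exponential (KS)", {
  set.seed(123)
  h <- hazard(den = plf_const(0.5))        # rate 2
  x <- vapply(runif(10000), function(u) solve_waiting_time(h, 0, u), 0)
  p <- ks_compare(x, function(q) stats::pexp(q, rate = 2))$p.value
  expect_gt(p, 0.01)
})
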
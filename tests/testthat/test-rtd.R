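# RTD model fitting and derived indices.

test_that("a pure exponential is recovered exactly", {
  ser <- synthetic_series(a = c(1, 0, 0), tau = c(5, 5, 5), t_max = 60)
  fit <- fit_concentration(ser)
  expect_equal(mean_residence_time(fit), 5, tolerance = 1e-3)
  expect_lt(fit$c_inf, 1e-6)
  expect_lt(fit$rms, 1e-6)
  expect_equal(sum(fit$a), 1, tolerance = 1e-4)
})

test_that("an asymptote plus one mode is recovered", {
  ser <- synthetic_series(a = c(0.7, 0, 0), tau = c(2, 2, 2), c_inf = 0.3,
                          t_max = 40)
  fit <- fit_concentration(ser)
  expect_equal(asymptotic_concentration(fit), 0.3, tolerance = 1e-3)
  expect_equal(mean_residence_time(fit), 2, tolerance = 1e-2)
})

test_that("three well-separated modes are recovered within 1 percent", {
  ser <- synthetic_series(a = c(0.5, 0.3, 0.2), tau = c(1, 10, 100),
                          t_max = 1000, n = 4000)
  fit <- fit_concentration(ser)
  expect_equal(fit$tau, c(1, 10, 100), tolerance = 0.01)
  expect_equal(fit$a, c(0.5, 0.3, 0.2), tolerance = 0.01)
  expect_lt(fit$c_inf, 0.01)
  expect_equal(mean_residence_time(fit), 23.5, tolerance = 0.01)
})

test_that("the RTD function is a normalized density with closed-form
          mean", {
  fit <- structure(list(a = c(1, 0, 0), tau = c(5, 50, 500), c_inf = 0),
                   class = "rtd_fit")
  expect_equal(rtd_function(fit, 0), 0.2)
  q <- integrate(function(t) rtd_function(fit, t), 0, Inf)$value
  expect_equal(q, 1, tolerance = 1e-6)
  # mixed fit: quadrature of t E(t) against the closed form, randomized
  set.seed(9)
  for (i in 1:20) {
    f <- structure(list(a = runif(3, 0.05, 1), tau = sort(10^runif(3, -1, 3)),
                        c_inf = runif(1, 0, 0.5)), class = "rtd_fit")
    tm <- mean_residence_time(f)
    quad <- integrate(function(t) t * rtd_function(f, t), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_lt(abs(tm - quad) / tm, 1e-4)
    expect_true(all(rtd_function(f, c(0, 1, 10)) >= 0))
  }
  bad <- structure(list(a = c(0, 0, 0), tau = c(1, 2, 3), c_inf = 1),
                   class = "rtd_fit")
  expect_error(mean_residence_time(bad), "degenerate")
  expect_error(rtd_function(bad, 1), "degenerate")
})

test_that("refitting a fitted curve is idempotent", {
  ser <- synthetic_series(a = c(0.6, 0.3, 0), tau = c(2, 20, 20),
                          c_inf = 0.1, t_max = 200, n = 2000)
  fit1 <- fit_concentration(ser)
  t <- ser$t
  fit2 <- fit_concentration(list(t = t,
                                 c_laa = predict_concentration(fit1, t)))
  expect_equal(mean_residence_time(fit2), mean_residence_time(fit1),
               tolerance = 1e-3)
  expect_equal(fit2$c_inf, fit1$c_inf, tolerance = 1e-3)
})

test_that("truncation refits stabilize once the window covers the slowest
          mode", {
  ser <- synthetic_series(a = c(0.5, 0.3, 0.2), tau = c(1, 10, 100),
                          t_max = 1200, n = 5000)
  tb <- truncation_study(ser, lengths = c(300, 500, 700, 1000, 1200))
  expect_equal(tb$status, rep("ok", 5))
  truth <- 23.5
  expect_true(all(abs(tb$t_m[tb$length >= 500] - truth) / truth < 0.01))
  one <- truncation_study(ser, lengths = 800)
  expect_equal(nrow(one), 1)
  expect_error(truncation_study(ser, lengths = c(500, 400)), "diff")
})

test_that("rank stability behaves as a Spearman correlation should", {
  vals <- cbind(w1 = c(3, 1, 2, 5, 4), w2 = c(2, 1, 3, 4, 5),
                ref = c(1, 2, 3, 4, 5))
  rs <- rank_stability(vals, reference = "ref")
  expect_equal(rs$rho[rs$length == "ref"], 1)
  rev <- cbind(a = 5:1, ref = 1:5)
  expect_equal(rank_stability(rev, "ref")$rho[1], -1)
  # hand-built Sum d^2 oracle for 5 subjects
  d2 <- sum((rank(vals[, "w1"]) - rank(vals[, "ref"]))^2)
  expect_equal(rs$rho[rs$length == "w1"], 1 - 6 * d2 / (5 * (25 - 1)))
})
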
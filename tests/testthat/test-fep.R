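ctx <- thermo_context()
kT <- ctx$kT

test_that("lambda schedules honour fine/coarse spacing and window counts", {
  sched <- make_lambda_schedule()
  expect_equal(sched$n_windows, 25L)
  expect_length(sched$values, 26L)
  gaps <- diff(sched$values)
  expect_equal(gaps[1:10], rep(0.025, 10), tolerance = 1e-9)
  expect_equal(gaps[11:25], rep(0.05, 15), tolerance = 1e-9)

  expect_equal(make_lambda_schedule(NULL)$n_windows, 20L)
  expect_equal(make_lambda_schedule(c(0, 1))$n_windows, 40L)
  expect_equal(make_lambda_schedule(c(0.5, 0.75))$n_windows, 25L)
  expect_error(make_lambda_schedule(c(0, 0.26)), "divide")
  expect_error(make_lambda_schedule(c(-0.1, 0.2)), "within")
})

test_that("exponential averaging matches degenerate and enumerated cases", {
  # constant samples: the free energy is that constant, exactly
  w <- window_samples(0, 0.05, forward_du = rep(1.25, 10),
                      backward_du = rep(1.25, 10))
  expect_equal(exp_estimator(w, "forward", ctx)$delta_g, 1.25,
               tolerance = 1e-12)
  expect_equal(exp_estimator(w, "backward", ctx)$delta_g, 1.25,
               tolerance = 1e-12)
  expect_equal(exp_estimator(w, "forward", ctx)$stderr, 0)

  # two-point sample {0, c}: direct enumeration of the average
  c0 <- 2.0
  w2 <- window_samples(0, 0.05, forward_du = c(0, c0))
  expect_equal(exp_estimator(w2, "forward", ctx)$delta_g,
               -kT * log((1 + exp(-c0 / kT)) / 2), tolerance = 1e-12)

  expect_error(exp_estimator(window_samples(0, 1, forward_du = 1:5),
                             "backward", ctx), ">= 2")
})

test_that("exponential averaging converges to the Gaussian closed form", {
  mu <- -0.8; sigma <- 0.6
  set.seed(11)
  w <- window_samples(0, 1, forward_du = rnorm(1e6, mu, sigma))
  est <- exp_estimator(w, "forward", ctx)
  expect_lt(abs(est$delta_g - (mu - sigma^2 / (2 * kT))),
            max(4 * est$stderr, 1e-3))
})

test_that("BAR recovers symmetric, Crooks-consistent and reference cases", {
  # same symmetric law in both directions -> dG = 0 within stderr
  set.seed(21)
  w0 <- window_samples(0, 1, rnorm(5000), rnorm(5000))
  est0 <- bar_estimator(w0, ctx)
  expect_lt(abs(est0$delta_g), 3 * est0$stderr)

  # Crooks-consistent Gaussian pair recovers the known truth
  truth <- -1.3; sigma <- 1
  w <- crooks_window(truth, sigma, 5000, seed = 22)
  est <- bar_estimator(w, ctx)
  expect_lt(abs(est$delta_g - truth), 3 * est$stderr)

  # agreement with an independent fixed-point reference on identical data
  expect_lt(abs(est$delta_g -
                  bar_reference(w$forward_du, w$backward_du, kT)), 1e-6)
  # also with unequal sample counts (exercises the nF/nB shift)
  set.seed(23)
  wu <- window_samples(0, 1,
                       rnorm(3000, truth + sigma^2 / (2 * kT), sigma),
                       rnorm(1500, truth - sigma^2 / (2 * kT), sigma))
  expect_lt(abs(bar_estimator(wu, ctx)$delta_g -
                  bar_reference(wu$forward_du, wu$backward_du, kT)), 1e-6)

  expect_error(bar_estimator(window_samples(0, 1, forward_du = 1:5), ctx),
               "both directions")
})

test_that("swapping forward/backward roles negates the BAR estimate", {
  w <- crooks_window(-0.7, 0.9, 2000, seed = 31)
  a <- bar_estimator(w, ctx)$delta_g
  b <- bar_estimator(window_samples(0, 1, -w$backward_du, -w$forward_du),
                     ctx)$delta_g
  expect_lt(abs(a + b), 1e-7)
})

test_that("BAR flags zero phase-space overlap", {
  w <- window_samples(0, 1, forward_du = rnorm(200, 20, 0.1),
                      backward_du = rnorm(200, -20, 0.1))
  est <- suppressWarnings(bar_estimator(w, ctx))
  expect_true(est$overlap_warning)
  wok <- crooks_window(0, 0.5, 200, seed = 41)
  expect_false(bar_estimator(wok, ctx)$overlap_warning)
})

test_that("BAR is at least as efficient as one-sided averaging", {
  # Crooks-consistent data, n = 2000, 10 seeds, 5% slack
  truth <- -0.4; sigma <- 1
  for (seed in 1:10) {
    w <- crooks_window(truth, sigma, 2000, seed = 100 + seed)
    bar_se <- bar_estimator(w, ctx)$stderr
    exp_se <- min(exp_estimator(w, "forward", ctx)$stderr,
                  exp_estimator(w, "backward", ctx)$stderr)
    expect_lte(bar_se, exp_se * 1.05)
  }
})

test_that("BAR error decays as one over root n", {
  truth <- -0.4; sigma <- 1
  ns <- c(1e2, 1e3, 1e4, 1e5)
  mean_err <- vapply(ns, function(n) {
    mean(vapply(1:8, function(s) {
      w <- crooks_window(truth, sigma, n, seed = 1000 + s)
      abs(bar_estimator(w, ctx)$delta_g - truth)
    }, numeric(1)))
  }, numeric(1))
  slope <- unname(coef(stats::lm(log(mean_err) ~ log(ns)))[2])
  expect_lt(abs(slope - (-0.5)), 0.1)
})

test_that("window combination sums free energies and errors in quadrature", {
  mk <- function(dg, se, lo, hi) {
    free_energy_estimate(dg, se, "bar", lambda_low = lo, lambda_high = hi)
  }
  one <- combine_windows(list(mk(-1.2, 0.3, 0, 1)))
  expect_equal(one$delta_g, -1.2)
  expect_equal(one$stderr, 0.3)

  two <- combine_windows(list(mk(1, 0.3, 0, 0.5), mk(-1, 0.4, 0.5, 1)))
  expect_equal(two$delta_g, 0)
  expect_equal(two$stderr, 0.5)

  many <- combine_windows(lapply(1:25, function(i) {
    mk(0.1, 0, (i - 1) / 25, i / 25)
  }))
  expect_equal(many$delta_g, 2.5, tolerance = 1e-12)

  expect_error(combine_windows(list(mk(1, 0, 0, 0.4), mk(1, 0, 0.5, 1))),
               "gap or overlap")
  expect_error(combine_windows(list(mk(1, 0, 0, 0.6), mk(1, 0, 0.5, 1))),
               "gap or overlap")
})

test_that("window subdivision of a linear profile leaves the total fixed", {
  # a linear dG(lambda) profile contributes dG proportional to window width
  total <- -3.7
  split_total <- function(bounds) {
    combine_windows(lapply(seq_len(length(bounds) - 1L), function(i) {
      free_energy_estimate(total * (bounds[i + 1] - bounds[i]), 0, "bar",
                           lambda_low = bounds[i],
                           lambda_high = bounds[i + 1])
    }))$delta_g
  }
  expect_equal(split_total(c(0, 1)), total, tolerance = 1e-12)
  expect_equal(split_total(seq(0, 1, 0.25)), total, tolerance = 1e-12)
  expect_equal(split_total(make_lambda_schedule()$values), total,
               tolerance = 1e-12)
})

test_that("bidirectional combination averages and half-splits the gap", {
  d <- free_energy_estimate(-7.5, 0.05, "bar")
  r <- free_energy_estimate(-7.7, 0.05, "bar")
  est <- bidirectional_combine(d, r)
  expect_equal(est$delta_g, -7.6)
  expect_equal(est$stderr, 0.1)
  expect_equal(bidirectional_combine(d, d)$stderr, 0)
  est2 <- bidirectional_combine(free_energy_estimate(-8.5, 0, "bar"),
                                free_energy_estimate(-8.9, 0, "bar"))
  expect_equal(est2$delta_g, -8.7)
  expect_equal(est2$stderr, 0.2)
})

test_that("replicate runs pool by concatenating matching windows", {
  r1 <- list(window_samples(0, 0.5, 1:3, 4:5),
             window_samples(0.5, 1, 1:2, 3:4))
  r2 <- list(window_samples(0, 0.5, 10, 20))
  pooled <- pool_window_samples(list(r1, r2))
  expect_length(pooled, 2L)
  expect_equal(pooled[[1]]$forward_du, c(1, 2, 3, 10))
  expect_equal(pooled[[1]]$backward_du, c(4, 5, 20))
  expect_equal(pooled[[2]]$forward_du, c(1, 2))
})
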
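test_that("cline probability matches closed forms", {
  s <- cline_spec(0.43, 0.05)
  expect_equal(cline_probability(0.43, s), 0.5)
  expect_equal(cline_probability(0.48, s), (1 + tanh(2)) / 2,
               tolerance = 1e-12)
  # width = 1 / maximum slope: central derivative equals 1/w
  s2 <- cline_spec(0.5, 0.1)
  num_slope <- (cline_probability(0.5 + 1e-7, s2) -
                  cline_probability(0.5 - 1e-7, s2)) / 2e-7
  expect_equal(num_slope, 10, tolerance = 1e-5)
})

test_that("cline curve is monotone, continuous at tail junctions, bounded", {
  specs <- withr::with_seed(11, lapply(1:40, function(i) {
    tails <- sample(c("none", "left", "right", "mirror", "both"), 1)
    scaling <- sample(c("none", "free"), 1)
    pmin <- runif(1, 0, 0.4); pmax <- runif(1, 0.6, 1)
    cline_spec(runif(1, 0.2, 0.8), runif(1, 0.02, 0.5),
               scaling = scaling, tails = tails, pmin = pmin, pmax = pmax,
               delta_l = runif(1, 0, 0.3), tau_l = runif(1, 0.05, 1),
               delta_r = runif(1, 0, 0.3), tau_r = runif(1, 0.05, 1))
  }))
  grid <- seq(0, 1, length.out = 2001)
  for (s in specs) {
    p <- cline_probability(grid, s)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= s$pmin - 1e-12 & p <= s$pmax + 1e-12))
    for (j in c(s$center - s$delta_l, s$center + s$delta_r)) {
      if (j > 0 && j < 1) {
        gap <- abs(cline_probability(j - 1e-13, s) -
                     cline_probability(j + 1e-13, s))
        expect_lt(gap, 1e-9)
      }
    }
  }
})

test_that("numerical max slope equals (pmax - pmin) / w for tail-less clines", {
  grid <- seq(0, 1, length.out = 20001)
  for (s in list(cline_spec(0.4, 0.08),
                 cline_spec(0.6, 0.3, scaling = "free",
                            pmin = 0.1, pmax = 0.9))) {
    p <- cline_probability(grid, s)
    max_slope <- max(diff(p)) / (grid[2] - grid[1])
    expect_equal(max_slope, (s$pmax - s$pmin) / s$width, tolerance = 1e-3)
  }
})

test_that("log-likelihoods match direct evaluation and stay finite", {
  s <- cline_spec(0.5, 0.1)
  d1 <- cline_data(0.5, 1, "bernoulli")
  expect_equal(cline_loglik(d1, s), log(0.5))
  d2 <- cline_data(0.5, 1, "binomial2")
  expect_equal(cline_loglik(d2, s), log(2) + 2 * log(0.5))
  # clamping: far right of a sharp cline p -> 1 exactly, but observing
  # y = 0 there must give the clamp's finite value, not -Inf
  d3 <- cline_data(c(0.9, 0.95), c(0, 0), "bernoulli")
  ll <- cline_loglik(d3, cline_spec(0.01, 0.001))
  expect_true(is.finite(ll))
  expect_equal(ll, 2 * log(1e-9), tolerance = 1e-7)
  expect_error(cline_data(numeric(0), numeric(0)), "empty")
  expect_error(cline_data(c(0.1, 0.2), c(0, 3), "binomial2"), "inconsistent")
})

test_that("fitting recovers planted parameters and is deterministic", {
  d <- sim_cline_bernoulli(300, 0.5, 0.1, seed = 21)
  f1 <- fit_cline(d, n_starts = 12, seed = 5)
  expect_true(f1$converged)
  expect_lt(abs(f1$spec$center - 0.5), 0.05)
  f2 <- fit_cline(d, n_starts = 12, seed = 5)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$loglik)
})

test_that("a perfect step drives width to its lower bound with a flag", {
  x <- seq(0.05, 0.95, length.out = 40)
  d <- cline_data(x, as.numeric(x > 0.5), "bernoulli")
  f <- fit_cline(d, n_starts = 10, seed = 2)
  expect_equal(f$spec$width, 1e-3, tolerance = 1e-6)
  expect_true(f$boundary)
})

test_that("grid search never beats the optimizer on small instances", {
  for (seed in 1:3) {
    d <- sim_cline_bernoulli(10, 0.45, 0.15, seed = seed)
    f <- fit_cline(d, n_starts = 15, seed = seed)
    cgrid <- seq(1e-4, 1 - 1e-4, length.out = 50)
    wgrid <- seq(1e-3, 2, length.out = 50)
    grid_best <- max(outer(cgrid, wgrid, Vectorize(function(cc, ww) {
      cline_loglik(d, cline_spec(cc, ww))
    })))
    expect_lte(grid_best, f$loglik + 1e-6)
  }
})

test_that("support intervals bracket the MLE and tighten with sample size", {
  widths <- sapply(c(100, 400), function(n) {
    median(sapply(1:3, function(s) {
      d <- sim_cline_bernoulli(n, 0.5, 0.08, seed = 100 + s)
      f <- fit_cline(d, n_starts = 10, seed = s)
      ci <- support_interval(d, f, "center")
      expect_lte(ci[1], f$spec$center)
      expect_gte(ci[2], f$spec$center)
      # profile at the interior endpoints sits delta below the max
      if (!any(attr(ci, "at_bound"))) {
        pl <- cytocline:::profile_loglik(d, f, "center", ci[1])
        expect_equal(pl, f$loglik - 2, tolerance = 1e-4)
      }
      diff(range(ci))
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("a parameter the data cannot constrain spans its bound, flagged", {
  # all-one responses: center is unidentifiable, profile is flat
  d <- cline_data(seq(0.1, 0.9, length.out = 30), rep(1, 30), "bernoulli")
  f <- fit_cline(d, n_starts = 8, seed = 3)
  ci <- support_interval(d, f, "center")
  expect_true(any(attr(ci, "at_bound")))
  f_bad <- f
  f_bad$converged <- FALSE
  expect_error(support_interval(d, f_bad, "center"), "converged")
})

test_that("model selection returns the brute-force AIC minimum", {
  d <- sim_cline_bernoulli(200, 0.5, 0.1, seed = 31)
  variants <- data.frame(scaling = c("none", "none", "free"),
                         tails = c("none", "mirror", "none"))
  best <- select_cline_model(d, variants, n_starts = 8, seed = 9)
  tab <- attr(best, "model_table")
  expect_equal(best$aic, min(tab$aic[tab$converged]))
  # single-variant list returns that variant
  one <- select_cline_model(d, data.frame(scaling = "none", tails = "none"),
                            n_starts = 8, seed = 9)
  expect_equal(one$spec$tails, "none")
  expect_equal(one$spec$scaling, "none")
})

test_that("data simulated without tails rarely selects the both-tails model", {
  hits <- sapply(1:10, function(s) {
    d <- sim_cline_bernoulli(150, 0.5, 0.1, seed = 200 + s)
    variants <- data.frame(scaling = "none", tails = c("none", "both"))
    best <- select_cline_model(d, variants, n_starts = 8, seed = s)
    both_k <- 2 + 4
    best$k <= both_k
  })
  expect_gte(mean(hits), 0.9)
})
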
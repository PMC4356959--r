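test_that("mean chronology averages year-wise and records sample depth", {
  a <- make_index("F01", 2000, c(1.0, 1.2))
  b <- make_index("F02", 2000, c(1.2, 0.8))
  ch <- mean_chronology(list(a, b))
  expect_equal(ch$value, c(1.1, 1.0))
  expect_equal(ch$depth, c(2L, 2L))
  expect_equal(attr(ch, "variant"), "standard")
  # identical series: chronology equals the series
  many <- lapply(sprintf("F%02d", 1:44), function(id)
    make_index(id, 1990, c(1.1, 0.9, 1.0)))
  ch44 <- mean_chronology(many)
  expect_equal(ch44$value, c(1.1, 0.9, 1.0))
  expect_equal(ch44$depth, rep(44L, 3))
})

test_that("biweight mean resists an outlier better than the arithmetic mean", {
  x <- c(rep(1.0, 29), 5.0)
  expect_lt(abs(biweight_mean(x) - 1), abs(mean(x) - 1))
  expect_equal(biweight_mean(rep(2, 10)), 2)
})

test_that("EPS follows n*rbar / (1 + (n-1)*rbar)", {
  expect_equal(eps(0.25, 12), 0.8)           # 3 / 3.75
  expect_equal(eps(0.3, 1), 0.3)             # n = 1 identity
  expect_equal(eps(-0.4, 1), -0.4)
  expect_equal(eps(1, c(1, 5, 40)), rep(1, 3))
  # monotone in both arguments
  rg <- seq(0.01, 0.9, by = 0.05)
  expect_true(all(diff(eps(rg, 20)) > 0))
  ng <- 2:50
  expect_true(all(diff(eps(0.1, ng)) > 0))
  expect_warning(e <- eps(-0.5, 10), "undefined")
  expect_true(is.na(e))
})

test_that("mean sensitivity measures relative year-to-year change", {
  expect_equal(mean_sensitivity(rep(1.3, 10)), 0)
  expect_equal(mean_sensitivity(c(1, 3, 1, 3)), 1)    # each term 2*2/4
  expect_equal(mean_sensitivity(c(1, 1, 3)), 0.5)     # terms 0 and 1
  x <- exp(rnorm(20, 0, 0.1))
  expect_equal(mean_sensitivity(5 * x), mean_sensitivity(x))  # scale invariant
  expect_error(mean_sensitivity(c(1, -1, 2)), "positive")
})

test_that("windowed rbar statistics handle identical series and single pairs", {
  vals <- exp(rnorm(30, 0, 0.1))
  ident <- lapply(1:3, function(i) make_index(paste0("F0", i), 1980,
                                              vals * exp(0)))
  st <- rbar_windowed(ident, 15)
  expect_true(all(abs(st$rbar - 1) < 1e-12))
  expect_true(all(st$rbar_se == 0))
  expect_equal(st$n_pairs, rep(3L, nrow(st)))
  expect_equal(nrow(st), 30 - 15 + 1)

  two <- lapply(1:2, function(i)
    make_index(paste0("F0", i), 1990, exp(rnorm(15, 0, 0.1))))
  st2 <- rbar_windowed(two, 15)
  expect_equal(st2$n_pairs, 1L)
  expect_true(is.na(st2$rbar_se))
  m <- as_series_matrix(two)
  expect_equal(st2$rbar, cor(m[, 1], m[, 2]))
})

test_that("window selection applies the rbar - 2 se criterion and pair-count tie-break", {
  st <- data.frame(start = c(1989, 1990, 1991), end = c(2003, 2004, 2005),
                   center = c(1996, 1997, 1998),
                   rbar = c(0.03, 0.035, 0.04),
                   rbar_se = c(0.02, 0.012, 0.021),
                   n_pairs = c(100L, 120L, 110L), depth = c(15L, 17L, 16L),
                   eps = NA)
  sel <- select_window(st)
  # only the middle window qualifies: 0.035 - 0.024 = 0.011 > 0
  expect_false(sel$no_signal)
  expect_equal(sel$start, 1990)
  expect_equal(sum(sel$table$qualified), 1)

  st$rbar_se <- c(0.005, 0.005, 0.005)  # all qualify
  sel2 <- select_window(st)
  expect_equal(sel2$start, 1990)        # n_pairs = 120 wins

  st$rbar <- c(0.01, 0.01, 0.01); st$rbar_se <- rep(0.02, 3)
  sel3 <- select_window(st)
  expect_true(sel3$no_signal)           # explicit outcome, not an error
})

test_that("AR standardization selects low orders for white noise and
           recovers AR(1) structure", {
  set.seed(11)
  ords <- replicate(100, otochron:::prewhiten_series(rnorm(30))$order)
  # AIC keeps the null order for most white-noise series (~77% by
  # simulation; bound allows Monte Carlo noise)
  expect_gte(mean(ords == 0), 0.62)

  rec <- replicate(50, {
    x <- as.numeric(arima.sim(list(ar = 0.7), 200))
    fit <- otochron:::prewhiten_series(x, 3)
    fit$order >= 1 && fit$phi[1] > 0.55 && fit$phi[1] < 0.85
  })
  expect_gte(mean(rec), 0.85)
})

test_that("the residual chronology of AR(1) inputs is prewhitened", {
  set.seed(13)
  # independent AR(1) index series: their mean chronology is still AR(1),
  # the residual chronology of the prewhitened series should not be
  run_once <- function() {
    series <- lapply(1:20, function(i)
      make_index(sprintf("F%02d", i), 1900,
                 1 + 0.08 * as.numeric(arima.sim(list(ar = 0.6), 100))))
    out <- ar_standardize(series, max_order = 3)
    c(std = acf(out$standard$value, plot = FALSE)$acf[2],
      res = acf(out$residual$value, plot = FALSE)$acf[2],
      ars = acf(out$arstan$value, plot = FALSE)$acf[2],
      mean_res = mean(out$residual$value),
      min_order = min(out$info$order))
  }
  reps <- replicate(5, run_once())
  expect_lt(mean(abs(reps["res", ])), 0.15)
  expect_true(all(reps["res", ] < reps["std", ]))
  expect_equal(unname(reps["mean_res", ]), rep(1, 5), tolerance = 1e-9)
  expect_true(all(reps["min_order", ] >= 1))
  # reintroducing the pooled AR raises the lag-1 autocorrelation again
  expect_gt(mean(reps["ars", ]), mean(reps["res", ]))
  expect_error(ar_standardize(list(make_index("A", 2000, rep(1, 6))), 3),
               "too short")
})

test_that("chronology of ratio indices averages near one on simulated data", {
  ds <- generate_dataset(sim_config(), seed = 99)
  dt <- detrend_dataset(ds$records, 9)
  ch <- mean_chronology(dt$ims)
  covered <- ch$depth >= 10
  expect_equal(mean(ch$value[covered]), 1, tolerance = 0.1)
})
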
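make_monthly <- function(years, fun) {
  df <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  df$value <- fun(df$year, df$month)
  df
}

test_that("seasonal means follow the austral season conventions", {
  const <- make_monthly(1990:1995, function(y, m) 7)
  for (s in c("annual", "DJF", "MAM", "JJA", "SON")) {
    env <- seasonal_means(const, s)
    expect_true(all(env$values == 7))
    expect_equal(env$season, s)
  }
  # DJF(y) = mean(Dec y-1, Jan y, Feb y)
  mm <- make_monthly(1999:2001, function(y, m) 0)
  mm$value[mm$year == 1999 & mm$month == 12] <- 0
  mm$value[mm$year == 2000 & mm$month %in% 1:2] <- 3
  djf <- seasonal_means(mm, "DJF")
  expect_equal(djf$values[djf$years == 2000], 2.0)
  expect_equal(djf$years, 2000:2001)  # DJF(1999) needs the absent Dec 1998
  # missing month drops the year
  mm2 <- mm[!(mm$year == 2000 & mm$month == 1), ]
  djf2 <- seasonal_means(mm2, "DJF")
  expect_false(2000 %in% djf2$years)
  expect_error(seasonal_means(mm, "XYZ"), "unknown season")
})

test_that("linear detrending removes an OLS line on year", {
  env <- env_series("sl", 1980:2009, 3 + 0.02 * (1980:2009))
  out <- linear_detrend(env)
  expect_equal(out$values, rep(0, 30), tolerance = 1e-9)
  expect_true("linear_detrended" %in% out$preprocessing)

  set.seed(2)
  e <- rnorm(30, 0, 0.03)
  e <- as.numeric(lm(e ~ I(1980:2009))$residuals)  # orthogonalised residuals
  env2 <- env_series("sl", 1980:2009, 1 + 0.05 * (1980:2009) + e)
  out2 <- linear_detrend(env2)
  expect_equal(out2$values, e, tolerance = 1e-9)
  expect_equal(mean(out2$values), 0, tolerance = 1e-12)
  expect_lt(abs(cor(out2$values, out2$years)), 1e-9)
})

test_that("t-based Pearson p-values match reference values and cor.test", {
  expect_equal(pearson_p(0, 15), 1)
  expect_equal(round(pearson_p(0.61, 15), 3), 0.016)
  expect_equal(round(pearson_p(-0.62, 15), 3), 0.014)
  expect_identical(pearson_p(0.4, 20), pearson_p(-0.4, 20))  # sign symmetry
  expect_equal(pearson_p(1, 10), 0)
  # monotone in |r| and in n
  rg <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(pearson_p(rg, 15)) < 0))
  expect_true(all(diff(pearson_p(0.4, c(5, 10, 20, 40))) < 0))
  # independent oracle: cor.test on data with that exact correlation
  set.seed(6)
  x <- rnorm(15); y <- rnorm(15)
  ct <- cor.test(x, y)
  expect_equal(pearson_p(ct$estimate[[1]], 15), ct$p.value, tolerance = 1e-12)
})

test_that("null rejection rate at p < 0.05 is nominal", {
  set.seed(19)
  r <- replicate(2000, cor(rnorm(15), rnorm(15)))
  rate <- mean(pearson_p(r, 15) < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("lagged correlations align current and previous years", {
  set.seed(44)
  vals <- 1 + as.numeric(arima.sim(list(ar = 0.5), 15, sd = 0.05))
  ch <- otochron:::new_chronology(1990:2004, vals, rep(10L, 15), "standard")
  env <- env_series("self", 1990:2004, vals)
  res <- lagged_correlations(ch, list(self = env))
  cur <- res[res$lag == "current", ]
  expect_equal(cur$r, 1)
  expect_equal(cur$n, 15L)
  prev <- res[res$lag == "previous", ]
  expect_equal(prev$n, 14L)  # env has no 1989 value
  expect_equal(prev$r, cor(vals[-1], vals[-15]))  # lag-1 autocorrelation

  # an env series covering 1989 gives n = 15 for both lags
  env2 <- env_series("full", 1989:2004, c(0.9, vals))
  res2 <- lagged_correlations(ch, list(full = env2), window = c(1990, 2004))
  expect_true(all(res2$n == 15L))
  expect_error(lagged_correlations(ch, list(self = env), window = c(1985, 2004)),
               "cover")
})

test_that("correlation tables pivot to the report layout with stars", {
  res <- data.frame(variable = c("sl", "sl"), season = "annual",
                    lag = c("current", "previous"), r = c(0.23, 0.61),
                    p = c(0.415, 0.016), n = 15,
                    significant = c(FALSE, TRUE))
  tab <- format_correlation_table(res)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$previous_sig, "*")
  expect_equal(tab$current_sig, "")
})
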
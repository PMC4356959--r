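test_that("critical correlation matches the one-tailed t quantile", {
  r <- critical_r(15, 0.99)
  # independent route: the one-tailed p of r* at n = 15 must be 0.01
  t <- r * sqrt(13) / sqrt(1 - r^2)
  expect_equal(pt(t, 13, lower.tail = FALSE), 0.01, tolerance = 1e-10)
  expect_gt(critical_r(10), critical_r(50))
})

test_that("leave-one-out master excludes the named series", {
  set.seed(3)
  base <- exp(cumsum(rnorm(30, 0, 0.05)))
  series <- lapply(1:4, function(i)
    make_index(paste0("F0", i), 1980, base * exp(rnorm(30, 0, 0.05))))
  m1 <- build_master(series, exclude_id = "F01")
  # perturbing the excluded series leaves the master unchanged
  series[[1]]$indices <- series[[1]]$indices * exp(rnorm(30, 0, 0.3))
  m2 <- build_master(series, exclude_id = "F01")
  expect_equal(m1$value, m2$value)
  expect_true(all(m1$depth <= 3))
  expect_error(build_master(series[1:2], exclude_id = "F01"), "at least 2")
})

test_that("identical series correlate perfectly with their master", {
  set.seed(8)
  vals <- exp(rnorm(40, 0, 0.1))
  series <- lapply(1:3, function(i) make_index(paste0("F0", i), 1970, vals))
  master <- build_master(series, exclude_id = "F01")
  x <- otochron:::filter_for_crossdating(series[[1]]$indices)
  seg <- segment_correlations(x, master, first_year = 1970)
  expect_true(all(seg$best_lag == 0))
  expect_true(all(seg$r_lag0 > 0.999))
  expect_false(any(seg$off_dating))
})

test_that("lag sign convention: a series dated too early has best lag +1", {
  set.seed(12)
  vals <- rnorm(40)
  master <- data.frame(year = 1961:2000, value = vals, depth = 10)
  # series values equal the master values of year + 1: growth recorded
  # one year before it actually happened (dated too early)
  x <- vals[2:40]
  seg <- segment_correlations(x, master, first_year = 1961,
                              seg_length = 15, max_lag = 2)
  expect_true(all(seg$best_lag == 1L))
  expect_true(all(seg$off_dating))
})

test_that("a one-year dating shift is flagged under a strong common signal", {
  set.seed(21)
  hits <- vapply(sample.int(1e6, 25), function(s) {
    ds <- generate_dataset(sim_config(n_fish = 15, transect_range = c(3, 3),
                                      common_share = 0.5), seed = s)
    ims <- detrend_dataset(ds$records, 9)$ims
    j <- which.max(vapply(ims, function(x) length(x$indices), 0))
    ims[[j]]$first_year <- ims[[j]]$first_year + 1L
    cd <- crossdate_dataset(ims)
    seg <- cd$segments[cd$segments$series == names(ims)[j], ]
    mean(seg$off_dating) > 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.85)
})

test_that("white-noise series fall below the 99% critical value", {
  set.seed(31)
  below <- unlist(replicate(20, {
    m <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(1971:2000, paste0("S", 1:20)))
    master <- build_master(m, exclude_id = "S1")
    x <- otochron:::filter_for_crossdating(m[, 1])
    segment_correlations(x, master, first_year = 1971)$low_corr
  }, simplify = FALSE))
  expect_gte(mean(below), 0.93)  # nominal rate 0.99
})

test_that("interseries correlation is 1 for identical series and ~0 for noise", {
  vals <- exp(rnorm(30, 0, 0.1))
  ident <- lapply(1:5, function(i) make_index(paste0("F0", i), 1980, vals))
  ic <- interseries_correlation(ident)
  expect_equal(ic$per_series$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(ic$mean_r, 1)

  set.seed(17)
  means <- replicate(20, {
    noise <- lapply(1:20, function(i)
      make_index(sprintf("F%02d", i), 1980, exp(rnorm(30, 0, 0.1))))
    interseries_correlation(noise)$mean_r
  })
  expect_lt(abs(mean(means)), 0.05)
  expect_error(interseries_correlation(ident[1:2]), "at least 3")
})

test_that("weak-signal data give a small positive interseries correlation", {
  # With pairwise rbar ~ 0.035 across n ~ 44 series, the correlation of one
  # series with the mean of the others is amplified to roughly
  # rbar * sqrt((n-1) / (1 + (n-2) rbar)) ~ 0.15, so the mean interseries
  # correlation sits well above rbar but stays small.
  set.seed(23)
  ir <- replicate(5, {
    ds <- generate_dataset(sim_config(), seed = sample.int(1e6, 1))
    interseries_correlation(detrend_dataset(ds$records, 9)$ims)$mean_r
  })
  expect_gte(mean(ir), 0.03)
  expect_lte(mean(ir), 0.27)
})
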
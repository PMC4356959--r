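# Shared fixtures and independent oracles, built in code at test time.

# Least-squares sinusoid amplitude: the independent gain oracle. Fits
# a + b*sin + c*cos over interior years and returns the fitted amplitude
# relative to the input amplitude.
sine_gain <- function(cutoff_years, wavelength, n_cycles = 10) {
  n <- max(40L, round(wavelength * n_cycles))
  t <- seq_len(n)
  y <- sin(2 * pi * t / wavelength)
  fit <- fit_spline(y, cutoff_years)
  interior <- t > wavelength & t < n - wavelength
  X <- cbind(sin(2 * pi * t / wavelength), cos(2 * pi * t / wavelength))
  b <- coef(lm(fit[interior] ~ X[interior, ] - 1))
  sqrt(sum(b^2))
}

# A small fish record with smoothly varying positive widths.
make_fish <- function(fish_id = "F01", n_transects = 3, years = 1985:2004,
                      seed = 1) {
  set.seed(seed)
  ny <- length(years)
  ages <- 13:(13 + ny - 1)
  onto <- ontogenetic_curve(ages)
  trs <- lapply(seq_len(n_transects), function(j)
    transect_series(fish_id, paste0("T", j), years[1],
                    onto * exp(rnorm(ny, 0, 0.1))))
  fish_record(fish_id, max(years) + 1, max(ages) + 1, trs)
}

# Fish records carrying a 9-year-period common signal plus a slow
# (18-year-period) fish-specific wobble: data whose common signal a
# flexible spline preserves while removing the individual wobble.
make_records_sine <- function(n_fish = 20, years = 1970:2004, seed = 1,
                              sig_amp = 0.15, wob_amp = 0.3, wob_per = 18) {
  set.seed(seed)
  common <- sig_amp * sin(2 * pi * (years - 1970) / 9)
  recs <- list()
  for (i in seq_len(n_fish)) {
    ny <- length(years)
    ages <- 13:(13 + ny - 1)
    onto <- ontogenetic_curve(ages)
    wob <- wob_amp * sin(2 * pi * (years - 1970) / wob_per +
                           runif(1, 0, 2 * pi))
    trs <- lapply(1:3, function(j)
      transect_series(sprintf("F%02d", i), paste0("T", j), years[1],
                      onto * exp(common + wob + rnorm(ny, 0, 0.12))))
    recs[[sprintf("F%02d", i)]] <-
      fish_record(sprintf("F%02d", i), max(years) + 1, max(ages) + 1, trs)
  }
  recs
}

# Index series helper: positive values around 1.
make_index <- function(owner, first_year, values, level = "fish") {
  index_series(owner, level, first_year, values)
}
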
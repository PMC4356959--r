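# Synthetic-data generator emulating a multi-decadal otolith biochronology
# study: a slow ontogenetic decline in increment width, a weak lagged common
# environmental signal shared by all fish, individual (fish-year) noise, and
# independent measurement noise per transect, all multiplicative on the log
# scale so widths stay positive and ratio detrending is the natural inverse.

#' Simulation configuration
#'
#' Defaults reproduce the sampling design of the emulated study: 44 fish
#' aged 27-49 at capture, captured 2005-2011, increments measurable only
#' after age 12, 3-5 transects per otolith, and a weak common signal (3.5%
#' of index variance) driven by the previous year's environmental state.
#'
#' @param n_fish Number of fish.
#' @param age_range Age range (years) at capture, inclusive.
#' @param capture_years Calendar years over which fish were captured.
#' @param capture_month Month of capture (the study does not state capture
#'   months; mid-year makes the last complete growth year `capture_year -
#'   1`).
#' @param min_age Minimum age (exclusive) of measurable increments.
#' @param transect_range Range of transects per fish.
#' @param r_inf,k Von Bertalanffy-type parameters of the expected otolith
#'   radius `r_inf * (1 - exp(-k * age))` (mm, 1/year); annual increments
#'   are its year-to-year differences.
#' @param phi AR(1) coefficient of the standardized environmental driver.
#' @param common_share Fraction of detrended-index variance carried by the
#'   common driver signal (the study's observable); converted internally to
#'   the log-scale driver coefficient `beta` unless `beta` is given.
#' @param beta Driver coefficient on log growth; overrides `common_share`.
#' @param lag Response lag in years (growth responds to the driver state
#'   `lag` years earlier).
#' @param sigma_f Fish-year noise s.d. (log scale).
#' @param sigma_t Transect measurement noise s.d. (log scale).
#' @param cutoff_years Detrending cutoff assumed in the share-to-beta
#'   conversion.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_fish = 44, age_range = c(27, 49),
                       capture_years = 2005:2011, capture_month = 6,
                       min_age = 12, transect_range = c(3, 5),
                       r_inf = 2, k = 0.04, phi = 0.5,
                       common_share = 0.035, beta = NULL, lag = 1,
                       sigma_f = 0.10, sigma_t = 0.15, cutoff_years = 9) {
  cfg <- list(n_fish = n_fish, age_range = age_range,
              capture_years = capture_years, capture_month = capture_month,
              min_age = min_age, transect_range = transect_range,
              r_inf = r_inf, k = k, phi = phi, common_share = common_share,
              beta = beta, lag = lag, sigma_f = sigma_f, sigma_t = sigma_t,
              cutoff_years = cutoff_years)
  if (n_fish < 2) stop("n_fish must be >= 2")
  if (phi < 0 || phi >= 1) stop("phi must satisfy 0 <= phi < 1")
  if (sigma_f < 0 || sigma_t < 0) stop("noise s.d. must be >= 0")
  if (common_share < 0 || common_share >= 1)
    stop("common_share must be in [0, 1)")
  if (age_range[1] <= min_age + 1)
    stop("age range must exceed min measured age")
  structure(cfg, class = "sim_config")
}

#' Simulate a standardized AR(1) environmental driver
#'
#' Stationary AR(1) with zero mean and unit marginal variance:
#' `z[t] = phi * z[t-1] + sqrt(1 - phi^2) * e[t]`, `z[1] ~ N(0, 1)`.
#'
#' @param years Calendar years to simulate.
#' @param phi AR(1) coefficient, `0 <= phi < 1`.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @return An [env_series()] named `"driver"`.
#' @export
simulate_driver <- function(years, phi = 0.5, seed = NULL) {
  if (phi < 0 || phi >= 1) stop("phi must satisfy 0 <= phi < 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(years)
  e <- rnorm(n)
  z <- as.numeric(stats::filter(c(e[1], sqrt(1 - phi^2) * e[-1]),
                                phi, method = "recursive"))
  env_series("driver", years, z)
}

#' Expected increment widths over age
#'
#' Annual increments of a von Bertalanffy-type otolith radius curve:
#' `width(a) = r_inf * (exp(-k (a - 1)) - exp(-k a))`, positive and strictly
#' decreasing, emulating the ontogenetic decline that detrending removes.
#'
#' @param ages Integer ages >= 1.
#' @param r_inf Asymptotic radius (mm).
#' @param k Growth coefficient (1/year).
#' @return Expected widths (mm).
#' @export
ontogenetic_curve <- function(ages, r_inf = 2, k = 0.04) {
  stopifnot(all(ages >= 1))
  w <- r_inf * (exp(-k * (ages - 1)) - exp(-k * ages))
  if (any(w <= 0)) stop("parameters yield non-positive widths")
  w
}

#' Convert a common-variance share to the driver coefficient
#'
#' The target `share` is the fraction of an individual mean series' variance
#' (after spline detrending, averaging over `m` transects) attributable to
#' the common driver. Detrending high-passes both signal and noise, so the
#' conversion weights each by the detrend filter's squared transfer function
#' `(1 - G(w))^2` over the relevant spectrum: the AR(1) spectrum for the
#' driver, flat for the white noise terms. Then
#' `beta^2 = share / (1 - share) * (sigma_f^2 + sigma_t^2 / m) * Aw / Az`.
#'
#' @param share Target common-variance share in `[0, 1)`.
#' @param sigma_f,sigma_t Noise s.d.s (log scale).
#' @param m Average number of transects per fish.
#' @param phi Driver AR(1) coefficient.
#' @param cutoff_years,response Detrend spline settings.
#' @return Non-negative `beta`.
#' @export
beta_for_share <- function(share, sigma_f = 0.10, sigma_t = 0.15, m = 4,
                           phi = 0.5, cutoff_years = 9, response = 0.5) {
  if (share == 0) return(0)
  w <- seq(1e-4, pi, length.out = 4096)
  h2 <- (1 - spline_gain(2 * pi / w, cutoff_years, response))^2
  sz <- (1 - phi^2) / (1 + phi^2 - 2 * phi * cos(w))
  az <- mean(h2 * sz)
  aw <- mean(h2)
  sqrt(share / (1 - share) * (sigma_f^2 + sigma_t^2 / m) * aw / az)
}

#' Generate a synthetic otolith biochronology dataset
#'
#' Per fish `f` and growth year `t`, the expected increment width is
#' `ontogenetic(age) * exp(beta * Z[t - lag] + eps[f, t])` with fish-year
#' noise `eps ~ N(0, sigma_f^2)`; each transect observes it with independent
#' log-scale noise `N(0, sigma_t^2)`. Increments exist only for ages above
#' `min_age` and complete growth years before capture (the outermost partial
#' increment is dropped). The environmental set contains the true driver (a
#' sea-level analogue), a monthly SST-like family correlated with it, and an
#' independent decoy index.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @return List with `records` (named list of [fish_record()]), `env`
#'   (list: `sea_level` [env_series()], `sst` monthly data frame, `decoy`
#'   [env_series()]), `truth` (driver series, `beta`, `common_share`,
#'   `lag`, noise s.d.s, per-fish table) and the `config`/`seed` used.
#' @export
generate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_fish
  fish_ids <- sprintf("F%02d", seq_len(n))
  pick <- function(x, n) if (length(x) == 1) rep(x, n) else
    sample(x, n, replace = TRUE)
  capture_year <- pick(config$capture_years, n)
  age <- pick(config$age_range[1]:config$age_range[2], n)
  n_tr <- pick(config$transect_range[1]:config$transect_range[2], n)
  first_years <- capture_year - age + config$min_age + 1L
  env_years <- (min(first_years) - config$lag - 5L):max(config$capture_years)
  driver <- simulate_driver(env_years, config$phi)
  beta <- if (!is.null(config$beta)) config$beta else
    beta_for_share(config$common_share, config$sigma_f, config$sigma_t,
                   m = mean(config$transect_range[1]:config$transect_range[2]),
                   phi = config$phi, cutoff_years = config$cutoff_years)
  records <- list()
  for (i in seq_len(n)) {
    ages <- (config$min_age + 1L):(age[i] - 1L)
    yrs <- assign_growth_years(ages, capture_year[i], config$capture_month)
    onto <- ontogenetic_curve(ages, config$r_inf, config$k)
    z <- driver$values[match(yrs - config$lag, driver$years)]
    log_common <- beta * z + rnorm(length(yrs), 0, config$sigma_f)
    transects <- lapply(seq_len(n_tr[i]), function(j) {
      w <- onto * exp(log_common + rnorm(length(yrs), 0, config$sigma_t))
      transect_series(fish_ids[i], sprintf("T%d", j), yrs[1], w)
    })
    records[[fish_ids[i]]] <- fish_record(
      fish_ids[i], capture_year[i], age[i], transects,
      min_age = config$min_age, transect_bounds = config$transect_range)
  }
  sea_level <- env_series("sea_level", driver$years, driver$values)
  sst <- expand.grid(month = 1:12, year = env_years)[, c("year", "month")]
  sst$value <- 0.6 * driver$values[match(sst$year, driver$years)] +
    0.8 * rnorm(nrow(sst))
  decoy <- simulate_driver(env_years, config$phi)
  decoy$name <- "decoy_index"
  truth <- list(driver = driver, beta = beta,
                common_share = config$common_share, lag = config$lag,
                sigma_f = config$sigma_f, sigma_t = config$sigma_t,
                fish = data.frame(fish_id = fish_ids,
                                  capture_year = capture_year,
                                  age_at_capture = age, n_transects = n_tr,
                                  first_year = first_years))
  list(records = records,
       env = list(sea_level = sea_level, sst = sst, decoy = decoy),
       truth = truth, config = config, seed = seed)
}

#' Write a generated dataset to plain-text files
#'
#' Emits `increments.csv` (long format readable by
#' [read_increment_csv()]), `sea_level.csv`, `sst_monthly.csv`,
#' `decoy_index.csv` and `truth.json`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_increment_csv(dataset$records, file.path(dir, "increments.csv"))
  write_env_csv(dataset$env$sea_level, file.path(dir, "sea_level.csv"))
  write_env_csv(dataset$env$sst, file.path(dir, "sst_monthly.csv"))
  write_env_csv(dataset$env$decoy, file.path(dir, "decoy_index.csv"))
  truth <- dataset$truth
  truth$driver <- list(years = truth$driver$years,
                       values = truth$driver$values)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
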
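#' Seasonal or annual means of a monthly series
#'
#' Austral season conventions: `DJF` for year `y` averages December of year
#' `y - 1` with January and February of year `y`; `MAM`, `JJA`, `SON`
#' average the labelled year's months; `annual` averages all 12 months of
#' the labelled calendar year. Years missing any required month are omitted.
#'
#' @param monthly Data frame with columns `year`, `month`, `value`.
#' @param season One of `"annual"`, `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @param name Variable name for the resulting series.
#' @return An [env_series()] with the requested season label.
#' @export
seasonal_means <- function(monthly, season, name = "env") {
  stopifnot(all(c("year", "month", "value") %in% names(monthly)))
  months <- switch(season,
                   annual = list(offs = rep(0L, 12), mon = 1:12),
                   DJF = list(offs = c(-1L, 0L, 0L), mon = c(12L, 1L, 2L)),
                   MAM = list(offs = rep(0L, 3), mon = 3:5),
                   JJA = list(offs = rep(0L, 3), mon = 6:8),
                   SON = list(offs = rep(0L, 3), mon = 9:11),
                   stop("unknown season: ", season))
  key <- paste(monthly$year, monthly$month)
  years <- sort(unique(monthly$year))
  vals <- vapply(years, function(y) {
    idx <- match(paste(y + months$offs, months$mon), key)
    if (any(is.na(idx))) NA_real_ else mean(monthly$value[idx])
  }, 0)
  keep <- !is.na(vals)
  if (!any(keep)) stop("no complete years for season ", season)
  env_series(name, years[keep], vals[keep], season = season)
}

#' Remove a linear trend from an environmental series
#'
#' Ordinary least-squares regression of the values on calendar year; the
#' residuals replace the values and `"linear_detrended"` is appended to the
#' series' provenance. Used e.g. to remove the secular rise from tide-gauge
#' sea level so that interannual variability remains.
#'
#' @param env An [env_series()] with at least 3 years.
#' @return The detrended [env_series()].
#' @export
linear_detrend <- function(env) {
  stopifnot(inherits(env, "env_series"))
  if (length(env$years) < 3) stop("need at least 3 years to detrend")
  if (length(unique(env$years)) < 2) stop("years are constant")
  res <- as.numeric(lm(env$values ~ env$years)$residuals)
  env_series(env$name, env$years, res, season = env$season,
             preprocessing = c(env$preprocessing, "linear_detrended"))
}

#' Two-sided p-value of a Pearson correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' `n - 2` degrees of freedom, two-sided. `|r| = 1` returns an exact 0.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param n Number of paired observations, >= 3 (vectorised).
#' @return Two-sided p-value(s).
#' @export
pearson_p <- function(r, n) {
  stopifnot(all(abs(r) <= 1), all(n >= 3))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  nn <- rep_len(n, length(r))
  t <- abs(r[ok]) * sqrt((nn[ok] - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-t, nn[ok] - 2)
  p
}

#' Correlate a chronology window against lagged environmental series
#'
#' For each environmental variable, Pearson correlations between the
#' chronology over its analysis window and (a) the same calendar years
#' ("current") and (b) the years shifted back one ("previous"), with
#' t-based two-sided p-values. Raw p-values are reported; no
#' multiple-testing correction is applied by default (set `adjust` for
#' Benjamini-Hochberg).
#'
#' @param chron A `chronology` data frame.
#' @param env_list Named list of [env_series()].
#' @param window Length-2 vector `c(start, end)`; defaults to the
#'   chronology's full span.
#' @param alpha Significance level for the `significant` flag.
#' @param adjust Apply Benjamini-Hochberg adjustment across all tests?
#' @return Data frame: `variable`, `season`, `lag` ("current"/"previous"),
#'   `r`, `p`, `n`, `significant`.
#' @export
lagged_correlations <- function(chron, env_list, window = NULL,
                                alpha = 0.05, adjust = FALSE) {
  if (is.null(window)) window <- range(chron$year)
  yrs <- window[1]:window[2]
  mic <- chron$value[match(yrs, chron$year)]
  if (any(is.na(mic)))
    stop("chronology does not cover the requested window")
  rows <- list()
  for (nm in names(env_list)) {
    env <- env_list[[nm]]
    for (lag in c("current", "previous")) {
      ey <- if (lag == "current") yrs else yrs - 1L
      ev <- env$values[match(ey, env$years)]
      ok <- complete.cases(mic, ev)
      if (sum(ok) < 3) {
        warning(sprintf("skipping %s (%s): fewer than 3 overlapping years",
                        nm, lag))
        next
      }
      r <- cor(mic[ok], ev[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = env$name, season = env$season, lag = lag, r = r,
        p = pearson_p(r, sum(ok)), n = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out
}

#' Reshape correlation results to a report table
#'
#' One row per variable/season with current- and previous-year correlations
#' side by side and significance stars, the conventional layout of
#' climate-growth correlation tables.
#'
#' @param results Data frame from [lagged_correlations()].
#' @param alpha Significance level for the stars.
#' @return Wide data frame.
#' @export
format_correlation_table <- function(results, alpha = 0.05) {
  star <- function(p) ifelse(p < alpha, "*", "")
  cur <- results[results$lag == "current", ]
  prev <- results[results$lag == "previous", ]
  key <- paste(cur$variable, cur$season)
  pk <- paste(prev$variable, prev$season)
  prev <- prev[match(key, pk), ]
  data.frame(variable = cur$variable, season = cur$season,
             current_r = round(cur$r, 2), current_p = round(cur$p, 3),
             current_sig = star(cur$p),
             previous_r = round(prev$r, 2), previous_p = round(prev$p, 3),
             previous_sig = star(prev$p))
}
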
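#' Tukey biweight robust mean
#'
#' One-step biweight location estimate (tuning constant 9 times the median
#' absolute deviation), the robust mean conventionally used for chronology
#' averaging.
#'
#' @param x Numeric vector (NAs dropped).
#' @param const Tuning constant.
#' @return Numeric scalar.
#' @export
biweight_mean <- function(x, const = 9) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  med <- median(x)
  s <- median(abs(x - med))
  if (s == 0) return(med)
  u <- (x - med) / (const * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  sum(w * x) / sum(w)
}

#' Build a mean index chronology (MIC)
#'
#' Averages individual mean series year by year to raise the
#' signal-to-noise ratio of the common growth signal, recording how many
#' series contribute to each year (sample depth).
#'
#' @param series List of [index_series()] (typically fish-level IMS) or an
#'   aligned matrix from [as_series_matrix()].
#' @param robust Use the Tukey biweight mean instead of the arithmetic mean?
#' @return A `chronology` data frame (`year`, `value`, `depth`) with
#'   attribute `variant = "standard"`.
#' @export
mean_chronology <- function(series, robust = FALSE) {
  m <- as_series_matrix(series)
  vals <- if (robust) apply(m, 1, biweight_mean)
  else rowMeans(m, na.rm = TRUE)
  depth <- rowSums(!is.na(m))
  keep <- depth >= 1 & is.finite(vals)
  new_chronology(as.integer(rownames(m))[keep], vals[keep], depth[keep],
                 "standard")
}

#' Expressed population signal
#'
#' `EPS = n * rbar / (1 + (n - 1) * rbar)`: the expected correlation between
#' a finite-sample mean chronology of `n` series with mean interseries
#' correlation `rbar` and the hypothetical noise-free population chronology.
#'
#' @param rbar Mean pairwise correlation (vectorised).
#' @param n Sample depth, >= 1.
#' @return EPS value(s); `NA` where the denominator is not positive.
#' @export
eps <- function(rbar, n) {
  stopifnot(all(n >= 1))
  denom <- 1 + (n - 1) * rbar
  out <- ifelse(denom > 0, n * rbar / denom, NA_real_)
  if (any(is.na(out) & !is.na(rbar)))
    warning("EPS undefined: 1 + (n - 1) * rbar <= 0")
  out
}

#' Mean sensitivity
#'
#' Mean relative year-to-year change, `mean(2 |x[t+1] - x[t]| /
#' (x[t+1] + x[t]))`; a dendrochronology statistic of high-frequency
#' variability, ranging 0 (constant) to 2.
#'
#' @param x Positive numeric series, length >= 2.
#' @return Numeric scalar in \[0, 2\].
#' @export
mean_sensitivity <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("series too short for mean sensitivity")
  if (any(x <= 0)) stop("mean sensitivity requires strictly positive values")
  n <- length(x)
  mean(2 * abs(x[-1] - x[-n]) / (x[-1] + x[-n]))
}

#' Windowed mean pairwise correlation (rbar) statistics
#'
#' For every sliding window, computes all Pearson correlations between pairs
#' of series that fully cover the window (self-correlations excluded), their
#' mean `rbar`, its standard error `sd(pairwise r) / sqrt(n_pairs)`, the
#' sample depth, and the resulting EPS. Windows covered by fewer than two
#' series are absent from the output, not zero.
#'
#' @param series List of [index_series()] or an aligned matrix.
#' @param window_length Window length in years (>= 5).
#' @param step Step between window starts.
#' @return Data frame with columns `start`, `end`, `center`, `rbar`,
#'   `rbar_se`, `n_pairs`, `depth`, `eps`.
#' @export
rbar_windowed <- function(series, window_length = 15, step = 1) {
  stopifnot(window_length >= 5)
  m <- as_series_matrix(series)
  yrs <- as.integer(rownames(m))
  starts <- seq(yrs[1], yrs[length(yrs)] - window_length + 1L, by = step)
  rows <- list()
  for (s in starts) {
    sub <- m[yrs >= s & yrs <= s + window_length - 1L, , drop = FALSE]
    cover <- which(colSums(is.na(sub)) == 0)
    depth <- length(cover)
    if (depth < 2) next
    cc <- cor(sub[, cover, drop = FALSE])
    pr <- cc[upper.tri(cc)]
    pr <- pr[is.finite(pr)]
    if (length(pr) == 0) next
    rbar <- mean(pr)
    se <- if (length(pr) > 1) sd(pr) / sqrt(length(pr)) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = s + window_length - 1L,
      center = s + (window_length - 1L) / 2,
      rbar = rbar, rbar_se = se, n_pairs = length(pr),
      depth = depth, eps = eps(rbar, depth))
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), end = integer(), center = numeric(),
                      rbar = numeric(), rbar_se = numeric(),
                      n_pairs = integer(), depth = integer(), eps = numeric()))
  do.call(rbind, rows)
}

#' Select the analysis window by signal adequacy
#'
#' A window qualifies when `rbar - 2 * rbar_se > 0`, i.e. its mean pairwise
#' correlation is distinguishable from zero. Among qualifying windows the one
#' with the largest number of pairwise correlations is chosen; remaining ties
#' go to the earliest start year. When no window qualifies the result is an
#' explicit "no adequate signal" outcome, not an error.
#'
#' @param stats Data frame from [rbar_windowed()].
#' @return List with `no_signal` (logical), `start`/`end` (chosen window,
#'   `NA` when `no_signal`), and `table` (the input with a `qualified`
#'   column).
#' @export
select_window <- function(stats) {
  if (nrow(stats) == 0)
    return(list(no_signal = TRUE, start = NA_integer_, end = NA_integer_,
                table = stats))
  qual <- !is.na(stats$rbar_se) & (stats$rbar - 2 * stats$rbar_se > 0)
  stats$qualified <- qual
  if (!any(qual))
    return(list(no_signal = TRUE, start = NA_integer_, end = NA_integer_,
                table = stats))
  q <- stats[qual, ]
  q <- q[order(-q$n_pairs, q$start), ]
  list(no_signal = FALSE, start = q$start[1], end = q$end[1], table = stats)
}

# Fit AR(p) by Yule-Walker with AIC order selection; returns prewhitened
# series (residuals recentred on the series mean, NA for the first p years),
# the order and coefficients. Non-stationary fits fall back to order 0.
prewhiten_series <- function(x, max_order = 3) {
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = max_order, method = "yule-walker"),
    error = function(e) NULL)
  fallback <- FALSE
  if (is.null(fit)) {
    ord <- 0L; phi <- numeric(); res <- x - mean(x); fallback <- TRUE
  } else {
    ord <- fit$order
    phi <- fit$ar
    if (ord > 0 && any(Mod(polyroot(c(1, -phi))) <= 1)) {
      ord <- 0L; phi <- numeric(); fallback <- TRUE
    }
    res <- if (ord == 0) x - mean(x) else as.numeric(fit$resid)
  }
  list(prewhitened = res + mean(x), order = ord, phi = phi,
       fallback = fallback)
}

#' Autoregressive (ARSTAN-style) standardization
#'
#' Fits an AR(p) model to each index series (order chosen by AIC, `0 <= p <=
#' max_order`), averages the prewhitened series into a *residual* chronology
#' rescaled to mean 1, and reintroduces the depth-weighted pooled AR
#' structure into that chronology to form the *ar_standardized* ("arstan")
#' variant. The plain standard chronology is always emitted for comparison.
#' Series whose AR fit is non-stationary fall back to order 0 and are
#' flagged.
#'
#' @param series List of [index_series()] or an aligned matrix; every series
#'   must be longer than `max_order + 5`.
#' @param max_order Maximum AR order considered.
#' @param robust Use the biweight mean when averaging.
#' @return List with chronologies `standard`, `residual`, `arstan`, a data
#'   frame `info` (series, selected order, lag-1 coefficient, fallback flag)
#'   and `pooled_ar` (pooled coefficient vector).
#' @export
ar_standardize <- function(series, max_order = 3, robust = FALSE) {
  m <- as_series_matrix(series)
  yrs <- as.integer(rownames(m))
  pw <- m * NA_real_
  info <- list()
  coefs <- list()
  lens <- numeric()
  for (j in seq_len(ncol(m))) {
    ok <- which(!is.na(m[, j]))
    x <- m[ok, j]
    if (length(x) <= max_order + 5)
      stop(sprintf("series %s too short for AR(%d) standardization",
                   colnames(m)[j], max_order))
    fit <- prewhiten_series(x, max_order)
    pw[ok, j] <- fit$prewhitened
    info[[j]] <- data.frame(series = colnames(m)[j], order = fit$order,
                            ar1 = if (fit$order >= 1) fit$phi[1] else 0,
                            fallback = fit$fallback)
    coefs[[j]] <- fit$phi
    lens[j] <- length(x)
  }
  standard <- mean_chronology(m, robust)
  vals <- if (robust) apply(pw, 1, biweight_mean) else rowMeans(pw, na.rm = TRUE)
  depth <- rowSums(!is.na(pw))
  keep <- depth >= 1 & is.finite(vals)
  vals <- vals[keep] / mean(vals[keep])
  residual <- new_chronology(yrs[keep], vals, depth[keep], "residual")
  pmax_ <- max(vapply(coefs, length, 0L))
  pooled <- if (pmax_ == 0) numeric() else {
    padded <- vapply(coefs, function(p) c(p, rep(0, pmax_ - length(p))),
                     numeric(pmax_))
    padded <- matrix(padded, nrow = pmax_)
    as.numeric(padded %*% lens / sum(lens))
  }
  ar_vals <- if (length(pooled) == 0) residual$value else
    as.numeric(stats::filter(residual$value - 1, pooled,
                             method = "recursive")) + 1
  arstan <- new_chronology(residual$year, ar_vals, residual$depth,
                           "ar_standardized")
  list(standard = standard, residual = residual, arstan = arstan,
       info = do.call(rbind, info), pooled_ar = pooled)
}
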
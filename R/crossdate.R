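# COFECHA-style dating quality control. Each series is compared against a
# leave-one-out master built from all other series after a common transform:
# high-pass ratio detrend (15-year cutoff spline), AR(1) prewhitening and
# z-scoring. Dating errors show up as segments whose best-matching lag is
# not zero, or whose lag-0 correlation falls below a critical value.

#' One-tailed critical correlation
#'
#' The t-based critical value of a Pearson correlation over `n` paired
#' observations: `r* = t* / sqrt(n - 2 + t*^2)` with `t*` the one-tailed
#' `conf` quantile on `n - 2` degrees of freedom. COFECHA convention is the
#' 99% point.
#'
#' @param n Number of paired observations (> 2).
#' @param conf One-tailed confidence level.
#' @return Critical correlation in (0, 1).
#' @export
critical_r <- function(n, conf = 0.99) {
  stopifnot(n > 2)
  t <- qt(conf, n - 2)
  t / sqrt(n - 2 + t^2)
}

# High-pass + prewhiten + z-score one numeric series for crossdating.
filter_for_crossdating <- function(x, highpass_cutoff = 15, prewhiten = TRUE) {
  if (length(x) >= 4) {
    fitted <- fit_spline(x, highpass_cutoff)
    if (all(fitted > 0)) x <- x / fitted else x <- x / mean(x)
  }
  if (prewhiten && length(x) >= 8) {
    fit <- tryCatch(stats::ar(x, aic = FALSE, order.max = 1,
                              method = "yule-walker"),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$order == 1) x <- as.numeric(fit$resid)
  }
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(x * 0)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Build a leave-one-out master chronology
#'
#' Transforms every series with the crossdating filter (high-pass ratio
#' detrend, optional AR(1) prewhitening, z-scoring), drops the excluded
#' series, and averages the rest per year.
#'
#' @param series List of [index_series()] / [transect_series()] or an aligned
#'   matrix.
#' @param exclude_id Series id(s) to leave out (`NULL` for none).
#' @param highpass_cutoff 50% frequency cutoff (years) of the high-pass
#'   spline.
#' @param prewhiten Remove AR(1) structure before averaging?
#' @return Data frame `year`, `value`, `depth`.
#' @export
build_master <- function(series, exclude_id = NULL, highpass_cutoff = 15,
                         prewhiten = TRUE) {
  m <- as_series_matrix(series)
  fm <- filter_series_matrix(m, highpass_cutoff, prewhiten)
  keep <- setdiff(colnames(fm), exclude_id)
  if (length(keep) < 2)
    stop("need at least 2 series besides the excluded one")
  fm <- fm[, keep, drop = FALSE]
  vals <- rowMeans(fm, na.rm = TRUE)
  depth <- rowSums(!is.na(fm))
  ok <- depth >= 1 & is.finite(vals)
  data.frame(year = as.integer(rownames(fm))[ok], value = vals[ok],
             depth = depth[ok])
}

# Apply the crossdating filter column-wise on an aligned matrix.
filter_series_matrix <- function(m, highpass_cutoff = 15, prewhiten = TRUE) {
  out <- m * NA_real_
  for (j in seq_len(ncol(m))) {
    ok <- which(!is.na(m[, j]))
    out[ok, j] <- filter_for_crossdating(m[ok, j], highpass_cutoff, prewhiten)
  }
  out
}

#' Lagged segment correlations of one series against a master
#'
#' Splits the series/master overlap into segments (default 15 years with 50%
#' overlap) and correlates each segment with the master at integer lags
#' `-max_lag..max_lag`. `r(lag) = cor(x[t], master[t + lag])`, so a best lag
#' of `+k` means the series' growth pattern matches the master `k` years
#' later, i.e. its assigned years are `k` years too early; `-k` means they
#' are `k` years too old. Ties between lags go to the smaller absolute lag,
#' then to the negative lag. A segment is flagged when its lag-0 correlation
#' falls below [critical_r()] (`low_corr`) or its best lag is non-zero
#' (`off_dating`).
#'
#' Both inputs must be on the same crossdating transform; use
#' [crossdate_dataset()] for the standard end-to-end workflow.
#'
#' @param x An [index_series()] (already filtered) or numeric vector.
#' @param master Data frame from [build_master()].
#' @param first_year First year of `x` when `x` is a bare numeric vector.
#' @param seg_length Segment length in years.
#' @param seg_overlap Fractional overlap between consecutive segments.
#' @param max_lag Maximum absolute lag tested (years).
#' @param conf One-tailed confidence for the critical correlation.
#' @return Data frame, one row per segment: `series`, `seg_start`,
#'   `seg_end`, `n`, `r_lag0`, `best_lag`, `r_best`, `crit_r`, `low_corr`,
#'   `off_dating`.
#' @export
segment_correlations <- function(x, master, first_year = NULL,
                                 seg_length = 15, seg_overlap = 0.5,
                                 max_lag = 2, conf = 0.99) {
  if (inherits(x, "index_series")) {
    first_year <- x$first_year
    sid <- x$owner_id
    x <- x$indices
  } else {
    if (is.null(first_year)) stop("first_year required for a bare vector")
    sid <- "series"
  }
  sy <- first_year + seq_along(x) - 1L
  mvals <- master$value[match(sy, master$year)]
  common <- which(!is.na(x) & !is.na(mvals))
  if (length(common) < seg_length)
    stop(sprintf("overlap with master (%d yr) shorter than segment length %d",
                 length(common), seg_length))
  lo <- min(common); hi <- max(common)
  step <- max(1L, as.integer(floor(seg_length * (1 - seg_overlap))))
  starts <- seq(lo, hi - seg_length + 1L, by = step)
  if (starts[length(starts)] + seg_length - 1L < hi)
    starts <- c(starts, hi - seg_length + 1L)
  lags <- -max_lag:max_lag
  rows <- list()
  for (s in starts) {
    sel <- s:(s + seg_length - 1L)
    rl <- vapply(lags, function(l) {
      mv <- master$value[match(sy[sel] + l, master$year)]
      ok <- complete.cases(x[sel], mv)
      if (sum(ok) < max(3L, seg_length - max_lag)) return(NA_real_)
      cor(x[sel][ok], mv[ok])
    }, 0)
    if (all(is.na(rl))) next
    ord <- order(-rl, abs(lags), lags, na.last = TRUE)
    best <- ord[1]
    r0 <- rl[lags == 0]
    crit <- critical_r(seg_length, conf)
    rows[[length(rows) + 1L]] <- data.frame(
      series = sid, seg_start = sy[s], seg_end = sy[s] + seg_length - 1L,
      n = seg_length, r_lag0 = r0, best_lag = lags[best], r_best = rl[best],
      crit_r = crit, low_corr = is.na(r0) | r0 < crit,
      off_dating = lags[best] != 0L)
  }
  do.call(rbind, rows)
}

#' Interseries correlation
#'
#' For every series, the Pearson correlation between it and the year-wise
#' mean of all other series over their common years; the mean of these
#' coefficients is the interseries correlation, a measure of common-signal
#' strength. Series overlapping the others' mean by fewer than
#' `min_overlap` years are flagged and excluded from the mean.
#'
#' @param series List of [index_series()] (typically IMS) or aligned matrix;
#'   at least 3 series.
#' @param min_overlap Minimum overlap in years.
#' @return List with `per_series` (data frame: `series`, `r`, `n_overlap`,
#'   `flagged`) and `mean_r`.
#' @export
interseries_correlation <- function(series, min_overlap = 5) {
  m <- as_series_matrix(series)
  if (ncol(m) < 3) stop("need at least 3 series")
  rows <- lapply(seq_len(ncol(m)), function(i) {
    others <- rowMeans(m[, -i, drop = FALSE], na.rm = TRUE)
    ok <- !is.na(m[, i]) & is.finite(others)
    n <- sum(ok)
    r <- if (n >= 3) cor(m[ok, i], others[ok]) else NA_real_
    data.frame(series = colnames(m)[i], r = r, n_overlap = n,
               flagged = n < min_overlap)
  })
  per <- do.call(rbind, rows)
  list(per_series = per,
       mean_r = mean(per$r[!per$flagged], na.rm = TRUE))
}

#' Crossdate a whole dataset
#'
#' Filters every series once, then checks each against its leave-one-out
#' master with [segment_correlations()], and computes the interseries
#' correlations of the raw (unfiltered) series.
#'
#' @param series List of [index_series()] (detrended transects or IMS).
#' @param seg_length,seg_overlap,max_lag,conf See [segment_correlations()].
#' @param highpass_cutoff,prewhiten See [build_master()].
#' @return List with `segments` (stacked segment table over all series),
#'   `interseries` (from [interseries_correlation()]) and `summary`
#'   (per-series flag counts).
#' @export
crossdate_dataset <- function(series, seg_length = 15, seg_overlap = 0.5,
                              max_lag = 2, conf = 0.99,
                              highpass_cutoff = 15, prewhiten = TRUE) {
  m <- as_series_matrix(series)
  fm <- filter_series_matrix(m, highpass_cutoff, prewhiten)
  yrs <- as.integer(rownames(fm))
  seg_all <- list()
  for (j in seq_len(ncol(fm))) {
    others <- fm[, -j, drop = FALSE]
    depth <- rowSums(!is.na(others))
    mv <- rowMeans(others, na.rm = TRUE)
    ok <- depth >= 1 & is.finite(mv)
    master <- data.frame(year = yrs[ok], value = mv[ok], depth = depth[ok])
    xs <- fm[, j]
    first <- yrs[which(!is.na(xs))[1]]
    xv <- xs[!is.na(xs)]
    seg <- tryCatch(
      segment_correlations(xv, master, first_year = first,
                           seg_length = seg_length,
                           seg_overlap = seg_overlap,
                           max_lag = max_lag, conf = conf),
      error = function(e) NULL)
    if (!is.null(seg)) {
      seg$series <- colnames(fm)[j]
      seg_all[[length(seg_all) + 1L]] <- seg
    }
  }
  segments <- do.call(rbind, seg_all)
  inter <- interseries_correlation(series)
  summ <- if (!is.null(segments))
    aggregate(cbind(low_corr = segments$low_corr,
                    off_dating = segments$off_dating),
              by = list(series = segments$series), FUN = sum)
  else NULL
  list(segments = segments, interseries = inter, summary = summ)
}
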
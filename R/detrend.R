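#' Detrend one transect series
#'
#' Removes the ontogenetic growth decline by fitting the cutoff-parameterised
#' smoothing spline ([fit_spline()]) and dividing by it. When the fitted
#' curve touches zero or below (rare, pathological series), the function
#' falls back to a horizontal-mean detrend for that series and flags it —
#' the standard behaviour of chronology software, keeping indices positive.
#'
#' @param ts A [transect_series()].
#' @param cutoff_years Spline 50% frequency cutoff in years.
#' @param response Amplitude response at the cutoff.
#' @return An [index_series()] (level `"transect"`) with attribute
#'   `"fallback"` (logical: horizontal-mean detrend used).
#' @export
detrend_series <- function(ts, cutoff_years = 9, response = 0.5) {
  fitted <- fit_spline(ts$widths, cutoff_years, response)
  fallback <- any(fitted <= 0)
  if (fallback) fitted <- rep(mean(ts$widths), length(ts$widths))
  idx <- detrend_ratio(ts$widths, fitted)
  out <- index_series(series_id(ts), "transect", ts$first_year, idx)
  attr(out, "fallback") <- fallback
  attr(out, "fitted") <- fitted
  out
}

#' Average transect indices into an individual mean series (IMS)
#'
#' Arithmetic mean of the detrended transect indices per year, over the
#' transects present in that year.
#'
#' @param indices List of transect-level [index_series()] for one fish.
#' @param owner_id Fish identifier; derived from the first transect id when
#'   omitted.
#' @return An [index_series()] at level `"fish"`.
#' @export
average_transects <- function(indices, owner_id = NULL) {
  if (length(indices) == 0) stop("no transect index series supplied")
  if (is.null(owner_id))
    owner_id <- sub("_[^_]*$", "", indices[[1]]$owner_id)
  m <- as_series_matrix(indices)
  vals <- rowMeans(m, na.rm = TRUE)
  yrs <- as.integer(rownames(m))
  keep <- is.finite(vals)
  index_series(owner_id, "fish", yrs[keep][1], vals[keep])
}

#' Detrend a whole dataset and form individual mean series
#'
#' Runs [detrend_series()] on every transect of every fish and averages each
#' fish's transects into its IMS.
#'
#' @param records List of [fish_record()] objects.
#' @param cutoff_years,response Spline settings, see [fit_spline()].
#' @return List with elements `ims` (named list of fish-level
#'   [index_series()]), `transect_indices` (named list of transect-level
#'   index series) and `report` (data frame, one row per transect:
#'   series id, length, fitted-curve minimum, index mean/variance,
#'   fallback flag).
#' @export
detrend_dataset <- function(records, cutoff_years = 9, response = 0.5) {
  ims <- list()
  tix <- list()
  rep_rows <- list()
  for (fr in records) {
    fish_idx <- list()
    for (tr in fr$transects) {
      di <- detrend_series(tr, cutoff_years, response)
      tix[[di$owner_id]] <- di
      fish_idx[[length(fish_idx) + 1L]] <- di
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        series = di$owner_id, n = length(di$indices),
        first_year = di$first_year,
        fitted_min = min(attr(di, "fitted")),
        index_mean = mean(di$indices), index_var = var(di$indices),
        fallback = attr(di, "fallback"))
    }
    ims[[fr$fish_id]] <- average_transects(fish_idx, fr$fish_id)
  }
  list(ims = ims, transect_indices = tix,
       report = do.call(rbind, rep_rows))
}

#' Scan candidate spline rigidities
#'
#' Runs the full detrend -> IMS -> windowed signal-statistics pipeline for
#' each candidate 50% frequency cutoff and tabulates the windowed mean
#' pairwise correlation, EPS and mean sensitivity. The chosen candidate
#' maximises the EPS of its selected window; ties are broken toward the
#' stiffer (larger-cutoff) spline, which is the less flexible and therefore
#' less overfitting-prone choice.
#'
#' @param records List of [fish_record()] objects.
#' @param candidates Numeric vector of candidate cutoffs (years), length >= 1.
#' @param window_length Window length in years for the signal statistics.
#' @param response Spline amplitude response at the cutoff.
#' @return List with `table` (one row per candidate: cutoff, best-window
#'   bounds, rbar, se, n_pairs, depth, eps, mean IMS sensitivity, qualified
#'   flag) and `chosen` (the selected cutoff).
#' @export
select_rigidity <- function(records, candidates, window_length = 15,
                            response = 0.5) {
  if (length(records) == 0) stop("empty dataset")
  if (length(candidates) < 1) stop("need at least one candidate cutoff")
  rows <- lapply(candidates, function(cu) {
    dt <- detrend_dataset(records, cu, response)
    st <- rbar_windowed(dt$ims, window_length)
    sel <- select_window(st)
    ms <- mean(vapply(dt$ims, function(s) mean_sensitivity(s$indices), 0))
    if (nrow(st) == 0)
      return(data.frame(cutoff_years = cu, window_start = NA, window_end = NA,
                        rbar = NA, rbar_se = NA, n_pairs = NA, depth = NA,
                        eps = NA, mean_sens = ms, qualified = FALSE))
    best <- if (!sel$no_signal)
      st[st$start == sel$start, , drop = FALSE][1, ]
    else st[which.max(st$rbar), , drop = FALSE]
    data.frame(cutoff_years = cu, window_start = best$start,
               window_end = best$end, rbar = best$rbar, rbar_se = best$rbar_se,
               n_pairs = best$n_pairs, depth = best$depth, eps = best$eps,
               mean_sens = ms, qualified = !sel$no_signal)
  })
  tab <- do.call(rbind, rows)
  pool <- if (any(tab$qualified)) tab[tab$qualified, ] else tab
  pool <- pool[!is.na(pool$eps), , drop = FALSE]
  chosen <- if (nrow(pool)) {
    best <- pool[order(-pool$eps, -pool$cutoff_years), ][1, ]
    best$cutoff_years
  } else candidates[1]
  list(table = tab, chosen = chosen)
}
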
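#' Read a long-format increment-width table
#'
#' Expects a UTF-8 CSV with header columns `fish_id`, `transect_id`, `year`,
#' `width_mm`, and optionally per-fish constants `capture_year` and
#' `age_at_capture`. Rows are grouped into one [fish_record()] per fish, with
#' one [transect_series()] per transect. Years within a transect must be
#' contiguous.
#'
#' @param path Path to the CSV file.
#' @param min_age,transect_bounds,validate Passed to [fish_record()].
#' @return Named list of [fish_record()] objects.
#' @export
read_increment_csv <- function(path, min_age = 12, transect_bounds = c(3, 5),
                               validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "transect_id", "year", "width_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(df$fish_id, df$transect_id, df$year)
  if (anyDuplicated(key))
    stop("duplicate (fish, transect, year) row: ", key[duplicated(key)][1])
  records <- list()
  for (fid in unique(df$fish_id)) {
    dfish <- df[df$fish_id == fid, ]
    transects <- list()
    for (tid in unique(dfish$transect_id)) {
      dt <- dfish[dfish$transect_id == tid, ]
      dt <- dt[order(dt$year), ]
      gaps <- which(diff(dt$year) != 1L)
      if (length(gaps))
        stop(sprintf("gap at %d in fish %s transect %s",
                     dt$year[gaps[1]] + 1L, fid, tid))
      transects[[length(transects) + 1L]] <-
        transect_series(fid, tid, dt$year[1], dt$width_mm)
    }
    cy <- if ("capture_year" %in% names(df)) dfish$capture_year[1] else NA
    ac <- if ("age_at_capture" %in% names(df)) dfish$age_at_capture[1] else NA
    records[[as.character(fid)]] <- fish_record(
      fid, cy, ac, transects, min_age = min_age,
      transect_bounds = transect_bounds,
      validate = validate && !is.na(cy))
  }
  records
}

#' Write fish records as a long-format increment CSV
#'
#' @param records List of [fish_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_increment_csv <- function(records, path) {
  rows <- lapply(records, function(fr) {
    do.call(rbind, lapply(fr$transects, function(tr) {
      data.frame(fish_id = fr$fish_id, transect_id = tr$transect_id,
                 year = series_years(tr), width_mm = tr$widths,
                 capture_year = fr$capture_year,
                 age_at_capture = fr$age_at_capture)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Assign calendar years to measured increments
#'
#' An increment's growth year runs from about November of one calendar year
#' through October of the next; the increment is labelled with the calendar
#' year containing most of that growth (the "current calendar year"). The
#' outermost, still-forming increment at capture is partial and is assumed
#' excluded from the measured ages, so the last measured increment is the
#' last *complete* one: labelled `capture_year` when capture falls in
#' November or December (the next growth year has already begun), otherwise
#' `capture_year - 1`.
#'
#' @param ages Increasing integer ordinal ages of the measured (complete)
#'   increments.
#' @param capture_year Calendar year of capture.
#' @param capture_month Month of capture, 1-12.
#' @return Integer vector of calendar years, one per age.
#' @export
assign_growth_years <- function(ages, capture_year, capture_month = 6) {
  ages <- as.integer(ages)
  if (length(ages) == 0) stop("no ages supplied")
  if (any(diff(ages) <= 0)) stop("ages must be increasing")
  stopifnot(capture_month >= 1, capture_month <= 12)
  last_complete <- capture_year - as.integer(capture_month < 11)
  years <- last_complete - (max(ages) - ages)
  if (any(years > capture_year))
    stop("labelled year exceeds capture year")
  as.integer(years)
}

#' Read an environmental series CSV
#'
#' Annual files have columns `year,value`; monthly files have
#' `year,month,value`. Monthly input is returned as a plain data frame for
#' use with [seasonal_means()]; annual input becomes an [env_series()].
#'
#' @param path Path to CSV.
#' @param name Variable name for the resulting series.
#' @param season Season label for annual input.
#' @return An [env_series()] (annual) or data frame (monthly).
#' @export
read_env_csv <- function(path, name = sub("\\.csv$", "", basename(path)),
                         season = "annual") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("month" %in% names(df)) {
    stopifnot(all(c("year", "month", "value") %in% names(df)))
    return(df[c("year", "month", "value")])
  }
  stopifnot(all(c("year", "value") %in% names(df)))
  df <- df[order(df$year), ]
  env_series(name, df$year, df$value, season = season)
}

#' Write an environmental series to CSV
#' @param x An [env_series()] or a monthly data frame (`year,month,value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_csv <- function(x, path) {
  df <- if (inherits(x, "env_series"))
    data.frame(year = x$years, value = x$values) else x
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
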
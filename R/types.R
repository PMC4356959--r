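#' Increment-width series for one measurement transect
#'
#' A `transect_series` holds the annual growth-increment widths (mm) measured
#' along one transect of one fish's otolith, aligned to contiguous calendar
#' years.
#'
#' @param fish_id,transect_id Identifiers (coerced to character).
#' @param first_year Calendar year of the first measured increment.
#' @param widths Numeric vector of increment widths in mm; all positive,
#'   length at least 2, one value per consecutive year.
#' @return An object of class `transect_series`.
#' @export
transect_series <- function(fish_id, transect_id, first_year, widths) {
  widths <- as.numeric(widths)
  if (length(widths) < 2L)
    stop("transect series must contain at least 2 increments")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop(sprintf("non-positive or missing width in series %s_%s",
                 fish_id, transect_id))
  first_year <- as.integer(first_year)
  structure(list(fish_id = as.character(fish_id),
                 transect_id = as.character(transect_id),
                 first_year = first_year,
                 widths = widths),
            class = "transect_series")
}

#' @export
print.transect_series <- function(x, ...) {
  cat(sprintf("<transect_series %s: %d increments, %d-%d, mean %.3f mm>\n",
              series_id(x), length(x$widths), x$first_year,
              x$first_year + length(x$widths) - 1L, mean(x$widths)))
  invisible(x)
}

#' Identifier of a series (fish id and transect id joined by "_")
#' @param x A `transect_series` or `index_series`.
#' @return Character scalar.
#' @export
series_id <- function(x) {
  if (inherits(x, "transect_series"))
    paste(x$fish_id, x$transect_id, sep = "_")
  else x$owner_id
}

#' Calendar years covered by a series
#' @param x A `transect_series` or `index_series`.
#' @return Integer vector of consecutive calendar years.
#' @export
series_years <- function(x) {
  n <- if (inherits(x, "transect_series")) length(x$widths) else length(x$indices)
  x$first_year + seq_len(n) - 1L
}

#' One fish's otolith record
#'
#' Groups the 3-5 measurement transects of one otolith with capture metadata.
#' Measured increments are restricted to ages above `min_age` because inner
#' increments (pelagic juvenile phase) cannot be measured reliably.
#'
#' @param fish_id Identifier.
#' @param capture_year Calendar year of capture (`NA` if unknown).
#' @param age_at_capture Age in years at capture (`NA` if unknown).
#' @param transects List of [transect_series()] for this fish.
#' @param sex,length_cm Optional metadata.
#' @param min_age Minimum age (exclusive) of measurable increments.
#' @param transect_bounds Allowed range of transect counts.
#' @param validate Check invariants (transect count, years vs capture year,
#'   measured ages above `min_age`)?
#' @return An object of class `fish_record`.
#' @export
fish_record <- function(fish_id, capture_year = NA, age_at_capture = NA,
                        transects = list(), sex = NA, length_cm = NA,
                        min_age = 12, transect_bounds = c(3, 5),
                        validate = TRUE) {
  if (validate) {
    nt <- length(transects)
    if (nt < transect_bounds[1] || nt > transect_bounds[2])
      stop(sprintf("fish %s has %d transects; expected %d-%d",
                   fish_id, nt, transect_bounds[1], transect_bounds[2]))
    for (tr in transects) {
      last <- max(series_years(tr))
      if (!is.na(capture_year) && last > capture_year)
        stop(sprintf("fish %s transect %s extends past capture year %d",
                     fish_id, tr$transect_id, capture_year))
      if (!is.na(capture_year) && !is.na(age_at_capture)) {
        first_age <- age_at_capture - (capture_year - tr$first_year)
        if (first_age <= min_age)
          stop(sprintf(
            "fish %s transect %s starts at age %d; increments must form after age %d",
            fish_id, tr$transect_id, first_age, min_age))
      }
    }
  }
  structure(list(fish_id = as.character(fish_id),
                 capture_year = as.integer(capture_year),
                 age_at_capture = as.integer(age_at_capture),
                 transects = transects, sex = sex, length_cm = length_cm),
            class = "fish_record")
}

#' @export
print.fish_record <- function(x, ...) {
  cat(sprintf("<fish_record %s: %d transects, captured %s at age %s>\n",
              x$fish_id, length(x$transects),
              ifelse(is.na(x$capture_year), "?", x$capture_year),
              ifelse(is.na(x$age_at_capture), "?", x$age_at_capture)))
  invisible(x)
}

#' Dimensionless detrended index series
#'
#' Ratio indices (width / fitted ontogenetic curve) for one transect, one fish
#' (individual mean series, IMS), or a chronology-level mean.
#'
#' @param owner_id Identifier of the series owner.
#' @param level One of `"transect"`, `"fish"`, `"chronology"`.
#' @param first_year Calendar year of the first index.
#' @param indices Positive numeric vector, one value per consecutive year.
#' @return An object of class `index_series`.
#' @export
index_series <- function(owner_id, level = c("transect", "fish", "chronology"),
                         first_year, indices) {
  level <- match.arg(level)
  indices <- as.numeric(indices)
  if (any(!is.finite(indices)) || any(indices <= 0))
    stop(sprintf("non-positive index in series %s", owner_id))
  structure(list(owner_id = as.character(owner_id), level = level,
                 first_year = as.integer(first_year), indices = indices),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("<index_series %s (%s): %d years from %d, mean %.3f>\n",
              x$owner_id, x$level, length(x$indices), x$first_year,
              mean(x$indices)))
  invisible(x)
}

#' Annual environmental series
#'
#' @param name Variable name (e.g. `"sea_level"`).
#' @param years Strictly increasing calendar years.
#' @param values One value per year.
#' @param season `"annual"` or one of the austral season codes
#'   `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @param preprocessing Character vector of provenance tags (e.g.
#'   `"linear_detrended"`).
#' @return An object of class `env_series`.
#' @export
env_series <- function(name, years, values,
                       season = c("annual", "DJF", "MAM", "JJA", "SON"),
                       preprocessing = character()) {
  season <- match.arg(season)
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values))
    stop("years and values must have equal length")
  if (any(diff(years) <= 0))
    stop("years must be strictly increasing")
  structure(list(name = as.character(name), season = season, years = years,
                 values = values, preprocessing = preprocessing),
            class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  prep <- if (length(x$preprocessing)) paste0(" [",
    paste(x$preprocessing, collapse = ","), "]") else ""
  cat(sprintf("<env_series %s (%s)%s: %d years %d-%d>\n",
              x$name, x$season, prep, length(x$years),
              min(x$years), max(x$years)))
  invisible(x)
}

# Align a list of transect_series / index_series (or pass through a matrix)
# into a years x series matrix with NA outside each series' coverage.

#' Align series into a year-by-series matrix
#'
#' @param series List of [transect_series()] or [index_series()] objects
#'   (or an already-aligned numeric matrix with years as rownames, returned
#'   unchanged).
#' @return Numeric matrix, rownames = calendar years, colnames = series ids.
#' @export
as_series_matrix <- function(series) {
  if (is.matrix(series)) return(series)
  if (inherits(series, c("transect_series", "index_series")))
    series <- list(series)
  stopifnot(length(series) >= 1)
  yrs <- lapply(series, series_years)
  all_years <- seq(min(unlist(yrs)), max(unlist(yrs)))
  m <- matrix(NA_real_, nrow = length(all_years), ncol = length(series),
              dimnames = list(all_years, vapply(series, series_id, "")))
  for (i in seq_along(series)) {
    v <- if (inherits(series[[i]], "transect_series"))
      series[[i]]$widths else series[[i]]$indices
    m[match(yrs[[i]], all_years), i] <- v
  }
  m
}

# internal chronology constructor
new_chronology <- function(years, values, depth, variant) {
  out <- data.frame(year = as.integer(years), value = as.numeric(values),
                    depth = as.integer(depth))
  attr(out, "variant") <- variant
  class(out) <- c("chronology", "data.frame")
  out
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology (%s): %d years %d-%d, mean %.3f, max depth %d>\n",
              attr(x, "variant"), nrow(x), min(x$year), max(x$year),
              mean(x$value), max(x$depth)))
  invisible(as.data.frame(x))
}
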
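#' Read a Tucson RWL ring-width file
#'
#' Parses the decadal-row Tucson exchange format used by chronology software.
#' Each data line carries a series id, the calendar year of its first value,
#' and up to ten integer widths; a series ends with a sentinel that also fixes
#' its units: `-9999` for the 0.001 mm dialect, `999` for the 0.01 mm dialect.
#' Lines are tokenised on whitespace, so series ids must not contain spaces.
#'
#' Series ids of the form `<fish>_<transect>` are split at the last underscore
#' to recover fish and transect identifiers; ids without an underscore get
#' transect id `"T1"`.
#'
#' @param path Path to an RWL file.
#' @return Named list of [transect_series()], one per series id.
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  buf <- list()  # id -> list(first_year, expect, tokens)
  order_seen <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 3)
      stop(sprintf("malformed decade row at line %d: fewer than 3 fields", i))
    id <- tok[1]
    yr <- suppressWarnings(as.integer(tok[2]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(yr) || any(is.na(vals)))
      stop(sprintf("malformed decade row at line %d: non-numeric field", i))
    if (is.null(buf[[id]])) {
      buf[[id]] <- list(first_year = yr, expect = yr, tokens = numeric(),
                        closed = FALSE)
      order_seen <- c(order_seen, id)
    } else {
      if (buf[[id]]$closed)
        stop(sprintf("series %s continues after its sentinel (line %d)", id, i))
      if (yr != buf[[id]]$expect)
        stop(sprintf(
          "malformed decade row at line %d: series %s expected year %d, found %d",
          i, id, buf[[id]]$expect, yr))
    }
    buf[[id]]$tokens <- c(buf[[id]]$tokens, vals)
    buf[[id]]$expect <- buf[[id]]$first_year + length(buf[[id]]$tokens)
    if (any(vals == -9999) || any(vals == 999))
      buf[[id]]$closed <- TRUE
  }
  out <- list()
  for (id in order_seen) {
    b <- buf[[id]]
    s1 <- match(-9999, b$tokens)
    s2 <- match(999, b$tokens)
    if (!is.na(s1)) { unit <- 0.001; send <- s1 }
    else if (!is.na(s2)) { unit <- 0.01; send <- s2 }
    else stop(sprintf("series %s has no terminal sentinel (-9999 or 999)", id))
    if (send != length(b$tokens))
      stop(sprintf("series %s has data after its sentinel", id))
    raw <- b$tokens[seq_len(send - 1L)]
    if (any(raw <= 0)) {
      bad <- which(raw <= 0)[1]
      stop(sprintf("non-positive width in series %s, year %d",
                   id, b$first_year + bad - 1L))
    }
    fid <- sub("_[^_]*$", "", id)
    tid <- if (grepl("_", id)) sub("^.*_", "", id) else "T1"
    out[[id]] <- transect_series(fid, tid, b$first_year, raw * unit)
  }
  out
}

#' Write series to a Tucson RWL file
#'
#' Emits the 0.001 mm integer dialect with a `-9999` terminal sentinel, the
#' most common dialect among chronology tools. Values round-trip through
#' [read_rwl()] at 0.001 mm precision.
#'
#' @param series A [transect_series()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  if (inherits(series, "transect_series")) series <- list(series)
  con <- file(path, "w")
  on.exit(close(con))
  for (ts in series) {
    id <- series_id(ts)
    if (grepl("\\s", id)) stop("series id must not contain whitespace: ", id)
    ints <- as.integer(round(ts$widths * 1000))
    yrs <- series_years(ts)
    vals <- c(ints, -9999L)
    yr <- ts$first_year
    pos <- 1L
    while (pos <= length(vals)) {
      decade_end <- (yr %/% 10L) * 10L + 9L
      take <- min(decade_end - yr + 1L, length(vals) - pos + 1L)
      row <- vals[pos:(pos + take - 1L)]
      writeLines(paste0(sprintf("%-8s", id), sprintf("%4d", yr),
                        paste(sprintf("%6d", row), collapse = "")), con)
      pos <- pos + take
      yr <- yr + take
    }
  }
  invisible(path)
}
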
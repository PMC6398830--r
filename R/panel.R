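#' Read a daily multi-pollutant panel
#'
#' Reads a date-indexed CSV holding daily pollutant concentrations, meteorology
#' and an event count, and validates it into the tidy panel layout used by the
#' fitting functions: one row per calendar day, one column per variable, blank
#' cells for missing concentrations.
#'
#' The date axis must be contiguous: a panel never silently drops a day, since
#' the latent autoregressive process bridges days on which every pollutant is
#' missing. Unparseable or blank pollutant cells become `NA` (missing), and are
#' later treated as unknowns by the samplers, never imputed at I/O time.
#'
#' @param path Path to a CSV file.
#' @param pollutants Character vector naming the pollutant columns. If `NULL`,
#'   every column other than `date_col`, `count_col`, `temp_col` and
#'   `rhum_col` is taken to be a pollutant.
#' @param date_col,count_col,temp_col,rhum_col Column names for the calendar
#'   date (ISO-8601), the daily event count, daily mean temperature (degrees
#'   Celsius) and daily mean relative humidity (percent).
#' @param extra_holidays Optional vector of `Date`s treated as public holidays
#'   in addition to weekends (see [holiday_indicator()]).
#'
#' @return A tibble of class `poll_panel` with columns `date`, the pollutant
#'   columns, `temperature`, `rel_humidity`, `count`, `holiday` and
#'   `time_index`, plus a `"pollutants"` attribute naming the pollutant
#'   columns.
#' @export
read_panel <- function(path, pollutants = NULL,
                       date_col = "date", count_col = "count",
                       temp_col = "temperature", rhum_col = "rel_humidity",
                       extra_holidays = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(date_col, count_col)) {
    if (!col %in% names(raw)) {
      abort(paste0("required column '", col, "' is missing"), class = "multipoll_format_error")
    }
  }
  if (is.null(pollutants)) {
    pollutants <- setdiff(names(raw), c(date_col, count_col, temp_col, rhum_col))
  } else if (!all(pollutants %in% names(raw))) {
    abort(paste0("pollutant column(s) not found: ",
                 paste(setdiff(pollutants, names(raw)), collapse = ", ")),
          class = "multipoll_format_error")
  }
  out <- tibble::tibble(date = as.Date(raw[[date_col]]))
  for (p in pollutants) out[[p]] <- suppressWarnings(as.numeric(raw[[p]]))
  out$temperature <- if (temp_col %in% names(raw)) as.numeric(raw[[temp_col]]) else NA_real_
  out$rel_humidity <- if (rhum_col %in% names(raw)) as.numeric(raw[[rhum_col]]) else NA_real_
  out$count <- as.integer(raw[[count_col]])
  new_panel(out, pollutants, extra_holidays = extra_holidays)
}

#' Assemble a panel from an in-memory data frame
#'
#' @param data A data frame with a `date` column, pollutant columns, optional
#'   `temperature` and `rel_humidity` columns, and a `count` column.
#' @inheritParams read_panel
#' @return A `poll_panel` tibble; see [read_panel()].
#' @export
as_panel <- function(data, pollutants = NULL, extra_holidays = NULL) {
  if (!all(c("date", "count") %in% names(data))) {
    abort("'data' needs at least 'date' and 'count' columns", class = "multipoll_format_error")
  }
  if (is.null(pollutants)) {
    pollutants <- setdiff(names(data),
                          c("date", "count", "temperature", "rel_humidity",
                            "holiday", "time_index"))
  }
  out <- tibble::as_tibble(data)
  out$date <- as.Date(out$date)
  if (!"temperature" %in% names(out)) out$temperature <- NA_real_
  if (!"rel_humidity" %in% names(out)) out$rel_humidity <- NA_real_
  out$count <- as.integer(out$count)
  new_panel(out[c("date", pollutants, "temperature", "rel_humidity", "count")],
            pollutants, extra_holidays = extra_holidays)
}

new_panel <- function(out, pollutants, extra_holidays = NULL) {
  if (anyNA(out$date)) abort("unparseable dates", class = "multipoll_alignment_error")
  if (anyDuplicated(out$date)) abort("duplicate dates", class = "multipoll_alignment_error")
  if (is.unsorted(out$date)) out <- out[order(out$date), ]
  span <- as.integer(diff(range(out$date))) + 1L
  if (span != nrow(out)) {
    abort(paste0("date axis is not contiguous: ", nrow(out), " rows span ",
                 span, " days"), class = "multipoll_alignment_error")
  }
  if (any(out$count < 0, na.rm = TRUE)) abort("negative counts")
  out$holiday <- holiday_indicator(out$date, extra_holidays)
  out$time_index <- seq_len(nrow(out))
  class(out) <- c("poll_panel", class(tibble::tibble()))
  attr(out, "pollutants") <- pollutants
  out
}

#' Write a panel back to CSV
#'
#' Inverse of [read_panel()]: missing pollutant cells are written as blank
#' fields so that a write/read round trip reproduces values and missingness
#' bit-exactly.
#'
#' @param data A `poll_panel` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  keep <- setdiff(names(data), c("holiday", "time_index"))
  readr::write_csv(data[keep], path, na = "")
  invisible(path)
}

#' Pollutant columns of a panel
#' @param data A `poll_panel` tibble.
#' @return Character vector of pollutant column names.
#' @export
pollutant_names <- function(data) {
  attr(data, "pollutants") %||%
    setdiff(names(data), c("date", "count", "temperature", "rel_humidity",
                           "holiday", "time_index"))
}

#' Weekend/holiday indicator
#'
#' Classifies each day as workday (`FALSE`) or weekend/holiday (`TRUE`):
#' Saturdays, Sundays and any supplied public-holiday dates. Public holidays
#' are supplied explicitly since no fixed national calendar is assumed.
#'
#' @param dates A `Date` vector.
#' @param extra_holidays Optional `Date` vector of public holidays.
#' @return Logical vector along `dates`.
#' @export
holiday_indicator <- function(dates, extra_holidays = NULL) {
  dates <- as.Date(dates)
  wd <- as.POSIXlt(dates)$wday
  out <- wd == 0L | wd == 6L
  if (!is.null(extra_holidays)) out <- out | dates %in% as.Date(extra_holidays)
  out
}

#' Standardize pollutant columns
#'
#' Centers and scales each pollutant column to mean 0, standard deviation 1
#' over its *observed* cells, using the sample (n - 1) standard deviation.
#' Different pollutants live on very different scales (for example mg/m3
#' versus micrograms/m3 versus particle counts), and the latent-concentration
#' model treats them exchangeably, so the fitting functions work on the
#' standardized scale and back-transform effect estimates afterwards.
#'
#' The center/scale pairs are recorded in the `"scaling"` attribute (also
#' retrievable with [pollutant_scaling()]) so that [destandardize_pollutants()]
#' and [backtransform_mu()] can restore original units exactly.
#'
#' @param data A `poll_panel` tibble (or any data frame with pollutant columns).
#' @param pollutants Columns to standardize; defaults to [pollutant_names()].
#' @return `data` with standardized pollutant columns and a `"scaling"`
#'   attribute: a tibble with columns `pollutant`, `center`, `scale`.
#' @export
standardize_pollutants <- function(data, pollutants = NULL) {
  pollutants <- pollutants %||% pollutant_names(data)
  center <- scale_ <- numeric(length(pollutants))
  for (i in seq_along(pollutants)) {
    x <- data[[pollutants[i]]]
    obs <- x[!is.na(x)]
    if (length(obs) < 2L) {
      abort(paste0("pollutant '", pollutants[i], "' has fewer than 2 observed values"),
            class = "multipoll_degenerate_error")
    }
    s <- sd(obs)
    if (!is.finite(s) || s == 0) {
      abort(paste0("pollutant '", pollutants[i], "' has zero spread"),
            class = "multipoll_degenerate_error")
    }
    center[i] <- mean(obs); scale_[i] <- s
    data[[pollutants[i]]] <- (x - center[i]) / s
  }
  attr(data, "scaling") <- tibble::tibble(pollutant = pollutants,
                                          center = center, scale = scale_)
  data
}

#' Retrieve standardization parameters
#' @param data A data frame previously passed through [standardize_pollutants()].
#' @return Tibble with columns `pollutant`, `center`, `scale`.
#' @export
pollutant_scaling <- function(data) {
  sc <- attr(data, "scaling")
  if (is.null(sc)) abort("no standardization parameters recorded; run standardize_pollutants() first")
  sc
}

#' Undo pollutant standardization
#' @param data A data frame returned by [standardize_pollutants()].
#' @return `data` with pollutant columns back on their original scales.
#' @export
destandardize_pollutants <- function(data) {
  sc <- pollutant_scaling(data)
  for (i in seq_len(nrow(sc))) {
    p <- sc$pollutant[i]
    data[[p]] <- data[[p]] * sc$scale[i] + sc$center[i]
  }
  attr(data, "scaling") <- NULL
  data
}

#' Observed-data interquartile ranges
#'
#' IQR of each pollutant over observed cells only, the denominator-free scale
#' on which effects are reported (percent increase per IQR change).
#'
#' @param data A panel-like data frame.
#' @param pollutants Pollutant columns; defaults to [pollutant_names()].
#' @return Tibble with columns `pollutant`, `iqr`.
#' @export
pollutant_iqr <- function(data, pollutants = NULL) {
  pollutants <- pollutants %||% pollutant_names(data)
  iqr <- vapply(pollutants, function(p) {
    q <- quantile(data[[p]], c(.25, .75), na.rm = TRUE, names = FALSE)
    q[2] - q[1]
  }, numeric(1))
  tibble::tibble(pollutant = pollutants, iqr = unname(iqr))
}

#' Descriptive panel summary
#'
#' Mask-aware descriptive statistics in the conventional layout of time-series
#' air-pollution studies: days observed, the 10th/25th/50th/75th/90th
#' percentiles and the IQR, computed over observed cells only.
#'
#' @param data A `poll_panel` tibble.
#' @return A tibble with one row per variable.
#' @export
panel_summary <- function(data) {
  vars <- c("count", "temperature", "rel_humidity", pollutant_names(data))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    q <- quantile(x, c(.1, .25, .5, .75, .9), na.rm = TRUE, names = FALSE)
    tibble::tibble(variable = v, n_days = sum(!is.na(x)),
                   p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
                   iqr = q[4] - q[2])
  })
  dplyr::bind_rows(rows)
}

# Internal: split a panel into the matrix pieces the samplers consume.
panel_matrices <- function(data, pollutants = NULL) {
  pollutants <- pollutants %||% pollutant_names(data)
  Y <- as.matrix(data[pollutants])
  dimnames(Y) <- list(NULL, pollutants)
  list(
    Y = Y,
    mask = !is.na(Y),
    dates = data$date,
    counts = data$count,
    temperature = data$temperature,
    rel_humidity = data$rel_humidity,
    holiday = if ("holiday" %in% names(data)) data$holiday else holiday_indicator(data$date),
    time_index = if ("time_index" %in% names(data)) data$time_index else seq_len(nrow(data))
  )
}
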
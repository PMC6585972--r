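#' Add sensor measurements
#'
#' Appends timestamped numeric measurements of one variable by one sensor.
#' Timestamps must be strictly increasing within the sensor's series for the
#' variable, and values must be finite. A sensor's physical location over time
#' is declared separately via [assign_sensor()]; points carry no location of
#' their own.
#'
#' @param store a [pheno_store()].
#' @param sensor sensor URI.
#' @param variable variable URI.
#' @param data a data frame with columns `timestamp` and `value`.
#' @param unit unit URI (recorded with the series).
#' @return the store, invisibly.
#' @export
add_sensor_series <- function(store, sensor, variable, data, unit = NA_character_) {
  assert_store(store)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("timestamp", "value") %in% names(data)))
  ts <- parse_instant(data$timestamp)
  value <- as.numeric(data$value)
  if (any(!is.finite(value))) stop("sensor values must be finite numbers", call. = FALSE)
  existing <- store$series[store$series$sensor == sensor &
    store$series$variable == variable, ]
  if (is.unsorted(ts, strictly = TRUE) || any(ts %in% existing$timestamp)) {
    stop("timestamps must be strictly increasing for sensor '", sensor, "'",
      call. = FALSE
    )
  }
  store$series <- dplyr::bind_rows(store$series, tibble::tibble(
    sensor = sensor, variable = variable, unit = unit, timestamp = ts, value = value
  ))
  invisible(store)
}

#' Assign a sensor to a location
#'
#' Declares that `sensor` measured `variable` at `location` over the half-open
#' span `[start, end)`. Spans for one (location, variable) pair must not
#' overlap — replacing a sensor means closing its span and opening the
#' successor's at the same instant, so the value at the replacement instant
#' comes from the new sensor. An open-ended assignment has `end = NA`.
#'
#' @param store a [pheno_store()].
#' @param location installation or position URI.
#' @param variable variable URI.
#' @param sensor sensor URI.
#' @param start,end span bounds (instants); `end = NA` for open-ended.
#' @return the store, invisibly.
#' @export
assign_sensor <- function(store, location, variable, sensor, start, end = NA) {
  assert_store(store)
  start <- parse_instant(start)
  end <- if (length(end) == 1 && is.na(end)[1]) {
    as.POSIXct(NA, tz = "UTC")
  } else {
    parse_instant(end)
  }
  if (!is.na(end) && !(start < end)) stop("`start` must precede `end`", call. = FALSE)
  a <- store$assignments
  same <- a[a$location == location & a$variable == variable, ]
  if (nrow(same)) {
    s2 <- ifelse(is.na(same$end), Inf, as.numeric(same$end))
    new_end <- if (is.na(end)) Inf else as.numeric(end)
    clash <- as.numeric(same$start) < new_end & as.numeric(start) < s2
    if (any(clash)) {
      i <- which(clash)[1]
      stop(
        "assignment overlaps existing span for (", location, ", ", variable,
        "): sensor '", same$sensor[i], "' over [", format_instant(same$start[i]),
        ", ", if (is.na(same$end[i])) "open" else format_instant(same$end[i]), ")",
        call. = FALSE
      )
    }
  }
  store$assignments <- dplyr::arrange(
    dplyr::bind_rows(a, tibble::tibble(
      location = location, variable = variable, sensor = sensor,
      start = start, end = end
    )),
    .data$location, .data$variable, .data$start
  )
  invisible(store)
}

#' Stitch an object's environmental series across its residence intervals
#'
#' Reconstructs the series of `variable` as sensed by `object`: for each
#' residence interval (from [residence_intervals()]) the points of the sensor
#' assigned to that interval's location are appended, using half-open interval
#' and span tests throughout. Sub-intervals with no assigned sensor, or with an
#' assigned sensor but no data, are reported as gaps — never interpolated.
#' Every output point carries its provenance (source sensor, location,
#' enclosing residence interval).
#'
#' @param store a [pheno_store()].
#' @param object object URI.
#' @param variable variable URI.
#' @param window length-2 vector (start, end) of instants.
#' @return a `stitched_series`: a tibble with columns `timestamp`, `value`,
#'   `sensor`, `location`, `interval_start`, `interval_end`, with attributes
#'   `object`, `variable`, `gaps` (a tibble `location`, `start`, `end`,
#'   `reason`) and `lost_points` (in-interval source points not served because
#'   their sensor was not assigned at that instant).
#' @export
stitch <- function(store, object, variable, window) {
  assert_store(store)
  w <- parse_instant(window)
  intervals <- residence_intervals(store, object, w[1], w[2])
  pts <- list()
  gaps <- list()
  lost <- 0L
  a <- store$assignments[store$assignments$variable == variable, ]
  for (i in seq_len(nrow(intervals))) {
    loc <- intervals$location[i]
    s <- intervals$start[i]
    e <- intervals$end[i]
    spans <- a[a$location == loc, ]
    loc_sensors <- unique(spans$sensor)
    src <- store$series[store$series$variable == variable &
      store$series$sensor %in% loc_sensors &
      store$series$timestamp >= s & store$series$timestamp < e, ]
    served <- rep(FALSE, nrow(src))
    cursor <- s
    if (nrow(spans)) {
      spans <- dplyr::arrange(spans, .data$start)
      for (j in seq_len(nrow(spans))) {
        cs <- max(spans$start[j], s)
        ce <- min(if (is.na(spans$end[j])) e else spans$end[j], e)
        if (!(cs < ce)) next
        if (cursor < cs) {
          gaps <- c(gaps, list(tibble::tibble(
            location = loc, start = cursor, end = cs, reason = "no sensor"
          )))
        }
        in_span <- src$sensor == spans$sensor[j] &
          src$timestamp >= cs & src$timestamp < ce
        served <- served | in_span
        if (!any(in_span)) {
          gaps <- c(gaps, list(tibble::tibble(
            location = loc, start = cs, end = ce, reason = "no data"
          )))
        } else {
          pts <- c(pts, list(tibble::tibble(
            timestamp = src$timestamp[in_span], value = src$value[in_span],
            sensor = spans$sensor[j], location = loc,
            interval_start = s, interval_end = e
          )))
        }
        cursor <- max(cursor, ce)
      }
    }
    if (cursor < e) {
      gaps <- c(gaps, list(tibble::tibble(
        location = loc, start = cursor, end = e, reason = "no sensor"
      )))
    }
    lost <- lost + sum(!served)
  }
  out <- dplyr::bind_rows(pts)
  if (!nrow(out)) {
    out <- tibble::tibble(
      timestamp = empty_instant(), value = double(), sensor = character(),
      location = character(), interval_start = empty_instant(),
      interval_end = empty_instant()
    )
  }
  out <- dplyr::arrange(out, .data$timestamp)
  gap_tbl <- if (length(gaps)) {
    dplyr::bind_rows(gaps)
  } else {
    tibble::tibble(
      location = character(), start = empty_instant(), end = empty_instant(),
      reason = character()
    )
  }
  structure(out,
    class = c("stitched_series", class(out)),
    object = object, variable = variable, window = w,
    gaps = gap_tbl, lost_points = lost
  )
}

#' @export
print.stitched_series <- function(x, ...) {
  cat(
    "Stitched series of", attr(x, "variable"), "for", attr(x, "object"), "-",
    nrow(x), "points,", nrow(attr(x, "gaps")), "gap(s),",
    attr(x, "lost_points"), "point(s) lost to unassigned spans\n"
  )
  NextMethod()
}

#' Registered thermal-time methods
#'
#' The default method, `daily_mean_above_base`, increments thermal time each
#' civil day by `max(0, mean(T) - base)` where the mean runs over the day's
#' stitched temperature points. Alternative accumulation methods can be
#' registered by name; the method name travels with every result, since the
#' method is part of the variable's definition.
#'
#' @param name method name.
#' @param fun function of `(values, base_temp)` returning the day's increment.
#' @return `thermal_time_methods()` returns the names of registered methods.
#' @export
thermal_time_methods <- function() names(.thermal_methods)

.thermal_methods <- new.env(parent = emptyenv())
.thermal_methods$daily_mean_above_base <- function(values, base_temp) {
  max(0, mean(values) - base_temp)
}

#' @rdname thermal_time_methods
#' @export
register_thermal_time_method <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  .thermal_methods[[name]] <- fun
  invisible(name)
}

#' Thermal time of an object
#'
#' Cumulative thermal time (degree-days) since sowing, computed on the
#' object's stitched temperature series so that moves between installations
#' are taken into account. Per civil day (in the store's configured time zone)
#' the increment is `max(0, daily mean - base_temp)`; the output is the
#' running sum, one value per day, non-decreasing. Days with no data
#' contribute zero and are flagged — gaps are surfaced, never filled.
#'
#' `base_temp` has no default: it is a biological parameter that must come
#' from per-species configuration.
#'
#' @param store a [pheno_store()].
#' @param object object URI.
#' @param variable temperature variable URI.
#' @param base_temp base temperature (same unit as the series, typically
#'   degrees Celsius).
#' @param sowing optional explicit origin instant; defaults to the object's
#'   earliest `Sowing` event (an error if neither exists).
#' @param window_end end of the accumulation window; defaults to just past the
#'   last stored point of the variable.
#' @param method a registered thermal-time method name.
#' @return a `thermal_time` tibble with columns `date`, `n_points`,
#'   `mean_temp`, `increment`, `thermal_time` and `no_data`, plus attributes
#'   `object`, `method` and `base_temp`.
#' @export
thermal_time <- function(store, object, variable, base_temp, sowing = NULL,
                         window_end = NULL, method = "daily_mean_above_base") {
  assert_store(store)
  if (missing(base_temp) || !is.numeric(base_temp)) {
    stop("`base_temp` is required (per-species configuration)", call. = FALSE)
  }
  fun <- .thermal_methods[[method]]
  if (is.null(fun)) stop("unknown thermal-time method '", method, "'", call. = FALSE)
  if (is.null(sowing)) {
    sow <- events_for(store, object, class_filter = "Sowing")
    if (!nrow(sow)) {
      stop("no Sowing event for '", object, "' and no explicit `sowing` origin",
        call. = FALSE
      )
    }
    sowing <- min(sow$timestamp)
  } else {
    sowing <- parse_instant(sowing)
  }
  if (is.null(window_end)) {
    relevant <- store$series[store$series$variable == variable, ]
    if (!nrow(relevant)) stop("no data for variable '", variable, "'", call. = FALSE)
    window_end <- max(relevant$timestamp) + 1
  } else {
    window_end <- parse_instant(window_end)
  }
  series <- stitch(store, object, variable, c(sowing, window_end))
  tz <- store$config$tz
  days <- seq(
    lubridate::as_date(sowing, tz = tz),
    lubridate::as_date(window_end - 1e-6, tz = tz),
    by = "day"
  )
  day_of <- lubridate::as_date(series$timestamp, tz = tz)
  by_day <- split(series$value, factor(as.character(day_of), levels = as.character(days)))
  n_points <- unname(vapply(by_day, length, integer(1)))
  mean_temp <- unname(vapply(by_day, function(v) {
    if (length(v)) mean(v) else NA_real_
  }, numeric(1)))
  increment <- unname(vapply(by_day, function(v) {
    if (length(v)) fun(v, base_temp) else 0
  }, numeric(1)))
  out <- tibble::tibble(
    date = days, n_points = n_points, mean_temp = mean_temp,
    increment = increment, thermal_time = cumsum(increment),
    no_data = n_points == 0L
  )
  structure(out,
    class = c("thermal_time", class(out)),
    object = object, method = method, base_temp = base_temp
  )
}

#' @export
print.thermal_time <- function(x, ...) {
  cat(
    "Thermal time for", attr(x, "object"), "- method", attr(x, "method"),
    "base", attr(x, "base_temp"), "\n"
  )
  NextMethod()
}
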
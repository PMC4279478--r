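#' Column schema for weather files
#'
#' Maps the package's canonical column names to the headers found in a
#' delimited weather file, and records unit conventions.
#'
#' @param timestamp,air_temp,rel_humidity,wind_speed,shortwave,ground_temp,pressure
#'   Header names in the file (set a name to `NULL` for optional columns
#'   that are absent).
#' @param rh_unit `"percent"` (default) or `"fraction"`; fractional humidity
#'   is multiplied by 100 on read.
#' @param sep Field separator (default comma).
#' @param tz Time zone for parsing timestamps (default `"UTC"`).
#' @return A list describing the schema.
#' @export
weather_schema <- function(timestamp = "timestamp", air_temp = "ta_c",
                           rel_humidity = "rh_pct", wind_speed = "wind_ms",
                           shortwave = "rs_wm2", ground_temp = "tsoil_c",
                           pressure = "p_kpa", rh_unit = c("percent",
                                                           "fraction"),
                           sep = ",", tz = "UTC") {
  list(timestamp = timestamp, air_temp = air_temp,
       rel_humidity = rel_humidity, wind_speed = wind_speed,
       shortwave = shortwave, ground_temp = ground_temp, pressure = pressure,
       rh_unit = match.arg(rh_unit), sep = sep, tz = tz)
}

#' Read a weather-station series from delimited text
#'
#' Reads, maps columns through the schema, coerces units, parses ISO-8601
#' timestamps and sorts by time. With `strict = FALSE` rows whose timestamp
#' or numeric fields fail to parse are dropped with a warning naming the
#' line numbers; with `strict = TRUE` they are an error.
#'
#' @param path Path to the delimited text file (one header row).
#' @param schema A [weather_schema()].
#' @param strict Fail on malformed rows instead of dropping them.
#' @return A data frame with the canonical [weather_sample()] columns,
#'   sorted by timestamp.
#' @export
read_weather <- function(path, schema = weather_schema(), strict = FALSE) {
  if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = schema$sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  need <- c("timestamp", "air_temp", "rel_humidity", "wind_speed", "shortwave")
  for (field in need) {
    if (!(schema[[field]] %in% names(raw))) {
      stop("cannot map required column '", field, "': no header named '",
           schema[[field]], "' in ", path, call. = FALSE)
    }
  }
  grab <- function(field) {
    nm <- schema[[field]]
    if (is.null(nm) || !(nm %in% names(raw))) rep(NA_character_, nrow(raw))
    else raw[[nm]]
  }
  ts <- parse_timestamps(grab("timestamp"), tz = schema$tz)
  num <- function(field) suppressWarnings(as.numeric(grab(field)))
  out <- data.frame(
    timestamp = ts,
    air_temp = num("air_temp"),
    rel_humidity = num("rel_humidity"),
    wind_speed = num("wind_speed"),
    shortwave = num("shortwave"),
    ground_temp = num("ground_temp"),
    pressure = num("pressure")
  )
  if (schema$rh_unit == "fraction") {
    out$rel_humidity <- out$rel_humidity * 100
  }
  out$pressure[is.na(out$pressure)] <- 101.3
  bad <- is.na(out$timestamp) | is.na(out$air_temp) | is.na(out$rel_humidity) |
    is.na(out$wind_speed) | is.na(out$shortwave)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header occupies line 1
    msg <- paste0("dropped ", sum(bad), " malformed row(s) at line(s) ",
                  paste(utils::head(lines, 10), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  validate_weather(out)
  out
}

# lenient elementwise ISO-8601 parser: unparseable entries become NA
parse_timestamps <- function(x, tz = "UTC") {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = tz))
  }
  out
}

#' Write a weather series as delimited text
#'
#' Inverse of [read_weather()] under the same schema: one header row,
#' ISO-8601 timestamps, '.' decimal separator.
#'
#' @param weather A weather series data frame.
#' @param path Output path.
#' @param schema A [weather_schema()] supplying the header names.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path, schema = weather_schema()) {
  out <- data.frame(
    format(weather$timestamp, "%Y-%m-%dT%H:%M:%S", tz = schema$tz),
    weather$air_temp, weather$rel_humidity, weather$wind_speed,
    weather$shortwave,
    weather$ground_temp %||% NA_real_,
    weather$pressure %||% 101.3,
    check.names = FALSE
  )
  names(out) <- c(schema$timestamp, schema$air_temp, schema$rel_humidity,
                  schema$wind_speed, schema$shortwave, schema$ground_temp,
                  schema$pressure)
  utils::write.table(out, path, sep = schema$sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Average a fine-resolution series onto a coarser step
#'
#' Aggregates raw readings into half-open windows `[t, t + target_step)` and
#' returns the arithmetic mean of each numeric column per window, the way a
#' station logger condenses 10-second samples into 15-minute records.
#'
#' @param raw A weather series at a fine, regular time step.
#' @param target_step Output step in minutes; the raw step must divide it.
#' @return A weather series at the target step; window start times label
#'   each row.
#' @export
resample_mean <- function(raw, target_step) {
  if (nrow(raw) < 2) stop("need at least two rows to infer the raw step",
                          call. = FALSE)
  steps <- diff(as.numeric(raw$timestamp))
  raw_step <- steps[1]
  if (any(abs(steps - raw_step) > 1e-6)) {
    stop("raw series is not regularly spaced", call. = FALSE)
  }
  target_s <- target_step * 60
  if (abs(target_s / raw_step - round(target_s / raw_step)) > 1e-9 ||
        target_s < raw_step) {
    stop(sprintf("raw step (%gs) must divide the target step (%gs)",
                 raw_step, target_s), call. = FALSE)
  }
  t0 <- as.numeric(raw$timestamp)
  win <- floor(t0 / target_s) * target_s
  num_cols <- setdiff(names(raw), "timestamp")
  agg <- stats::aggregate(raw[num_cols], by = list(win = win), FUN = mean,
                          na.rm = FALSE)
  out <- data.frame(timestamp = as.POSIXct(agg$win,
                                           origin = "1970-01-01",
                                           tz = attr(raw$timestamp, "tzone")
                                             %||% "UTC"))
  out <- cbind(out, agg[num_cols])
  out[order(out$timestamp), , drop = FALSE]
}

#' Specification for the synthetic clear-sky weather generator
#'
#' Defaults describe a hot, dry, clear mid-August day of the kind on which
#' apple sunburn develops: solar radiation peaking at 900 W m-2, air
#' temperature swinging 18-32 degC and peaking at 14:00, humidity
#' anticorrelated with temperature between 25 and 70 percent, and light
#' gusty wind around 2.5 m/s.
#'
#' @param date Calendar date of the first day (anything `as.Date()` accepts).
#' @param n_days Number of consecutive days.
#' @param step Time step in minutes (default 15).
#' @param peak_shortwave Clear-sky solar maximum, W m-2.
#' @param air_temp_min,air_temp_max Daily air-temperature extremes, degC.
#' @param air_temp_peak_hour Clock hour of maximum air temperature.
#' @param rh_min,rh_max Relative-humidity extremes, percent.
#' @param wind_mean Mean wind speed, m/s.
#' @param wind_jitter_sd Gaussian wind noise standard deviation, m/s.
#' @param pressure Barometric pressure, kPa.
#' @param sunrise_hour,sunset_hour Clock hours bounding the solar half-sine.
#' @param seed Integer RNG seed; a fixed seed gives a bit-identical series.
#' @return A list of generator settings.
#' @export
synthetic_weather_spec <- function(date = "2013-08-20", n_days = 1,
                                   step = 15, peak_shortwave = 900,
                                   air_temp_min = 18, air_temp_max = 32,
                                   air_temp_peak_hour = 14,
                                   rh_min = 25, rh_max = 70,
                                   wind_mean = 2.5, wind_jitter_sd = 0.5,
                                   pressure = 101.3,
                                   sunrise_hour = 6, sunset_hour = 20,
                                   seed = 42L) {
  stopifnot(peak_shortwave >= 0, air_temp_min <= air_temp_max,
            rh_min >= 0, rh_max <= 100, rh_min <= rh_max,
            wind_mean >= 0, wind_jitter_sd >= 0, step > 0, n_days >= 1,
            sunrise_hour < sunset_hour)
  list(date = as.Date(date), n_days = n_days, step = step,
       peak_shortwave = peak_shortwave, air_temp_min = air_temp_min,
       air_temp_max = air_temp_max, air_temp_peak_hour = air_temp_peak_hour,
       rh_min = rh_min, rh_max = rh_max, wind_mean = wind_mean,
       wind_jitter_sd = wind_jitter_sd, pressure = pressure,
       sunrise_hour = sunrise_hour, sunset_hour = sunset_hour,
       seed = as.integer(seed))
}

#' Generate a seeded synthetic clear-sky weather series
#'
#' Emulates the diurnal cycle a clear-sky weather station records: a
#' truncated half-sine of solar radiation between sunrise and sunset, an
#' air-temperature sinusoid between the daily extremes peaking at the
#' configured hour, relative humidity linearly anticorrelated with air
#' temperature, and wind as a truncated Gaussian around the mean. The
#' generator is deterministic for a fixed seed and leaves the caller's RNG
#' state untouched.
#'
#' @param spec A [synthetic_weather_spec()].
#' @return A weather series data frame at the requested step.
#' @export
#' @examples
#' w <- generate_synthetic(synthetic_weather_spec(seed = 1))
#' max(w$shortwave)
generate_synthetic <- function(spec = synthetic_weather_spec()) {
  n_per_day <- as.integer(24 * 60 / spec$step)
  start <- as.POSIXct(paste(spec$date, "00:00:00"), tz = "UTC")
  ts <- start + seq(0, by = spec$step * 60,
                    length.out = n_per_day * spec$n_days)
  hour <- ((as.numeric(ts) - as.numeric(start)) / 3600) %% 24
  daylen <- spec$sunset_hour - spec$sunrise_hour
  rs <- spec$peak_shortwave *
    pmax(0, sin(pi * (hour - spec$sunrise_hour) / daylen))
  rs[hour < spec$sunrise_hour | hour > spec$sunset_hour] <- 0
  amp <- (spec$air_temp_max - spec$air_temp_min) / 2
  mid <- (spec$air_temp_max + spec$air_temp_min) / 2
  ta <- mid + amp * sin(2 * pi * (hour - spec$air_temp_peak_hour + 6) / 24)
  frac <- if (amp > 0) (ta - spec$air_temp_min) / (2 * amp) else 0.5
  rh <- spec$rh_max - (spec$rh_max - spec$rh_min) * frac
  wind <- with_local_seed(spec$seed, {
    pmax(0, spec$wind_mean + stats::rnorm(length(ts), 0, spec$wind_jitter_sd))
  })
  out <- data.frame(timestamp = ts, air_temp = ta, rel_humidity = rh,
                    wind_speed = wind, shortwave = rs,
                    ground_temp = NA_real_, pressure = spec$pressure)
  validate_weather(out)
  out
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
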
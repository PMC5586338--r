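#' Daily average temperature
#'
#' The median of the daily maximum and minimum, i.e. their midpoint
#' `(tmax + tmin) / 2`.  Inverted inputs are an error, never silently
#' swapped.
#'
#' @param tmax,tmin numeric vectors, degrees C.
#' @return numeric vector of daily averages.
#' @export
daily_average <- function(tmax, tmin) {
  bad <- which(tmin > tmax)
  if (length(bad) > 0L) {
    stop("tmin > tmax at position ", bad[1L], " (", length(bad),
         " value(s))")
  }
  (tmax + tmin) / 2
}

#' Cumulative growing degree days
#'
#' Accumulated thermal time from January 1: on each day whose average
#' temperature strictly exceeds the base (5.5 degrees C by default) the day
#' contributes, and the contributions are summed.  Two conventions are
#' offered: `"excess"` (the default, standard degree days) adds
#' `tavg - base`; `"full"` adds the whole `tavg`.  A day at exactly the
#' base temperature contributes nothing under either convention.
#'
#' @param weather data frame with columns `station`, `date`, and either
#'   `tavg` or both `tmax`/`tmin` (e.g. from [read_weather()] or
#'   [simulate_temperatures()]).  Daily coverage must be continuous from
#'   January 1 of each year through the last date present: gaps are an
#'   error naming the first missing date.
#' @param base base temperature, degrees C.
#' @param convention `"excess"` or `"full"`.
#' @return a `gdd_series` data frame: `station`, `date`, `year`, `gdd`
#'   (cumulative), nondecreasing in date within each station-year.
#' @export
cumulative_gdd <- function(weather, base = 5.5,
                           convention = c("excess", "full")) {
  convention <- match.arg(convention)
  wx <- as.data.frame(weather)
  if (is.null(wx$tavg)) {
    if (is.null(wx$tmax) || is.null(wx$tmin)) {
      stop("weather needs 'tavg' or both 'tmax' and 'tmin'")
    }
    wx$tavg <- daily_average(wx$tmax, wx$tmin)
  }
  wx$date <- as.Date(wx$date)
  wx$year <- as.integer(format(wx$date, "%Y"))
  groups <- split(wx, list(wx$station, wx$year), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$date), , drop = FALSE]
    start <- as.Date(paste0(g$year[1L], "-01-01"))
    full <- seq(start, max(g$date), by = "day")
    miss <- full[!full %in% g$date]
    if (length(miss) > 0L) {
      stop("gap in daily series for station ", g$station[1L], " ",
           g$year[1L], ": first missing day ", format(miss[1L]))
    }
    contrib <- ifelse(g$tavg > base,
                      if (convention == "excess") g$tavg - base else g$tavg,
                      0)
    data.frame(station = g$station, date = g$date, year = g$year,
               gdd = cumsum(contrib), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out[order(out$station, out$date), ],
            class = c("gdd_series", "data.frame"))
}

#' Growing-degree-day anomaly against a reference series
#'
#' Pointwise difference between a cumulative GDD series and a reference
#' (e.g. a long-term mean) matched by station and day of year, the
#' departure-from-climatology view of a warm or cold spring.
#'
#' @param series,reference `gdd_series` data frames (see
#'   [cumulative_gdd()]); `reference` must cover every station and
#'   month-day present in `series`.
#' @return data frame `station`, `date`, `anomaly` (degree C days).
#' @export
gdd_anomaly <- function(series, reference) {
  extra <- setdiff(unique(series$station), unique(reference$station))
  if (length(extra) > 0L) {
    stop("reference lacks station(s): ", paste(extra, collapse = ", "))
  }
  md <- function(d) format(as.Date(d), "%m-%d")
  key_s <- paste(series$station, md(series$date))
  key_r <- paste(reference$station, md(reference$date))
  hit <- match(key_s, key_r)
  if (anyNA(hit)) {
    stop("reference does not cover ", key_s[which(is.na(hit))[1L]])
  }
  data.frame(station = series$station, date = as.Date(series$date),
             anomaly = series$gdd - reference$gdd[hit],
             stringsAsFactors = FALSE)
}

#' Attach the GDD covariate to a survey
#'
#' Joins each observation's visit date to the cumulative GDD of its site's
#' weather station, so the cumulative link model can be fitted on thermal
#' time instead of calendar time.  Sites whose nearest station is flagged
#' unrepresentative are dropped from the returned survey (with a message
#' giving the dropped observation count), mirroring the exclusion of sites
#' whose station records do not reflect local conditions.
#'
#' @param survey a [phenology_survey()].
#' @param gdd a `gdd_series` from [cumulative_gdd()].
#' @param station_map data frame with columns `site`, `station`, and
#'   optionally logical `excluded`.
#' @return the survey with a `gdd` column, excluded sites removed.
#' @export
attach_gdd <- function(survey, gdd, station_map) {
  stopifnot(all(c("site", "station") %in% names(station_map)))
  if (is.null(station_map$excluded)) station_map$excluded <- FALSE
  d <- as.data.frame(survey)
  unmapped <- setdiff(unique(d$site), station_map$site)
  if (length(unmapped) > 0L) {
    stop("no station mapped for site(s): ", paste(unmapped, collapse = ", "))
  }
  drop_sites <- station_map$site[station_map$excluded]
  if (length(drop_sites) > 0L) {
    n_drop <- sum(d$site %in% drop_sites)
    if (n_drop > 0L) {
      message("dropping ", n_drop, " observation(s) from excluded site(s): ",
              paste(intersect(drop_sites, unique(d$site)), collapse = ", "))
    }
    d <- d[!d$site %in% drop_sites, , drop = FALSE]
  }
  stn <- station_map$station[match(d$site, station_map$site)]
  hit <- match(paste(stn, d$date), paste(gdd$station, as.Date(gdd$date)))
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1L]
    stop("no GDD value for station ", stn[i], " on ", format(d$date[i]))
  }
  d$gdd <- gdd$gdd[hit]
  structure(d, sites = attr(survey, "sites"),
            class = c("phenology_survey", "data.frame"))
}
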
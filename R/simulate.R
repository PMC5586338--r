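#' Parameters for the synthetic survey generator
#'
#' The generator mirrors the study design the analysis assumes: several
#' sites visited about every 10 days through May-June, 20 trees per site,
#' and the five most developed strobili scored per tree and visit on the
#' 1-7 ordinal scale.  Scores are drawn from a latent logistic development
#' process: on day `d` the linear predictor is
#' `eta = beta_day * (d + site_effect + year_effect + tree_offset)` and
#' `P(score <= x) = plogis(thresholds[x] - eta)`.
#'
#' Sign convention: a positive `site_effect` (or year effect, or tree
#' offset) means *earlier* development — the site reaches every stage that
#' many days sooner, because its latent predictor at a given calendar day is
#' larger.  The true time lag between sites i and j (day at which site i
#' reaches a stage minus day at which site j does) is therefore
#' `site_effect[j] - site_effect[i]`.
#'
#' Tree offsets are drawn once per tree and reused across years, which is
#' what induces between-year rank correlation of individuals.  They enter on
#' the day scale so `tree_sd` is interpretable in days.
#'
#' @param sites named numeric vector: site code -> site effect in days.
#' @param years named numeric vector: year -> year effect in days (names are
#'   calendar years).
#' @param beta_day latent development rate, logit units per day; must be
#'   positive.
#' @param thresholds six strictly increasing latent cutpoints (logit units).
#'   The default places the stage transitions between mid-May and
#'   mid-June for a site/year/tree with zero effects.
#' @param tree_sd standard deviation of the tree-level offset, days.
#' @param visit_interval days between visits (>= 1).
#' @param n_trees trees per site (>= 2).
#' @param n_replicates strobili scored per tree-visit.
#' @param season character vector `c(first, last)` of month-day visit
#'   window limits, `"%m-%d"`.
#' @param clock `"day"` for calendar-driven development, `"gdd"` to drive
#'   the latent state by accumulated growing degree days instead (see
#'   `gdd_lookup`); with `"gdd"`, `beta_day` is interpreted per GDD unit.
#' @param gdd_lookup for `clock = "gdd"`, a function
#'   `(site, dates) -> numeric` returning the cumulative GDD at each visit
#'   date for that site, e.g. built from [cumulative_gdd()] output.
#' @return an object of class `simulation_params`.
#' @seealso [simulate_survey()]
#' @export
simulation_params <- function(sites = c(BE = 12, BL = 8, RM = 5, LD = 3,
                                        AC = 0),
                              years = c(`2014` = 0),
                              beta_day = 0.3,
                              thresholds = 0.3 * c(18, 25, 31, 36, 41, 47),
                              tree_sd = 2,
                              visit_interval = 10,
                              n_trees = 20,
                              n_replicates = 5,
                              season = c("05-01", "06-30"),
                              clock = c("day", "gdd"),
                              gdd_lookup = NULL) {
  clock <- match.arg(clock)
  if (is.null(names(sites)) || is.null(names(years))) {
    stop("'sites' and 'years' must be named vectors")
  }
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (beta_day <= 0) stop("beta_day must be positive")
  if (n_trees < 2L) stop("n_trees must be at least 2")
  if (visit_interval < 1L) stop("visit_interval must be at least 1")
  if (tree_sd < 0) stop("tree_sd must be nonnegative")
  if (clock == "gdd" && !is.function(gdd_lookup)) {
    stop("clock = \"gdd\" requires a gdd_lookup function")
  }
  structure(list(sites = sites, years = years, beta_day = beta_day,
                 thresholds = thresholds, tree_sd = tree_sd,
                 visit_interval = as.integer(visit_interval),
                 n_trees = as.integer(n_trees),
                 n_replicates = as.integer(n_replicates),
                 season = season, clock = clock, gdd_lookup = gdd_lookup),
            class = "simulation_params")
}

#' Simulate a phenology survey
#'
#' Draws ordinal strobilus scores for every site, year, tree, visit, and
#' replicate from the latent logistic process described in
#' [simulation_params()].  Identical seed gives an identical survey.
#'
#' @param params a [simulation_params()] object.
#' @param seed integer RNG seed.
#' @return a [phenology_survey()].
#' @examples
#' p <- simulation_params(sites = c(A = 0, B = 6), years = c(`2015` = 0),
#'                        n_trees = 5)
#' sv <- simulate_survey(p, seed = 1)
#' table(sv$site, sv$score)
#' @export
simulate_survey <- function(params, seed) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(as.integer(seed))
  K <- length(params$thresholds) + 1L
  trees <- sprintf("T%02d", seq_len(params$n_trees))
  # one offset per (site, tree), shared across years
  offsets <- matrix(stats::rnorm(length(params$sites) * params$n_trees,
                                 sd = params$tree_sd),
                    nrow = length(params$sites),
                    dimnames = list(names(params$sites), trees))
  rows <- vector("list", length(params$sites) * length(params$years))
  k <- 0L
  for (yi in seq_along(params$years)) {
    yr <- names(params$years)[yi]
    visits <- seq(as.Date(paste0(yr, "-", params$season[1L])),
                  as.Date(paste0(yr, "-", params$season[2L])),
                  by = params$visit_interval)
    days <- day_from_may1(visits)
    for (si in seq_along(params$sites)) {
      site <- names(params$sites)[si]
      time_axis <- if (params$clock == "gdd") {
        params$gdd_lookup(site, visits)
      } else {
        days
      }
      g <- expand.grid(replicate = seq_len(params$n_replicates),
                       visit = seq_along(visits),
                       tree = trees,
                       stringsAsFactors = FALSE)
      eta <- params$beta_day *
        (time_axis[g$visit] + params$sites[si] + params$years[yi] +
           offsets[site, g$tree])
      u <- stats::rlogis(nrow(g), location = eta)
      score <- findInterval(u, params$thresholds) + 1L
      rows[[k <- k + 1L]] <- data.frame(site = site, tree = g$tree,
                                        date = visits[g$visit],
                                        score = score,
                                        replicate = g$replicate,
                                        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  if (length(unique(obs$score)) == 1L) {
    warning("degenerate parameters: all simulated scores are stage ",
            obs$score[1L])
  }
  phenology_survey(obs)
}

#' Parameters for the synthetic daily temperature generator
#'
#' Daily average temperature follows a sinusoidal seasonal cycle (warmest in
#' mid-July) plus i.i.d. Gaussian noise and an optional per-station-year
#' anomaly; tmax/tmin are placed symmetrically around it at
#' `diurnal_range / 2`.  Defaults approximate a Scottish Highlands climate.
#'
#' @param stations character vector of station codes.
#' @param years integer vector of years to simulate.
#' @param annual_mean mean of the seasonal cycle, degrees C.
#' @param annual_amplitude half peak-to-trough amplitude, degrees C.
#' @param noise_sd daily noise standard deviation, degrees C (>= 0).
#' @param diurnal_range tmax - tmin, degrees C (>= 0).
#' @param year_anomaly named numeric vector of additive degrees-C offsets,
#'   names `"STATION.YEAR"` (e.g. `c(BE.2014 = 2)`); unnamed entries apply
#'   to all station-years.
#' @return an object of class `temperature_sim_params`.
#' @export
temperature_sim_params <- function(stations = c("S1"),
                                   years = 2014L,
                                   annual_mean = 8,
                                   annual_amplitude = 5.5,
                                   noise_sd = 2,
                                   diurnal_range = 6,
                                   year_anomaly = numeric()) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (diurnal_range < 0) stop("diurnal_range must be nonnegative")
  structure(list(stations = stations, years = as.integer(years),
                 annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 noise_sd = noise_sd, diurnal_range = diurnal_range,
                 year_anomaly = year_anomaly),
            class = "temperature_sim_params")
}

#' Simulate daily station temperatures
#'
#' Generates daily tmax/tmin for each station from January 1 to June 30 of
#' each simulated year — the accumulation window of the thermal-time index.
#' Deterministic under a fixed seed.
#'
#' @param params a [temperature_sim_params()] object.
#' @param seed integer RNG seed.
#' @return data frame with columns `station`, `date`, `year`, `tmax`,
#'   `tmin`, `tavg`.
#' @export
simulate_temperatures <- function(params, seed) {
  stopifnot(inherits(params, "temperature_sim_params"))
  set.seed(as.integer(seed))
  rows <- list()
  for (st in params$stations) {
    for (yr in params$years) {
      dates <- seq(as.Date(paste0(yr, "-01-01")),
                   as.Date(paste0(yr, "-06-30")), by = "day")
      doy <- as.integer(format(dates, "%j"))
      anom <- 0
      key <- paste(st, yr, sep = ".")
      if (length(params$year_anomaly) > 0L) {
        if (!is.null(names(params$year_anomaly)) &&
            key %in% names(params$year_anomaly)) {
          anom <- params$year_anomaly[[key]]
        } else if (is.null(names(params$year_anomaly))) {
          anom <- params$year_anomaly[1L]
        }
      }
      tavg <- params$annual_mean +
        params$annual_amplitude * cos(2 * pi * (doy - 196) / 365.25) +
        anom +
        stats::rnorm(length(dates), sd = params$noise_sd)
      rows[[key]] <- data.frame(station = st, date = dates,
                                year = yr,
                                tmax = tavg + params$diurnal_range / 2,
                                tmin = tavg - params$diurnal_range / 2,
                                tavg = tavg,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
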
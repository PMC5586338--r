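#' Day-of-season covariate counting from May 1
#'
#' Maps calendar dates to the day covariate used throughout the phenology
#' models: May 1 of the date's own year is day 1 (May 1 is counted,
#' i.e. the count is inclusive), so June 30 is day 61.
#'
#' @param date a `Date` vector, or anything `as.Date()` accepts.
#' @return integer vector of day numbers (dates before May 1 give values
#'   smaller than 1; they are still translation-consistent).
#' @examples
#' day_from_may1(as.Date("2014-05-01"))  # 1
#' day_from_may1(as.Date("2014-06-30"))  # 61
#' @export
day_from_may1 <- function(date) {
  date <- as.Date(date)
  yr <- format(date, "%Y")
  as.integer(date - as.Date(paste0(yr, "-05-01"))) + 1L
}

#' Construct and validate a phenology survey
#'
#' A phenology survey is a data frame with one row per strobilus score:
#' columns `site`, `tree`, `date`, `year`, `day`, `score`, `replicate`.
#' Scores are ordinal stages 1-7 (stage 5 = peak pollen shedding);
#' `replicate` indexes the five most developed strobili scored per tree and
#' visit.  Validation enforces the score and replicate ranges, uniqueness of
#' (site, tree, date, replicate), the May-June survey window, and that every
#' site-year has at least two distinct visit dates.
#'
#' @param observations data frame with columns `site`, `tree`, `date`,
#'   `score` and optionally `year`, `replicate` (defaulted from the data).
#' @param sites optional data frame of site metadata (`site`, `latitude`,
#'   `longitude`, `altitude`), kept as an attribute.
#' @return a `phenology_survey` data frame.
#' @export
phenology_survey <- function(observations, sites = NULL) {
  obs <- as.data.frame(observations)
  needed <- c("site", "tree", "date", "score")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs$site <- as.character(obs$site)
  obs$tree <- as.character(obs$tree)
  obs$date <- as.Date(obs$date)
  if (anyNA(obs$date)) stop("unparsable date(s) in observations")
  obs$year <- as.integer(format(obs$date, "%Y"))
  if (is.null(obs$replicate)) {
    obs$replicate <- stats::ave(seq_len(nrow(obs)),
                                obs$site, obs$tree, obs$date,
                                FUN = seq_along)
  }
  obs$replicate <- as.integer(obs$replicate)
  obs$score <- as.integer(obs$score)
  obs$day <- day_from_may1(obs$date)
  obs <- obs[c("site", "tree", "date", "year", "day", "score", "replicate")]

  bad <- validate_observations(obs)
  if (nrow(bad) > 0L) {
    stop("invalid observations (", nrow(bad), " row(s)); first problem: row ",
         bad$row[1L], ": ", bad$reason[1L])
  }
  sy <- unique(obs[c("site", "year")])
  for (i in seq_len(nrow(sy))) {
    sel <- obs$site == sy$site[i] & obs$year == sy$year[i]
    if (length(unique(obs$date[sel])) < 2L) {
      stop("site ", sy$site[i], " in ", sy$year[i],
           " has fewer than 2 distinct visit dates")
    }
  }
  structure(obs, sites = sites, class = c("phenology_survey", "data.frame"))
}

# Row-level checks shared by phenology_survey() and read_survey().
# Returns a data frame (row, reason), empty when all rows pass.
validate_observations <- function(obs) {
  reasons <- character(nrow(obs))
  bad_score <- is.na(obs$score) | obs$score < 1L | obs$score > 7L
  reasons[bad_score] <- paste0("score ", obs$score[bad_score],
                               " outside 1-7")
  bad_rep <- !bad_score & (is.na(obs$replicate) | obs$replicate < 1L |
                             obs$replicate > 5L)
  reasons[bad_rep] <- paste0("replicate ", obs$replicate[bad_rep],
                             " outside 1-5")
  month <- as.integer(format(obs$date, "%m"))
  bad_window <- reasons == "" & !(month %in% c(5L, 6L))
  reasons[bad_window] <- paste0("date ", format(obs$date[bad_window]),
                                " outside May-June survey window")
  key <- paste(obs$site, obs$tree, obs$date, obs$replicate, sep = "\r")
  dup <- reasons == "" & duplicated(key)
  reasons[dup] <- "duplicate (site, tree, date, replicate)"
  data.frame(row = which(reasons != ""),
             reason = reasons[reasons != ""],
             stringsAsFactors = FALSE)
}

#' Read a phenology survey from a delimited text file
#'
#' Reads a CSV of strobilus observations into a validated
#' [phenology_survey()].  The column layout is configurable through
#' `col_map`; wide layouts carrying one column per strobilus replicate
#' (e.g. `score1`..`score5`) are melted to long form on read.  Rows that
#' fail validation are dropped and reported in the `"rejected"` attribute
#' with a per-row reason.
#'
#' @param path path to a delimited text file with a header row.
#' @param col_map named character vector mapping the internal names
#'   `site`, `tree`, `date`, `score`, `replicate` to the file's column
#'   names.  For wide files, `score` may name several columns, one per
#'   replicate, and `replicate` is ignored.
#' @param sep field separator, default comma.
#' @return a `phenology_survey`; attribute `"rejected"` holds a data frame
#'   of dropped rows and reasons (zero rows if all passed).
#' @export
read_survey <- function(path,
                        col_map = c(site = "site", tree = "tree",
                                    date = "date", score = "score",
                                    replicate = "replicate"),
                        sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  defaults <- c(site = "site", tree = "tree", date = "date",
                score = "score", replicate = "replicate")
  map <- defaults
  map[names(col_map)] <- col_map
  score_cols <- col_map[names(col_map) == "score"]
  if (length(score_cols) == 0L) score_cols <- "score"

  for (nm in c("site", "tree", "date")) {
    if (!map[[nm]] %in% names(raw)) {
      stop("missing mandatory column: ", map[[nm]])
    }
  }
  if (!all(score_cols %in% names(raw))) {
    stop("missing mandatory column: ",
         paste(setdiff(score_cols, names(raw)), collapse = ", "))
  }

  if (length(score_cols) > 1L) {
    # wide layout: one score column per replicate, melted to long form
    long <- do.call(rbind, lapply(seq_along(score_cols), function(r) {
      data.frame(site = raw[[map[["site"]]]],
                 tree = raw[[map[["tree"]]]],
                 date = raw[[map[["date"]]]],
                 score = raw[[score_cols[r]]],
                 replicate = r,
                 src_row = seq_len(nrow(raw)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    long <- data.frame(site = raw[[map[["site"]]]],
                       tree = raw[[map[["tree"]]]],
                       date = raw[[map[["date"]]]],
                       score = raw[[score_cols]],
                       stringsAsFactors = FALSE)
    long$replicate <- if (map[["replicate"]] %in% names(raw)) {
      raw[[map[["replicate"]]]]
    } else {
      stats::ave(seq_len(nrow(long)), long$site, long$tree, long$date,
                 FUN = seq_along)
    }
    long$src_row <- seq_len(nrow(raw))
  }

  parsed_date <- as.Date(long$date, optional = TRUE)
  obs <- data.frame(site = as.character(long$site),
                    tree = as.character(long$tree),
                    date = parsed_date,
                    year = as.integer(format(parsed_date, "%Y")),
                    day = day_from_may1(parsed_date),
                    score = suppressWarnings(as.integer(long$score)),
                    replicate = suppressWarnings(as.integer(long$replicate)),
                    stringsAsFactors = FALSE)

  reasons <- character(nrow(obs))
  reasons[is.na(obs$date)] <- "unparsable date"
  checked <- validate_observations(obs[!is.na(obs$date), , drop = FALSE])
  if (nrow(checked) > 0L) {
    ok_rows <- which(!is.na(obs$date))
    reasons[ok_rows[checked$row]] <- checked$reason
  }
  rejected <- data.frame(row = long$src_row[reasons != ""],
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  obs <- obs[reasons == "", , drop = FALSE]
  if (nrow(obs) == 0L) stop("no valid observations in ", path)
  survey <- phenology_survey(obs)
  attr(survey, "rejected") <- rejected
  survey
}

#' Write a phenology survey to CSV
#'
#' Dates are written in ISO-8601 regardless of the input dialect, so a
#' write/read round trip preserves every observation exactly.
#'
#' @param survey a [phenology_survey()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- as.data.frame(survey)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out[c("site", "tree", "date", "score", "replicate")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read daily weather-station records
#'
#' Reads station, date, and daily maximum/minimum air temperature (degrees
#' Celsius) from a CSV, computes the daily average as the midpoint of the
#' two (the median of two values), and verifies continuous date coverage
#' within each station-year, warning with the gap count when days are
#' missing.
#'
#' @param path path to a CSV with columns `station`, `date`, `tmax`, `tmin`.
#' @return data frame with columns `station`, `date`, `year`, `tmax`,
#'   `tmin`, `tavg`.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("station", "date", "tmax", "tmin")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  wx <- data.frame(station = as.character(raw$station),
                   date = as.Date(raw$date),
                   tmax = as.numeric(raw$tmax),
                   tmin = as.numeric(raw$tmin),
                   stringsAsFactors = FALSE)
  if (anyNA(wx$date)) {
    stop("unparsable date at row ", which(is.na(wx$date))[1L])
  }
  inverted <- which(wx$tmin > wx$tmax)
  if (length(inverted) > 0L) {
    stop("tmin > tmax at row ", inverted[1L], " (",
         length(inverted), " row(s) affected)")
  }
  wx$year <- as.integer(format(wx$date, "%Y"))
  wx$tavg <- daily_average(wx$tmax, wx$tmin)
  gaps <- weather_gaps(wx)
  if (nrow(gaps) > 0L) {
    warning(nrow(gaps), " gap(s) in daily coverage, first: ",
            gaps$station[1L], " ", format(gaps$date[1L]))
  }
  wx[order(wx$station, wx$date), c("station", "date", "year",
                                   "tmax", "tmin", "tavg")]
}

# Missing days between the first and last record of each station-year.
weather_gaps <- function(wx) {
  out <- lapply(split(wx, list(wx$station, wx$year), drop = TRUE),
                function(g) {
                  full <- seq(min(g$date), max(g$date), by = "day")
                  miss <- full[!full %in% g$date]
                  if (length(miss) == 0L) return(NULL)
                  data.frame(station = g$station[1L], date = miss,
                             stringsAsFactors = FALSE)
                })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    data.frame(station = character(), date = as.Date(character()))
  } else {
    rownames(out) <- NULL
    out
  }
}
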
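#' Write analysis results to machine-readable report files
#'
#' Emits delimited-text tables for whichever results are supplied — the
#' pairwise lag matrix, exceedance-probability curves, and the rank
#' consistency table — plus a run log recording the seed, the options used,
#' and the package version.  Identical inputs and seed produce
#' byte-identical files.
#'
#' @param results named list; recognized elements are `lags` (a
#'   [pairwise_lag_table()] result), `exceedance` (a data frame of
#'   predicted curves, e.g. columns `site`, `day`, `prob`), and `ranks` (a
#'   [consistency_table()] result).  At least one must be present.
#' @param dir output directory, created if needed.
#' @param seed,options recorded in the run log.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(results, dir, seed = NA_integer_,
                         options = list()) {
  known <- intersect(c("lags", "exceedance", "ranks"), names(results))
  known <- known[!vapply(results[known], is.null, logical(1))]
  if (length(known) == 0L) {
    stop("no analysis results to write")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  for (nm in known) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(results[[nm]]), path, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, path)
  }
  log_path <- file.path(dir, "run_log.txt")
  opt_lines <- if (length(options) > 0L) {
    paste0(names(options), " = ", vapply(options, function(x)
      paste(format(x), collapse = ","), character(1)))
  } else "(none)"
  writeLines(c(paste0("phenolag version: ",
                      as.character(utils::packageVersion("phenolag"))),
               paste0("seed: ", seed),
               "options:",
               paste0("  ", opt_lines),
               paste0("tables: ", paste(basename(written), collapse = ", "))),
             log_path)
  invisible(c(written, log_path))
}
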
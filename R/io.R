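#' Read a raw-measurement table
#'
#' Reads `measurements.csv` (columns `solute`, `replicate`, `tau_min`,
#' `mass_g`, `dry_fraction`, optional `a_w`; comma-separated, `.` decimal
#' point). Numeric columns that arrive with `,` decimal separators are
#' normalised with a warning. Schema violations are reported with the
#' offending column and row.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_measurements <- function(path) {
  df <- read_table_checked(path,
    required = c("solute", "replicate", "tau_min", "mass_g", "dry_fraction"),
    numeric_cols = c("tau_min", "mass_g", "dry_fraction", "a_w"))
  check_range(df, path, "tau_min", lower = 0, closed_lower = TRUE)
  check_range(df, path, "mass_g", lower = 0)
  check_range(df, path, "dry_fraction", lower = 0, upper = 1,
              closed_upper = TRUE)
  if ("a_w" %in% names(df)) {
    check_range(df, path, "a_w", lower = 0, upper = 1, allow_na = TRUE)
  }
  df
}

#' Read an initial-state table
#'
#' Reads `initial.csv` (columns `solute`, `replicate`, `m0_g`, `s0`): the
#' initial mass and dry-matter fraction of every sample series.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_initial <- function(path) {
  df <- read_table_checked(path,
    required = c("solute", "replicate", "m0_g", "s0"),
    numeric_cols = c("m0_g", "s0"))
  check_range(df, path, "m0_g", lower = 0)
  check_range(df, path, "s0", lower = 0, upper = 1, closed_upper = TRUE)
  df
}

read_table_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      if (any(grepl(",", v, fixed = TRUE))) {
        warning(path, ": column '", col,
                "' uses ',' as decimal separator; normalised", call. = FALSE)
        v <- gsub(",", ".", v, fixed = TRUE)
      }
      v <- suppressWarnings(as.numeric(v))
    }
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(path, ": column '", col, "' is not numeric at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

check_range <- function(df, path, col, lower = -Inf, upper = Inf,
                        closed_lower = FALSE, closed_upper = FALSE,
                        allow_na = FALSE) {
  v <- df[[col]]
  bad <- (if (closed_lower) v < lower else v <= lower) |
    (if (closed_upper) v > upper else v >= upper)
  if (allow_na) bad[is.na(v)] <- FALSE
  if (any(bad, na.rm = TRUE)) {
    stop(path, ": column '", col, "' out of range at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write kinetics tables to CSV
#'
#' Writes the replicate-averaged table as `kinetics.csv` and the
#' per-replicate table as `kinetics_by_rep.csv` in `dir`.
#'
#' @param kinetics an `od_kinetics` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_kinetics <- function(kinetics, dir) {
  stopifnot(inherits(kinetics, "od_kinetics"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "kinetics.csv"),
             file.path(dir, "kinetics_by_rep.csv"))
  utils::write.csv(kinetics$averaged, paths[1], row.names = FALSE, na = "")
  utils::write.csv(kinetics$by_rep, paths[2], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a kinetics table written by [write_kinetics()]
#'
#' @param path CSV path (`kinetics.csv` or `kinetics_by_rep.csv`).
#' @return data.frame; empty CR cells become `NA`.
#' @export
read_kinetics <- function(path) {
  df <- read_table_checked(path,
    required = c("solute", "tau_min"),
    numeric_cols = c("tau_min", "WC", "SG", "WL", "WLT", "CR", "a_w"))
  df
}

#' Write a model-fit report to CSV
#'
#' One row per (solute, response, family); parameters a family does not
#' have are left empty.
#'
#' @param report an `od_fit_report` data.frame from [fit_report()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_fit_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a Tukey report to CSV
#'
#' Flattens an `od_tukey` object into the report layout: the letter-group
#' rows followed by the contrast rows.
#'
#' @param tukey an `od_tukey` object.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_tukey_report <- function(tukey, path) {
  stopifnot(inherits(tukey, "od_tukey"))
  g <- tukey$groups
  co <- tukey$contrasts
  out <- rbind(
    data.frame(factor = tukey$factor, kind = "group", level = g$level,
               letter = g$letter, mean = g$mean, contrast = "",
               limit = NA_real_, difference = NA_real_, significant = NA,
               stringsAsFactors = FALSE),
    data.frame(factor = tukey$factor, kind = "contrast", level = "",
               letter = "", mean = NA_real_, contrast = co$contrast,
               limit = co$limit, difference = co$difference,
               significant = co$significant, stringsAsFactors = FALSE)
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a run manifest
#'
#' Records what a pipeline run did: command, input/output paths, seed,
#' config hash, package version and timestamp, as JSON next to the
#' outputs.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param inputs,outputs character vectors of paths.
#' @param seed integer seed or `NA`.
#' @param config_path optional config file to hash (md5).
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, command, inputs = character(),
                           outputs = character(), seed = NA,
                           config_path = NULL) {
  manifest <- list(
    command = command,
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    seed = seed,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA,
    package_version = as.character(utils::packageVersion("odkinetics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
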
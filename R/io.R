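#' Read a caliper measurement CSV
#'
#' Expected columns: `animal_id`, `group_id`, `day`, `width_mm`, `length_mm`
#' and optionally `alive` (0/1). Comma-separated, `.` decimal, UTF-8, header
#' required. Validation errors report 1-based file line numbers (header is
#' line 1). Transposed width/length pairs are swapped with a warning naming
#' the lines, per the caliper convention.
#'
#' @param path CSV file path.
#' @return A [caliper_records()] table.
#' @export
read_caliper_csv <- function(path) {
  if (!file.exists(path)) {
    stop_ftgr("file not found: ", path, class = "ftgr_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("animal_id", "group_id", "day", "width_mm", "length_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_ftgr("missing column(s) in ", path, ": ",
              paste(missing_cols, collapse = ", "), class = "ftgr_schema_error")
  }
  for (col in c("day", "width_mm", "length_mm")) {
    if (is.character(df[[col]])) {
      if (any(grepl(",", df[[col]], fixed = TRUE))) {
        bad <- which(grepl(",", df[[col]], fixed = TRUE)) + 1L
        stop_ftgr("column '", col, "' uses a locale decimal comma at line(s) ",
                  paste(bad, collapse = ", "), "; use '.' as decimal separator",
                  class = "ftgr_schema_error")
      }
      suppressWarnings(num <- as.numeric(df[[col]]))
      if (anyNA(num)) {
        bad <- which(is.na(num)) + 1L
        stop_ftgr("non-numeric '", col, "' at line(s) ",
                  paste(bad, collapse = ", "), class = "ftgr_schema_error")
      }
      df[[col]] <- num
    }
  }
  # re-map row indices in record validation messages to file lines
  withCallingHandlers(
    caliper_records(df),
    ftgr_swap_warning = function(w) {
      rows <- as.integer(regmatches(conditionMessage(w),
                                    gregexpr("[0-9]+", conditionMessage(w)))[[1L]])
      warn_ftgr("width > length at line(s) ",
                paste(rows + 1L, collapse = ", "),
                " of ", path, "; swapped to restore the caliper convention",
                class = "ftgr_swap_warning")
      invokeRestart("muffleWarning")
    },
    error = function(e) {
      if (inherits(e, "ftgr_duplicate_error")) {
        rows <- as.integer(regmatches(conditionMessage(e),
                                      gregexpr("[0-9]+", conditionMessage(e)))[[1L]])
        stop_ftgr("duplicate (animal_id, day) at line(s) ",
                  paste(rows + 1L, collapse = ", "), " of ", path,
                  class = "ftgr_duplicate_error")
      }
    })
}

#' Write caliper records to CSV
#'
#' @param records A [caliper_records()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caliper_csv <- function(records, path) {
  df <- as.data.frame(records)
  df$alive <- as.integer(df$alive)
  utils::write.csv(
    df[, c("animal_id", "group_id", "day", "width_mm", "length_mm", "alive")],
    path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a thermal trace CSV
#'
#' Expected columns: `time_s`, `temp_C` and `laser_on` (0/1). If `laser_on`
#' is absent, supply `switch_times`: the laser state starts at `initial_on`
#' and toggles at each listed time.
#'
#' @param path CSV file path.
#' @param switch_times Optional numeric vector of toggle times, s.
#' @param initial_on Laser state before the first toggle.
#' @return A [thermal_trace()].
#' @export
read_thermal_csv <- function(path, switch_times = NULL, initial_on = TRUE) {
  if (!file.exists(path)) {
    stop_ftgr("file not found: ", path, class = "ftgr_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("time_s", "temp_C") %in% names(df))) {
    stop_ftgr("thermal CSV needs columns time_s and temp_C",
              class = "ftgr_schema_error")
  }
  if (!"laser_on" %in% names(df)) {
    if (is.null(switch_times)) {
      stop_ftgr("no laser_on column and no switch_times supplied",
                class = "ftgr_schema_error")
    }
    n_toggles <- vapply(df$time_s,
                        function(t) sum(switch_times <= t), integer(1))
    df$laser_on <- xor(initial_on, n_toggles %% 2L == 1L)
  }
  thermal_trace(df$time_s, df$temp_C, df$laser_on)
}

#' Write a thermal trace to CSV
#'
#' @param trace A [thermal_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermal_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$laser_on <- as.integer(df$laser_on)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write FTGR or TGI results as tidy CSV
#'
#' Columns: `group_id`, `day`, `statistic`, `value`, `convention`.
#'
#' @param x An `ftgr_trace` or the data.frame returned by [compute_tgi()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stat_csv <- function(x, path) {
  df <- if (inherits(x, "ftgr_trace")) {
    as.data.frame(x)
  } else {
    data.frame(group_id = x$group_id, day = x$eval_day, statistic = "TGI",
               value = x$tgi, convention = NA_character_)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a run manifest
#'
#' Every CLI run writes one manifest (JSON) alongside its outputs so the
#' output can be reproduced from inputs + manifest alone: package version,
#' seed, convention flags, MD5 digests of the input files and of the config.
#'
#' @param seed Integer seed used (or `NULL`).
#' @param inputs Character vector of input file paths.
#' @param config Parsed config list (or `NULL`).
#' @param flags Named list of convention/threshold flags.
#' @return A list; serialise with [write_manifest()].
#' @export
run_manifest <- function(seed = NULL, inputs = character(0), config = NULL,
                         flags = list()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(d), basename(inputs)))
  } else list()
  config_hash <- if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(yaml::as.yaml(config), tmp)
    unname(tools::md5sum(tmp))
  } else NA_character_
  list(tool = "ftgr",
       version = as.character(utils::packageVersion("ftgr")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, config_hash = config_hash,
       input_digests = digests, flags = flags)
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
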
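#' Tumor volume from caliper width and length
#'
#' Converts a two-axis digital caliper measurement to an ellipsoid-approximate
#' tumor volume using the standard preclinical formula
#' \eqn{V = 0.5 \cdot w^2 \cdot l} (mm^3), where \eqn{w} is the short axis
#' (width) and \eqn{l} the long axis (length).
#'
#' @param width Tumor width in mm (short axis). Vectorised.
#' @param length Tumor length in mm (long axis). Vectorised.
#' @return Tumor volume in mm^3.
#' @examples
#' compute_volume(4, 7.5) # 60 mm^3
#' @export
compute_volume <- function(width, length) {
  if (!is.numeric(width) || !is.numeric(length)) {
    stop_ftgr("width and length must be numeric", class = "ftgr_invalid_measurement")
  }
  if (any(!is.finite(width)) || any(!is.finite(length)) ||
      any(width <= 0) || any(length <= 0)) {
    stop_ftgr("caliper dimensions must be positive and finite",
              class = "ftgr_invalid_measurement")
  }
  0.5 * width^2 * length
}

#' Construct a validated table of caliper records
#'
#' One row per animal x day measurement. Enforces the caliper convention
#' length >= width by swapping transposed pairs with a warning, checks that
#' days are unique within an animal, and attaches per-row volumes.
#'
#' @param df A data.frame with columns `animal_id`, `group_id`, `day`,
#'   `width_mm`, `length_mm` and optionally `alive` (logical or 0/1,
#'   default alive).
#' @return A data.frame of class `caliper_records` with an added
#'   `volume_mm3` column.
#' @export
caliper_records <- function(df) {
  required <- c("animal_id", "group_id", "day", "width_mm", "length_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_ftgr("missing columns: ", paste(missing_cols, collapse = ", "),
              class = "ftgr_schema_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"alive" %in% names(df)) df$alive <- TRUE
  df$alive <- as.logical(df$alive)
  if (anyNA(df$alive)) {
    stop_ftgr("alive column must be logical or 0/1", class = "ftgr_schema_error")
  }
  if (!is.numeric(df$day) || any(!is.finite(df$day)) || any(df$day != round(df$day))) {
    stop_ftgr("day must be integer-valued", class = "ftgr_schema_error")
  }
  if (!is.numeric(df$width_mm) || !is.numeric(df$length_mm) ||
      anyNA(df$width_mm) || anyNA(df$length_mm)) {
    stop_ftgr("width_mm and length_mm must be numeric and non-missing",
              class = "ftgr_schema_error")
  }
  if (any(df$width_mm <= 0) || any(df$length_mm <= 0)) {
    bad <- which(df$width_mm <= 0 | df$length_mm <= 0)
    stop_ftgr("non-positive caliper dimension at row(s) ",
              paste(bad, collapse = ", "), class = "ftgr_invalid_measurement")
  }
  key <- paste(df$animal_id, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop_ftgr("duplicate (animal_id, day) at row(s) ",
              paste(dup, collapse = ", "), class = "ftgr_duplicate_error")
  }
  swap <- df$width_mm > df$length_mm
  if (any(swap)) {
    warn_ftgr("width > length at row(s) ", paste(which(swap), collapse = ", "),
              "; swapping to restore the caliper convention",
              class = "ftgr_swap_warning")
    tmp <- df$width_mm[swap]
    df$width_mm[swap] <- df$length_mm[swap]
    df$length_mm[swap] <- tmp
  }
  df$volume_mm3 <- compute_volume(df$width_mm, df$length_mm)
  class(df) <- c("caliper_records", "data.frame")
  df
}

#' Group-mean tumor volume series on the measurement grid
#'
#' Averages per-animal volumes over animals alive at each day, producing the
#' mean-volume series \eqn{V(t_n)} on which FTGR and TGI operate. Animals
#' flagged dead are removed from the mean from their first non-alive day
#' onward; the per-day animal count is reported so composition changes are
#' visible.
#'
#' @param records A `caliper_records` table (or a data.frame acceptable to
#'   [caliper_records()]).
#' @param group_id Which group to aggregate.
#' @param interpolate_gaps If `TRUE`, a missing interior day for an animal is
#'   filled by linear interpolation in log-volume (growth is multiplicative);
#'   the default `FALSE` raises an error on a ragged grid so that repaired
#'   data can never silently fabricate a trigger.
#' @return An object of class `volume_series`: list with `group_id`, `days`
#'   (uniform integer grid), `volumes` (mm^3, group means), `n_animals`.
#' @export
group_mean_series <- function(records, group_id, interpolate_gaps = FALSE) {
  if (!inherits(records, "caliper_records")) records <- caliper_records(records)
  rec <- records[records$group_id == group_id, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop_ftgr("no records for group '", group_id, "'", class = "ftgr_empty_group")
  }
  # censor: once an animal is non-alive it stays excluded
  rec <- rec[order(rec$animal_id, rec$day), , drop = FALSE]
  keep <- unlist(lapply(split(rec$alive, rec$animal_id), function(a) cumprod(a) > 0),
                 use.names = FALSE)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop_ftgr("no alive measurements for group '", group_id, "'",
              class = "ftgr_empty_group")
  }
  days <- sort(unique(rec$day))
  if (length(days) > 1L) {
    steps <- diff(days)
    if (length(unique(steps)) != 1L) {
      stop_ftgr("measurement days are not on a uniform grid: ",
                paste(days, collapse = ", "), class = "ftgr_grid_error")
    }
  }
  # each animal must cover the grid from its first to its last day
  per_animal <- split(rec, rec$animal_id)
  for (nm in names(per_animal)) {
    a <- per_animal[[nm]]
    expected <- days[days >= min(a$day) & days <= max(a$day)]
    missing_days <- setdiff(expected, a$day)
    if (length(missing_days)) {
      if (!interpolate_gaps) {
        stop_ftgr("animal '", nm, "' missing day(s) ",
                  paste(missing_days, collapse = ", "),
                  " (set interpolate_gaps = TRUE to repair in log-volume)",
                  class = "ftgr_grid_error")
      }
      filled <- stats::approx(a$day, log(a$volume_mm3), xout = expected)$y
      a <- data.frame(animal_id = nm, group_id = group_id, day = expected,
                      width_mm = NA_real_, length_mm = NA_real_, alive = TRUE,
                      volume_mm3 = exp(filled))
      per_animal[[nm]] <- a
    }
  }
  rec <- do.call(rbind, per_animal)
  vols <- tapply(rec$volume_mm3, factor(rec$day, levels = days), mean)
  n <- tapply(rec$volume_mm3, factor(rec$day, levels = days), length)
  volume_series(group_id = group_id, days = days,
                volumes = as.numeric(vols), n_animals = as.integer(n))
}

#' Construct a volume series on a uniform day grid
#'
#' @param group_id Group label.
#' @param days Strictly increasing integer day grid with constant step.
#' @param volumes Positive mean volumes (mm^3), one per day.
#' @param n_animals Optional per-day animal counts.
#' @return A `volume_series` object.
#' @export
volume_series <- function(group_id, days, volumes, n_animals = NULL) {
  if (length(days) != length(volumes)) {
    stop_ftgr("days and volumes must have equal length", class = "ftgr_grid_error")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop_ftgr("volumes must be positive and finite", class = "ftgr_invalid_measurement")
  }
  if (any(days != round(days)) || any(diff(days) <= 0)) {
    stop_ftgr("days must be strictly increasing integers", class = "ftgr_grid_error")
  }
  if (length(days) > 2L && length(unique(diff(days))) != 1L) {
    stop_ftgr("day grid must have a constant step", class = "ftgr_grid_error")
  }
  if (is.null(n_animals)) n_animals <- rep(NA_integer_, length(days))
  structure(list(group_id = group_id, days = as.integer(days),
                 volumes = as.numeric(volumes),
                 n_animals = as.integer(n_animals)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat("Mean tumor volume series, group '", x$group_id, "'\n", sep = "")
  cat("  days ", min(x$days), "..", max(x$days),
      " (step ", grid_step(x), "), ", length(x$days), " points\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.volume_series <- function(x, ...) {
  data.frame(group_id = x$group_id, day = x$days, volume_mm3 = x$volumes,
             n_animals = x$n_animals)
}

#' @export
plot.volume_series <- function(x, ..., log = "y") {
  graphics::plot(x$days, x$volumes, type = "b", pch = 16, log = log,
                 xlab = "day", ylab = expression(volume ~ (mm^3)),
                 main = paste("Group", x$group_id), ...)
  invisible(x)
}

grid_step <- function(series) {
  if (length(series$days) < 2L) return(NA_integer_)
  as.integer(series$days[2L] - series$days[1L])
}

#' Percent growth over one grid step
#'
#' The backward interval growth rate
#' \eqn{100 \cdot (V(d) - V(d-h)) / V(d-h)} at day `d`, where `h` is the grid
#' step. This is the bracketed sub-expression of the FTGR indicator, exposed
#' for plots and diagnostics.
#'
#' @param series A `volume_series`.
#' @param day Day on the grid (its predecessor must also be on the grid).
#' @return Growth over the preceding step, in percent.
#' @export
interval_growth_rate <- function(series, day) {
  stopifnot(inherits(series, "volume_series"))
  i <- match(day, series$days)
  if (is.na(i) || i < 2L) {
    stop_ftgr("day ", day, " and its predecessor must both be on the grid",
              class = "ftgr_grid_error")
  }
  100 * (series$volumes[i] - series$volumes[i - 1L]) / series$volumes[i - 1L]
}
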
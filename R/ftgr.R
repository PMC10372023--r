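#' Fluctuation of tumor growth rate (FTGR)
#'
#' For a mean-volume series \eqn{V(t_n)} on a uniform grid (step `h`, 2 days
#' by default), FTGR at the triplet \eqn{(t_{n-1}, t_n, t_{n+1})} of adjacent
#' grid points is the difference between the forward and backward percent
#' growth:
#' \deqn{\mathrm{FTGR} = \frac{V(t_{n+1}) - V(t_n)}{V(t_n)} \cdot 100\%
#'       - \frac{V(t_n) - V(t_{n-1})}{V(t_{n-1})} \cdot 100\%}
#' (with grid points two days apart, \eqn{t_{n\pm1}} are the study's
#' \eqn{t_{n\pm2}}-day time points). Negative values mean the growth rate is
#' still declining — the ongoing immune response suffices; a value rising
#' above 0 signals accelerating growth and is the cue for a booster
#' irradiation.
#'
#' Two day-labelling conventions are supported. Under `"latest"` (default,
#' causal) the value of the triplet ending at \eqn{t_{n+1}} is reported at
#' day \eqn{t_{n+1}}, so every value only uses measurements at or before its
#' label day and can drive same-day decisions. Under `"middle"` it is
#' reported at the central day \eqn{t_n}.
#'
#' @param series A [volume_series()] with at least 3 grid points and positive
#'   volumes.
#' @param label_convention `"latest"` (causal, default) or `"middle"`.
#' @return An object of class `ftgr_trace`: list with `days`, `values`
#'   (percent), `label_convention`, `group_id` and the grid step `h`.
#' @examples
#' s <- volume_series("G", days = c(0, 2, 4, 6), volumes = c(60, 80, 90, 120))
#' compute_ftgr(s) # -20.83% at day 4, +20.83% at day 6
#' @export
compute_ftgr <- function(series, label_convention = c("latest", "middle")) {
  stopifnot(inherits(series, "volume_series"))
  label_convention <- match.arg(label_convention)
  v <- series$volumes
  d <- series$days
  if (length(v) < 3L) {
    stop_ftgr("FTGR needs at least 3 grid points", class = "ftgr_grid_error")
  }
  if (any(v <= 0)) {
    stop_ftgr("FTGR undefined for non-positive volumes",
              class = "ftgr_invalid_measurement")
  }
  n <- length(v)
  fwd <- 100 * (v[3:n] - v[2:(n - 1L)]) / v[2:(n - 1L)]
  bwd <- 100 * (v[2:(n - 1L)] - v[1:(n - 2L)]) / v[1:(n - 2L)]
  vals <- fwd - bwd
  days <- if (label_convention == "latest") d[3:n] else d[2:(n - 1L)]
  structure(list(days = as.integer(days), values = as.numeric(vals),
                 label_convention = label_convention,
                 group_id = series$group_id, h = grid_step(series)),
            class = "ftgr_trace")
}

#' @export
print.ftgr_trace <- function(x, ...) {
  cat("FTGR trace (", x$label_convention, " day labels), group '",
      x$group_id, "'\n", sep = "")
  df <- as.data.frame(x)
  df$value <- sprintf("%+.2f%%", df$value)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ftgr_trace <- function(x, ...) {
  data.frame(group_id = x$group_id, day = x$days, statistic = "FTGR",
             value = x$values, convention = x$label_convention)
}

#' @export
plot.ftgr_trace <- function(x, threshold = 0, ...) {
  graphics::plot(x$days, x$values, type = "b", pch = 16,
                 xlab = "day", ylab = "FTGR (%)",
                 main = paste("Group", x$group_id), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' First day an FTGR trace rises above a threshold
#'
#' @param trace An `ftgr_trace`.
#' @param threshold Percent threshold (default 0; crossing is strict `>`).
#' @param after Only consider label days strictly greater than this.
#' @return The first qualifying label day, or `NA` if the trace never
#'   crosses.
#' @export
ftgr_crossing_day <- function(trace, threshold = 0, after = -Inf) {
  stopifnot(inherits(trace, "ftgr_trace"))
  i <- which(trace$values > threshold & trace$days > after)
  if (length(i) == 0L) NA_integer_ else trace$days[i[1L]]
}

#' Tumor growth inhibition (TGI)
#'
#' \deqn{\mathrm{TGI} = \left[1 - \frac{T_t / T_0}{C_t / C_0}\right]
#'       \cdot 100\%}
#' where \eqn{T} and \eqn{C} are mean tumor volumes of the treated and
#' control (vehicle) groups, subscript 0 the post-randomization baseline
#' (day 0) and subscript \eqn{t} the evaluation day. TGI is 0 when both arms
#' share the same fold-change and approaches 100\% as the treated arm's
#' fold-change vanishes.
#'
#' @param treated,control `volume_series` objects containing day 0 and
#'   `eval_day`.
#' @param eval_day Evaluation day \eqn{t}.
#' @param baseline_day Baseline day (default 0, randomization).
#' @return A data.frame with `group_id`, `eval_day` and `tgi` (percent).
#' @examples
#' trt <- volume_series("T", c(0, 20), c(62, 124))
#' ctl <- volume_series("C", c(0, 20), c(58, 580))
#' compute_tgi(trt, ctl, eval_day = 20)$tgi # 80
#' @export
compute_tgi <- function(treated, control, eval_day, baseline_day = 0) {
  stopifnot(inherits(treated, "volume_series"), inherits(control, "volume_series"))
  v_at <- function(series, day, what) {
    i <- match(day, series$days)
    if (is.na(i)) {
      stop_ftgr(what, " series for group '", series$group_id,
                "' has no day ", day, class = "ftgr_grid_error")
    }
    series$volumes[i]
  }
  t0 <- v_at(treated, baseline_day, "treated")
  tt <- v_at(treated, eval_day, "treated")
  c0 <- v_at(control, baseline_day, "control")
  ct <- v_at(control, eval_day, "control")
  tgi <- (1 - (tt / t0) / (ct / c0)) * 100
  data.frame(group_id = treated$group_id, eval_day = eval_day, tgi = tgi)
}
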
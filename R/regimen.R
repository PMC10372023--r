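#' On-demand irradiation policy
#'
#' A booster irradiation is given on the first measurement day whose FTGR
#' value rises strictly above `trigger_threshold`, subject to a cap on the
#' number of boosts and a refractory gap between events.
#'
#' @param trigger_threshold FTGR threshold, percent. Crossing is strict
#'   (`>`); an exact hit waits.
#' @param max_boosts Maximum number of booster events after the initial one
#'   (`Inf` = stop only when the trace stays below threshold).
#' @param min_gap_days Minimum days between consecutive events; a crossing
#'   inside the window is suppressed (and logged by the trial runner).
#' @param initial_event_day Day of the vaccination-site first irradiation.
#' @return A `regimen_policy` list.
#' @export
regimen_policy <- function(trigger_threshold = 0, max_boosts = Inf,
                           min_gap_days = 0, initial_event_day = 0) {
  stopifnot(is.finite(trigger_threshold), max_boosts >= 0, min_gap_days >= 0)
  structure(list(trigger_threshold = trigger_threshold,
                 max_boosts = max_boosts,
                 min_gap_days = as.integer(min_gap_days),
                 initial_event_day = as.integer(initial_event_day)),
            class = "regimen_policy")
}

#' Boost decision from the latest FTGR value
#'
#' Inspects the last (most recent) value of a causal FTGR trace and the
#' event history, and decides among `"boost"` (threshold strictly exceeded,
#' boosts remain, refractory gap respected), `"wait"`, and `"stop"` (the
#' boost budget is exhausted). Traces with middle day labels are rejected:
#' they would let a decision read a measurement taken after the decision
#' day.
#'
#' @param trace An `ftgr_trace` with `label_convention = "latest"`.
#' @param policy A [regimen_policy()].
#' @param history Integer vector of past event days (including the initial
#'   irradiation), or a `regimen_log`.
#' @return `"boost"`, `"wait"` or `"stop"` with attribute `day` (the
#'   decision day).
#' @export
detect_triggers <- function(trace, policy = regimen_policy(), history = integer(0)) {
  stopifnot(inherits(trace, "ftgr_trace"), inherits(policy, "regimen_policy"))
  if (trace$label_convention != "latest") {
    stop_ftgr("on-demand decisions need the causal ('latest') label ",
              "convention; got '", trace$label_convention, "'",
              class = "ftgr_noncausal_error")
  }
  if (inherits(history, "regimen_log")) history <- history$events$day
  day <- trace$days[length(trace$days)]
  value <- trace$values[length(trace$values)]
  boosts_used <- sum(history != policy$initial_event_day)
  decision <- if (value > policy$trigger_threshold) {
    if (boosts_used >= policy$max_boosts) "stop"
    else if (length(history) > 0L &&
             day - max(history) < policy$min_gap_days) "wait"
    else "boost"
  } else "wait"
  structure(decision, day = day)
}

#' Run a closed-loop on-demand irradiation trial on the simulator
#'
#' Simulates a treated cohort forward one measurement interval at a time;
#' after each measurement the group-mean series is rebuilt, the causal FTGR
#' trace recomputed, and [detect_triggers()] consulted. A `"boost"` decision
#' injects a new treatment pulse the same day. A control (vehicle) cohort
#' with the same growth parameters and no events is simulated alongside for
#' TGI scoring. Decisions only ever see measurements at or before the
#' decision day, and measurement noise is pre-drawn from the seed so the
#' schedule cannot perturb it.
#'
#' @param params A [growth_sim_params()].
#' @param effect A [treatment_effect()].
#' @param policy A [regimen_policy()]; ignored when `boost_days` is given.
#' @param n_animals Animals per arm.
#' @param seed Integer seed (drives both arms' measurement noise).
#' @param boost_days Optional fixed booster days, overriding adaptive
#'   triggering (for regimen sweeps).
#' @param label Regimen label carried into outputs.
#' @return A `regimen_log`: events table, trigger/suppressed days, treated
#'   and control `volume_series`, final `ftgr_trace`, decision log, seed.
#' @export
run_adaptive_trial <- function(params, effect, policy = regimen_policy(),
                               n_animals = 6L, seed = 1L, boost_days = NULL,
                               label = "adaptive") {
  stopifnot(inherits(params, "growth_sim_params"),
            inherits(effect, "treatment_effect"))
  days <- seq(0L, params$horizon, by = params$step)
  nd <- length(days)
  noise <- with_seed(seed, list(
    treated = draw_noise_factors(n_animals, nd, params$noise_cv),
    control = draw_noise_factors(n_animals, nd, params$noise_cv)))

  event_days <- policy$initial_event_day
  trigger_days <- integer(0)
  suppressed_days <- integer(0)
  decisions <- character(nd)
  latent <- numeric(nd)
  V <- params$V0
  t_prev <- 0
  for (j in seq_len(nd)) {
    V <- integrate_growth(V, t_prev, days[j], params, effect, event_days)
    latent[j] <- V
    t_prev <- days[j]
    measured <- latent[seq_len(j)]
    means <- colMeans(sweep(noise$treated[, seq_len(j), drop = FALSE],
                            2L, measured, `*`))
    decisions[j] <- "wait"
    if (!is.null(boost_days)) {
      if (days[j] %in% boost_days) {
        event_days <- c(event_days, days[j])
        decisions[j] <- "boost"
      }
    } else if (j >= 3L) {
      series <- volume_series(label, days[seq_len(j)], means,
                              rep(n_animals, j))
      trace <- compute_ftgr(series, "latest")
      d <- detect_triggers(trace, policy, event_days)
      decisions[j] <- as.character(d)
      if (d == "boost") {
        event_days <- c(event_days, days[j])
        trigger_days <- c(trigger_days, days[j])
      } else if (d == "wait" &&
                 trace$values[length(trace$values)] > policy$trigger_threshold) {
        suppressed_days <- c(suppressed_days, days[j])
      }
    }
  }
  treated_means <- colMeans(sweep(noise$treated, 2L, latent, `*`))
  treated <- volume_series(label, days, treated_means, rep(n_animals, nd))
  control_latent <- simulate_latent(params, NULL, integer(0), days)
  control_means <- colMeans(sweep(noise$control, 2L, control_latent, `*`))
  control <- volume_series("control", days, control_means, rep(n_animals, nd))
  events <- do.call(rbind, lapply(sort(event_days), irradiation_event))
  structure(list(label = label, events = events, trigger_days = trigger_days,
                 suppressed_days = suppressed_days,
                 decisions = data.frame(day = days, decision = decisions),
                 series = treated, control = control,
                 ftgr = compute_ftgr(treated, "latest"),
                 policy = policy, effect = effect, params = params,
                 n_animals = as.integer(n_animals), seed = as.integer(seed)),
            class = "regimen_log")
}

#' @export
print.regimen_log <- function(x, ...) {
  cat("On-demand irradiation trial '", x$label, "' (seed ", x$seed, ")\n",
      sep = "")
  cat("  events on day(s):   ", paste(x$events$day, collapse = ", "), "\n")
  if (length(x$trigger_days)) {
    cat("  FTGR triggers:      ", paste(x$trigger_days, collapse = ", "), "\n")
  }
  if (length(x$suppressed_days)) {
    cat("  suppressed (gap):   ", paste(x$suppressed_days, collapse = ", "), "\n")
  }
  tg <- compute_tgi(x$series, x$control, eval_day = x$params$horizon)
  cat(sprintf("  TGI at day %d:      %.1f%%\n", x$params$horizon, tg$tgi))
  invisible(x)
}

#' Score alternative regimens by TGI at a common evaluation day
#'
#' @param logs A (optionally named) list of `regimen_log`s sharing growth
#'   parameters and measurement grid.
#' @param eval_day Evaluation day for TGI (each log's own control arm is its
#'   reference).
#' @return Data.frame with `regimen`, `n_events`, `boost_days`, `tgi`,
#'   sorted by descending TGI (stable for ties).
#' @export
compare_regimens <- function(logs, eval_day) {
  stopifnot(length(logs) >= 1L)
  grids <- lapply(logs, function(l) l$series$days)
  if (length(unique(lapply(grids, paste, collapse = ","))) != 1L) {
    stop_ftgr("regimen logs do not share a measurement grid",
              class = "ftgr_grid_error")
  }
  rows <- lapply(seq_along(logs), function(i) {
    l <- logs[[i]]
    nm <- if (!is.null(names(logs)) && nzchar(names(logs)[i])) names(logs)[i]
          else l$label
    boosts <- setdiff(l$events$day, l$policy$initial_event_day)
    data.frame(regimen = nm, n_events = nrow(l$events),
               boost_days = paste(boosts, collapse = ";"),
               tgi = compute_tgi(l$series, l$control, eval_day)$tgi)
  })
  out <- do.call(rbind, rows)
  out[order(-out$tgi), , drop = FALSE]
}
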
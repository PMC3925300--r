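# R surface over the C++ hourly kernel: population containers, the single-hour
# step, full runs, and the two output writers (summary and daily detail).

#' Construct a population state
#'
#' @param stage Integer vector of stage codes (1 egg ... 5 mature adult), one
#'   entry per live agent.
#' @param acc Degree-hours accumulated in the current stage.
#' @param thr Individual degree-hour thresholds (use `Inf` for mature adults).
#' @param fertile Logical; whether the agent can reproduce once mature.
#' @param birth_hour Simulation hour at which each agent was created.
#' @param hour Current simulation hour index (0 at the start).
#' @return An object of class `population_state`.
#' @export
population_state <- function(stage = integer(0), acc = numeric(0),
                             thr = numeric(0), fertile = logical(0),
                             birth_hour = integer(0), hour = 0L) {
  n <- length(stage)
  stopifnot(length(acc) == n, length(thr) == n, length(fertile) == n,
            length(birth_hour) == n)
  out <- list(stage = as.integer(stage), acc = as.numeric(acc),
              thr = as.numeric(thr), fertile = as.logical(fertile),
              birth_hour = as.integer(birth_hour), hour = as.integer(hour),
              cum_eggs = 0, cum_births = 0, deaths_natural = 0,
              deaths_human = 0, adult_deaths = 0, cap_exceeded = FALSE)
  class(out) <- "population_state"
  out
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population at hour %d: %d live agents\n", x$hour, length(x$stage)))
  print(table(factor(STAGES[x$stage], levels = STAGES)))
  invisible(x)
}

# number of live agents
#' @export
length.population_state <- function(x) length(x$stage)

.engine_par <- function(stage_params, repro, interv, engine) {
  list(
    T_min = unname(stage_params$T_min),
    K = unname(stage_params$K),
    T_max = stage_params$T_max,
    gamma = stage_params$gamma,
    mort_mode = if (identical(stage_params$mortality, "temperature")) 1L else 0L,
    M_star = unname(stage_params$M_star),
    quadratics = unname(stage_params$quadratics),
    r = repro$r, r_var = repro$r_var, female_fraction = repro$female_fraction,
    t_S = interv$t_S, S = interv$S, r_red = interv$r_red,
    sterile_offspring = identical(interv$offspring_policy, "sterile"),
    D_m = if (identical(engine$D_m, "thermal_unit")) 0L else 1L,
    N_m = engine$N_m,
    reproduction_hour = engine$reproduction_hour,
    literal_exponent = engine$literal_hourly_exponent
  )
}

#' Advance the population by one hour
#'
#' Applies the scheduler's event order to every live agent for a single hour
#' at ambient temperature `T`: stage transition, daily reproduction (at the
#' configured reproduction hour, with the daily fertility-loss test after
#' countermeasures begin), natural death, then human-induced death for adults
#' after countermeasures begin. Eggs laid this hour join the population but
#' are first processed next hour.
#'
#' @param state A [population_state()].
#' @param T Ambient temperature for this hour, degrees C.
#' @param stage_params,repro,interv,engine Parameter containers.
#' @return The updated `population_state` (hour index incremented by one).
#' @export
step_hour <- function(state, T, stage_params = medflysim::stage_params(),
                      repro = reproduction_params(),
                      interv = intervention_params(),
                      engine = engine_config()) {
  par <- .engine_par(stage_params, repro, interv, engine)
  res <- .abs_advance(state, as.numeric(T), par, FALSE)
  new <- res$state
  new <- c(new, state[setdiff(names(state), names(new))])
  class(new) <- "population_state"
  new
}

#' Run a full simulation
#'
#' Iterates the hourly scheduler from the current state until all agents are
#' dead (extirpation) or the temperature series is exhausted, recording daily
#' stage counts and temperature summaries.
#'
#' @param state Initial [population_state()] (see [instantiate_population()]).
#' @param temps A [temperature_series()] with no missing hours (gap-fill
#'   first); its length bounds the run.
#' @param stage_params,repro,interv,engine Parameter containers.
#' @return An object of class `simulation_result` with fields:
#'   \describe{
#'     \item{t_e}{extirpation time in days (`NA` unless extirpated); the first
#'       day by whose end no agents remain, `ceiling(hour/24)`.}
#'     \item{terminated_by}{`"EXTIRPATED"`, `"TEMPS_EXHAUSTED"`, or
#'       `"CAP_EXCEEDED"` (ran out of temperatures after hitting the agent
#'       cap).}
#'     \item{daily_counts}{matrix, one row per simulated day, live agents by
#'       stage at day end.}
#'     \item{daily_temps}{matrix of per-day min/mean/max temperature.}
#'     \item{cumulative_eggs, cumulative_births, cumulative_adult_deaths,
#'       deaths_natural, deaths_human}{run totals; births count instantiated
#'       (female) agents while eggs count all eggs laid.}
#'     \item{hours}{hours simulated; `final_state` the closing population.}
#'   }
#' @export
run_simulation <- function(state, temps, stage_params = medflysim::stage_params(),
                           repro = reproduction_params(),
                           interv = intervention_params(),
                           engine = engine_config()) {
  if (inherits(temps, "temperature_series")) {
    if (any(temps$missing)) stop("temperature series has missing hours; gap-fill first")
    tv <- temps$temp
  } else tv <- as.numeric(temps)
  if (!length(tv)) stop("temperature series is empty")
  if (!is.null(engine$rng_seed)) set.seed(engine$rng_seed)

  par <- .engine_par(stage_params, repro, interv, engine)
  res <- .abs_advance(state, tv, par, TRUE)

  nd <- res$days_recorded
  counts <- res$day_counts[seq_len(nd), , drop = FALSE]
  colnames(counts) <- STAGES
  dtemps <- res$day_temps[seq_len(nd), , drop = FALSE]
  colnames(dtemps) <- c("tmin", "tmean", "tmax")

  extirpated <- res$status == 1
  terminated_by <- if (extirpated) "EXTIRPATED"
                   else if (res$state$cap_exceeded) "CAP_EXCEEDED"
                   else "TEMPS_EXHAUSTED"
  out <- list(
    t_e = if (extirpated) ceiling(res$te_hour / 24) else NA_real_,
    terminated_by = terminated_by,
    daily_counts = counts,
    daily_temps = dtemps,
    cumulative_eggs = res$state$cum_eggs,
    cumulative_births = res$state$cum_births,
    cumulative_adult_deaths = res$state$adult_deaths,
    deaths_natural = res$state$deaths_natural,
    deaths_human = res$state$deaths_human,
    hours = res$hours_run,
    cap_exceeded = res$state$cap_exceeded,
    final_state = structure(c(res$state[c("stage", "acc", "thr", "fertile",
                                          "birth_hour", "hour")],
                              res$state[c("cum_eggs", "cum_births",
                                          "deaths_natural", "deaths_human",
                                          "adult_deaths", "cap_exceeded")]),
                            class = "population_state")
  )
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation result:", x$terminated_by, "\n")
  if (!is.na(x$t_e)) cat(sprintf("  time to extirpation t_e = %g days\n", x$t_e))
  cat(sprintf("  %d hours simulated; %g eggs laid, %g female agents created\n",
              x$hours, x$cumulative_eggs, x$cumulative_births))
  cat(sprintf("  deaths: %g natural, %g human-induced (%g adults in total)\n",
              x$deaths_natural, x$deaths_human, x$cumulative_adult_deaths))
  invisible(x)
}

#' @export
summary.simulation_result <- function(object, ...) {
  tot <- rowSums(object$daily_counts)
  cat("Daily live-agent totals:\n")
  print(summary(tot))
  print(object)
  invisible(object)
}

#' Plot daily stage counts
#'
#' Simple per-day live-agent count curves, one line per stage.
#'
#' @param x A `simulation_result`.
#' @param log_y Use a log scale for counts.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.simulation_result <- function(x, log_y = FALSE, ...) {
  m <- x$daily_counts
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1, col = seq_len(ncol(m)),
                    xlab = "day", ylab = "live agents",
                    log = if (log_y) "y" else "", ...)
  graphics::legend("topright", legend = colnames(m), col = seq_len(ncol(m)),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a run summary file
#'
#' Key-value text file with every model parameter, the seed, an execution
#' timestamp, total hours, the extirpation time (when reached), and cumulative
#' egg and adult-death counts.
#'
#' @param result A `simulation_result`.
#' @param path Output file.
#' @param stage_params,repro,interv,engine The parameter containers used for
#'   the run.
#' @param seed Seed recorded in the header (if any).
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path, stage_params = medflysim::stage_params(),
                          repro = reproduction_params(),
                          interv = intervention_params(),
                          engine = engine_config(), seed = engine$rng_seed) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(key, val) cat(sprintf("%s: %s\n", key, paste(val, collapse = " ")),
                              file = con)
  w("execution_timestamp", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) w("rng_seed", seed)
  for (s in c("e", "l", "p", "a")) {
    w(paste0("T_min_", s), stage_params$T_min[[s]])
    w(paste0("K_", s), stage_params$K[[s]])
    w(paste0("M_star_", s), stage_params$M_star[[s]])
  }
  w("T_max", stage_params$T_max)
  w("gamma", stage_params$gamma)
  w("mortality_model", stage_params$mortality)
  w("D_m", engine$D_m)
  w("N_m", engine$N_m)
  w("r", repro$r)
  w("r_var", repro$r_var)
  w("female_fraction", repro$female_fraction)
  w("r_red", interv$r_red)
  w("S", interv$S)
  w("t_S", interv$t_S)
  w("offspring_policy", interv$offspring_policy)
  w("total_hours", result$hours)
  w("terminated_by", result$terminated_by)
  if (!is.na(result$t_e)) w("t_e_days", result$t_e)
  w("cumulative_eggs", result$cumulative_eggs)
  w("cumulative_births", result$cumulative_births)
  w("cumulative_adult_deaths", result$cumulative_adult_deaths)
  w("deaths_natural", result$deaths_natural)
  w("deaths_human", result$deaths_human)
  w("cap_exceeded", result$cap_exceeded)
  invisible(path)
}

#' Write the daily detail CSV
#'
#' One row per simulated day: day index, min/mean/max temperature, and the
#' number of living agents in each developmental stage at day end. Output
#' stops at extirpation.
#'
#' @param result A `simulation_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_daily_detail <- function(result, path) {
  df <- data.frame(day = seq_len(nrow(result$daily_counts)),
                   result$daily_temps, result$daily_counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
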
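# Top-level configuration and the end-to-end outbreak analysis chain:
# initialization -> LHS batch -> extirpation statistics -> PRCC -> degree-day
# comparator. Also the bundled synthetic fixtures used in tests and examples.

#' Assemble a scenario configuration
#'
#' @param name Outbreak label.
#' @param facts An [outbreak_facts()] object (flies found, trap sensitivity,
#'   sex ratio, `t_S`).
#' @param ranges Named parameter ranges varied by the batch layer
#'   ([default_param_ranges()] by default).
#' @param stage_params,repro,interv,engine Base parameter containers; design
#'   rows override individual entries. `interv$t_S` is taken from `facts$t_S`.
#' @param age_structure Stable stage distribution used for initialization.
#' @param population_scale Multiplier on the initial population total
#'   (down-scaling for desk-size studies).
#' @param runs Batch size.
#' @param q Extirpation quantile reported (0.95 for the standard rule).
#' @param first_find_date Optional `Date` anchoring the temperature series.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(name, facts,
                            ranges = default_param_ranges(),
                            stage_params = medflysim::stage_params(),
                            repro = reproduction_params(),
                            interv = intervention_params(t_S = facts$t_S),
                            engine = engine_config(),
                            age_structure = medflysim::age_structure(),
                            population_scale = 1, runs = 100, q = 0.95,
                            first_find_date = NULL) {
  if (runs < 1) stop("runs must be >= 1")
  out <- list(name = name, facts = facts, ranges = ranges,
              stage_params = stage_params, repro = repro, interv = interv,
              engine = engine, age_structure = age_structure,
              population_scale = population_scale, runs = runs, q = q,
              first_find_date = first_find_date)
  class(out) <- "scenario_config"
  out
}

#' Pooled ABS stage proportions across replicates
#'
#' Runs `replicates` simulations from the same initial stage counts and pools
#' the daily stage counts across replicates before normalizing, giving mean
#' stage proportions per day. Row 1 is day 0 (the initial distribution);
#' row `d + 1` is the end of day `d`.
#'
#' @param counts Integer initial agents per stage (length 5).
#' @param temps Temperature series covering at least `days` days.
#' @param stage_params,repro,interv,engine Parameter containers.
#' @param replicates Number of replicate runs.
#' @param days Number of days to tabulate.
#' @param base_seed Seed; replicate i uses `base_seed + i`.
#' @return `(days + 1) x 5` matrix of pooled stage proportions.
#' @export
replicate_stage_proportions <- function(counts, temps,
                                        stage_params = medflysim::stage_params(),
                                        repro = reproduction_params(),
                                        interv = intervention_params(),
                                        engine = engine_config(),
                                        replicates = 100, days = 20,
                                        base_seed = 1L) {
  pooled <- matrix(0, days + 1, 5, dimnames = list(NULL, STAGES))
  pooled[1, ] <- counts * replicates
  for (i in seq_len(replicates)) {
    set.seed(base_seed + i)
    pop <- instantiate_population(counts, stage_params, engine)
    res <- run_simulation(pop, temps, stage_params, repro, interv, engine)
    nd <- min(days, nrow(res$daily_counts))
    if (nd > 0)
      pooled[1 + seq_len(nd), ] <- pooled[1 + seq_len(nd), ] +
        res$daily_counts[seq_len(nd), ]
  }
  tot <- rowSums(pooled)
  ok <- tot > 0
  pooled[ok, ] <- pooled[ok, , drop = FALSE] / tot[ok]
  pooled[!ok, ] <- NA_real_
  pooled
}

#' Bundled synthetic fixture scenarios
#'
#' Deterministic desk-scale scenarios used throughout the tests and examples:
#' \describe{
#'   \item{`"warm"`}{120 days with 15/28 degrees C daily extremes, a small
#'     outbreak (1 fly found) and countermeasures from day 2.}
#'   \item{`"cold_snap"`}{the warm scenario with a 3-day sub-zero cold snap
#'     starting on day 45 (both extremes depressed 17 degrees C), the
#'     mechanism by which winter cold shortens extirpation while lengthening
#'     the degree-day quarantine.}
#'   \item{`"leslie_constant"`}{constant 24 degrees C, fixed stage mortalities
#'     (0, 0.6, 0.2, 0.15), thermal-unit development, 100 mature females, and
#'     the matching 40-age-class Leslie model for validation (see the methods
#'     vignette for the class-to-stage map and the low constant fecundity used
#'     so totals decrease).}
#' }
#'
#' @param name One of `"warm"`, `"cold_snap"`, `"leslie_constant"`.
#' @param days Optional override of the series length in days.
#' @return List with elements `config` (a [scenario_config()]), `temps` (a
#'   [temperature_series()]); the Leslie fixture adds `leslie`
#'   (a [leslie_model()]), `counts` (initial stage counts), `days` and
#'   `replicates`.
#' @export
make_fixture_scenario <- function(name = c("warm", "cold_snap", "leslie_constant"),
                                  days = NULL) {
  name <- match.arg(name)
  if (name %in% c("warm", "cold_snap")) {
    nd <- if (is.null(days)) 120L else as.integer(days)
    snap <- if (name == "cold_snap")
      list(start = 45L, length = 3L, depth = 17) else NULL
    temps <- synthesize_fixture(nd, 15, 28, cold_snap = snap, seed = 20090101L)
    cfg <- scenario_config(
      name = name,
      facts = outbreak_facts(flies_found = 1, trap_sensitivity = 0.025, t_S = 2),
      population_scale = 0.05, runs = 100, q = 0.95,
      interv = intervention_params(t_S = 2, S = 0.0275, r_red = 0.75)
    )
    return(list(config = cfg, temps = temps))
  }

  # leslie_constant: constant 24 C and the fixed-mortality validation setup
  nd <- if (is.null(days)) 30L else as.integer(days)
  temps <- temperature_series(rep(24, 24 * nd))
  sp <- stage_params(
    T_min = c(9.6, 5.0, 13.8, 7.9),
    K = c(33.4, 186.8, 124.0, 80.5),
    T_max = 35,
    M_star = c(0.00, 0.60, 0.20, 0.15),
    gamma = 0.05,
    mortality = "fixed"
  )
  repro <- reproduction_params(r = 1, r_var = 0, female_fraction = 0.1)
  interv <- intervention_params()       # no countermeasures in validation
  engine <- engine_config(D_m = "thermal_unit")
  # 40 daily age classes; stage boundaries from the continuous durations the
  # T_min/K values imply at 24 C (egg 2.3 d, larva 9.8 d, pupa 12.2 d, 5 d to
  # maturity -> mature females from class 30). A class whose day straddles a
  # stage boundary gets a duration-weighted (geometric-mean) survival, so the
  # matrix reproduces the simulator's mid-day stage switches.
  Tc <- 24
  inc <- pmax(0, Tc - sp$T_min)                    # degree-hours per hour
  bounds <- cumsum(24 * sp$K / inc) / 24           # stage end, days of life
  surv_by_stage <- 1 - c(sp$M_star, sp$M_star[["a"]])[c(1, 2, 3, 4, 4)]
  b <- c(0, bounds, Inf)
  stage_of <- function(age) findInterval(age, b, left.open = TRUE)
  stage_map <- vapply(1:40, stage_of, 0L)
  surv <- vapply(1:40, function(k) {
    over <- pmax(0, pmin(k + 1, b[-1]) - pmax(k, b[-length(b)]))
    prod(surv_by_stage^over)
  }, 0)
  f_daily <- repro$r * repro$female_fraction       # daily female eggs per mature
  n0 <- numeric(40); n0[30] <- 100
  les <- leslie_model(survival = surv,
                      fecundity = ifelse(stage_map == 5, f_daily, 0),
                      n0 = n0, stage_map = stage_map)
  counts <- c(0L, 0L, 0L, 0L, 100L)
  cfg <- scenario_config(
    name = "leslie_constant",
    facts = outbreak_facts(flies_found = 1, trap_sensitivity = 0.025, t_S = 0),
    stage_params = sp, repro = repro, interv = interv, engine = engine,
    runs = 100
  )
  list(config = cfg, temps = temps, leslie = les, counts = counts,
       days = 20L, replicates = 100L)
}

#' End-to-end outbreak analysis
#'
#' Chains the full pipeline for one scenario: initial-population estimation
#' from trap facts, Latin hypercube sampling over the parameter ranges, the
#' simulation batch, extirpation statistics, PRCC sensitivity analysis, and
#' the degree-day quarantine-length comparator.
#'
#' @param config A [scenario_config()].
#' @param temps A gap-free [temperature_series()].
#' @param base_seed Integer seed governing the design and all runs.
#' @param extirpated_only Use only extirpated runs for the PRCC response
#'   (default); censored runs carry no observed `t_e`.
#' @param ddql_T_min,ddql_K_generation,ddql_generations Comparator settings;
#'   defaults use the egg base temperature and the egg-to-adult sum of thermal
#'   constants.
#' @return Object of class `outbreak_report`: `N_range`, `t_S`, `t_m`, `t_q`,
#'   `QL`, `t_q_minus_QL`, plus the full `batch` and `prcc` tables.
#' @export
analyze_outbreak <- function(config, temps, base_seed = 1L,
                             extirpated_only = TRUE,
                             ddql_T_min = config$stage_params$T_min[["e"]],
                             ddql_K_generation = sum(config$stage_params$K),
                             ddql_generations = 3) {
  stopifnot(inherits(config, "scenario_config"))
  stage <- "initialization"
  report <- tryCatch({
    sens <- config$ranges$trap_sensitivity
    if (is.null(sens)) sens <- rep(config$facts$trap_sensitivity, 2)
    f_lo <- config$facts; f_lo$trap_sensitivity <- sens[2]
    f_hi <- config$facts; f_hi$trap_sensitivity <- sens[1]
    N_range <- c(estimate_population_size(f_lo, config$age_structure,
                                          config$population_scale)$total,
                 estimate_population_size(f_hi, config$age_structure,
                                          config$population_scale)$total)

    stage <- "design"
    set.seed(base_seed)
    design <- lhs_sample(config$ranges, config$runs)

    stage <- "batch"
    batch <- run_batch(config, temps, design, base_seed = base_seed)

    stage <- "statistics"
    stats <- extirpation_stats(batch, q = config$q)

    stage <- "prcc"
    keep <- if (extirpated_only)
      !is.na(batch$t_e) & batch$terminated_by == "EXTIRPATED"
    else !is.na(batch$t_e)
    pr <- prcc(design[keep, , drop = FALSE], batch$t_e[keep])

    stage <- "degree-day comparator"
    QL <- degree_day_quarantine_length(temps, ddql_T_min, ddql_K_generation,
                                       ddql_generations)

    list(name = config$name, N_range = N_range, t_S = config$facts$t_S,
         t_m = stats$t_m, t_q = stats$t_q, q = config$q,
         QL = as.numeric(QL),
         t_q_minus_QL = stats$t_q - as.numeric(QL),
         n_runs = stats$n_runs, n_extirpated = stats$n_extirpated,
         batch = batch, prcc = pr, base_seed = base_seed)
  }, error = function(e) {
    stop("outbreak analysis failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  class(report) <- "outbreak_report"
  report
}

#' @export
print.outbreak_report <- function(x, ...) {
  cat("Outbreak analysis:", x$name, "\n")
  cat(sprintf("  initial population N: %d-%d insects (all stages)\n",
              min(x$N_range), max(x$N_range)))
  cat(sprintf("  t_S: %g days; runs: %d (%d extirpated)\n",
              x$t_S, x$n_runs, x$n_extirpated))
  cat(sprintf("  t_m: %.1f days; t_%.2f: %s days\n", x$t_m, x$q,
              format(x$t_q)))
  cat(sprintf("  degree-day quarantine length QL: %s days; t_q - QL: %s\n",
              format(x$QL), format(x$t_q_minus_QL)))
  cat("  top PRCC parameters:\n")
  print(utils::head(x$prcc[, c("parameter", "coefficient", "statistic", "p")], 5),
        digits = 3)
  invisible(x)
}

#' Write an outbreak report to files
#'
#' Writes the per-run batch CSV, the PRCC table CSV, and a human-readable
#' summary.
#'
#' @param report An [analyze_outbreak()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outbreak_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$batch, file.path(dir, "batch.csv"), row.names = FALSE)
  utils::write.csv(report$prcc, file.path(dir, "prcc.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(report)), file.path(dir, "report.txt"))
  invisible(dir)
}
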
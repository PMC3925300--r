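# YAML scenario files for the command-line layer: one file mirrors one
# outbreak row (detection facts, parameter ranges, engine flags, temperature
# source, batch size).

#' Read a scenario configuration from YAML
#'
#' Recognized keys: `name`, `first_find_date`, `flies_found`,
#' `trap_sensitivity` (scalar used for point estimates),
#' `trap_sensitivity_range` (`[min, max]`, also entered into the LHS ranges),
#' `sex_ratio_female`, `t_S`, `S`, `r_red`, `offspring_policy`,
#' `age_structure` (map with `e`, `l`, `p`, `a_imm`, `a_mat`),
#' `population_scale`, `runs`, `q`, `ranges` (map of `[min, max]`), plus any
#' flat parameter keys understood by [read_param_config()] (e.g. `T_min_l`,
#' `K_p`, `M_star_a`, `gamma`, `D_m`, `N_m`). `temps` may name an hourly CSV
#' (resolved relative to the YAML file) or one of the bundled fixture names.
#'
#' @param path YAML file.
#' @return List with `config` (a [scenario_config()]) and `temps` (a
#'   [temperature_series()] or `NULL` if the file names none).
#' @export
read_scenario_config <- function(path) {
  kv <- yaml::read_yaml(path)
  g <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default

  base <- read_param_config(path)   # flat parameter keys share the format

  sens_range <- g("trap_sensitivity_range", NULL)
  sens <- g("trap_sensitivity",
            if (!is.null(sens_range)) mean(unlist(sens_range)) else 0.025)
  facts <- outbreak_facts(flies_found = g("flies_found", 1),
                          trap_sensitivity = sens,
                          sex_ratio_female = g("sex_ratio_female", 0.5),
                          t_S = g("t_S", 0))

  ranges <- default_param_ranges()
  if (!is.null(kv$ranges))
    for (nm in names(kv$ranges)) ranges[[nm]] <- as.numeric(unlist(kv$ranges[[nm]]))
  if (!is.null(sens_range)) ranges$trap_sensitivity <- as.numeric(unlist(sens_range))

  astr <- if (!is.null(kv$age_structure))
    do.call(age_structure, lapply(kv$age_structure, as.numeric))
  else age_structure()

  cfg <- scenario_config(
    name = g("name", sub("\\.[^.]+$", "", basename(path))),
    facts = facts, ranges = ranges,
    stage_params = base$stage_params, repro = base$repro,
    interv = intervention_params(t_S = g("t_S", 0), S = g("S", 0),
                                 r_red = g("r_red", 0),
                                 offspring_policy = g("offspring_policy", "sterile")),
    engine = base$engine, age_structure = astr,
    population_scale = g("population_scale", 1),
    runs = g("runs", 100), q = g("q", 0.95),
    first_find_date = if (!is.null(kv$first_find_date))
      as.Date(kv$first_find_date) else NULL
  )

  temps <- NULL
  if (!is.null(kv$temps)) {
    if (kv$temps %in% c("warm", "cold_snap", "leslie_constant")) {
      temps <- make_fixture_scenario(kv$temps)$temps
    } else {
      tp <- if (file.exists(kv$temps)) kv$temps
            else file.path(dirname(path), kv$temps)
      if (!file.exists(tp)) stop("temperature file not found: ", kv$temps)
      temps <- read_hourly_csv(tp)
    }
  }
  list(config = cfg, temps = temps)
}
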
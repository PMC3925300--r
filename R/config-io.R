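# Flat key-value parameter config files. Keys follow the standard symbols:
# T_min_l, K_p, M_star_a, gamma, T_max, r, r_var, female_fraction, r_red, S,
# t_S, N_m, D_m.

#' Write a parameter set to a flat YAML config file
#'
#' @param path File to write.
#' @param stage_params,repro,interv,engine Parameter containers as produced by
#'   [stage_params()], [reproduction_params()], [intervention_params()] and
#'   [engine_config()].
#' @return `path`, invisibly.
#' @seealso [read_param_config()]
#' @export
write_param_config <- function(path, stage_params = medflysim::stage_params(),
                               repro = reproduction_params(),
                               interv = intervention_params(),
                               engine = engine_config()) {
  sp <- stage_params
  kv <- list()
  for (s in c("e", "l", "p", "a")) {
    kv[[paste0("T_min_", s)]] <- unname(sp$T_min[[s]])
    kv[[paste0("K_", s)]] <- unname(sp$K[[s]])
    kv[[paste0("M_star_", s)]] <- unname(sp$M_star[[s]])
  }
  kv$T_max <- sp$T_max
  kv$gamma <- sp$gamma
  kv$mortality_model <- sp$mortality
  for (g in rownames(sp$quadratics))
    kv[[paste0("mu_coeffs_", g)]] <- unname(as.numeric(sp$quadratics[g, ]))
  kv$r <- repro$r
  kv$r_var <- repro$r_var
  kv$female_fraction <- repro$female_fraction
  kv$t_S <- interv$t_S
  kv$S <- interv$S
  kv$r_red <- interv$r_red
  kv$offspring_policy <- interv$offspring_policy
  kv$D_m <- engine$D_m
  kv$N_m <- engine$N_m
  kv$reproduction_hour <- engine$reproduction_hour
  if (!is.null(engine$rng_seed)) kv$rng_seed <- engine$rng_seed
  yaml::write_yaml(kv, path, precision = 15L)
  invisible(path)
}

#' Read a parameter set from a flat YAML config file
#'
#' Unknown keys are ignored; absent keys keep their defaults.
#'
#' @param path File written by [write_param_config()] (or hand-authored with
#'   the same keys).
#' @return List with elements `stage_params`, `repro`, `interv`, `engine`.
#' @export
read_param_config <- function(path) {
  kv <- yaml::read_yaml(path)
  g <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  quad <- mortality_quadratics()
  for (grp in rownames(quad)) {
    co <- kv[[paste0("mu_coeffs_", grp)]]
    if (!is.null(co)) quad[grp, ] <- as.numeric(co)
  }
  sp <- stage_params(
    T_min = vapply(c("e", "l", "p", "a"),
                   function(s) g(paste0("T_min_", s), stage_params()$T_min[[s]]), 0),
    K = vapply(c("e", "l", "p", "a"),
               function(s) g(paste0("K_", s), stage_params()$K[[s]]), 0),
    T_max = g("T_max", 35),
    M_star = vapply(c("e", "l", "p", "a"),
                    function(s) g(paste0("M_star_", s), stage_params()$M_star[[s]]), 0),
    gamma = g("gamma", 0.05),
    mortality = g("mortality_model", "temperature"),
    quadratics = quad
  )
  list(
    stage_params = sp,
    repro = reproduction_params(r = g("r", 20), r_var = g("r_var", 3.57),
                                female_fraction = g("female_fraction", 0.5)),
    interv = intervention_params(t_S = g("t_S", 0), S = g("S", 0),
                                 r_red = g("r_red", 0),
                                 offspring_policy = g("offspring_policy", "sterile")),
    engine = engine_config(D_m = g("D_m", "thermal_unit"), N_m = g("N_m", 1e6),
                           rng_seed = kv$rng_seed,
                           reproduction_hour = g("reproduction_hour", 0))
  )
}
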
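# Parameter containers shared by every other module. All tabulated thermal
# constants K are in day-degrees; individual transition thresholds are stored
# in degree-hours (C = 24 * K) because development accumulates per-hour degree
# excesses.

.stage4 <- c("e", "l", "p", "a")

.named4 <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 4L)
  if (length(x) != 4L) stop(what, " must have length 1 or 4", call. = FALSE)
  names(x) <- .stage4
  x
}

#' Default temperature-dependent mortality quadratics
#'
#' Daily mortality as a quadratic in temperature, `mu(T) = a2*T^2 + a1*T + a0`,
#' one curve per stage group: eggs and larvae share one curve, pupae and adults
#' each have their own. Evaluated values are clamped to `[0, 1]`.
#'
#' @return A 3x3 numeric matrix with rows `el`, `p`, `a` and columns
#'   `a2`, `a1`, `a0`.
#' @export
#' @examples
#' mortality_quadratics()
mortality_quadratics <- function() {
  m <- rbind(
    el = c(0.00040, -0.0145, 0.1314),
    p  = c(0.00050, -0.0207, 0.2142),
    a  = c(0.00049, -0.0187, 0.1846)
  )
  colnames(m) <- c("a2", "a1", "a0")
  m
}

# literature-review parameter ranges varied between runs of an outbreak
# (minimum, maximum); midpoints serve as point defaults.
.param_ranges <- list(
  M_star_e = c(0.0198, 0.1200),
  M_star_l = c(0.0068, 0.0946),
  M_star_p = c(0.0016, 0.0465),
  M_star_a = c(0.0245, 0.1340),
  S        = c(0.005, 0.050),
  T_min_e  = c(9.6, 12.5),
  K_e      = c(27.27, 33.80),
  T_min_l  = c(5.0, 10.8),
  K_l      = c(94.50, 186.78),
  T_min_p  = c(9.1, 13.8),
  K_p      = c(123.96, 169.49),
  T_min_a  = c(7.9, 9.9),
  K_a      = c(58.20, 105.71),
  r        = c(5.0, 35.0),
  r_red    = c(0.5, 1.0),
  trap_sensitivity = c(0.02, 0.03)
)

#' Literature-derived parameter ranges
#'
#' Named `[min, max]` intervals for the inputs varied between simulations of an
#' outbreak: per-stage mortality at optimum temperature (`M_star_x`), base
#' temperatures (`T_min_x`), thermal constants (`K_x`), fecundity `r`, daily
#' fertility-loss probability `r_red`, human-induced adult mortality `S`, and
#' the trap sensitivity that induces the initial population size.
#'
#' @param which Optional character vector selecting a subset by name.
#' @return Named list of length-2 numeric vectors `c(min, max)`.
#' @export
#' @examples
#' default_param_ranges(c("M_star_p", "r"))
default_param_ranges <- function(which = NULL) {
  if (is.null(which)) return(.param_ranges)
  missing <- setdiff(which, names(.param_ranges))
  if (length(missing)) stop("unknown parameter range(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  .param_ranges[which]
}

.range_mid <- function(key) mean(.param_ranges[[key]])

#' Stage-specific thermal and mortality parameters
#'
#' @param T_min Base developmental temperatures in degrees C, length 4 in stage
#'   order (egg, larva, pupa, adult). Development rate is zero at or below
#'   `T_min`. The adult entry governs maturation of newly emerged adults.
#' @param K Thermal constants in day-degrees above `T_min` required to complete
#'   each stage; the adult entry is the time from emergence to sexual maturity.
#' @param T_max Temperature in degrees C above which development halts.
#' @param M_star Daily mortality proportion per stage at the optimum
#'   temperature (interpreted as the fixed daily mortality `M_x` when
#'   `mortality = "fixed"`).
#' @param gamma Standard deviation of the individual development threshold as a
#'   proportion of its mean.
#' @param mortality `"temperature"` to add the temperature quadratics to
#'   `M_star` each hour, `"fixed"` to use `M_star` alone.
#' @param quadratics Mortality quadratic coefficients, as
#'   [mortality_quadratics()].
#' @return An object of class `stage_params`.
#' @export
#' @examples
#' sp <- stage_params(gamma = 0)
#' sp$K
stage_params <- function(T_min = c(.range_mid("T_min_e"), .range_mid("T_min_l"),
                                   .range_mid("T_min_p"), .range_mid("T_min_a")),
                         K = c(.range_mid("K_e"), .range_mid("K_l"),
                               .range_mid("K_p"), .range_mid("K_a")),
                         T_max = 35,
                         M_star = c(.range_mid("M_star_e"), .range_mid("M_star_l"),
                                    .range_mid("M_star_p"), .range_mid("M_star_a")),
                         gamma = 0.05,
                         mortality = c("temperature", "fixed"),
                         quadratics = mortality_quadratics()) {
  mortality <- match.arg(mortality)
  out <- list(
    T_min = .named4(as.numeric(T_min), "T_min"),
    K = .named4(as.numeric(K), "K"),
    T_max = as.numeric(T_max)[1],
    M_star = .named4(as.numeric(M_star), "M_star"),
    gamma = as.numeric(gamma)[1],
    mortality = mortality,
    quadratics = quadratics
  )
  class(out) <- "stage_params"
  out
}

#' Reproduction parameters
#'
#' @param r Mean eggs laid per mature female per daily reproduction event.
#' @param r_var Variance of the egg count (3.57 is the literature-survey
#'   estimate accompanying the `r` range).
#' @param female_fraction Share of eggs instantiated as (female) agents; the
#'   simulator follows females only.
#' @return An object of class `reproduction_params`.
#' @export
reproduction_params <- function(r = 20, r_var = 3.57, female_fraction = 0.5) {
  out <- list(r = as.numeric(r)[1], r_var = as.numeric(r_var)[1],
              female_fraction = as.numeric(female_fraction)[1])
  class(out) <- "reproduction_params"
  out
}

#' Countermeasure (intervention) parameters
#'
#' @param t_S Whole days from the first find (simulation start) to the start of
#'   human intervention.
#' @param S Additional daily mortality proportion applied to adults after
#'   intervention begins (bait sprays, insecticide, intensified trapping).
#' @param r_red Daily probability that a fertile mature female permanently
#'   loses fertility after intervention begins (sterile-male matings).
#' @param offspring_policy `"sterile"`: eggs laid after `t_S` never reproduce
#'   (no host fruit after stripping); `"inherit"`: they remain fertile and are
#'   subject to the same rules as their parents.
#' @return An object of class `intervention_params`.
#' @export
intervention_params <- function(t_S = 0, S = 0, r_red = 0,
                                offspring_policy = c("sterile", "inherit")) {
  offspring_policy <- match.arg(offspring_policy)
  out <- list(t_S = as.numeric(t_S)[1], S = as.numeric(S)[1],
              r_red = as.numeric(r_red)[1], offspring_policy = offspring_policy)
  class(out) <- "intervention_params"
  out
}

#' Engine configuration
#'
#' @param D_m Developmental transition model: `"thermal_unit"` accumulates
#'   degree-hours against an individual threshold; `"hourly_probability"`
#'   makes transition a per-hour random event with probability proportional to
#'   the hourly degree excess, matching the thermal-unit mode in expectation.
#' @param N_m Hard cap on live agents; egg creation is truncated at the cap.
#' @param rng_seed Optional integer seed applied before a run.
#' @param reproduction_hour Hour-of-day (0-23, simulation-relative) at which
#'   the daily reproduction event happens.
#' @param literal_hourly_exponent If `TRUE`, use the raw `M^(1/24)` per-hour
#'   death rule instead of survival compounding `1 - (1 - M)^(1/24)`. Kept for
#'   comparison only: the raw exponent makes per-hour probabilities larger
#'   than the daily rate.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(D_m = c("thermal_unit", "hourly_probability"),
                          N_m = 1e6, rng_seed = NULL, reproduction_hour = 0,
                          literal_hourly_exponent = FALSE) {
  D_m <- match.arg(D_m)
  out <- list(D_m = D_m, N_m = as.numeric(N_m)[1],
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)[1],
              reproduction_hour = as.integer(reproduction_hour)[1],
              literal_hourly_exponent = isTRUE(literal_hourly_exponent))
  class(out) <- "engine_config"
  out
}

#' Validate a full parameter set
#'
#' Checks every container invariant and returns findings rather than erroring,
#' so a scenario loader can report all problems at once.
#'
#' @param stage_params A [stage_params()] object.
#' @param repro A [reproduction_params()] object.
#' @param interv An [intervention_params()] object.
#' @param engine An [engine_config()] object.
#' @return Character vector of violations, empty when all invariants hold.
#'   Each entry names the offending field and the rule it breaks.
#' @export
#' @examples
#' validate_params(stage_params(), reproduction_params(),
#'                 intervention_params(), engine_config())
validate_params <- function(stage_params = medflysim::stage_params(),
                            repro = reproduction_params(),
                            interv = intervention_params(),
                            engine = engine_config()) {
  v <- character(0)
  sp <- stage_params
  for (s in .stage4) {
    if (sp$T_min[[s]] >= sp$T_max)
      v <- c(v, sprintf("T_min_%s: T_min >= T_max (%g >= %g)", s, sp$T_min[[s]], sp$T_max))
    if (!(sp$K[[s]] > 0))
      v <- c(v, sprintf("K_%s: must be > 0 (is %g)", s, sp$K[[s]]))
    if (sp$M_star[[s]] < 0 || sp$M_star[[s]] > 1)
      v <- c(v, sprintf("M_star_%s: must lie in [0, 1] (is %g)", s, sp$M_star[[s]]))
  }
  if (sp$gamma < 0) v <- c(v, sprintf("gamma: must be >= 0 (is %g)", sp$gamma))
  if (any(sp$quadratics[, "a2"] <= 0))
    v <- c(v, "quadratics: a2 must be > 0 for every stage group")

  if (repro$r < 0) v <- c(v, sprintf("r: must be >= 0 (is %g)", repro$r))
  if (repro$r_var < 0) v <- c(v, sprintf("r_var: must be >= 0 (is %g)", repro$r_var))
  if (repro$female_fraction < 0 || repro$female_fraction > 1)
    v <- c(v, sprintf("female_fraction: must lie in [0, 1] (is %g)", repro$female_fraction))

  if (interv$t_S < 0) v <- c(v, sprintf("t_S: must be >= 0 (is %g)", interv$t_S))
  if (interv$S < 0 || interv$S > 1)
    v <- c(v, sprintf("S: must lie in [0, 1] (is %g)", interv$S))
  if (interv$r_red < 0 || interv$r_red > 1)
    v <- c(v, sprintf("r_red: must lie in [0, 1] (is %g)", interv$r_red))

  if (!(engine$N_m > 0)) v <- c(v, sprintf("N_m: must be > 0 (is %g)", engine$N_m))
  v
}

#' @export
print.stage_params <- function(x, ...) {
  cat("Stage parameters (", x$mortality, " mortality, gamma = ", x$gamma,
      ", T_max = ", x$T_max, " C)\n", sep = "")
  print(rbind(T_min = x$T_min, K = x$K, M_star = x$M_star))
  invisible(x)
}
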
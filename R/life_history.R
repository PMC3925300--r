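# The three biological submodels -- development, reproduction, mortality -- as
# pure seedable functions of temperature and parameters. The C++ engine kernel
# applies the same formulas; these R versions are the reference surface for
# unit tests and for users inspecting the model piecewise.

#' Hourly thermal increment towards a stage transition
#'
#' Each degree above the stage's base temperature counts for one degree-hour
#' during the hour, except that development halts entirely above `T_max`.
#'
#' @param T Ambient temperature in degrees C (vectorized).
#' @param T_min Base developmental temperature in degrees C.
#' @param T_max Temperature above which development halts.
#' @return Degree-hours accrued during one hour at `T`.
#' @export
#' @examples
#' thermal_increment(26, 12, 35)  # 14
#' thermal_increment(36, 12, 35)  # 0: development halts above T_max
thermal_increment <- function(T, T_min, T_max = 35) {
  ifelse(T > T_max, 0, pmax(0, T - T_min))
}

#' Draw an individual development threshold
#'
#' The tabulated thermal constant `K` (day-degrees) converts to a degree-hour
#' threshold `24 K`; individual variation multiplies it by `1 + gamma z` with
#' `z` standard normal, redrawing in the rare case of a non-positive result.
#'
#' @param K Thermal constant in day-degrees (> 0).
#' @param gamma Standard deviation of the threshold as a proportion of its
#'   mean (>= 0).
#' @param n Number of draws.
#' @return Degree-hour threshold(s), strictly positive.
#' @export
#' @examples
#' set.seed(1); draw_threshold(30, 0)      # exactly 720
draw_threshold <- function(K, gamma, n = 1) {
  stopifnot(K > 0, gamma >= 0)
  out <- 24 * K * (1 + gamma * stats::rnorm(n))
  while (any(bad <- out <= 0))
    out[bad] <- 24 * K * (1 + gamma * stats::rnorm(sum(bad)))
  out
}

#' Is a stage transition due?
#'
#' @param accumulated Degree-hours accumulated since entering the stage.
#' @param threshold Individual degree-hour threshold for leaving it.
#' @return Logical; `TRUE` once `accumulated >= threshold` (boundary
#'   inclusive). Accumulation in excess of the threshold carries into the next
#'   stage.
#' @export
transition_due <- function(accumulated, threshold) accumulated >= threshold

#' Per-hour transition probability (hourly-probability development mode)
#'
#' The expected per-hour fraction of the stage's total development at the
#' current temperature, so that the mean transition time matches the
#' thermal-unit mode at constant temperature.
#'
#' @inheritParams thermal_increment
#' @param K Thermal constant in day-degrees (> 0).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' hourly_transition_probability(26, 12, 35, 30)  # 14/720
hourly_transition_probability <- function(T, T_min, T_max = 35, K) {
  stopifnot(K > 0)
  pmin(1, thermal_increment(T, T_min, T_max) / (24 * K))
}

.quad_group <- c(egg = "el", larva = "el", pupa = "p",
                 adult_immature = "a", adult_mature = "a")

.match_stage <- function(stage) {
  if (is.numeric(stage)) return(STAGES[stage])
  match.arg(stage, STAGES, several.ok = FALSE)
}

#' Temperature-dependent daily mortality component
#'
#' Evaluates the stage group's quadratic `mu(T) = a2 T^2 + a1 T + a0` (eggs and
#' larvae share one curve) and clamps the result to `[0, 1]`. The quadratics
#' are essentially zero at their vertices, the optimum temperature band.
#'
#' @param stage Stage name (see [stage_names()]) or index 1-5.
#' @param T Ambient temperature in degrees C (vectorized).
#' @param quadratics Coefficient matrix as [mortality_quadratics()].
#' @return Daily mortality proportion(s) in `[0, 1]`.
#' @export
#' @examples
#' mu_temperature("adult_mature", 25)  # 0.02335
mu_temperature <- function(stage, T, quadratics = mortality_quadratics()) {
  grp <- .quad_group[[.match_stage(stage)]]
  co <- quadratics[grp, ]
  pmin(1, pmax(0, co[["a2"]] * T^2 + co[["a1"]] * T + co[["a0"]]))
}

#' Total daily natural mortality
#'
#' Additive composition of the stage's mortality at optimum temperature
#' (`M_star`, varied between runs) and the temperature-dependent component,
#' clamped to `[0, 1]`. The composition is additive because the quadratics are
#' approximately zero at the optimum, so `M_star` is the mortality there.
#'
#' @inheritParams mu_temperature
#' @param M_star Daily mortality at optimum temperature, in `[0, 1]`.
#' @return Daily mortality proportion(s) in `[0, 1]`.
#' @export
daily_natural_mortality <- function(stage, T, M_star,
                                    quadratics = mortality_quadratics()) {
  stopifnot(M_star >= 0, M_star <= 1)
  pmin(1, pmax(0, M_star + mu_temperature(stage, T, quadratics)))
}

#' Convert a daily death probability to an hourly one
#'
#' Survival compounding: `1 - (1 - daily)^(1/24)`, so 24 independent hourly
#' trials reproduce the daily probability exactly.
#'
#' @param daily Daily death probability in `[0, 1]` (vectorized).
#' @param literal_exponent If `TRUE`, return the raw `daily^(1/24)` instead.
#'   That variant makes each hourly probability larger than the daily rate and
#'   is retained only for comparison with the raw rule.
#' @return Hourly probability in `[0, 1]`.
#' @export
#' @examples
#' p <- hourly_death_probability(0.15)
#' 1 - (1 - p)^24  # 0.15
hourly_death_probability <- function(daily, literal_exponent = FALSE) {
  stopifnot(all(daily >= 0 & daily <= 1))
  if (literal_exponent) daily^(1 / 24) else 1 - (1 - daily)^(1 / 24)
}

#' Draw a daily egg count
#'
#' Rounded normal draw with mean `r` and variance `r_var`, clamped at zero.
#'
#' @param r Mean eggs per female per reproduction event (>= 0).
#' @param r_var Variance of the egg count (>= 0).
#' @param n Number of draws.
#' @return Non-negative integer egg count(s).
#' @export
daily_eggs <- function(r, r_var, n = 1) {
  stopifnot(r >= 0, r_var >= 0)
  pmax(0L, as.integer(round(stats::rnorm(n, r, sqrt(r_var)))))
}

#' Daily sterilization event
#'
#' After countermeasures begin, each fertile mature female is tested once per
#' day and permanently loses fertility with probability `r_red` (wild females
#' mating with released sterile males).
#'
#' @param r_red Daily fertility-loss probability in `[0, 1]`.
#' @param n Number of independent trials.
#' @return Logical vector; `TRUE` means fertility is lost.
#' @export
sterilization_event <- function(r_red, n = 1) {
  stopifnot(r_red >= 0, r_red <= 1)
  stats::runif(n) < r_red
}
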
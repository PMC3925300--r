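# Convert trap-capture facts into an initial agent population: trap
# sensitivity scales flies found up to an adult female estimate, and a stable
# age distribution infers the unobserved immature stages.

#' Stable age structure across the five compartments
#'
#' Default proportions are the stable stage distribution at 24 degrees C used
#' to infer immatures from trapped adults: 0.436 eggs, 0.403 larvae, 0.137
#' pupae, 0.012 immature adults, 0.012 mature adults.
#'
#' @param e,l,p,a_imm,a_mat Non-negative proportions; must sum to 1 within
#'   1e-9 (renormalize upstream if supplying alternatives).
#' @return Named numeric vector of class `age_structure`.
#' @export
age_structure <- function(e = 0.436, l = 0.403, p = 0.137,
                          a_imm = 0.012, a_mat = 0.012) {
  x <- c(egg = e, larva = l, pupa = p, adult_immature = a_imm, adult_mature = a_mat)
  if (any(x < 0)) stop("age structure proportions must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) stop("age structure proportions must sum to 1 (got ",
                                   sum(x), ")")
  class(x) <- c("age_structure", class(x))
  x
}

#' Outbreak detection facts
#'
#' @param flies_found Adult flies caught in the first three days after
#'   detection (>= 1).
#' @param trap_sensitivity Proportion of the adult population the trapping
#'   grid captures per adult life span (standard urban grids: 0.02-0.03).
#' @param sex_ratio_female Proportion of trapped adults assumed female (even
#'   sex ratio by default).
#' @param t_S Days from first find to the start of countermeasures.
#' @return List of class `outbreak_facts`.
#' @export
outbreak_facts <- function(flies_found, trap_sensitivity,
                           sex_ratio_female = 0.5, t_S = 0) {
  if (flies_found < 1) stop("flies_found must be >= 1")
  if (!(trap_sensitivity > 0 && trap_sensitivity <= 1))
    stop("trap_sensitivity must lie in (0, 1]")
  out <- list(flies_found = flies_found, trap_sensitivity = trap_sensitivity,
              sex_ratio_female = sex_ratio_female, t_S = t_S)
  class(out) <- "outbreak_facts"
  out
}

#' Estimate the initial population from trap captures
#'
#' Adult females `N_0 = (flies_found / trap_sensitivity) * sex_ratio_female`;
#' the total across all stages is `round(N_0 / p_mature)` and per-stage counts
#' follow the age-structure proportions, with the rounding residual assigned
#' to the largest compartment so counts sum exactly to the total.
#'
#' @param facts An [outbreak_facts()] object.
#' @param structure An [age_structure()] (its mature-adult share must be
#'   positive).
#' @param scale Optional multiplier on the total (down-scaling for desk-size
#'   experiments); applied before rounding.
#' @return List with `N0_females`, `total`, and integer `counts` by stage.
#' @export
#' @examples
#' estimate_population_size(outbreak_facts(3, 0.02))$total  # 6250
estimate_population_size <- function(facts, structure = age_structure(),
                                     scale = 1) {
  p_mat <- structure[["adult_mature"]]
  if (!(p_mat > 0)) stop("mature-adult share of the age structure must be > 0")
  N0 <- facts$flies_found / facts$trap_sensitivity * facts$sex_ratio_female
  total <- round(N0 / p_mat * scale)
  counts <- round(total * as.numeric(structure))
  resid <- total - sum(counts)
  big <- which.max(structure)
  counts[big] <- counts[big] + resid
  counts <- as.integer(counts)
  names(counts) <- STAGES
  list(N0_females = N0 * scale, total = as.integer(total), counts = counts)
}

#' Instantiate an initial agent population
#'
#' Creates agents stage by stage. Each non-mature agent draws its individual
#' development threshold and starts at a uniformly distributed fraction of it
#' (uniform progress through the stage avoids synchronized-molting artifacts);
#' mature adults start fertile.
#'
#' @param counts Integer vector of agents per stage, in stage order (named or
#'   not); e.g. the `counts` element of [estimate_population_size()].
#' @param stage_params A [stage_params()] object (thresholds use its `K` and
#'   `gamma`).
#' @param engine An [engine_config()]; the total must not exceed its cap and
#'   hourly-probability mode needs no thresholds.
#' @return A [population_state()] at hour 0.
#' @export
instantiate_population <- function(counts, stage_params = medflysim::stage_params(),
                                   engine = engine_config()) {
  counts <- as.integer(counts)
  if (length(counts) != 5L) stop("counts must have one entry per stage (5)")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total > engine$N_m) stop("initial population (", total,
                               ") exceeds the agent cap N_m = ", engine$N_m)
  stage <- rep.int(1:5, counts)
  n <- length(stage)
  thr <- rep(Inf, n)
  acc <- numeric(n)
  thermal <- identical(engine$D_m, "thermal_unit")
  for (s in 1:4) {
    idx <- which(stage == s)
    if (!length(idx)) next
    if (thermal) {
      thr[idx] <- draw_threshold(stage_params$K[[.stage_par_idx[s]]],
                                 stage_params$gamma, length(idx))
      acc[idx] <- stats::runif(length(idx)) * thr[idx]
    } else {
      thr[idx] <- 0
    }
  }
  population_state(stage = stage, acc = acc, thr = thr,
                   fertile = rep(TRUE, n), birth_hour = rep(0L, n))
}
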
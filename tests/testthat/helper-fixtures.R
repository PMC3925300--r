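# shared builders for small deterministic test populations and parameter sets

# stage parameters with fixed (temperature-independent) mortality and no
# individual variation, for hand-checkable development arithmetic
fixed_params <- function(T_min = c(12, 12, 12, 12), K = c(30, 100, 150, 60),
                         M = c(0, 0, 0, 0), gamma = 0, T_max = 35) {
  stage_params(T_min = T_min, K = K, T_max = T_max, M_star = M,
               gamma = gamma, mortality = "fixed")
}

no_repro <- function() reproduction_params(r = 0, r_var = 0)

# population of n agents all in one stage, thresholds already drawn
mono_population <- function(n, stage, thr = Inf, fertile = stage == 5L) {
  population_state(stage = rep(as.integer(stage), n), acc = rep(0, n),
                   thr = rep(thr, n), fertile = rep(fertile, n),
                   birth_hour = rep(0L, n))
}

const_temps <- function(days, T) rep(T, 24 * days)

# independent single-agent development oracle: hour at which an egg reaches
# the mature adult stage under constant temperature, thermal-unit mode with
# degree-hour carry-over
oracle_maturation_hour <- function(T, T_min, K, T_max = 35) {
  inc <- pmax(0, T - T_min)
  if (T > T_max) inc[] <- 0
  acc <- 0; stage <- 1L; thr <- 24 * K[1]; h <- 0L
  while (stage < 5L) {
    h <- h + 1L
    acc <- acc + inc[min(stage, 4L)]
    while (stage < 5L && acc >= thr) {
      acc <- acc - thr
      stage <- stage + 1L
      thr <- if (stage < 5L) 24 * K[min(stage, 4L)] else Inf
    }
    if (h > 1e6) stop("oracle did not terminate")
  }
  h
}
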
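# Batch orchestration: Latin hypercube draws over the literature parameter
# ranges, multi-run execution, extirpation-time statistics, PRCC sensitivity
# analysis, and the regulatory degree-day quarantine-length comparator.

#' Latin hypercube sample over named parameter ranges
#'
#' For each parameter independently, `[min, max]` is partitioned into `n`
#' equal strata with one uniform draw per stratum, permuted independently
#' across runs (so each column is a stratified sample and columns are
#' mutually independent). Degenerate ranges (`min == max`) yield a constant
#' column.
#'
#' @param ranges Named list of `c(min, max)` intervals, e.g.
#'   [default_param_ranges()].
#' @param n Number of runs (rows), >= 1.
#' @return Numeric `n x length(ranges)` design matrix with the range names as
#'   column names.
#' @export
#' @examples
#' set.seed(1)
#' d <- lhs_sample(list(a = c(0, 1), b = c(5, 5)), 4)
lhs_sample <- function(ranges, n) {
  stopifnot(n >= 1, length(ranges) >= 1)
  for (nm in names(ranges))
    if (ranges[[nm]][1] > ranges[[nm]][2])
      stop("range for ", nm, " has min > max")
  u <- lhs::randomLHS(as.integer(n), length(ranges))
  lo <- vapply(ranges, `[`, 0, 1)
  hi <- vapply(ranges, `[`, 0, 2)
  out <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(out) <- names(ranges)
  out
}

# merge one design-matrix row into the scenario's base parameter containers
.apply_design_row <- function(scenario, row) {
  sp <- scenario$stage_params
  repro <- scenario$repro
  interv <- scenario$interv
  facts <- scenario$facts
  for (nm in names(row)) {
    val <- unname(row[[nm]])
    if (grepl("^M_star_[elpa]$", nm)) sp$M_star[[sub("M_star_", "", nm)]] <- val
    else if (grepl("^T_min_[elpa]$", nm)) sp$T_min[[sub("T_min_", "", nm)]] <- val
    else if (grepl("^K_[elpa]$", nm)) sp$K[[sub("K_", "", nm)]] <- val
    else if (nm == "gamma") sp$gamma <- val
    else if (nm == "T_max") sp$T_max <- val
    else if (nm == "r") repro$r <- val
    else if (nm == "r_var") repro$r_var <- val
    else if (nm == "female_fraction") repro$female_fraction <- val
    else if (nm == "r_red") interv$r_red <- val
    else if (nm == "S") interv$S <- val
    else if (nm == "t_S") interv$t_S <- val
    else if (nm == "trap_sensitivity") facts$trap_sensitivity <- val
    else stop("design column '", nm, "' does not map to a parameter")
  }
  list(stage_params = sp, repro = repro, interv = interv, facts = facts)
}

#' Execute a batch of simulations over a design matrix
#'
#' Runs one simulation per design row with seed `base_seed + row index`, so
#' runs are reproducible and independent. Per-row failures are recorded, not
#' fatal.
#'
#' @param scenario A [scenario_config()].
#' @param temps A gap-free [temperature_series()].
#' @param design Design matrix from [lhs_sample()] (columns named after
#'   parameter config keys; a `trap_sensitivity` column drives the initial
#'   population size).
#' @param base_seed Integer base seed.
#' @return An object of class `batch_result`: a `data.frame` with the sampled
#'   parameters plus `seed`, `t_e`, `terminated_by`, and `N_init`.
#' @export
run_batch <- function(scenario, temps, design, base_seed = 1L) {
  n <- nrow(design)
  t_e <- rep(NA_real_, n)
  term <- rep(NA_character_, n)
  n_init <- rep(NA_integer_, n)
  seeds <- base_seed + seq_len(n)
  for (i in seq_len(n)) {
    row <- as.list(design[i, , drop = TRUE])
    ok <- tryCatch({
      pars <- .apply_design_row(scenario, row)
      set.seed(seeds[i])
      est <- estimate_population_size(pars$facts, scenario$age_structure,
                                      scale = scenario$population_scale)
      pop <- instantiate_population(est$counts, pars$stage_params, scenario$engine)
      res <- run_simulation(pop, temps, pars$stage_params, pars$repro,
                            pars$interv, scenario$engine)
      t_e[i] <- res$t_e
      term[i] <- res$terminated_by
      n_init[i] <- est$total
      TRUE
    }, error = function(e) {
      term[i] <<- paste0("ERROR: ", conditionMessage(e))
      FALSE
    })
    if (!ok) next
  }
  out <- data.frame(design, seed = seeds, N_init = n_init, t_e = t_e,
                    terminated_by = term, check.names = FALSE)
  class(out) <- c("batch_result", "data.frame")
  out
}

#' Extirpation-time statistics for a batch
#'
#' `t_m` is the mean extirpation time over extirpated runs. `t_q` is the
#' smallest time by which at least a fraction `q` of *all* runs have shown
#' extirpation; non-extirpated runs count as not yet extirpated (censored
#' above), so `t_q` is `NA` if fewer than `q` of the runs extirpated at all.
#'
#' @param batch A [run_batch()] result (or any data.frame with `t_e` and
#'   `terminated_by` columns).
#' @param q Quantile, default 0.95.
#' @return List with `t_m`, `t_q`, `q`, `n_runs`, `n_extirpated`.
#' @export
#' @examples
#' b <- data.frame(t_e = c(100, 200), terminated_by = "EXTIRPATED")
#' extirpation_stats(b)   # t_m 150, t_q 200
extirpation_stats <- function(batch, q = 0.95) {
  ext <- !is.na(batch$t_e) & batch$terminated_by == "EXTIRPATED"
  if (!any(ext)) stop("no extirpated runs in the batch")
  te <- batch$t_e[ext]
  n_all <- nrow(batch)
  t_m <- mean(te)
  ts <- sort(te)
  frac <- seq_along(ts) / n_all
  idx <- which(frac >= q)
  t_q <- if (length(idx)) ts[idx[1]] else NA_real_
  list(t_m = t_m, t_q = t_q, q = q, n_runs = n_all, n_extirpated = sum(ext))
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every design column and the response, then correlates the
#' residuals of each ranked parameter and the ranked response after linearly
#' removing all other ranked parameters. The test statistic is
#' `t = PRCC * sqrt((N - 2 - k) / (1 - PRCC^2))` with `k` controlled
#' parameters, with a two-sided p-value from the t distribution. p-values are
#' reported raw (no multiple-testing correction).
#'
#' @param design Numeric matrix or data.frame of inputs (runs x parameters).
#' @param response Numeric response vector (e.g. `t_e`); rows with `NA`
#'   response must be dropped beforehand (see `extirpated_only` in
#'   [analyze_outbreak()]).
#' @return `data.frame` of class `prcc_result` with columns `parameter`,
#'   `coefficient`, `statistic`, `p`, ordered by `|coefficient|` decreasing.
#'   Constant columns get `NA` coefficients and are flagged in the `note`
#'   column.
#' @export
prcc <- function(design, response) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  if (anyNA(y)) stop("response contains NA; drop those runs first")
  n <- nrow(X)
  k_tot <- ncol(X)
  if (n <= k_tot + 2) stop("need more runs than parameters + 2")
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  coef <- stat <- p <- rep(NA_real_, k_tot)
  k <- k_tot - 1L  # controlled parameters per test
  for (j in seq_len(k_tot)) {
    if (const[j]) next
    Z <- cbind(1, R[, setdiff(which(!const), j), drop = FALSE])
    rx_res <- stats::lm.fit(Z, R[, j])$residuals
    ry_res <- stats::lm.fit(Z, ry)$residuals
    cj <- suppressWarnings(stats::cor(rx_res, ry_res))
    if (is.na(cj)) next
    coef[j] <- cj
    df <- n - 2 - k
    stat[j] <- cj * sqrt(df / (1 - cj^2))
    p[j] <- 2 * stats::pt(-abs(stat[j]), df)
  }
  out <- data.frame(parameter = colnames(X), coefficient = coef,
                    statistic = stat, p = p,
                    note = ifelse(const, "constant column", ""),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient), na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("prcc_result", "data.frame")
  out
}

#' PRCC significance test statistic
#'
#' @param coefficient Partial rank correlation coefficient.
#' @param N Number of runs.
#' @param k Number of controlled parameters.
#' @return The t-type test statistic with `N - 2 - k` degrees of freedom.
#' @export
#' @examples
#' prcc_statistic(-0.60, 10000, 15)
prcc_statistic <- function(coefficient, N, k) {
  coefficient * sqrt((N - 2 - k) / (1 - coefficient^2))
}

#' Three-generation degree-day quarantine length
#'
#' Walks the hourly series accumulating `max(0, T - T_min) / 24` day-degrees
#' per hour and returns the day (1-based, `ceiling(hour/24)`) on which the
#' cumulative accumulation first reaches `generations * K_generation`
#' day-degrees. This is the regulatory comparator: the time needed for the
#' stated number of complete insect generations under local temperatures.
#'
#' @param temps A [temperature_series()] (or plain numeric hourly vector).
#' @param T_min Base temperature in degrees C for the accumulation.
#' @param K_generation Day-degrees per complete generation (> 0). Defaults to
#'   the egg-to-ovipositing-adult total of the stage thermal constants.
#' @param generations Number of generations (>= 1), 3 for the standard rule.
#' @return Day index (numeric), or `NA` with a `"not_reached"` attribute when
#'   the series ends before the target is met.
#' @export
#' @examples
#' ql <- degree_day_quarantine_length(rep(26, 24 * 80), 12, 340, 3)  # day 73
degree_day_quarantine_length <- function(temps, T_min,
                                         K_generation = sum(stage_params()$K),
                                         generations = 3) {
  if (!(K_generation > 0)) stop("K_generation must be > 0")
  if (generations < 1) stop("generations must be >= 1")
  tv <- if (inherits(temps, "temperature_series")) temps$temp else as.numeric(temps)
  dd <- cumsum(pmax(0, tv - T_min) / 24)
  target <- generations * K_generation
  hit <- which(dd >= target)
  if (!length(hit)) return(structure(NA_real_, not_reached = TRUE))
  ceiling(hit[1] / 24)
}
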
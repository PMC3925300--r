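test_that("development freezes below the base temperature", {
  pop <- population_state(stage = 1L, acc = 0, thr = 720, fertile = TRUE,
                          birth_hour = 0L)
  out <- step_hour(pop, 10, fixed_params(), no_repro())
  expect_identical(out$hour, 1L)
  expect_identical(out$stage, pop$stage)
  expect_identical(out$acc, pop$acc)
  expect_identical(out$thr, pop$thr)
})

test_that("a fertile mature female lays a deterministic clutch at the daily hour", {
  pop <- mono_population(1, 5L)
  out <- step_hour(pop, 20, fixed_params(),
                   reproduction_params(r = 10, r_var = 0, female_fraction = 1))
  expect_identical(sum(out$stage == 1L), 10L)
  expect_identical(out$cum_eggs, 10)
  expect_identical(out$cum_births, 10)
  # not the reproduction hour: nothing laid
  out2 <- step_hour(out, 20, fixed_params(),
                    reproduction_params(r = 10, r_var = 0, female_fraction = 1))
  expect_identical(out2$cum_eggs, 10)
})

test_that("certain daily mortality empties the population in one hour", {
  pop <- mono_population(50, 2L, thr = 1e6)
  out <- step_hour(pop, 20, fixed_params(M = c(1, 1, 1, 1)), no_repro())
  expect_length(out$stage, 0L)
  expect_identical(out$deaths_natural, 50)
})

test_that("agent counts are conserved: initial + births - deaths = final", {
  set.seed(31)
  pop <- instantiate_population(c(30L, 30L, 20L, 10L, 10L),
                                stage_params(gamma = 0.05))
  res <- run_simulation(pop, const_temps(40, 24), stage_params(),
                        reproduction_params(r = 6, r_var = 2),
                        intervention_params(t_S = 5, S = 0.02, r_red = 0.6))
  expect_identical(100 + res$cumulative_births - res$deaths_natural -
                     res$deaths_human, length(res$final_state$stage) + 0)
  expect_true(all(res$daily_counts >= 0))
})

test_that("with mortality and reproduction off, the live count is constant", {
  pop <- instantiate_population(c(20L, 20L, 20L, 20L, 20L), fixed_params())
  res <- run_simulation(pop, const_temps(30, 24), fixed_params(), no_repro())
  expect_identical(res$terminated_by, "TEMPS_EXHAUSTED")
  expect_true(is.na(res$t_e))
  expect_true(all(rowSums(res$daily_counts) == 100))
})

test_that("constant-temperature maturation matches the step-by-step oracle", {
  cases <- list(list(T = 26, K = c(30, 100, 150, 60)),
                list(T = 24, K = c(33.4, 186.8, 124, 80.5)),
                list(T = 19.5, K = c(27.27, 94.5, 123.96, 58.2)))
  for (cs in cases) {
    expected <- oracle_maturation_hour(cs$T, c(12, 12, 12, 12), cs$K)
    sp <- fixed_params(K = cs$K)
    pop <- population_state(stage = 1L, acc = 0, thr = 24 * cs$K[1],
                            fertile = TRUE, birth_hour = 0L)
    res <- run_simulation(pop, rep(cs$T, expected + 24), sp, no_repro())
    st <- res$final_state
    expect_identical(st$stage, 5L)
    # re-run stopping one hour short of the oracle: not yet mature
    res2 <- run_simulation(population_state(stage = 1L, acc = 0,
                                            thr = 24 * cs$K[1], fertile = TRUE,
                                            birth_hour = 0L),
                           rep(cs$T, expected - 1), sp, no_repro())
    expect_lt(res2$final_state$stage, 5L)
  }
})

test_that("fixed adult mortality decays the cohort binomially", {
  set.seed(11)
  survivors <- replicate(60, {
    pop <- mono_population(100, 5L, fertile = FALSE)
    res <- run_simulation(pop, const_temps(5, 24),
                          fixed_params(M = c(0, 0, 0, 0.15)), no_repro())
    length(res$final_state$stage)
  })
  expected <- 100 * 0.85^5                      # 44.37
  se <- sqrt(100 * 0.85^5 * (1 - 0.85^5)) / sqrt(60)
  expect_lt(abs(mean(survivors) - expected), 3 * se)
})

test_that("hourly-probability mode matches thermal-unit mode in expectation", {
  # egg survival curve under geometric transition: P(still egg after h hours)
  set.seed(12)
  n <- 400
  pop <- mono_population(n, 1L, thr = 0)
  eng <- engine_config(D_m = "hourly_probability")
  res <- run_simulation(pop, const_temps(4, 26), fixed_params(K = c(30, 1e6, 1e6, 1e6)),
                        no_repro(), engine = eng)
  p <- 14 / 720
  for (d in 1:4) {
    expected <- n * (1 - p)^(24 * d)
    se <- sqrt(n * (1 - p)^(24 * d) * (1 - (1 - p)^(24 * d)))
    expect_lt(abs(res$daily_counts[d, "egg"] - expected), 4 * se + 1)
  }
})

test_that("countermeasures gate on t_S and sterilize offspring and dams", {
  sp <- fixed_params(K = c(30, 100, 150, 60))
  rp <- reproduction_params(r = 4, r_var = 0, female_fraction = 1)
  # r_red = 1: the dam loses fertility at the first post-t_S reproduction hour
  ip <- intervention_params(t_S = 0, S = 0, r_red = 1)
  set.seed(13)
  pop <- mono_population(1, 5L)
  res <- run_simulation(pop, const_temps(5, 20), sp, rp, ip)
  expect_identical(res$cumulative_eggs, 4)        # one clutch, then sterile
  st <- res$final_state
  expect_false(any(st$fertile))                   # offspring sterile by policy
  # inherit policy keeps offspring fertile
  ip2 <- intervention_params(t_S = 0, S = 0, r_red = 1,
                             offspring_policy = "inherit")
  set.seed(13)
  res2 <- run_simulation(mono_population(1, 5L), const_temps(5, 20), sp, rp, ip2)
  expect_true(any(res2$final_state$fertile))
  # pre-t_S reproduction is unaffected: t_S = 3 allows three clutches
  ip3 <- intervention_params(t_S = 3, S = 0, r_red = 1)
  set.seed(13)
  res3 <- run_simulation(mono_population(1, 5L), const_temps(5, 20), sp, rp, ip3)
  expect_gte(res3$cumulative_eggs, 3 * 4)
})

test_that("the agent cap truncates new eggs and flags the run", {
  pop <- mono_population(1, 5L)
  eng <- engine_config(N_m = 5)
  res <- run_simulation(pop, const_temps(1, 20), fixed_params(),
                        reproduction_params(r = 10, r_var = 0, female_fraction = 1),
                        engine = eng)
  expect_true(res$cap_exceeded)
  expect_identical(res$terminated_by, "CAP_EXCEEDED")
  expect_lte(max(rowSums(res$daily_counts)), 5)
})

test_that("extirpation time is the first day with nobody alive", {
  # certain death in the first hour: t_e = 1 day
  pop <- mono_population(10, 3L, thr = 1e6)
  res <- run_simulation(pop, const_temps(10, 20), fixed_params(M = c(1, 1, 1, 1)),
                        no_repro())
  expect_identical(res$terminated_by, "EXTIRPATED")
  expect_identical(res$t_e, 1)
  expect_identical(nrow(res$daily_counts), 1L)    # output stops at extirpation
  # empty initial population: immediate extirpation at day 0
  res0 <- run_simulation(population_state(), const_temps(2, 20), fixed_params(),
                         no_repro())
  expect_identical(res0$terminated_by, "EXTIRPATED")
  expect_identical(res0$t_e, 0)
})

test_that("stronger mortality does not lengthen median extirpation time", {
  sp_lo <- stage_params(gamma = 0.05)
  sp_hi <- sp_lo; sp_hi$M_star <- sp_lo$M_star + 0.05
  temps <- const_temps(150, 22)
  run_te <- function(sp, ip, seed) {
    set.seed(seed)
    pop <- instantiate_population(c(8L, 8L, 4L, 2L, 3L), sp)
    run_simulation(pop, temps, sp, reproduction_params(r = 10),
                   ip)$t_e
  }
  ip <- intervention_params(t_S = 2, S = 0.02, r_red = 0.8)
  te_lo <- vapply(1:200, function(i) run_te(sp_lo, ip, 1000 + i), 0)
  te_hi <- vapply(1:200, function(i) run_te(sp_hi, ip, 1000 + i), 0)
  expect_lte(median(te_hi, na.rm = TRUE), median(te_lo, na.rm = TRUE))

  ip_s <- intervention_params(t_S = 2, S = 0.05, r_red = 0.8)
  ip_w <- intervention_params(t_S = 2, S = 0.005, r_red = 0.8)
  te_s <- vapply(1:200, function(i) run_te(sp_lo, ip_s, 3000 + i), 0)
  te_w <- vapply(1:200, function(i) run_te(sp_lo, ip_w, 3000 + i), 0)
  expect_lte(median(te_s, na.rm = TRUE), median(te_w, na.rm = TRUE))
})

test_that("summary files are complete and reproducible", {
  sp <- fixed_params(); rp <- no_repro(); ip <- intervention_params()
  eng <- engine_config(rng_seed = 5L)
  pop <- mono_population(5, 5L, fertile = FALSE)
  res <- run_simulation(pop, const_temps(3, 20), sp, rp, ip, eng)
  path <- withr::local_tempfile(fileext = ".txt")
  write_summary(res, path, sp, rp, ip, eng)
  lines <- readLines(path)
  keys <- sub(":.*", "", lines)
  expect_true(all(c("T_min_e", "K_p", "M_star_a", "T_max", "gamma", "D_m", "N_m",
                    "r", "r_var", "r_red", "S", "t_S", "total_hours",
                    "cumulative_eggs", "cumulative_adult_deaths", "rng_seed")
                  %in% keys))
  # t_e appears iff the run extirpated
  expect_identical("t_e_days" %in% keys, res$terminated_by == "EXTIRPATED")
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_summary(res, path2, sp, rp, ip, eng)
  drop_ts <- function(f) grep("execution_timestamp", readLines(f),
                              value = TRUE, invert = TRUE)
  expect_identical(drop_ts(path), drop_ts(path2))
})

test_that("daily detail rows conserve the stage totals", {
  set.seed(21)
  pop <- instantiate_population(c(10L, 10L, 10L, 5L, 5L), stage_params())
  res <- run_simulation(pop, const_temps(10, 22), stage_params(), no_repro())
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_detail(res, path)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), nrow(res$daily_counts))
  expect_identical(ncol(df), 9L)   # day, 3 temps, 5 stages
  expect_equal(rowSums(df[, 5:9]), unname(rowSums(res$daily_counts)))
})
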
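# Deterministic Leslie matrix projection used as the validation oracle for
# the agent-based simulator under constant conditions: daily age classes,
# fecundities on the first row, survival probabilities on the subdiagonal.

#' Construct a Leslie matrix model
#'
#' @param survival Daily survival probability per age class (length m, in
#'   `[0, 1]`); entry i is the probability of advancing from class i to i+1.
#'   The last class has no successor, so its entry only matters through
#'   reproduction.
#' @param fecundity Daily female eggs per individual per age class (length m,
#'   >= 0).
#' @param n0 Initial abundance per age class (length m).
#' @param stage_map Integer vector (length m) mapping each age class to a
#'   stage code 1-5, used to aggregate projections into stage proportions.
#' @return Object of class `leslie_model` with the projection matrix in `$L`.
#' @export
leslie_model <- function(survival, fecundity, n0, stage_map) {
  m <- length(survival)
  if (length(fecundity) != m || length(n0) != m || length(stage_map) != m)
    stop("survival, fecundity, n0 and stage_map must have equal length")
  if (any(survival < 0 | survival > 1)) stop("survivals must lie in [0, 1]")
  if (any(fecundity < 0)) stop("fecundities must be >= 0")
  L <- matrix(0, m, m)
  L[1, ] <- fecundity
  if (m > 1) L[cbind(2:m, 1:(m - 1))] <- survival[1:(m - 1)]
  out <- list(L = L, survival = survival, fecundity = fecundity,
              n0 = as.numeric(n0), stage_map = as.integer(stage_map))
  class(out) <- "leslie_model"
  out
}

#' Project a Leslie model forward
#'
#' Iterated matrix-vector product `n(t+1) = L n(t)`, daily steps.
#'
#' @param model A [leslie_model()].
#' @param days Number of days to project (>= 0).
#' @return List with `abundance` (`(days+1) x m` matrix, row 1 the initial
#'   vector), `totals`, and `stage_props` (`(days+1) x 5`, proportions per
#'   stage; `NA` rows where the total is zero).
#' @export
leslie_project <- function(model, days) {
  if (days < 0) stop("days must be >= 0")
  m <- length(model$n0)
  ab <- matrix(0, days + 1, m)
  ab[1, ] <- model$n0
  for (t in seq_len(days)) ab[t + 1, ] <- as.numeric(model$L %*% ab[t, ])
  totals <- rowSums(ab)
  props <- matrix(NA_real_, days + 1, 5,
                  dimnames = list(NULL, STAGES))
  for (s in 1:5) {
    cols <- which(model$stage_map == s)
    props[, s] <- if (length(cols)) rowSums(ab[, cols, drop = FALSE]) else 0
  }
  ok <- totals > 0
  props[ok, ] <- props[ok, , drop = FALSE] / totals[ok]
  props[!ok, ] <- NA_real_
  list(abundance = ab, totals = totals, stage_props = props)
}

#' Maximum stage-proportion discrepancy between ABS and Leslie projections
#'
#' @param abs_props Matrix of mean ABS stage proportions (days x 5), e.g.
#'   pooled across replicates.
#' @param leslie_props Matrix of Leslie stage proportions with the same rows.
#' @param days Optional row subset (e.g. `1:10`) over which to take the
#'   maximum.
#' @return Maximum over days and stages of the absolute proportion difference.
#' @export
compare_abs_leslie <- function(abs_props, leslie_props, days = NULL) {
  if (!all(dim(abs_props) == dim(leslie_props)))
    stop("proportion matrices must have equal dimensions")
  d <- abs(abs_props - leslie_props)
  if (!is.null(days)) d <- d[days, , drop = FALSE]
  max(d, na.rm = TRUE)
}
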
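#' Clock models
#'
#' Branch-rate model for the cognate death process: either a strict clock
#' (all branches share one rate) or an uncorrelated lognormal relaxed clock,
#' where each branch's rate multiplier is drawn i.i.d. from a lognormal with
#' mean 1 (log-mean \eqn{-\sigma^2/2}).
#'
#' @param kind `"strict"` or `"relaxed-lognormal"`.
#' @param mean_rate overall rate scale (per year); for the Dollo process this
#'   is absorbed into the death rate, so the default 1 leaves `mu` on the
#'   per-year scale.
#' @param sigma log-scale standard deviation of the relaxed clock (>= 0).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "relaxed-lognormal"),
                        mean_rate = 1, sigma = 0) {
  kind <- match.arg(kind)
  stopifnot(mean_rate > 0, sigma >= 0)
  structure(list(kind = kind, mean_rate = mean_rate, sigma = sigma),
            class = "clock_model")
}

#' Draw per-branch clock-rate multipliers
#'
#' @param clock a [clock_model()].
#' @param tt a [time_tree()] (only its branch count is used).
#' @param seed RNG seed (draws are reproducible and do not disturb the
#'   global RNG stream).
#' @return numeric vector of multipliers, one per node (branch above each
#'   node; the root entry is 1 and unused). Strict clocks give all 1;
#'   relaxed clocks give mean-1 lognormal draws.
#' @export
branch_rates <- function(clock, tt, seed = 1) {
  nn <- length(tt$parent)
  if (clock$kind == "strict" || clock$sigma == 0) return(rep(1, nn))
  r <- withr_seed(seed, stats::rlnorm(nn, meanlog = -clock$sigma^2 / 2,
                                      sdlog = clock$sigma))
  r[tt_root(tt)] <- 1
  r
}

#' Dollo parameters
#'
#' @param lam cognate birth intensity (births per lineage-year; profiled out
#'   of the ascertainment-corrected likelihood, kept for simulation).
#' @param mu per-lineage cognate death rate (per year).
#' @export
dollo_params <- function(lam = 1, mu) {
  stopifnot(lam > 0, mu > 0)
  structure(list(lam = lam, mu = mu), class = "dollo_params")
}

#' Probability that a living cognate survives a branch
#'
#' The death process is a one-way (alive to dead, absorbing) exponential
#' kill at rate `mu`, so survival over duration `t` is \eqn{e^{-\mu t}}.
#'
#' @param mu death rate (per year), >= 0.
#' @param t duration (years), >= 0.
#' @return survival probability.
#' @export
survival_probability <- function(mu, t) {
  if (any(mu < 0) || any(t < 0)) stop("mu and t must be nonnegative")
  exp(-mu * t)
}

# ---- core pruning machinery -------------------------------------------------
#
# A cognate is born exactly once, at a uniformly-distributed point on the
# tree (branch measure in raw years) or on a stem of length
# root_height * stem_factor above the root. Below the birth point it
# survives each branch with probability exp(-mu * c_b * T_b) where c_b is
# the branch's clock multiplier; death is absorbing and inherited. Tips
# descend state alive -> '1', dead -> '0'; '?' is compatible with both.
#
# For birth on the branch above node c (duration T, effective death rate
# m = mu * c_b), integrating the birth position u (distance above c) gives
#   I_b = outside_b * [ D_c * T + (A_c - D_c) * (1 - exp(-m T)) / m ]
# where A_c / D_c are the alive/dead partial likelihoods at c and
# outside_b indicates that every tip outside c's clade is 0/?.
# Patterns are handled as columns of a matrix, all vectorized.

# partial likelihood matrices for a 0/1/NA data matrix (taxa x K),
# rows aligned with tt$labels
dollo_partials <- function(tt, mu, states) {
  n <- tt$n_tips
  nn <- 2L * n - 1L
  K <- ncol(states)
  dur <- tt_durations(tt)
  m_eff <- mu * tt$clock_rate
  psurv <- exp(-m_eff * dur)  # NA at root
  La <- matrix(0, nn, K)
  Ld <- matrix(0, nn, K)
  # tips: P(obs | alive), P(obs | dead)
  x <- states
  La[1:n, ] <- ifelse(is.na(x), 1, ifelse(x == 1L, 1, 0))
  Ld[1:n, ] <- ifelse(is.na(x), 1, ifelse(x == 0L, 1, 0))
  kids <- tt_children(tt)
  for (v in tt_postorder(tt)) {
    c1 <- kids[[v]][1]; c2 <- kids[[v]][2]
    f1 <- psurv[c1] * La[c1, ] + (1 - psurv[c1]) * Ld[c1, ]
    f2 <- psurv[c2] * La[c2, ] + (1 - psurv[c2]) * Ld[c2, ]
    La[v, ] <- f1 * f2
    Ld[v, ] <- Ld[c1, ] * Ld[c2, ]
  }
  list(La = La, Ld = Ld, dur = dur, m_eff = m_eff)
}

# integrated birth-placement weight I(pattern) for each column, plus the
# total birth measure; stem_factor scales the stem length relative to the
# root height.
dollo_integral <- function(tt, mu, states, stem_factor = 1) {
  n <- tt$n_tips
  nn <- 2L * n - 1L
  root <- tt_root(tt)
  K <- ncol(states)
  states <- cbind(states, rep(0L, n))  # all-absent column rides along
  pp <- dollo_partials(tt, mu, states)
  # outside indicator: all tips outside clade(c) are 0/NA
  absent_ok <- ifelse(is.na(states), 1, 1 - states)  # n x (K+1)
  cm <- tt_clade_matrix(tt)
  # outside_b,k = 1 iff no presence among tips outside the clade
  not_ok <- 1 - absent_ok
  outside <- ((!cm) %*% not_ok) == 0  # nn x (K+1) logical
  dur <- pp$dur; m <- pp$m_eff
  I <- numeric(K + 1L)
  for (v in seq_len(nn)) {
    if (v == root) next
    w <- if (m[v] > 0) (1 - exp(-m[v] * dur[v])) / m[v] else dur[v]
    I <- I + outside[v, ] * (pp$Ld[v, ] * (dur[v] - w) + pp$La[v, ] * w)
  }
  stem <- tt$height[root] * stem_factor
  if (stem > 0) {
    w <- if (mu > 0) (1 - exp(-mu * stem)) / mu else stem
    I <- I + pp$Ld[root, ] * (stem - w) + pp$La[root, ] * w
  }
  total <- sum(dur[-root]) + stem
  list(I = I[seq_len(K)], I0 = I[K + 1L], total = total)
}

#' Log-probability of one tip pattern under the stochastic Dollo process
#'
#' Integrates the single birth point uniformly over the tree (plus a stem of
#' length `root height * stem_factor` above the root) with intensity `lam`;
#' below the birth the cognate dies at rate `mu` (scaled by the branch clock
#' multipliers), and tips outside the birth clade must be absent. Patterns
#' incompatible with single origin get `-Inf`, not an error.
#'
#' @param tt a [time_tree()]; its `clock_rate` entries are used (see
#'   [branch_rates()]).
#' @param params a [dollo_params()].
#' @param pattern 0/1/NA vector named by (or aligned with) tip labels.
#' @param stem_factor stem length as a fraction of root height (default 1).
#' @return log of the lam-weighted birth integral.
#' @export
dollo_pattern_loglik <- function(tt, params, pattern, stem_factor = 1) {
  if (!is.null(names(pattern))) pattern <- pattern[tt$labels]
  st <- matrix(as.integer(pattern), ncol = 1)
  di <- dollo_integral(tt, params$mu, st, stem_factor)
  log(params$lam) + log(di$I[1])
}

#' Ascertainment-corrected Dollo log-likelihood of a cognate matrix
#'
#' Sum over columns of the single-birth pattern log-probabilities,
#' conditioned on observability: each column's probability is normalized by
#' the total birth weight of patterns with at least one presence
#' (`1 - P(all-absent)`), the correction for the fact that cognate sets
#' absent from every sampled variety can never enter the data. The birth
#' intensity is profiled out (it contributes a constant given the number of
#' observed columns), so the result depends only on the tree, clock
#' multipliers and `mu`. Missing entries are marginalized over both states.
#'
#' @param tt a [time_tree()].
#' @param params a [dollo_params()] (only `mu` matters here).
#' @param m a [cognate_matrix()] whose taxa match the tree's tips.
#' @param stem_factor stem length as a fraction of root height.
#' @return log-likelihood (scalar).
#' @export
dollo_matrix_loglik <- function(tt, params, m, stem_factor = 1) {
  st <- m$states[tt$labels, , drop = FALSE]
  pres <- colSums(st == 1L, na.rm = TRUE)
  if (any(pres == 0)) {
    stop("column(s) ", paste(which(pres == 0), collapse = ", "),
         " unobservable (no presence)")
  }
  di <- dollo_integral(tt, params$mu, st, stem_factor)
  K <- ncol(st)
  sum(log(di$I)) - K * log(di$total - di$I0)
}
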
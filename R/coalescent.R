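#' Bayesian skyline parameters
#'
#' Piecewise-constant coalescent prior: the n-1 coalescent intervals
#' (ordered from the tips backwards) are partitioned into `m` contiguous
#' groups; each group shares one effective size (on the coalescent time
#' scale, years).
#'
#' @param group_sizes integer partition of n-1 (each >= 1).
#' @param pop_sizes positive effective sizes, one per group.
#' @export
skyline_params <- function(group_sizes, pop_sizes) {
  stopifnot(length(group_sizes) == length(pop_sizes),
            all(group_sizes >= 1), all(pop_sizes > 0))
  structure(list(group_sizes = as.integer(group_sizes),
                 pop_sizes = as.numeric(pop_sizes)),
            class = "skyline_params")
}

# per-coalescent-interval effective size, tipward first
skyline_interval_sizes <- function(sk) rep(sk$pop_sizes, sk$group_sizes)

#' Skyline coalescent log-prior of a time tree
#'
#' Standard piecewise-constant coalescent density: with `k` lineages through
#' an inter-event interval of length `t` under current size `N`, the
#' interval contributes \eqn{-t\,k(k-1)/(2N)}, and each coalescence
#' contributes \eqn{-\log N}. Sizes are constant within groups of
#' consecutive coalescent intervals. Tips may have nonzero heights
#' (heterochronous sampling changes `k` at sample times).
#'
#' @param tt a [time_tree()].
#' @param sk a [skyline_params()] whose group sizes sum to n-1.
#' @return log-density.
#' @export
skyline_log_prior <- function(tt, sk) {
  n <- tt$n_tips
  if (sum(sk$group_sizes) != n - 1) {
    stop("group sizes must sum to n-1 coalescent intervals")
  }
  Ns <- skyline_interval_sizes(sk)
  events <- rbind(
    data.frame(h = tt$height[1:n], type = 1L),            # sampling: +1 lineage
    data.frame(h = tt$height[(n + 1):(2 * n - 1)], type = -1L))  # coalescence
  events <- events[order(events$h, -events$type), ]
  k <- 0L
  ll <- 0
  coal_seen <- 0L
  h_prev <- 0
  for (i in seq_len(nrow(events))) {
    h <- events$h[i]
    N <- Ns[min(coal_seen + 1L, length(Ns))]
    dt <- h - h_prev
    if (dt > 0 && k >= 2) ll <- ll - dt * k * (k - 1) / (2 * N)
    if (events$type[i] == 1L) {
      k <- k + 1L
    } else {
      ll <- ll - log(N)
      k <- k - 1L
      coal_seen <- coal_seen + 1L
    }
    h_prev <- h
  }
  ll
}

#' Calibration priors on clade ages
#'
#' Normal prior on the height of the most recent common ancestor of a named
#' taxon set, evaluated on the current topology (monophyly of the set is not
#' enforced). The default spread, `sd = 102.04` years, places 95% of the
#' mass within +/-200 years of the mean.
#'
#' @param taxa character vector naming the calibrated tip set.
#' @param mean prior mean age (years BP).
#' @param sd prior standard deviation (years).
#' @export
calibration_prior <- function(taxa, mean, sd = 200 / stats::qnorm(0.975)) {
  stopifnot(length(taxa) >= 1, sd > 0)
  structure(list(taxa = taxa, mean = mean, sd = sd),
            class = "calibration_prior")
}

#' @rdname calibration_prior
#' @param tt a [time_tree()] containing the calibrated taxa.
#' @param cal a [calibration_prior()].
#' @return log-density of the MRCA height under the calibration normal.
#' @export
calibration_log_prior <- function(tt, cal) {
  node <- tt_mrca(tt, cal$taxa)
  stats::dnorm(tt$height[node], cal$mean, cal$sd, log = TRUE)
}

#' Simulate a coalescent time tree under a skyline size profile
#'
#' Standard backwards-in-time coalescent with piecewise-constant effective
#' size: while `k` lineages remain, the waiting time to the next coalescence
#' is exponential with rate \eqn{k(k-1)/(2N)} under the current size, and
#' the size profile switches at each coalescent event per the skyline
#' grouping. Pairs to merge are chosen uniformly. Optionally rescaled so the
#' root sits at `root_age_BP` exactly.
#'
#' @param n_tips number of tips (>= 2).
#' @param root_age_BP if not `NULL`, rescale all node heights so the root
#'   age equals this value.
#' @param skyline a [skyline_params()] with groups summing to n-1, or a
#'   single number (constant size).
#' @param labels optional tip labels.
#' @param seed RNG seed.
#' @return A [time_tree()] with tips at height 0.
#' @export
simulate_tree <- function(n_tips, root_age_BP = NULL, skyline = 1000,
                          labels = NULL, seed = 1) {
  stopifnot(n_tips >= 2)
  if (!inherits(skyline, "skyline_params")) {
    skyline <- skyline_params(n_tips - 1L, skyline)
  }
  Ns <- skyline_interval_sizes(skyline)
  labels <- labels %||% sprintf("t%02d", seq_len(n_tips))
  withr_seed(seed, {
    n <- n_tips
    nn <- 2L * n - 1L
    parent <- rep(NA_integer_, nn)
    height <- numeric(nn)
    active <- 1:n
    t_now <- 0
    nxt <- n + 1L
    coal <- 0L
    while (length(active) > 1) {
      k <- length(active)
      N <- Ns[coal + 1L]
      t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / (2 * N))
      pair <- sample(active, 2)
      parent[pair] <- nxt
      height[nxt] <- t_now
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1L
      coal <- coal + 1L
    }
    if (!is.null(root_age_BP)) height <- height * root_age_BP / max(height)
    time_tree(labels, parent, height)
  })
}
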
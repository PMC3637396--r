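#' MCMC configuration
#'
#' Chain controls, model flags and prior settings for [mcmc_run()]. Defaults
#' are deliberately diffuse package choices where the model leaves them
#' open; every one can be overridden.
#'
#' @param chain_length total iterations.
#' @param thin sampling interval.
#' @param burnin burn-in fraction in `[0, 1)` discarded by summaries.
#' @param seed RNG seed; two runs with the same data, config and seed give
#'   identical traces.
#' @param clock `"strict"` or `"relaxed-lognormal"`.
#' @param diffusion scalar law: `"cauchy"`, `"gamma"`, `"lognormal"` or
#'   `"homogeneous"`.
#' @param skyline_groups number of skyline size groups (capped at n-1).
#' @param calibration a [calibration_prior()] or `NULL`.
#' @param stem_factor Dollo stem length over root height.
#' @param beta power on the (Dollo x RRW) likelihood: 1 = posterior,
#'   0 = prior-only; intermediate values drive stepping-stone estimation.
#' @param use_dollo,use_rrw,use_coalescent,use_calibration switches for the
#'   corresponding log-density components.
#' @param fixed_tree if `TRUE`, topology and node heights stay at their
#'   initial values (requires `init_tree`).
#' @param fixed_pops optional numeric vector fixing the skyline sizes
#'   (no size moves, no size prior); useful for prior-sampling checks.
#' @param fixed_sigma optional 2x2 base diffusion covariance; fixes the
#'   precision matrix (no moves, no hyperprior), e.g. for controlled
#'   comparisons of the branch-scalar laws at a common base rate.
#' @param fixed_locations if `TRUE`, ancestral node locations stay at their
#'   initial values (no location moves); used when the diffusion history is
#'   fully observed, as in scalar-law comparisons on synthetic data.
#' @param init_tree optional starting [time_tree()].
#' @param priors named list overriding any of: `mu_meanlog`, `mu_sdlog`,
#'   `clock_sigma_rate`, `pop_min`, `pop_max`, `lv_sd`, `z_sd`,
#'   `shape_meanlog`, `shape_sdlog`.
#' @param adapt_frac fraction of the chain used as a proposal-scale
#'   adaptation window (always inside the burn-in; the chain is Markovian
#'   afterwards).
#' @param report_every iterations between structured log lines (0 = silent).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 20000, thin = 20, burnin = 0.1,
                        seed = 1,
                        clock = c("strict", "relaxed-lognormal"),
                        diffusion = c("gamma", "cauchy", "lognormal", "homogeneous"),
                        skyline_groups = 5, calibration = NULL,
                        stem_factor = 1, beta = 1,
                        use_dollo = TRUE, use_rrw = TRUE,
                        use_coalescent = TRUE, use_calibration = TRUE,
                        fixed_tree = FALSE, init_tree = NULL,
                        fixed_pops = NULL, fixed_sigma = NULL,
                        fixed_locations = FALSE,
                        priors = list(), adapt_frac = 0.1,
                        report_every = 0) {
  stopifnot(chain_length >= thin, burnin >= 0, burnin < 1,
            beta >= 0, beta <= 1)
  defaults <- list(mu_meanlog = log(2e-4), mu_sdlog = 2,
                   clock_sigma_rate = 1, pop_min = 10, pop_max = 1e6,
                   lv_sd = 5, z_sd = 1.5,
                   shape_meanlog = 0, shape_sdlog = 1)
  defaults[names(priors)] <- priors
  structure(list(chain_length = as.integer(chain_length),
                 thin = as.integer(thin), burnin = burnin, seed = seed,
                 clock = match.arg(clock), diffusion = match.arg(diffusion),
                 skyline_groups = as.integer(skyline_groups),
                 calibration = calibration, stem_factor = stem_factor,
                 beta = beta, use_dollo = use_dollo, use_rrw = use_rrw,
                 use_coalescent = use_coalescent,
                 use_calibration = use_calibration,
                 fixed_tree = fixed_tree, init_tree = init_tree,
                 fixed_pops = fixed_pops, fixed_sigma = fixed_sigma,
                 fixed_locations = fixed_locations,
                 priors = defaults, adapt_frac = adapt_frac,
                 report_every = report_every),
            class = "mcmc_config")
}

# ---- target density ---------------------------------------------------------

mcmc_state_sigma <- function(state) {
  v1 <- exp(state$lv[1]); v2 <- exp(state$lv[2])
  rho <- tanh(state$z)
  matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2, 2)
}

# bare-bones diffusion_model construction (validation skipped: the sampler
# parameterization guarantees positive-definiteness)
mcmc_diffusion <- function(state, config) {
  structure(list(kind = config$diffusion, sigma = mcmc_state_sigma(state),
                 shape = if (config$diffusion %in% c("gamma", "lognormal"))
                   state$shape else 1),
            class = "diffusion_model")
}

# component evaluators; `model` carries immutable data
mcmc_components <- function(state, model, which = NULL) {
  cfg <- model$config
  all_names <- c("dollo", "rrw_tip", "rrw_int", "coal", "cal", "prior")
  which <- which %||% all_names
  out <- numeric(0)
  if ("dollo" %in% which) {
    out["dollo"] <- if (cfg$use_dollo && !is.null(model$m)) {
      dollo_matrix_loglik(state$tt, dollo_params(1, state$mu), model$m,
                          cfg$stem_factor)
    } else 0
  }
  if (any(c("rrw_tip", "rrw_int") %in% which)) {
    if (cfg$use_rrw) {
      parts <- rrw_loglik_parts(state$tt, mcmc_diffusion(state, cfg))
      out["rrw_tip"] <- parts[["tip"]]
      out["rrw_int"] <- parts[["internal"]]
    } else {
      out["rrw_tip"] <- 0
      out["rrw_int"] <- 0
    }
  }
  if ("coal" %in% which) {
    out["coal"] <- if (cfg$use_coalescent) {
      skyline_log_prior(state$tt, skyline_params(model$group_sizes, state$pops))
    } else 0
  }
  if ("cal" %in% which) {
    out["cal"] <- if (cfg$use_calibration && !is.null(cfg$calibration)) {
      calibration_log_prior(state$tt, cfg$calibration)
    } else 0
  }
  if ("prior" %in% which) out["prior"] <- mcmc_log_prior_params(state, model)
  out
}

mcmc_log_prior_params <- function(state, model) {
  cfg <- model$config
  pr <- cfg$priors
  lp <- stats::dlnorm(state$mu, pr$mu_meanlog, pr$mu_sdlog, log = TRUE)
  if (cfg$clock == "relaxed-lognormal") {
    lp <- lp + stats::dexp(state$clock_sigma, pr$clock_sigma_rate, log = TRUE)
    br <- state$tt$clock_rate[-tt_root(state$tt)]
    s <- max(state$clock_sigma, 1e-8)
    lp <- lp + sum(stats::dlnorm(br, -s^2 / 2, s, log = TRUE))
  }
  if (cfg$use_coalescent && is.null(cfg$fixed_pops)) {
    if (any(state$pops < pr$pop_min | state$pops > pr$pop_max)) return(-Inf)
    lp <- lp - sum(log(state$pops))  # scale-invariant within bounds
  }
  if (cfg$use_rrw) {
    if (is.null(cfg$fixed_sigma)) {
      lp <- lp + sum(stats::dnorm(state$lv, 0, pr$lv_sd, log = TRUE)) +
        stats::dnorm(state$z, 0, pr$z_sd, log = TRUE)
    }
    if (cfg$diffusion %in% c("gamma", "lognormal")) {
      lp <- lp + stats::dlnorm(state$shape, pr$shape_meanlog, pr$shape_sdlog,
                               log = TRUE)
    }
    dm <- mcmc_diffusion(state, cfg)
    lp <- lp + scalar_log_density(dm, state$tt$diff_scalar[-tt_root(state$tt)])
  }
  lp
}

# tip displacements are data (powered by beta); internal displacements are
# latent-variable structure and stay at full weight like any other prior --
# unless ancestral locations are observed (fixed_locations), in which case
# every displacement is data
mcmc_log_target <- function(comps, config) {
  int_w <- if (isTRUE(config$fixed_locations)) config$beta else 1
  config$beta * (comps["dollo"] + comps["rrw_tip"]) +
    int_w * comps["rrw_int"] + comps["coal"] + comps["cal"] + comps["prior"]
}

# ---- initialization ---------------------------------------------------------

mcmc_init_state <- function(model) {
  cfg <- model$config
  tt <- cfg$init_tree
  if (is.null(tt)) {
    root_guess <- if (!is.null(cfg$calibration)) {
      cfg$calibration$mean * 2.5
    } else 1000
    if (!is.null(model$m)) {
      d <- cognate_similarity(model$m)$distance
      d[!is.finite(d)] <- mean(d[is.finite(d)])
      hc <- stats::hclust(stats::as.dist(d), method = "average")
      phy <- ape::as.phylo(hc)
      phy$edge.length <- phy$edge.length + 1e-6  # break zero-height ties
      tt <- as_time_tree(phy)
      tt$height <- tt$height * root_guess / max(tt$height)
    } else {
      tt <- simulate_tree(model$n_tips, root_age_BP = root_guess,
                          labels = model$labels, seed = cfg$seed + 7L)
    }
  }
  n <- tt$n_tips
  # locations: tips fixed; internal nodes at descendant-tip means, pushed
  # onto land if needed
  if (!is.null(model$tip_loc)) {
    tt$location[seq_len(n), ] <- model$tip_loc[tt$labels, , drop = FALSE]
    cm <- tt_clade_matrix(tt)
    for (v in (n + 1):(2 * n - 1)) {
      if (all(is.finite(tt$location[v, ]))) next  # keep supplied locations
      p <- colMeans(model$tip_loc[tt$labels[cm[v, ]], , drop = FALSE])
      if (!is.null(model$mask) && !point_on_land(model$mask, p)) {
        p <- nudge_to_land(p, model$mask)
      }
      tt$location[v, ] <- p
    }
  }
  lvz <- if (!is.null(cfg$fixed_sigma)) {
    sg <- cfg$fixed_sigma
    list(lv = log(c(sg[1, 1], sg[2, 2])),
         z = atanh(sg[1, 2] / sqrt(sg[1, 1] * sg[2, 2])))
  } else list(lv = init_lv(model, tt), z = 0)
  list(tt = tt, mu = exp(cfg$priors$mu_meanlog), clock_sigma = 0.3,
       pops = cfg$fixed_pops %||%
         rep(max(tt$height) / 2, length(model$group_sizes)),
       lv = lvz$lv, z = lvz$z, shape = 1)
}

init_lv <- function(model, tt) {
  if (is.null(model$tip_loc)) return(c(log(1e-3), log(1e-3)))
  v <- apply(model$tip_loc, 2, stats::var)
  v <- pmax(v, 1e-6) / max(tt$height)
  log(v)
}

nudge_to_land <- function(p, mask, tries = 2000) {
  step <- 0.05
  for (i in seq_len(tries)) {
    cand <- p + stats::rnorm(2, 0, step)
    if (point_on_land(mask, cand)) return(cand)
    step <- step * 1.02
  }
  # fall back to a mask vertex
  r <- mask$rings[[1]]
  c(lat = mean(r[, 2]), lon = mean(r[, 1]))
}

# ---- moves ------------------------------------------------------------------

is_ancestor <- function(tt, a, b) {
  # is a an ancestor of b?
  v <- b
  while (!is.na(tt$parent[v])) {
    v <- tt$parent[v]
    if (v == a) return(TRUE)
  }
  FALSE
}

mcmc_moves <- function(model) {
  cfg <- model$config
  mv <- list()
  add <- function(name, weight, scale, fun) {
    mv[[name]] <<- list(name = name, weight = weight, scale = scale, fun = fun)
  }
  nn <- 2L * model$n_tips - 1L
  n <- model$n_tips

  if (!cfg$fixed_tree) {
    add("height_slide", 3, NA, function(state, scale) {
      tt <- state$tt
      internal <- setdiff((n + 1):nn, tt_root(tt))
      if (!length(internal)) return(NULL)
      v <- internal[sample.int(length(internal), 1)]
      kids <- which(!is.na(tt$parent) & tt$parent == v)
      lo <- max(tt$height[kids]); hi <- tt$height[tt$parent[v]]
      tt$height[v] <- stats::runif(1, lo, hi)
      state$tt <- tt
      list(state = state, lh = 0,
           recompute = c("dollo", "rrw_tip", "rrw_int", "coal", "cal"))
    })
    add("root_scale", 1, 0.2, function(state, scale) {
      tt <- state$tt
      root <- tt_root(tt)
      kids <- which(!is.na(tt$parent) & tt$parent == root)
      c_ <- exp(stats::runif(1, -scale, scale))
      h <- tt$height[root] * c_
      if (h <= max(tt$height[kids])) return(NULL)
      tt$height[root] <- h
      state$tt <- tt
      list(state = state, lh = log(c_),
           recompute = c("dollo", "rrw_tip", "rrw_int", "coal", "cal"))
    })
    add("tree_scale", 1, 0.15, function(state, scale) {
      tt <- state$tt
      c_ <- exp(stats::runif(1, -scale, scale))
      internal <- (n + 1):nn
      tt$height[internal] <- tt$height[internal] * c_
      if (any(tt$height[tt$parent[!is.na(tt$parent)]] <=
              tt$height[which(!is.na(tt$parent))])) return(NULL)
      state$tt <- tt
      list(state = state, lh = length(internal) * log(c_),
           recompute = c("dollo", "rrw_tip", "rrw_int", "coal", "cal"))
    })
    # ridge move for the time/rate non-identifiability: scale every internal
    # height by c while dividing the death rate and diffusion variance by c
    # (and scaling the coalescent sizes), which leaves the Dollo and RRW
    # likelihoods invariant -- acceptance is then governed by the calibration
    # and the parameter priors, the only terms that pin absolute time
    add("time_rate_scale", 2, 0.3, function(state, scale) {
      tt <- state$tt
      c_ <- exp(stats::runif(1, -scale, scale))
      internal <- (n + 1):nn
      tt$height[internal] <- tt$height[internal] * c_
      if (any(tt$height[tt$parent[!is.na(tt$parent)]] <=
              tt$height[which(!is.na(tt$parent))])) return(NULL)
      state$tt <- tt
      lh <- length(internal) * log(c_)
      state$mu <- state$mu / c_
      lh <- lh - log(c_)
      if (cfg$use_coalescent && is.null(cfg$fixed_pops)) {
        state$pops <- state$pops * c_
        lh <- lh + length(state$pops) * log(c_)
      }
      if (cfg$use_rrw && is.null(cfg$fixed_sigma)) {
        state$lv <- state$lv - log(c_)
      }
      list(state = state, lh = lh,
           recompute = c("dollo", "rrw_tip", "rrw_int", "coal", "cal",
                         "prior"))
    })
    add("narrow_exchange", 3, NA, function(state, scale) {
      tt <- state$tt
      root <- tt_root(tt)
      # nodes with a grandparent; swap with their "uncle"
      has_gp <- which(!is.na(tt$parent) & !is.na(tt$parent[tt$parent]))
      if (!length(has_gp)) return(NULL)
      v <- has_gp[sample.int(length(has_gp), 1)]
      p <- tt$parent[v]; gp <- tt$parent[p]
      sibs <- which(!is.na(tt$parent) & tt$parent == gp)
      u <- setdiff(sibs, p)
      if (length(u) != 1) return(NULL)
      if (tt$height[p] <= tt$height[u]) return(NULL)
      tt$parent[v] <- gp; tt$parent[u] <- p
      state$tt <- tt
      list(state = state, lh = 0,
           recompute = c("dollo", "rrw_tip", "rrw_int", "coal", "cal", "prior"))
    })
    add("exchange", 1.5, NA, function(state, scale) {
      tt <- state$tt
      root <- tt_root(tt)
      nonroot <- setdiff(seq_len(nn), root)
      ab <- nonroot[sample.int(length(nonroot), 2)]
      a <- ab[1]; b <- ab[2]
      pa <- tt$parent[a]; pb <- tt$parent[b]
      if (pa == pb) return(NULL)
      if (tt$height[pb] <= tt$height[a] || tt$height[pa] <= tt$height[b]) {
        return(NULL)
      }
      if (is_ancestor(tt, a, pb) || is_ancestor(tt, b, pa)) return(NULL)
      tt$parent[a] <- pb; tt$parent[b] <- pa
      state$tt <- tt
      list(state = state, lh = 0,
           recompute = c("dollo", "rrw_tip", "rrw_int", "coal", "cal", "prior"))
    })
  }
  if (cfg$use_dollo && !is.null(model$m)) {
    add("mu_scale", 1, 0.5, function(state, scale) {
      c_ <- exp(stats::runif(1, -scale, scale))
      state$mu <- state$mu * c_
      list(state = state, lh = log(c_), recompute = c("dollo", "prior"))
    })
  }
  if (cfg$clock == "relaxed-lognormal") {
    add("clock_sigma", 0.5, 0.4, function(state, scale) {
      c_ <- exp(stats::runif(1, -scale, scale))
      state$clock_sigma <- state$clock_sigma * c_
      list(state = state, lh = log(c_), recompute = "prior")
    })
    add("clock_rate", 2, 0.6, function(state, scale) {
      tt <- state$tt
      root <- tt_root(tt)
      v <- setdiff(seq_len(nn), root)[sample.int(nn - 1L, 1)]
      c_ <- exp(stats::runif(1, -scale, scale))
      tt$clock_rate[v] <- tt$clock_rate[v] * c_
      state$tt <- tt
      list(state = state, lh = log(c_), recompute = c("dollo", "prior"))
    })
  }
  if (cfg$use_coalescent && is.null(cfg$fixed_pops)) {
    add("pop_scale", 1, 0.8, function(state, scale) {
      g <- sample.int(length(state$pops), 1)
      c_ <- exp(stats::runif(1, -scale, scale))
      state$pops[g] <- state$pops[g] * c_
      list(state = state, lh = log(c_), recompute = c("coal", "prior"))
    })
  }
  if (cfg$use_rrw && is.null(cfg$fixed_sigma)) {
    add("sigma_geo", 1.5, 0.4, function(state, scale) {
      i <- sample.int(3, 1)
      if (i <= 2) state$lv[i] <- state$lv[i] + stats::rnorm(1, 0, scale)
      else state$z <- state$z + stats::rnorm(1, 0, scale)
      list(state = state, lh = 0,
           recompute = c("rrw_tip", "rrw_int", "prior"))
    })
  }
  if (cfg$use_rrw) {
    if (cfg$diffusion %in% c("gamma", "lognormal")) {
      add("shape_scale", 0.5, 0.4, function(state, scale) {
        c_ <- exp(stats::runif(1, -scale, scale))
        state$shape <- state$shape * c_
        list(state = state, lh = log(c_), recompute = "prior")
      })
      # per-branch Metropolis sweep over all scalars: each branch's accept
      # ratio needs only its own displacement density plus the scalar law,
      # so one sweep refreshes every phi_b (a valid composed kernel, hence
      # always "accepted" at the outer level)
      # the scalars' full conditionals are mutually independent given the
      # locations, so the whole sweep is one vectorized accept/reject;
      # tip-branch displacement densities are data (enter ^beta), internal
      # ones are prior (full weight)
      add("phi_sweep", 3, NA, function(state, scale) {
        tt <- state$tt
        root <- tt_root(tt)
        dm <- mcmc_diffusion(state, cfg)
        sig <- dm$sigma
        v <- which(!is.na(tt$parent) &
                     is.finite(tt$location[, 1]) &
                     is.finite(tt$location[tt$parent, 1]))
        if (!length(v)) return(NULL)
        d1 <- tt$location[v, 1] - tt$location[tt$parent[v], 1]
        d2 <- tt$location[v, 2] - tt$location[tt$parent[v], 2]
        tb <- tt$height[tt$parent[v]] - tt$height[v]
        det_s <- sig[1, 1] * sig[2, 2] - sig[1, 2]^2
        q <- (d1^2 * sig[2, 2] - 2 * d1 * d2 * sig[1, 2] +
                d2^2 * sig[1, 1]) / (det_s * tb)
        phi0 <- tt$diff_scalar[v]
        c_ <- exp(stats::runif(length(v), -1.2, 1.2))
        phi1 <- phi0 * c_
        w <- ifelse(v <= n | isTRUE(cfg$fixed_locations), cfg$beta, 1)
        ldisp <- function(phi) -log(phi) - 0.5 * q / phi  # up to constants
        lprior <- function(phi) {
          if (dm$kind == "gamma") {
            stats::dgamma(phi, dm$shape, rate = dm$shape, log = TRUE)
          } else {
            stats::dlnorm(phi, -dm$shape^2 / 2, dm$shape, log = TRUE)
          }
        }
        lr <- w * (ldisp(phi1) - ldisp(phi0)) +
          lprior(phi1) - lprior(phi0) + log(c_)
        acc <- log(stats::runif(length(v))) < lr
        tt$diff_scalar[v[acc]] <- phi1[acc]
        state$tt <- tt
        list(state = state, lh = Inf,
             recompute = c("rrw_tip", "rrw_int", "prior"))
      })
    }
    if (cfg$diffusion == "cauchy") {
      # exact Gibbs sweep under the power posterior:
      # gamma_b | displacement ~ Gamma(beta + 1/2, (1 + beta q_b)/2)
      add("phi_gibbs", 3, NA, function(state, scale) {
        tt <- state$tt
        sig <- mcmc_state_sigma(state)
        v <- which(!is.na(tt$parent) &
                     is.finite(tt$location[, 1]) &
                     is.finite(tt$location[tt$parent, 1]))
        if (!length(v)) return(NULL)
        d1 <- tt$location[v, 1] - tt$location[tt$parent[v], 1]
        d2 <- tt$location[v, 2] - tt$location[tt$parent[v], 2]
        tb <- tt$height[tt$parent[v]] - tt$height[v]
        det_s <- sig[1, 1] * sig[2, 2] - sig[1, 2]^2
        q <- (d1^2 * sig[2, 2] - 2 * d1 * d2 * sig[1, 2] +
                d2^2 * sig[1, 1]) / (det_s * tb)
        w <- ifelse(v <= n | isTRUE(cfg$fixed_locations), cfg$beta, 1)
        g <- stats::rgamma(length(v), shape = w + 0.5, rate = (1 + w * q) / 2)
        tt$diff_scalar[v] <- 1 / g
        state$tt <- tt
        list(state = state, lh = Inf,
             recompute = c("rrw_tip", "rrw_int", "prior"))
      })
    }
    if (!cfg$fixed_locations) {
    add("location", 4, 0.3, function(state, scale) {
      tt <- state$tt
      internal <- (n + 1):nn
      v <- internal[sample.int(length(internal), 1)]
      cand <- tt$location[v, ] + stats::rnorm(2, 0, scale)
      if (!is.null(model$mask) && !point_on_land(model$mask, cand)) {
        return(NULL)  # water has prior zero: auto-reject
      }
      tt$location[v, ] <- cand
      state$tt <- tt
      list(state = state, lh = 0, recompute = c("rrw_tip", "rrw_int"))
    })
    # per-node Metropolis sweep: each node's conditional involves only its
    # incident branches, so one sweep refreshes every ancestral location
    # (composed kernel, always "accepted" at the outer level)
    add("location_sweep", 4, NA, function(state, scale) {
      tt <- state$tt
      sig <- mcmc_state_sigma(state)
      det_s <- sig[1, 1] * sig[2, 2] - sig[1, 2]^2
      ldisp2 <- function(d1, d2, cb) {
        q <- (d1^2 * sig[2, 2] - 2 * d1 * d2 * sig[1, 2] +
                d2^2 * sig[1, 1]) / (det_s * cb)
        -log(cb) - 0.5 * q
      }
      internal <- (n + 1):nn
      for (v in internal[sample.int(length(internal))]) {
        cand <- tt$location[v, ] + stats::rnorm(2, 0, 0.25)
        if (!is.null(model$mask) && !point_on_land(model$mask, cand)) next
        lr <- 0
        p <- tt$parent[v]
        if (!is.na(p)) {
          cb <- (tt$height[p] - tt$height[v]) * tt$diff_scalar[v]
          lr <- lr + ldisp2(cand[1] - tt$location[p, 1],
                            cand[2] - tt$location[p, 2], cb) -
            ldisp2(tt$location[v, 1] - tt$location[p, 1],
                   tt$location[v, 2] - tt$location[p, 2], cb)
        }
        for (k in which(!is.na(tt$parent) & tt$parent == v)) {
          w <- if (k <= n) cfg$beta else 1
          cb <- (tt$height[v] - tt$height[k]) * tt$diff_scalar[k]
          lr <- lr + w * (ldisp2(tt$location[k, 1] - cand[1],
                                 tt$location[k, 2] - cand[2], cb) -
                            ldisp2(tt$location[k, 1] - tt$location[v, 1],
                                   tt$location[k, 2] - tt$location[v, 2], cb))
        }
        if (log(stats::runif(1)) < lr) tt$location[v, ] <- cand
      }
      state$tt <- tt
      list(state = state, lh = Inf, recompute = c("rrw_tip", "rrw_int"))
    })
    add("location_translate", 1.5, 0.5, function(state, scale) {
      # rigid shift of every ancestral location: internal displacements are
      # unchanged, so under the prior this moves the whole cloud freely
      tt <- state$tt
      internal <- (n + 1):nn
      shift <- stats::rnorm(2, 0, scale)
      newloc <- sweep(tt$location[internal, , drop = FALSE], 2, -shift)
      if (!is.null(model$mask)) {
        for (i in seq_along(internal)) {
          if (!point_on_land(model$mask, newloc[i, ])) return(NULL)
        }
      }
      tt$location[internal, ] <- newloc
      state$tt <- tt
      list(state = state, lh = 0, recompute = c("rrw_tip", "rrw_int"))
    })
    # independence resimulation of the whole ancestral history from the
    # RRW process (root uniform over the mask box, displacements from the
    # current diffusion). The proposal density of the internal displacements
    # cancels against the rrw_int prior factor in the Hastings ratio, so at
    # beta = 0 acceptance reduces to the all-on-land indicator -- which is
    # what lets the prior-only chain hop between separate landmasses.
    if (!is.null(model$mask)) {
      add("location_resim", 1, NA, function(state, scale) {
        tt <- state$tt
        dm <- mcmc_diffusion(state, cfg)
        old_int <- rrw_loglik_parts(tt, dm)[["internal"]]
        if (!is.finite(old_int)) return(NULL)
        bb <- mask_bbox(model$mask)
        root <- tt_root(tt)
        internal <- (n + 1):nn
        ord <- internal[order(tt$height[internal], decreasing = TRUE)]
        ch <- chol(dm$sigma)
        for (v in ord) {
          cand <- if (v == root) {
            c(stats::runif(1, bb[3], bb[4]), stats::runif(1, bb[1], bb[2]))
          } else {
            tb <- tt$height[tt$parent[v]] - tt$height[v]
            tt$location[tt$parent[v], ] +
              as.vector(t(ch) %*% stats::rnorm(2)) *
              sqrt(tb * tt$diff_scalar[v])
          }
          if (!point_on_land(model$mask, cand)) return(NULL)
          tt$location[v, ] <- cand
        }
        state$tt <- tt
        new_int <- rrw_loglik_parts(tt, dm)[["internal"]]
        list(state = state, lh = old_int - new_int,
             recompute = c("rrw_tip", "rrw_int"))
      })
    }
    }
    # independence proposal over the mask bounding box: keeps latent
    # locations mobile when the likelihood power is small
    bbox <- if (!is.null(model$mask) && !cfg$fixed_locations)
      mask_bbox(model$mask) else NULL
    if (!is.null(bbox)) {
      add("location_jump", 1.5, NA, function(state, scale) {
        tt <- state$tt
        internal <- (n + 1):nn
        v <- internal[sample.int(length(internal), 1)]
        cand <- c(stats::runif(1, bbox[3], bbox[4]),
                  stats::runif(1, bbox[1], bbox[2]))
        if (!point_on_land(model$mask, cand)) return(NULL)
        tt$location[v, ] <- cand
        state$tt <- tt
        list(state = state, lh = 0, recompute = c("rrw_tip", "rrw_int"))
      })
    }
  }
  mv
}

mcmc_record_row <- function(it, state, comps, config) {
  root <- tt_root(state$tt)
  sig <- mcmc_state_sigma(state)
  c(state = it, log_post = unname(mcmc_log_target(comps, config)),
    log_lik_dollo = unname(comps["dollo"]),
    log_lik_rrw = unname(comps["rrw_tip"]) +
      if (isTRUE(config$fixed_locations)) unname(comps["rrw_int"]) else 0,
    log_rrw_internal = unname(comps["rrw_int"]),
    root_height = state$tt$height[root], mu = state$mu,
    clock_sigma = state$clock_sigma,
    root_lat = unname(state$tt$location[root, 1]),
    root_lon = unname(state$tt$location[root, 2]),
    diff_var_lat = sig[1, 1], diff_var_lon = sig[2, 2],
    diff_cor = sig[1, 2] / sqrt(sig[1, 1] * sig[2, 2]),
    diff_shape = state$shape,
    setNames(state$pops, paste0("pop_size_", seq_along(state$pops))))
}

# ---- main driver ------------------------------------------------------------

#' Run the joint MCMC
#'
#' Metropolis-within-Gibbs sampler over tree topology, node heights, the
#' Dollo death rate, clock model, skyline population sizes, diffusion
#' precision, branch diffusion scalars, and internal-node locations. The
#' target is
#' `beta * (Dollo log-lik + RRW log-lik) + skyline + calibration + priors`,
#' with proposals into water auto-rejected (the zero-water prior).
#'
#' @param m a [cognate_matrix()], or `NULL` for geography-only / prior-only
#'   runs.
#' @param geo tibble/data frame with `taxon`, `lat`, `lon` tip coordinates,
#'   or `NULL`.
#' @param mask a [land_mask()] or `NULL` (no land constraint).
#' @param config an [mcmc_config()].
#' @return A `lexigeo_trace`: list with `samples` (tibble, one row per
#'   retained state), `trees` (list of sampled [time_tree()]s),
#'   `acceptance` (per-move rates), `config`, `burnin`, `sample_interval`.
#' @export
mcmc_run <- function(m = NULL, geo = NULL, mask = NULL, config = mcmc_config()) {
  labels <- if (!is.null(m)) m$taxa
             else if (!is.null(config$init_tree)) config$init_tree$labels
             else if (!is.null(geo)) geo$taxon
             else stop("need data or an init_tree to define the taxa")
  n <- length(labels)
  tip_loc <- NULL
  if (!is.null(geo)) {
    validate_taxon_geo(geo)
    if (!setequal(geo$taxon, labels)) stop("coordinate taxa do not match matrix taxa")
    tip_loc <- as.matrix(geo[match(labels, geo$taxon), c("lat", "lon")])
    rownames(tip_loc) <- labels
  } else if (config$use_rrw) {
    config$use_rrw <- FALSE
  }
  groups <- min(config$skyline_groups, n - 1L)
  gs <- rep((n - 1L) %/% groups, groups)
  gs[seq_len((n - 1L) %% groups)] <- gs[seq_len((n - 1L) %% groups)] + 1L
  model <- list(m = m, tip_loc = tip_loc, mask = mask, config = config,
                labels = labels, n_tips = n, group_sizes = gs)

  withr_seed(config$seed, {
    state <- mcmc_init_state(model)
    comps <- mcmc_components(state, model)
    if (!is.finite(mcmc_log_target(comps, config))) {
      stop("initial state has zero posterior density")
    }
    moves <- mcmc_moves(model)
    wts <- vapply(moves, function(x) x$weight, 1)
    acc <- rej <- setNames(numeric(length(moves)), names(moves))
    adapt_until <- floor(config$chain_length * config$adapt_frac)
    n_keep <- config$chain_length %/% config$thin
    trees <- vector("list", n_keep)
    rows <- vector("list", n_keep)
    ki <- 0L
    for (it in seq_len(config$chain_length)) {
      if (!length(moves)) {  # fully constrained model: constant chain
        if (it %% config$thin == 0) {
          ki <- ki + 1L
          trees[[ki]] <- state$tt
          rows[[ki]] <- mcmc_record_row(it, state, comps, config)
        }
        next
      }
      mi <- sample.int(length(moves), 1, prob = wts)
      mv <- moves[[mi]]
      prop <- mv$fun(state, mv$scale)
      if (is.null(prop)) {
        rej[mi] <- rej[mi] + 1
      } else {
        newc <- comps
        newc[prop$recompute] <- mcmc_components(prop$state, model,
                                                prop$recompute)
        lr <- if (is.infinite(prop$lh) && prop$lh > 0) {
          Inf  # Gibbs draw: always accept
        } else {
          mcmc_log_target(newc, config) - mcmc_log_target(comps, config) +
            prop$lh
        }
        if (log(stats::runif(1)) < lr) {
          state <- prop$state; comps <- newc; acc[mi] <- acc[mi] + 1
        } else rej[mi] <- rej[mi] + 1
      }
      if (it <= adapt_until && !is.na(mv$scale) && (acc[mi] + rej[mi]) %% 50 == 0) {
        rate <- acc[mi] / max(1, acc[mi] + rej[mi])
        moves[[mi]]$scale <- mv$scale * exp(0.5 * (rate - 0.3))
      }
      if (it %% config$thin == 0) {
        ki <- ki + 1L
        trees[[ki]] <- state$tt
        rows[[ki]] <- mcmc_record_row(it, state, comps, config)
      }
      if (config$report_every > 0 && it %% config$report_every == 0) {
        message(sprintf("iter %d  log_post %.2f  acc %s", it,
                        mcmc_log_target(comps, config),
                        paste(sprintf("%s=%.2f", names(moves),
                                      acc / pmax(1, acc + rej)),
                              collapse = " ")))
      }
    }
    rates <- acc / pmax(1, acc + rej)
    low <- rates[rates < 0.01 & (acc + rej) > 100]
    if (length(low)) {
      warning("low acceptance for move(s): ",
              paste(names(low), collapse = ", "), call. = FALSE)
    }
    structure(list(
      samples = tibble::as_tibble(do.call(rbind, rows)),
      trees = trees, acceptance = rates, config = config,
      burnin = config$burnin, sample_interval = config$thin),
      class = "lexigeo_trace")
  })
}

#' @export
print.lexigeo_trace <- function(x, ...) {
  cat(sprintf("<lexigeo_trace> %d samples (every %d states, burn-in %.0f%%)\n",
              nrow(x$samples), x$sample_interval, 100 * x$burnin))
  cat("  acceptance:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

# post-burn-in sample indices
trace_keep <- function(trace) {
  n <- nrow(trace$samples)
  if (!n) return(integer(0))
  seq.int(floor(n * trace$burnin) + 1L, n)
}

#' Write a trace as a tab-delimited log file
#' @param trace a `lexigeo_trace`.
#' @param path output path; trees are written next to it as
#'   `<path>.trees` annotated NEXUS.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_trees_nexus(trace$trees, paste0(path, ".trees"))
  invisible(path)
}
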
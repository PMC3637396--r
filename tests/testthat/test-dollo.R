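test_that("survival probability is the exponential kill kernel", {
  expect_equal(survival_probability(0, 123), 1.0)
  expect_equal(survival_probability(1 / 500, 500), exp(-1))
  expect_equal(survival_probability(0.001, 693.147), 0.5, tolerance = 1e-6)
  expect_error(survival_probability(-1, 1), "nonnegative")
})

test_that("2-tip pattern likelihood matches the closed form and the grid oracle", {
  tt <- two_tip_tree(700)
  mu <- 1e-3
  p <- dollo_params(lam = 1, mu = mu)
  # closed form: birth on A's branch, or on the stem with death down B
  Tb <- 700; S <- 700
  closed <- (1 - exp(-mu * Tb)) / mu +
    exp(-mu * Tb) * (1 - exp(-mu * Tb)) * (1 - exp(-mu * S)) / mu
  expect_equal(dollo_pattern_loglik(tt, p, c(A = 1, B = 0)), log(closed),
               tolerance = 1e-9)
  # independent fine-grid quadrature
  or <- oracle_dollo_integral(tt, mu, c(1L, 0L), n_grid = 4000)
  expect_equal(dollo_pattern_loglik(tt, p, c(A = 1, B = 0)), log(or),
               tolerance = 1e-8)
})

test_that("no-death shared pattern reduces to the stem integral", {
  tt <- two_tip_tree(700)
  p <- dollo_params(lam = 2, mu = 1e-12)
  # only stem births can explain (1,1); with mu ~ 0 survival is certain
  expect_equal(dollo_pattern_loglik(tt, p, c(A = 1, B = 1)),
               log(2) + log(700), tolerance = 1e-6)
})

test_that("patterns spanning the root are impossible without a stem", {
  tt <- three_tip_tree()
  p <- dollo_params(lam = 1, mu = 5e-4)
  # A and C span the root; no stem -> single-origin constraint violated
  expect_identical(dollo_pattern_loglik(tt, p, c(A = 1, B = 0, C = 1),
                                        stem_factor = 0), -Inf)
  expect_gt(dollo_pattern_loglik(tt, p, c(A = 1, B = 0, C = 1),
                                 stem_factor = 1), -Inf)
})

test_that("matrix log-likelihood equals the enumeration oracle (3 tips)", {
  tt <- three_tip_tree()
  mu <- 8e-4
  st <- cbind(c(1L, 1L, 0L), c(1L, 0L, 0L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  rownames(st) <- tt$labels
  m <- cognate_matrix(st)
  mine <- dollo_matrix_loglik(tt, dollo_params(1, mu), m)
  orac <- oracle_dollo_matrix_loglik(tt, mu, st)
  expect_equal(mine, orac, tolerance = 1e-7)
})

test_that("missing entries are marginalized, not dropped", {
  tt <- three_tip_tree()
  mu <- 8e-4
  stq <- cbind(c(1L, NA, 0L))
  rownames(stq) <- tt$labels
  mine <- dollo_matrix_loglik(tt, dollo_params(1, mu), cognate_matrix(stq))
  orac <- oracle_dollo_matrix_loglik(tt, mu, stq)
  expect_equal(mine, orac, tolerance = 1e-7)
  # marginalization identity: I(1,?,0) = I(1,0,0) + I(1,1,0)
  i_q <- exp(dollo_pattern_loglik(tt, dollo_params(1, mu), c(A = 1, B = NA, C = 0)))
  i_0 <- exp(dollo_pattern_loglik(tt, dollo_params(1, mu), c(A = 1, B = 0, C = 0)))
  i_1 <- exp(dollo_pattern_loglik(tt, dollo_params(1, mu), c(A = 1, B = 1, C = 0)))
  expect_equal(i_q, i_0 + i_1, tolerance = 1e-10)
})

test_that("observable pattern probabilities normalize to one (<= 4 tips)", {
  for (tt in list(three_tip_tree(), four_tip_tree())) {
    n <- tt$n_tips
    mu <- 6e-4
    pats <- as.matrix(expand.grid(rep(list(0:1), n)))[-1, , drop = FALSE]
    p <- dollo_params(1, mu)
    tot_I <- sum(apply(pats, 1, function(x) {
      exp(dollo_pattern_loglik(tt, p, setNames(x, tt$labels)))
    }))
    dur <- tt$height[tt$parent] - tt$height
    root <- which(is.na(tt$parent))
    L_tot <- sum(dur[-root], na.rm = TRUE) + tt$height[root]
    I0 <- oracle_dollo_integral(tt, mu, rep(0L, n))
    expect_equal(tot_I / (L_tot - I0), 1, tolerance = 1e-6)
  }
})

test_that("corrected likelihood ignores the birth intensity", {
  fx <- make_fixture("tiny4")
  tt <- fx$truth$tree
  l1 <- dollo_matrix_loglik(tt, dollo_params(lam = 1, mu = 4e-4), fx$matrix)
  l2 <- dollo_matrix_loglik(tt, dollo_params(lam = 2, mu = 4e-4), fx$matrix)
  expect_equal(l1, l2)
})

test_that("likelihood is invariant to permuting tips with identical data", {
  tt <- four_tip_tree()
  # A and B are sister tips on equal-length branches: swapping their data
  # relabels the tree without changing the likelihood
  st <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L), c(0L, 1L, 1L, 1L))
  rownames(st) <- tt$labels
  st2 <- st[c(2, 1, 3, 4), ]
  rownames(st2) <- tt$labels
  p <- dollo_params(1, 7e-4)
  expect_equal(dollo_matrix_loglik(tt, p, cognate_matrix(st)),
               dollo_matrix_loglik(tt, p, cognate_matrix(st2)),
               tolerance = 1e-12)
})

test_that("relaxed clock multipliers enter the death process", {
  tt <- three_tip_tree()
  tt2 <- tt
  tt2$clock_rate <- c(2, 2, 2, 2, 1)
  p <- dollo_params(1, 5e-4)
  st <- cbind(c(1L, 1L, 0L)); rownames(st) <- tt$labels
  m <- cognate_matrix(st)
  # doubling all branch rates = doubling mu
  expect_equal(dollo_matrix_loglik(tt2, p, m, stem_factor = 0),
               dollo_matrix_loglik(tt, dollo_params(1, 1e-3), m,
                                   stem_factor = 0),
               tolerance = 1e-9)
})

test_that("branch_rates: strict clock and degenerate relaxed clock give 1", {
  tt <- four_tip_tree()
  expect_equal(branch_rates(clock_model("strict"), tt), rep(1, 7))
  expect_equal(branch_rates(clock_model("relaxed-lognormal", sigma = 0), tt),
               rep(1, 7))
  r <- branch_rates(clock_model("relaxed-lognormal", sigma = 0.5), tt, seed = 3)
  expect_true(all(r > 0))
  # mean-1 law of large numbers
  big <- time_tree(sprintf("t%d", 1:2), c(3L, 3L, NA), c(0, 0, 1))
  set.seed(1)
  draws <- replicate(40, branch_rates(clock_model("relaxed-lognormal",
                                                  sigma = 0.5),
                                      four_tip_tree(), seed = sample.int(1e6, 1)))
  expect_equal(mean(draws), 1, tolerance = 0.05)
  r5 <- withr::with_seed(1, stats::rlnorm(1e5, -0.5^2 / 2, 0.5))
  expect_equal(mean(r5), 1, tolerance = 0.01)
})
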
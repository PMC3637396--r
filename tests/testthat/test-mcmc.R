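test_that("identical seeds give identical traces", {
  fx <- make_fixture("tiny4")
  cal <- calibration_prior(c("A", "B", "C", "D"), mean = 1000, sd = 200)
  cfg <- mcmc_config(chain_length = 600, thin = 10, seed = 42,
                     calibration = cal, diffusion = "gamma")
  t1 <- suppressWarnings(mcmc_run(fx$matrix, fx$geo, fx$mask, cfg))
  t2 <- suppressWarnings(mcmc_run(fx$matrix, fx$geo, fx$mask, cfg))
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$trees[[30]], t2$trees[[30]])
  t3 <- suppressWarnings(mcmc_run(fx$matrix, fx$geo, fx$mask,
                                  mcmc_config(chain_length = 600, thin = 10,
                                              seed = 43, calibration = cal,
                                              diffusion = "gamma")))
  expect_false(identical(t1$samples$log_post, t3$samples$log_post))
})

test_that("prior-only sampling reproduces the calibration normal", {
  # two tips: the root height is the only height, so its prior-only marginal
  # is exactly the calibration normal (truncated at 0, negligible mass there)
  init <- simulate_tree(2, root_age_BP = 480, labels = c("A", "B"), seed = 1)
  cal <- calibration_prior(c("A", "B"), mean = 500, sd = 102.04)
  cfg <- mcmc_config(chain_length = 30000, thin = 30, burnin = 0.2, seed = 7,
                     calibration = cal, init_tree = init,
                     use_dollo = FALSE, use_rrw = FALSE,
                     use_coalescent = FALSE)
  tr <- suppressWarnings(mcmc_run(NULL, NULL, NULL, cfg))
  h <- tr$samples$root_height[trace_keep(tr)]
  h_thin <- h[seq(1, length(h), by = 8)]  # cut autocorrelation before KS
  ks <- suppressWarnings(stats::ks.test(h_thin, "pnorm", 500, 102.04))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(h), 500, tolerance = 0.03)
})

test_that("prior-only sampling matches the coalescent generative law (n=4)", {
  N <- 800
  init <- simulate_tree(4, labels = LETTERS[1:4], skyline = N, seed = 3)
  cfg <- mcmc_config(chain_length = 30000, thin = 30, burnin = 0.2, seed = 11,
                     init_tree = init, skyline_groups = 1, fixed_pops = N,
                     use_dollo = FALSE, use_rrw = FALSE,
                     use_calibration = FALSE)
  tr <- suppressWarnings(mcmc_run(NULL, NULL, NULL, cfg))
  keep <- trace_keep(tr)
  roots <- tr$samples$root_height[keep]
  roots <- roots[seq(1, length(roots), by = 8)]
  # direct Monte-Carlo draws from the generative coalescent
  direct <- vapply(1:600, function(i) {
    max(simulate_tree(4, skyline = N, seed = 100000 + i)$height)
  }, 1)
  ks <- suppressWarnings(stats::ks.test(roots, direct))
  expect_gt(ks$p.value, 0.01)
  # root age expectation: sum over k of 2N/(k(k-1)) for k=4..2; wide band
  # because the exponential tail makes the MC mean converge slowly
  expect_equal(mean(roots), N * (2 / 12 + 2 / 6 + 2 / 2), tolerance = 0.2)
})

test_that("posterior recovers a strongly supported 8-tip topology", {
  tree <- simulate_tree(8, root_age_BP = 1000, skyline = 700, seed = 21)
  truth <- simulation_truth(tree, dollo_params(lam = 0.15, mu = 5e-4),
                            diffusion_model("homogeneous", sigma = diag(1e-4, 2)),
                            root_location = c(lat = 0.5, lon = 0.5), seed = 21)
  mask <- make_land_mask("unit_square")
  truth$tree <- simulate_locations(truth, mask)
  m <- simulate_dollo_cognates(truth, n_meanings = 300)
  geo <- tibble::tibble(taxon = tree$labels,
                        lat = truth$tree$location[1:8, 1],
                        lon = truth$tree$location[1:8, 2])
  cal <- calibration_prior(tree$labels, mean = 1000, sd = 100)
  cfg <- mcmc_config(chain_length = 6000, thin = 20, seed = 5,
                     calibration = cal, diffusion = "homogeneous")
  tr <- suppressWarnings(mcmc_run(m, geo, mask, cfg))
  mcc <- mcc_tree(tr)
  rf <- suppressWarnings(ape::dist.topo(as_phylo(mcc$tree), as_phylo(tree)))
  expect_equal(as.numeric(rf), 0)
})

test_that("low-acceptance moves warn instead of failing", {
  fx <- make_fixture("tiny4")
  cfg <- mcmc_config(chain_length = 3000, thin = 30, seed = 2,
                     use_calibration = FALSE, diffusion = "gamma")
  expect_warning(mcmc_run(fx$matrix, fx$geo, fx$mask, cfg),
                 "low acceptance")
})

test_that("trace tidiers return well-formed tibbles", {
  fx <- make_fixture("tiny4")
  cfg <- mcmc_config(chain_length = 500, thin = 10, seed = 3,
                     use_calibration = FALSE, diffusion = "gamma")
  tr <- suppressWarnings(mcmc_run(fx$matrix, fx$geo, fx$mask, cfg))
  td <- tidy(tr)
  expect_true(all(c("state", "parameter", "value") %in% names(td)))
  expect_true("root_height" %in% td$parameter)
  g <- glance(tr)
  expect_equal(nrow(g), 1L)
  expect_true(g$root_height_hpd_low <= g$root_height_median)
  f <- withr::local_tempfile(fileext = ".log")
  write_trace(tr, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".trees")))
  logged <- utils::read.delim(f)
  expect_equal(nrow(logged), nrow(tr$samples))
})
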
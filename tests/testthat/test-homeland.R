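test_that("hpd_interval finds the shortest window, earliest on ties", {
  expect_equal(unname(hpd_interval(rep(3.5, 10), 0.95)), c(3.5, 3.5))
  # 0..99, level 0.95 -> 95 points -> earliest width-94 window
  expect_equal(unname(hpd_interval(0:99, 0.95)), c(0, 94))
  # brute-force cross-check on irregular samples
  set.seed(13)
  x <- rexp(40)
  got <- hpd_interval(x, 0.8)
  xs <- sort(x)
  m <- ceiling(0.8 * 40)
  widths <- sapply(1:(40 - m + 1), function(i) xs[i + m - 1] - xs[i])
  i <- which.min(widths)
  expect_equal(unname(got), c(xs[i], xs[i + m - 1]))
  expect_error(hpd_interval(1:10, 1.2), "level")
})

test_that("HPD of a unimodal sample is narrower than the equal-tailed interval", {
  set.seed(14)
  x <- rnorm(1e4)
  h <- hpd_interval(x, 0.9)
  q <- quantile(x, c(0.05, 0.95))
  expect_lte(h[["high"]] - h[["low"]], unname(q[2] - q[1]) + 1e-9)
  # skewed case: strictly narrower
  y <- rlnorm(1e4)
  hy <- hpd_interval(y, 0.9)
  qy <- quantile(y, c(0.05, 0.95))
  expect_lt(hy[["high"]] - hy[["low"]], unname(qy[2] - qy[1]))
  # the interval always contains the median
  for (lv in c(0.5, 0.8, 0.95)) {
    hh <- hpd_interval(y, lv)
    expect_true(hh[["low"]] <= median(y) && median(y) <= hh[["high"]])
  }
})

# small synthetic trace builder: wraps a list of trees as a lexigeo_trace
fake_trace <- function(trees, burnin = 0) {
  structure(list(
    samples = tibble::tibble(state = seq_along(trees),
                             root_height = vapply(trees, function(t) max(t$height), 1)),
    trees = trees, burnin = burnin, sample_interval = 1,
    acceptance = c(none = 1)), class = "lexigeo_trace")
}

test_that("mcc_tree scores topologies by exhaustive clade counts", {
  ta <- three_tip_tree()                      # ((A,B),C)
  tb <- time_tree(c("A", "B", "C"), c(5L, 4L, 4L, 5L, NA),
                  c(0, 0, 0, 350, 1000))      # ((B,C),A)
  trace <- fake_trace(list(ta, ta, ta, tb))
  mcc <- mcc_tree(trace)
  expect_equal(sort(mcc$tree$labels), c("A", "B", "C"))
  # winner is the majority topology: the {A,B} clade is present
  n <- 3
  key_ab <- sum(2^(match(c("A", "B"), ta$labels) - 1))
  expect_true(key_ab %in% lexigeo:::tt_clades(mcc$tree)[(n + 1):(2 * n - 1)])
  # clade-product score: root clade p=1, {A,B} p=3/4
  expect_equal(mcc$log_clade_score, log(1) + log(3 / 4))
  # supports equal exhaustive clade counts
  root_v <- lexigeo:::tt_root(mcc$tree)
  expect_equal(mcc$support[root_v], 1)
  expect_equal(sort(unique(round(mcc$support, 6))), c(0.75, 1))
})

test_that("mcc heights are per-clade posterior medians", {
  t1 <- three_tip_tree(); t1$height[5] <- 900
  t2 <- three_tip_tree(); t2$height[5] <- 1000
  t3 <- three_tip_tree(); t3$height[5] <- 1400
  mcc <- mcc_tree(fake_trace(list(t1, t2, t3)))
  expect_equal(max(mcc$tree$height), 1000)
  expect_equal(mcc$tree$height[lexigeo:::tt_mrca(mcc$tree, c("A", "B"))], 400)
  empty <- structure(list(samples = tibble::tibble(), trees = list(),
                          burnin = 0, sample_interval = 1),
                     class = "lexigeo_trace")
  expect_error(mcc_tree(empty), "post-burn-in")
})

test_that("location HPD polygon covers the requested mass", {
  set.seed(15)
  pts <- cbind(lat = rnorm(800, 44, 0.3), lon = rnorm(800, 142, 0.3))
  poly <- lexigeo:::hpd_polygon_from_points(pts, level = 0.8,
                                            grid_resolution = 0.05)
  inside <- mean(apply(pts, 1, function(p) point_in_hpd(poly, p)))
  expect_equal(inside, 0.8, tolerance = 0.05)
  # degenerate cloud: a tiny polygon containing the point
  pts0 <- cbind(lat = rep(44, 50) + rnorm(50, 0, 1e-9),
                lon = rep(142, 50) + rnorm(50, 0, 1e-9))
  p0 <- lexigeo:::hpd_polygon_from_points(pts0, level = 0.8,
                                          grid_resolution = 0.05)
  expect_true(point_in_hpd(p0, c(44, 142)))
  expect_lt(hpd_polygon_area(p0), 1)
  expect_error(lexigeo:::hpd_polygon_from_points(pts[1:5, ]), "at least 10")
})

test_that("mask intersection keeps the polygon on land", {
  mask <- make_land_mask("two_islands")
  set.seed(16)
  # cloud centered on the coastline of the southern island
  pts <- cbind(lat = rnorm(600, 45.4, 0.4), lon = rnorm(600, 142.5, 0.4))
  poly <- lexigeo:::hpd_polygon_from_points(pts, level = 0.8, mask = mask,
                                            grid_resolution = 0.05)
  for (ring in poly$rings) {
    mid <- colMeans(ring)
    expect_true(point_on_land(mask, c(mid[2], mid[1])) ||
                  any(apply(ring, 1, function(v) point_on_land(mask, c(v[2], v[1])))))
  }
  f <- withr::local_tempfile(fileext = ".geojson")
  write_hpd_geojson(poly, f, ages = 1288)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$features[[1]]$properties$level, 0.8)
  expect_equal(gj$features[[1]]$properties$median_age_BP, 1288)
})

test_that("homeland BF is the posterior-to-prior odds ratio", {
  mk <- function(lats) {
    n <- length(lats)
    trees <- lapply(lats, function(la) {
      tt <- two_tip_tree(1000)
      tt$location <- rbind(c(43, 142), c(43, 142), c(la, 142))
      tt
    })
    fake_trace(trees)
  }
  split <- region_split(boundary_lat = 43.5)
  post <- mk(c(rep(44, 75), rep(43, 25)))
  prior <- mk(c(rep(44, 50), rep(43, 50)))
  r <- homeland_region_bf(post, prior, split)
  expect_equal(r$bf, 3)
  expect_false(r$bound)
  # posterior equal to prior -> BF 1
  expect_equal(homeland_region_bf(prior, prior, split)$bf, 1)
  # 600/200 posterior vs 300/500 prior -> BF 5
  r2 <- homeland_region_bf(mk(c(rep(44, 600), rep(43, 200))),
                           mk(c(rep(44, 300), rep(43, 500))), split)
  expect_equal(r2$bf, 5)
  # relabeling north/south inverts the BF
  flip <- region_split(boundary_lat = 43.5)
  mirror <- function(tr) {
    tr$trees <- lapply(tr$trees, function(t) {
      t$location[, 1] <- 87 - t$location[, 1]  # reflect around 43.5
      t
    })
    tr
  }
  r3 <- homeland_region_bf(mirror(post), mirror(prior), flip)
  expect_equal(r3$bf, 1 / r$bf, tolerance = 1e-12)
  # one-sided bound when a region is empty
  r4 <- homeland_region_bf(mk(rep(44, 50)), prior, split)
  expect_true(r4$bound)
  # `within` drops samples outside the focal polygon from both traces
  box <- cbind(c(140, 145, 145, 140), c(40, 40, 45, 45))
  post2 <- mk(c(rep(44, 30), rep(43, 10), rep(46, 60)))  # 46 is outside
  r5 <- homeland_region_bf(post2, prior, split, within = box)
  expect_equal(r5$posterior_north + r5$posterior_south, 40)
  expect_equal(r5$bf, (30 / 10) / (50 / 50))
})

test_that("region split from mask uses the polygon centroid latitude", {
  mask <- make_land_mask("unit_square")
  expect_equal(region_split_from_mask(mask)$boundary_lat, 0.5, tolerance = 1e-9)
})

test_that("randomization control permutes deterministically and pools HPDs", {
  fx <- make_fixture("tiny4")
  cfg <- mcmc_config(chain_length = 300, thin = 10, burnin = 0.3, seed = 1,
                     use_dollo = FALSE, use_coalescent = TRUE,
                     diffusion = "homogeneous")
  rc1 <- suppressWarnings(
    randomization_control(fx$matrix, fx$geo, fx$mask, cfg, n_reps = 50,
                          seed = 9, root_calibration =
                            calibration_prior(fx$matrix$taxa, 1500, 400)))
  expect_length(rc1$permutations, 50)
  rc2 <- suppressWarnings(
    randomization_control(fx$matrix, fx$geo, fx$mask, cfg, n_reps = 50,
                          seed = 9, root_calibration =
                            calibration_prior(fx$matrix$taxa, 1500, 400)))
  expect_identical(rc1$permutations, rc2$permutations)
  expect_s3_class(rc1$pooled_hpd, "hpd_polygon")
  expect_equal(rc1$n_failed, 0L)
})
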
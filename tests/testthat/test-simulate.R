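test_that("single-lineage Dollo equilibrium matches the closed form", {
  # one lineage of length t: E[surviving cognates] = (lam/mu)(1 - e^(-mu t))
  lam <- 0.05; mu <- 1e-3; t_len <- 1500
  tt <- time_tree(c("A", "B"), c(3L, 3L, NA), c(0, t_len - 1e-9, t_len))
  # tip B sits just below the root: its branch is ~0, so tip A's history is
  # a single lineage of length t (the stem is disabled)
  counts <- vapply(1:800, function(i) {
    truth <- simulation_truth(tt, dollo_params(lam, mu),
                              diffusion_model("homogeneous"),
                              root_location = c(0, 0), seed = i)
    m <- tryCatch(simulate_dollo_cognates(truth, n_meanings = 50,
                                          stem_factor = 0),
                  error = function(e) NULL)
    if (is.null(m)) 0 else sum(m$states["A", ] == 1L)
  }, 1)
  expect_equal(mean(counts), (lam / mu) * (1 - exp(-mu * t_len)),
               tolerance = 0.06)
})

test_that("high death rates leave mostly singleton columns", {
  tt <- simulate_tree(8, root_age_BP = 1000, seed = 33)
  truth <- simulation_truth(tt, dollo_params(lam = 0.3, mu = 0.03),
                            diffusion_model("homogeneous"),
                            root_location = c(0, 0), seed = 33)
  m <- simulate_dollo_cognates(truth, n_meanings = 100)
  singleton <- mean(colSums(m$states == 1L) == 1)
  expect_gt(singleton, 0.9)
})

test_that("simulated matrices always satisfy the observability invariant", {
  for (seed in 1:5) {
    tt <- simulate_tree(6, root_age_BP = 900, seed = seed)
    truth <- simulation_truth(tt, dollo_params(0.03, 4e-4),
                              diffusion_model("homogeneous"),
                              root_location = c(0, 0),
                              borrowing_rate = 0.2, seed = seed)
    m <- simulate_dollo_cognates(truth, n_meanings = 40)
    expect_s3_class(m, "cognate_matrix")  # constructor enforces observability
    expect_true(all(colSums(m$states == 1L) >= 1))
  }
})

test_that("borrowing transfers cognates between contemporaneous lineages", {
  # two long parallel lineages: with heavy borrowing their vocabularies
  # should be much more similar than without
  tt <- time_tree(c("A", "B"), c(3L, 3L, NA), c(0, 0, 4000))
  sim_sim <- function(br, seed) {
    truth <- simulation_truth(tt, dollo_params(0.05, 1e-3),
                              diffusion_model("homogeneous"),
                              root_location = c(0, 0),
                              borrowing_rate = br, seed = seed)
    m <- simulate_dollo_cognates(truth, n_meanings = 100)
    cognate_similarity(m)$similarity["A", "B"]
  }
  s_clean <- mean(vapply(1:30, function(i) sim_sim(0, i), 1))
  s_borrow <- mean(vapply(1:30, function(i) sim_sim(0.5, 1000 + i), 1))
  expect_gt(s_borrow, s_clean + 0.1)
})

test_that("fixture catalogue is deterministic and matches its contract", {
  expect_error(make_fixture("nope"), "tiny4")
  f1 <- make_fixture("tiny4")
  f2 <- make_fixture("tiny4")
  expect_identical(f1$matrix$states, f2$matrix$states)
  expect_equal(length(f1$matrix$taxa), 4L)
  expect_lte(ncol(f1$matrix$states), 15L)

  i1 <- make_fixture("island19")
  expect_equal(length(i1$matrix$taxa), 19L)
  expect_gte(ncol(i1$matrix$states), 250L)
  expect_lte(ncol(i1$matrix$states), 450L)
  expect_true(point_on_land(i1$mask, i1$truth$root_location))
  # all taxa have coordinates on land
  for (k in seq_len(19)) {
    expect_true(point_on_land(i1$mask, c(i1$geo$lat[k], i1$geo$lon[k])))
  }
  b1 <- make_fixture("borrowed19")
  expect_equal(b1$truth$borrowing_rate, 0.2)
  expect_identical(i1$truth$tree$height, b1$truth$tree$height)
})

test_that("fixture files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("tiny4", dir = dir)
  m <- read_nexus_binary(file.path(dir, "tiny4.nex"))
  expect_equal(unname(m$states), unname(fx$matrix$states))
  g <- read_taxon_geo(file.path(dir, "tiny4_coords.tsv"))
  expect_equal(g$taxon, fx$geo$taxon)
  mk <- read_land_mask(file.path(dir, "tiny4_mask.geojson"))
  expect_true(point_on_land(mk, c(0.5, 0.5)))
  truth <- yaml::read_yaml(file.path(dir, "tiny4_truth.yaml"))
  expect_equal(truth$mu, fx$truth$params$mu)
  trees <- read_trees_nexus(file.path(dir, "tiny4_true_tree.trees"))
  expect_equal(sort(trees[[1]]$labels), sort(fx$truth$tree$labels))
  expect_equal(max(trees[[1]]$height), max(fx$truth$tree$height),
               tolerance = 1e-6)
})

test_that("annotated tree NEXUS round-trips heights, rates and locations", {
  fx <- make_fixture("tiny4")
  tt <- fx$truth$tree
  f <- withr::local_tempfile(fileext = ".trees")
  write_trees_nexus(list(tt, tt), f)
  back <- read_trees_nexus(f)
  expect_length(back, 2L)
  b <- back[[1]]
  perm <- match(tt$labels, b$labels)
  expect_equal(b$height[perm], tt$height[1:4], tolerance = 1e-6)
  expect_equal(sort(b$height), sort(tt$height), tolerance = 1e-5)
  expect_equal(b$location[perm, ], tt$location[1:4, ], tolerance = 1e-6)
})
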
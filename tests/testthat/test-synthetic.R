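test_that("disjoint layout yields non-overlapping supports", {
  cfg <- tiny_config(K = 2)
  cfg$layout <- "disjoint"
  truth <- make_ground_truth(cfg, seed = 3)
  overlap <- sum(truth$spatial_maps[1, ] * truth$spatial_maps[2, ])
  expect_identical(overlap, 0)
  expect_true(all(rowSums(abs(truth$spatial_maps)) > 0))
})

test_that("ground truth and study are bit-identical under a fixed seed", {
  cfg <- tiny_config()
  t1 <- make_ground_truth(cfg, seed = 42)
  t2 <- make_ground_truth(cfg, seed = 42)
  expect_identical(t1$spatial_maps, t2$spatial_maps)
  expect_identical(t1$condition_betas, t2$condition_betas)

  ev <- tiny_events()
  s1 <- simulate_study(t1, 2, 2, ev, seed = 9)
  s2 <- simulate_study(t2, 2, 2, ev, seed = 9)
  expect_identical(s1$sessions[[4]]$bold$values, s2$sessions[[4]]$bold$values)
  expect_identical(s1$sessions[[1]]$confounds, s2$sessions[[1]]$confounds)
})

test_that("an 11-network, 9-condition truth has an 11 x 9 beta matrix", {
  cfg <- tiny_config(K = 11, conditions = paste0("c", 1:9))
  truth <- make_ground_truth(cfg, seed = 1)
  expect_equal(dim(truth$condition_betas), c(11, 9))
})

test_that("generator rejects invalid configurations", {
  expect_error(make_ground_truth(tiny_config(K = 1), 1), "n_networks")
  cfg <- tiny_config(); cfg$conditions <- character(0)
  expect_error(make_ground_truth(cfg, 1), "condition")
  truth <- make_ground_truth(tiny_config(), 1)
  bad_ev <- event_table(1, 2, "nonexistent")
  expect_error(simulate_study(truth, 1, 1, bad_ev, 1), "unknown condition")
})

test_that("noiseless mixing makes voxel series proportional to their network", {
  cfg <- tiny_config(K = 2, noise_sd = 0)
  cfg$layout <- "disjoint"
  truth <- make_ground_truth(cfg, seed = 4)
  study <- simulate_study(truth, 1, 1, tiny_events(), seed = 6,
                          tc_noise_sd = 0, nuisance_scale = 0, baseline = 0)
  y <- study$sessions[[1]]$bold$values
  tc <- study$sessions[[1]]$network_tc
  support1 <- which(truth$spatial_maps[1, ] > 0)
  for (v in support1[1:5]) {
    expect_equal(abs(cor(y[v, ], tc[, 1])), 1, tolerance = 1e-9)
  }
})

test_that("without coupling, condition-modulated covariance vanishes in expectation", {
  cfg <- tiny_config(K = 2, noise_sd = 0)
  truth <- make_ground_truth(cfg, seed = 8)
  truth$condition_betas[] <- 0        # pure noise time courses
  ev <- tiny_events()
  gate <- condition_regressors(ev, 300, 0.5,
                               conditions = truth$conditions)[, "a_target"]
  mods <- vapply(1:100, function(r) {
    st <- simulate_study(truth, 1, 1, ev, seed = 1000 + r, tc_noise_sd = 1,
                         nuisance_scale = 0, baseline = 0)
    tc <- st$sessions[[1]]$network_tc[seq_along(gate), ]
    mean(gate * tc[, 1] * tc[, 2])     # condition-modulated cross-moment
  }, numeric(1))
  expect_lt(abs(mean(mods)), 3 * sd(mods) / sqrt(length(mods)) + 0.01)
})

test_that("toy masks have exactly the requested supports", {
  masks <- make_toy_masks(list(1:20), c(5, 5, 4))
  expect_equal(sum(masks[[1]]), 20)
  two <- make_toy_masks(list(3:7, 3:7), c(5, 5, 4))
  expect_identical(two[[1]], two[[2]])
  expect_error(make_toy_masks(list(c(1, 200)), c(5, 5, 4)), "out of range")

  # hand-counted Jaccard on three sets with known intersections
  tri <- make_toy_masks(list(1:6, 4:9, c(1, 9, 10)), c(5, 5, 4))
  expect_equal(jaccard(tri[[1]], tri[[2]]), 3 / 9)
  expect_equal(jaccard(tri[[1]], tri[[3]]), 1 / 8)
  expect_equal(jaccard(tri[[2]], tri[[3]]), 1 / 8)
})

test_that("voxel noise variance tracks the configured noise_sd within 10%", {
  cfg <- tiny_config(K = 2, noise_sd = 2)
  cfg$grid_shape <- c(12, 12, 8)        # V = 1152
  truth <- make_ground_truth(cfg, seed = 10)
  ev <- simulate_events(cfg$conditions, 520, 0.5, trials_per_condition = 10,
                        duration = 2, seed = 2)
  study <- simulate_study(truth, 1, 1, ev, seed = 3, tc_noise_sd = 0,
                          nuisance_scale = 0, baseline = 0)
  ses <- study$sessions[[1]]
  signal <- crossprod(truth$spatial_maps, t(ses$network_tc))
  resid <- ses$bold$values - signal
  expect_equal(sd(as.vector(resid)), 2, tolerance = 0.1)
})

test_that("a session round-trips through NIfTI and TSV writers", {
  cfg <- tiny_config(K = 2)
  truth <- make_ground_truth(cfg, seed = 12)
  expect_equal(truth$tr_seconds, 0.5)
  study <- simulate_study(truth, 1, 1, tiny_events(), seed = 13)
  ses <- study$sessions[[1]]
  dir <- withr::local_tempdir()
  paths <- write_session(ses, dir)
  back <- read_bold(paths["bold"], paths["mask"], subject = 1, session = 1)
  expect_equal(back$values, ses$bold$values, tolerance = 1e-6)
  expect_equal(back$tr_seconds, 0.5)
  ev2 <- read_events(paths["events"])
  expect_equal(as.data.frame(ev2), as.data.frame(ses$events), tolerance = 1e-12)
})
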
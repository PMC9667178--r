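orthogonal_design <- function(n = 64) {
  # orthogonal task columns plus constant, exactly known coefficients
  t1 <- rep(c(1, -1), n / 2)
  t2 <- rep(c(1, 1, -1, -1), n / 4)
  t3 <- rep(c(1, -1, -1, 1), n / 4)
  vals <- cbind(r1 = t1, r2 = t2, r3 = t3, constant = rep(1, n))
  netica:::new_design_matrix(vals, c("condition", "condition", "condition",
                                     "constant"), 0.5)
}

test_that("temporal sorting recovers exact coefficients on orthogonal designs", {
  dm <- orthogonal_design()
  y <- dm$values[, "r1"]
  b <- temporal_sort(y, dm)
  expect_equal(b$beta[b$regressor == "r1"], 1, tolerance = 1e-10)
  expect_equal(b$beta[b$regressor %in% c("r2", "r3")], c(0, 0), tolerance = 1e-10)
  expect_equal(attr(b, "r_squared"), 1, tolerance = 1e-10)

  y2 <- 2 * dm$values[, "r1"] - 0.5 * dm$values[, "r3"]
  b2 <- temporal_sort(y2, dm)
  expect_equal(b2$beta[b2$regressor == "r1"], 2, tolerance = 1e-12)
  expect_equal(b2$beta[b2$regressor == "r3"], -0.5, tolerance = 1e-12)

  # rank deficiency names the collinear column
  bad_vals <- cbind(dm$values, dup = dm$values[, "r1"])
  bad <- netica:::new_design_matrix(bad_vals, c(dm$roles, "condition"), 0.5)
  expect_error(temporal_sort(y, bad), "collinear")
})

test_that("noise betas shrink with series length", {
  set.seed(9)
  beta_mag <- vapply(c(200, 3200), function(T) {
    t1 <- rnorm(T); t2 <- rnorm(T)
    dm <- netica:::new_design_matrix(cbind(a = t1, b = t2, constant = rep(1, T)),
                                     c("condition", "condition", "constant"), 0.5)
    mean(abs(replicate(20, {
      b <- temporal_sort(rnorm(T), dm)
      b$beta[1]
    })))
  }, numeric(1))
  expect_gt(beta_mag[1] / beta_mag[2], 2.5)   # ~ sqrt(16) = 4 expected
})

test_that("session averaging keeps primary betas only", {
  bt <- tibble::tibble(
    subject = rep(1, 6), session = rep(1:2, each = 3),
    component = rep(1, 6),
    regressor = rep(c("a", "a_tderiv", "constant"), 2),
    role = rep(c("condition", "temporal-derivative", "constant"), 2),
    beta = c(1, 9, 9, 3, 9, 9)
  )
  out <- aggregate_betas(bt)
  expect_equal(nrow(out), 1)
  expect_equal(out$beta, 2)                    # mean of {1, 3}, derivatives excluded

  single <- aggregate_betas(bt[bt$session == 1, ])
  expect_equal(single$beta, 1)                 # single session: identity

  twelve <- dplyr::bind_rows(lapply(1:12, function(s) {
    dplyr::mutate(bt[1, ], session = s)
  }))
  out12 <- aggregate_betas(twelve)
  expect_equal(out12$beta, 1)
})

test_that("paired contrasts reproduce hand-computed t statistics", {
  betas <- tibble::tibble(
    subject = rep(1:3, each = 2),
    component = rep(1, 6),
    condition = rep(c("A", "B"), 3),
    beta = c(2, 1, 4, 2, 6, 3)                 # differences 1, 2, 3
  )
  res <- paired_contrast_test(betas, "A", "B", n_tests = 66)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$p_corrected, min(1, res$p * 66))

  # equal conditions: t = 0, p = 1 (zero-variance warning path)
  eq <- dplyr::mutate(betas, beta = rep(c(1, 1), 3))
  expect_warning(res_eq <- paired_contrast_test(eq, "A", "B"), "zero-variance")
  expect_equal(res_eq$t, 0)
  expect_equal(res_eq$p, 1)

  # swapping conditions negates t and preserves p
  swap <- paired_contrast_test(betas, "B", "A", n_tests = 66)
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
})

test_that("condition betas are recovered across the simulated pipeline", {
  cfg <- tiny_config(K = 3, conditions = c("a_target", "a_control", "a_rest"),
                     noise_sd = 0.5)
  truth <- make_ground_truth(cfg, seed = 31)
  ev <- tiny_events(conditions = cfg$conditions)
  study <- simulate_study(truth, 2, 2, ev, seed = 32, tc_noise_sd = 0.1)
  datasets <- lapply(study$sessions, `[[`, "bold")
  dec <- group_ica(datasets, k_session = 3, n_runs = 3, seed = 33)
  comps <- zscore_components(back_reconstruct(dec, lapply(datasets, intensity_normalize)))
  designs <- lapply(study$sessions, function(s) {
    build_design_matrix(s$events, ncol(s$bold$values), truth$tr_seconds,
                        conditions = truth$conditions)
  })
  betas <- aggregate_betas(sort_components(comps, designs))

  # match components to truth networks by spatial correlation, align signs
  cc <- cor(t(comps$sessions[[1]]$maps), t(truth$spatial_maps))
  matched <- apply(abs(cc), 2, which.max)
  signs <- sign(cc[cbind(matched, seq_len(3))])
  est <- t(sapply(seq_len(3), function(net) {
    k <- matched[net]
    v <- betas[betas$component == k, ]
    agg <- tapply(v$beta, v$condition, mean)
    unname(agg[colnames(truth$condition_betas)]) * signs[net]
  }))
  expect_gt(cor(as.vector(est), as.vector(truth$condition_betas)), 0.95)
})
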
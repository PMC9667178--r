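make_bold <- function(values, tr = 0.5) {
  V <- nrow(values)
  bold_dataset(values, array(TRUE, c(V, 1, 1)), tr)
}

test_that("intensity normalization rescales to percent of temporal mean", {
  # second voxel: mean exactly 200 with one 220 sample -> that sample maps to 110
  v2 <- c(rep((2000 - 220) / 9, 9), 220)
  d <- make_bold(rbind(rep(500, 10), v2))
  out <- intensity_normalize(d)
  expect_equal(out$values[1, ], rep(100, 10))
  expect_equal(mean(v2), 200)
  expect_equal(unname(out$values[2, 10]), 110)

  # idempotent up to tolerance
  twice <- intensity_normalize(out)
  expect_equal(twice$values, out$values, tolerance = 1e-12)

  # zero-mean voxels are excluded with a message
  dz <- make_bold(rbind(rep(100, 10), c(rep(0, 5), rep(0, 5))))
  expect_message(nz <- intensity_normalize(dz), "excluded")
  expect_equal(nrow(nz$values), 1)
  expect_equal(sum(nz$mask), 1)
})

test_that("MDL order selection behaves on noise, structure, and flat spectra", {
  # pure i.i.d. noise: order <= 3 in at least 95% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    estimate_order_mdl(matrix(rnorm(500 * 20), 500, 20)) <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # five dominant eigenvalues: order 5, matching a brute-force criterion curve
  ev <- c(50, 40, 30, 20, 10, rep(0.5, 25))
  n <- 5000
  k_hat <- estimate_order_mdl(eigenvalues = ev, n = n)
  expect_equal(as.integer(k_hat), 5L)
  p <- length(ev)
  brute <- vapply(0:(p - 1), function(k) {
    tail_ev <- ev[(k + 1):p]
    -n * (p - k) * (mean(log(tail_ev)) - log(mean(tail_ev))) +
      0.5 * k * (2 * p - k) * log(n)
  }, numeric(1))
  expect_equal(attr(k_hat, "mdl"), brute, tolerance = 1e-9)

  # equal eigenvalues: criterion minimized at zero sources
  expect_equal(as.integer(estimate_order_mdl(eigenvalues = rep(2, 10), n = 1000)), 0L)

  expect_error(estimate_order_mdl(matrix(rnorm(10), 5, 2)), "3 time points")
})

test_that("PCA reduction records retained variance faithfully", {
  # exact rank 3: all variance retained at k = 3, zero reconstruction error at full k
  set.seed(2)
  basis <- matrix(rnorm(6 * 40), 6, 40)
  X <- matrix(rnorm(6 * 3), 6, 3) %*% basis[1:3, ]
  out <- pca_reduce(X, 3)
  expect_equal(out$step$retained_variance, 1, tolerance = 1e-10)
  expect_error(pca_reduce(X, 5), "rank")

  Y <- matrix(rnorm(5 * 30), 5, 30)
  full <- pca_reduce(Y, 5)
  recon <- full$step$projection %*% full$reduced + full$step$means
  expect_equal(recon, Y, tolerance = 1e-10)

  # known eigenvalues {4, 2, 1, 1} -> retained variance 6/8 at k = 2
  H <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1,
                1, -1, 1, -1, 1, -1, 1, -1,
                1, 1, -1, -1, 1, 1, -1, -1,
                1, 1, 1, 1, -1, -1, -1, -1,
                1, -1, -1, 1, 1, -1, -1, 1), 5, 8, byrow = TRUE)
  rows <- H[2:5, ] / sqrt(8)                       # orthonormal, zero-mean rows
  X2 <- diag(sqrt(c(4, 2, 1, 1))) %*% rows
  out2 <- pca_reduce(X2, 2)
  expect_equal(out2$step$retained_variance, 0.75, tolerance = 1e-10)
})

test_that("group concatenation preserves shared session subspaces", {
  set.seed(3)
  sess <- pca_reduce(matrix(rnorm(30 * 200), 30, 200), 4)
  one <- concat_group_reduce(list(sess$reduced), 4)
  # subspace angle between row spaces is zero: principal angles via svd
  b1 <- svd(t(sess$reduced))$u
  b2 <- svd(t(one$reduced))$u
  angles <- svd(crossprod(b1, b2))$d
  expect_equal(angles, rep(1, 4), tolerance = 1e-8)

  two <- concat_group_reduce(list(sess$reduced, sess$reduced), 4)
  b3 <- svd(t(two$reduced))$u
  expect_equal(svd(crossprod(b1, b3))$d, rep(1, 4), tolerance = 1e-8)

  expect_error(concat_group_reduce(list(sess$reduced,
                                        matrix(0, 4, 10)), 2), "voxel dimension")
})

test_that("Infomax unmixes super-Gaussian sources", {
  set.seed(4)
  V <- 3000
  S <- matrix(sign(rnorm(2 * V)) * rexp(2 * V), 2, V)    # Laplacian-like
  X <- matrix(c(1, 0.3, 0.5, 1), 2, 2) %*% S
  fit <- infomax_ica(X, seed = 1)
  cc <- abs(cor(t(fit$sources), t(S)))
  expect_true(all(apply(cc, 2, max) >= 0.95))
  expect_false(fit$non_identifiable)

  # already-independent input: unmixing is a signed permutation after scaling
  fit2 <- infomax_ica(S, seed = 2)
  W <- fit2$unmixing
  Wn <- abs(W) / apply(abs(W), 1, max)
  expect_true(all(rowSums(Wn > 0.95) == 1))
  expect_true(all(colSums(Wn > 0.95) == 1))

  # unmixing reproduces the sources from centered input
  rec <- fit$unmixing %*% (X - rowMeans(X))
  expect_equal(rec, fit$sources, tolerance = 1e-8)

  # Gaussian-only sources are flagged non-identifiable
  G <- matrix(rnorm(2 * V), 2, V)
  fitg <- infomax_ica(G, seed = 3)
  expect_true(fitg$non_identifiable)

  # determinism under a fixed seed
  expect_identical(infomax_ica(X, seed = 9)$sources,
                   infomax_ica(X, seed = 9)$sources)
})

test_that("Icasso stability separates strong sources from noise", {
  set.seed(5)
  V <- 1500
  S <- matrix(sign(rnorm(3 * V)) * rexp(3 * V), 3, V)
  X <- (matrix(rnorm(9, sd = 0.2), 3, 3) + diag(3)) %*% S

  # identical seeds for every run: all runs equal, quality exactly 1
  # within-cluster similarity is exactly 1; quality differs from 1 only by
  # the residual between-cluster |correlation| of distinct sources
  same <- icasso_stability(X, seed = 1, seeds = rep(7, 5))
  expect_equal(same$quality, rep(1, 3), tolerance = 0.01)

  strong <- icasso_stability(X, n_runs = 10, seed = 2)
  expect_true(all(strong$quality >= 0.9))

  noise <- icasso_stability(matrix(rnorm(3 * V), 3, V), n_runs = 10, seed = 2)
  expect_lt(mean(noise$quality), mean(strong$quality))

  expect_error(icasso_stability(X, n_runs = 1), "n_runs")
})

test_that("back-reconstruction matches direct ICA for a single session", {
  # each network driven mainly by its own condition so the time-course
  # mixing is full rank (K networks need >= K independent drivers)
  cfg <- tiny_config(K = 3, conditions = c("c1", "c2", "c3"), noise_sd = 0.05)
  set.seed(20)
  cfg$condition_betas <- diag(2, 3) + matrix(runif(9, -0.3, 0.3), 3)
  truth <- make_ground_truth(cfg, seed = 21)
  study <- simulate_study(truth, 1, 1, tiny_events(conditions = cfg$conditions),
                          seed = 22, tc_noise_sd = 0.05)
  datasets <- lapply(study$sessions, `[[`, "bold")
  norm <- lapply(datasets, intensity_normalize)
  dec <- group_ica(datasets, k_session = 3, n_runs = 1, seed = 23)
  comps <- back_reconstruct(dec, norm)

  direct <- pca_reduce(t(norm[[1]]$values), 3)
  dfit <- infomax_ica(direct$reduced, seed = 23)
  cc <- abs(cor(t(comps$sessions[[1]]$maps), t(dfit$sources)))
  expect_true(all(apply(cc, 2, max) >= 0.99))

  # variance accounting: reduced-data reconstruction residual is bounded
  ses <- comps$sessions[[1]]
  Xi <- crossprod(dec$session_steps[[1]]$projection,
                  t(norm[[1]]$values) - dec$session_steps[[1]]$means)
  recon <- t(ses$time_courses %*% ses$maps)
  resid <- sum((Xi - crossprod(dec$session_steps[[1]]$projection, t(recon)))^2) /
    sum(Xi^2)
  expect_lte(resid, (1 - dec$group_step$retained_variance) + 0.05)

  # ground-truth recovery on near-noiseless data
  mc <- abs(cor(t(ses$maps), t(truth$spatial_maps)))
  expect_true(all(apply(mc, 2, max) >= 0.95))
})

test_that("Z-scoring standardizes maps with the population convention", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE)
  expect_warning(z <- zscore_components(m), "zero-variance")
  expect_equal(z[1, ], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(z[1, ], (c(1, 2, 3) - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z[2, ], c(5, 5, 5))                  # flagged, left unscaled

  zz <- zscore_components(z[1, , drop = FALSE])
  expect_equal(zz[1, ], z[1, ], tolerance = 1e-12)  # idempotent
  expect_equal(mean(z[1, ]), 0, tolerance = 1e-6)
  expect_equal(mean(z[1, ]^2), 1, tolerance = 1e-6)
})
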
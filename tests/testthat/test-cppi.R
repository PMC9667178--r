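test_that("PPI terms are centered element-wise products", {
  tc <- c(1, -1, 1, -1); psych <- c(1, 1, -1, -1)
  expect_equal(ppi_term(tc, psych), c(1, -1, -1, 1))

  z <- ppi_term(c(5, 5, 5, 5), psych)            # constant tc -> zero
  expect_equal(as.numeric(z), rep(0, 4))
  expect_true(isTRUE(attr(z, "degenerate")))

  z2 <- ppi_term(tc, rep(0, 4))
  expect_equal(as.numeric(z2), rep(0, 4))
  expect_error(ppi_term(1:3, 1:4), "length")
})

test_that("partial correlation matches the closed-form recursion", {
  # all pairwise correlations exactly 0.5: partial r = 1/3
  sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
  d <- exact_cor_data(sigma, n = 24, seed = 2)
  expect_equal(cor(d)[1, 2], 0.5, tolerance = 1e-12)
  pc <- partial_correlation(d[, 1], d[, 2], d[, 3, drop = FALSE])
  expect_equal(pc$r, 1 / 3, tolerance = 1e-10)

  # empty controls equal plain Pearson
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)

  # y = x: r = 1 for any controls not spanning x
  z <- rnorm(30)
  expect_equal(partial_correlation(x, x, cbind(z))$r, 1, tolerance = 1e-10)

  # random triples against the 3-variable recursion formula
  for (i in 1:50) {
    set.seed(100 + i)
    m <- matrix(rnorm(25 * 3), 25, 3)
    r12 <- cor(m[, 1], m[, 2]); r13 <- cor(m[, 1], m[, 3]); r23 <- cor(m[, 2], m[, 3])
    expected <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
    got <- partial_correlation(m[, 1], m[, 2], m[, 3, drop = FALSE])$r
    expect_equal(got, expected, tolerance = 1e-10)
  }
  expect_error(partial_correlation(x[1:4], y[1:4], matrix(rnorm(12), 4)), "degrees")
})

make_cppi_inputs <- function(K = 11, T = 220, seed = 1) {
  set.seed(seed)
  ev <- simulate_events(c("tg", "ct"), T, 0.5, trials_per_condition = 6, seed = seed)
  dm <- build_design_matrix(ev, T, 0.5, basis_kind = "canonical")
  tc <- matrix(rnorm(T * K), T, K)
  list(dm = dm, tc = tc)
}

test_that("cPPI matrices cover all pairs symmetrically", {
  inp <- make_cppi_inputs(K = 11)
  psych <- psych_contrast(inp$dm, "tg", "ct")
  m <- cppi_matrix(inp$tc, inp$dm, NULL, psych, subject = 1)
  expect_equal(sum(!is.na(m$r[upper.tri(m$r)])), 55)   # 11 choose 2
  expect_true(all(is.na(diag(m$r))))
  expect_identical(m$r, t(m$r))
  expect_true(all(abs(m$r[upper.tri(m$r)]) <= 1))

  # permuting networks permutes the matrix consistently
  perm <- c(3, 1, 2, 4:11)
  mp <- cppi_matrix(inp$tc[, perm], inp$dm, NULL, psych, subject = 1)
  expect_equal(mp$r, m$r[perm, perm], tolerance = 1e-10)

  expect_error(psych_contrast(inp$dm, "tg", "tg"), "degenerate")
  expect_error(cppi_matrix(inp$tc[, 1:2], inp$dm, NULL, psych), "3 networks")
})

test_that("a condition-modulated pair stands out in a single strong subject", {
  cfg <- tiny_config(K = 4, conditions = c("tg", "ct"),
                     coupling = list(list(i = 1, j = 2, condition = "tg",
                                          strength = 3)),
                     noise_sd = 0.2)
  truth <- make_ground_truth(cfg, seed = 41)
  ev <- tiny_events(conditions = c("tg", "ct"), seed = 42)
  study <- simulate_study(truth, 1, 1, ev, seed = 43, tc_noise_sd = 0.3)
  ses <- study$sessions[[1]]
  n_scans <- nrow(ses$network_tc)
  dm <- build_design_matrix(ses$events, n_scans, 0.5, conditions = truth$conditions)
  psych <- psych_contrast(dm, "tg", "ct")
  m <- cppi_matrix(ses$network_tc, dm, as.matrix(ses$confounds), psych)
  ut <- m$r[upper.tri(m$r)]
  expect_equal(which.max(ut), 1L)                 # pair (1,2) is first in column order
  expect_gt(m$r[1, 2], 0)
})

test_that("group interaction tests use Fisher-z with plain-r reporting", {
  rs <- tanh(c(0.1, 0.2, 0.3))
  mats <- lapply(seq_along(rs), function(s) {
    R <- matrix(NA, 3, 3)
    R[upper.tri(R)] <- c(rs[s], 0, 0)
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    structure(list(r = R, p = R, subject = s, task = "t"),
              class = "interaction_matrix")
  })
  res <- group_interaction_tests(mats, n_tests = 3)
  row12 <- res[res$net_i == 1 & res$net_j == 2, ]
  expect_equal(row12$t, 3.4641, tolerance = 1e-4)
  expect_equal(row12$df, 2)
  expect_equal(row12$mean_r, mean(rs), tolerance = 1e-12)   # raw r, not z
  expect_equal(row12$sd_r, sd(rs), tolerance = 1e-12)
  expect_equal(row12$p_corrected, min(1, row12$p * 3))

  # all-zero correlations: p = 1
  zero <- lapply(1:3, function(s) {
    R <- matrix(0, 3, 3); diag(R) <- NA
    structure(list(r = R, p = R, subject = s, task = "t"),
              class = "interaction_matrix")
  })
  rz <- group_interaction_tests(zero)
  expect_true(all(rz$p == 1))
  expect_error(group_interaction_tests(mats[1:2]), "3 subjects")
})

make_task_mats <- function(vals_by_task, K = 3) {
  lapply(vals_by_task, function(vals) {
    lapply(seq_along(vals), function(s) {
      R <- matrix(0, K, K); diag(R) <- NA
      R[1, 2] <- R[2, 1] <- vals[s]
      R[1, 3] <- R[3, 1] <- 0.05 * s
      R[2, 3] <- R[3, 2] <- -0.05 * s
      structure(list(r = R, p = R, subject = s, task = "x"),
                class = "interaction_matrix")
    })
  })
}

test_that("cross-task ANOVA isolates a shifted task with df = 2", {
  # per-subject pair values shifted by {0, 0, delta} with delta large
  base <- c(0.11, 0.09, 0.12, 0.10, 0.08)
  mats <- make_task_mats(list(a = base, b = base, c = base + 0.5))
  out <- interaction_anova(mats, n_tests = 3)
  row12 <- out$anova[out$anova$net_i == 1 & out$anova$net_j == 2, ]
  expect_equal(row12$df1, 2)                      # 3 tasks -> numerator df 2
  expect_true(row12$significant)
  ph <- out$posthoc[out$posthoc$net_i == 1 & out$posthoc$net_j == 2, ]
  involving_c <- ph$p[ph$task_a == "c" | ph$task_b == "c"]
  other <- ph$p[!(ph$task_a == "c" | ph$task_b == "c")]
  expect_true(all(involving_c < 0.05))
  expect_true(all(other > 0.05))

  # identical matrices across tasks: F = 0, p = 1
  same <- make_task_mats(list(a = base, b = base, c = base))
  outs <- interaction_anova(same)
  expect_true(all(outs$anova$F == 0))
  expect_true(all(outs$anova$p == 1))

  bad <- mats; bad$a <- bad$a[1:3]
  expect_error(interaction_anova(bad), "unbalanced")
})

test_that("difference graphs keep only doubly-gated edges", {
  base <- c(0.11, 0.09, 0.12, 0.10, 0.08)
  same <- make_task_mats(list(a = base, b = base))
  out_same <- interaction_anova(same)
  expect_equal(nrow(difference_graph(out_same, "a", "b")), 0)

  mats <- make_task_mats(list(a = base, b = base + 0.5))
  out <- interaction_anova(mats, n_tests = 1)
  dg <- difference_graph(out, "b", "a")
  expect_equal(nrow(dg), 1)
  expect_equal(dg$weight, 0.5, tolerance = 1e-6)
  dg_rev <- difference_graph(out, "a", "b")
  expect_equal(dg_rev$weight, -0.5, tolerance = 1e-6)

  # edge count equals pairs passing both gates
  n_pass <- sum(out$posthoc$p < 0.05 &
                  ((out$posthoc$task_a == "b" & out$posthoc$task_b == "a") |
                     (out$posthoc$task_a == "a" & out$posthoc$task_b == "b")))
  expect_equal(nrow(dg), n_pass)
})

test_that("display scaling is signed log significance", {
  expect_equal(display_scale(0.4, 0.01), 2)
  expect_equal(display_scale(-0.4, 0.01), -2)
  expect_equal(display_scale(0.9, 1), 0)
  expect_warning(v <- display_scale(0.5, 0), "clipped")
  expect_true(is.finite(v))
})
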
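# Shared fixtures, built in code at test time.

# small ground truth + study used by several suites
tiny_config <- function(K = 3, conditions = c("a_target", "a_control"),
                        coupling = list(), noise_sd = 0.5) {
  list(n_networks = K, grid_shape = c(12, 12, 6), conditions = conditions,
       coupling = coupling, noise_sd = noise_sd, tr_seconds = 0.5,
       layout = "spread")
}

tiny_events <- function(conditions = c("a_target", "a_control"), n_scans = 300,
                        seed = 11) {
  simulate_events(conditions, n_scans, 0.5, trials_per_condition = 6,
                  duration = 2, seed = seed)
}

# independent-matrix oracle: Pearson correlation matching of row sets
match_rows <- function(est, truth) {
  cc <- abs(stats::cor(t(est), t(truth)))
  apply(cc, 2, max)                      # best match per truth row
}

# independent histogram implementation for the complexity oracle
oracle_complexity <- function(values, m, range = c(0, 1)) {
  breaks <- seq(range[1], range[2], length.out = m + 1)
  cnt <- numeric(m)
  for (v in values) {
    placed <- FALSE
    for (b in seq_len(m)) {
      hi_ok <- if (b == m) v <= breaks[b + 1] else v < breaks[b + 1]
      if (v >= breaks[b] && hi_ok) { cnt[b] <- cnt[b] + 1; placed <- TRUE; break }
    }
    stopifnot(placed)
  }
  p <- cnt / sum(cnt)
  1 - sum(abs(p - 1 / m)) / (2 * (m - 1) / m)
}

# brute-force BH step-up: largest i with p_(i) <= i*q/m, reject the i smallest
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  imax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) imax <- i
  rej <- rep(FALSE, m)
  if (imax > 0) rej[o[seq_len(imax)]] <- TRUE
  rej
}

# data matrix with an exact sample correlation structure: columns of E are
# centered and orthonormal, so cor(E %*% t(L)) equals tcrossprod(L) scaled
exact_cor_data <- function(sigma, n = 24, seed = 1) {
  set.seed(seed)
  k <- nrow(sigma)
  raw <- matrix(rnorm(n * k), n, k)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  E <- qr.Q(qr(raw))[, seq_len(k)]
  L <- t(chol(sigma))
  E %*% t(L)
}
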
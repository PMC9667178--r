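#' Intensity normalization to percent of temporal mean
#'
#' Each voxel time series is rescaled so its temporal mean is 100, the
#' standard pre-ICA step that equalizes voxel amplitudes across the brain.
#' Voxels with zero temporal mean cannot be scaled and are dropped from the
#' mask, with a message reporting the count.
#'
#' @param data a `bold_dataset`
#' @return a `bold_dataset` with normalized values (and possibly a reduced
#'   mask)
#' @export
intensity_normalize <- function(data) {
  stopifnot(inherits(data, "bold_dataset"))
  m <- rowMeans(data$values)
  bad <- m == 0
  if (any(bad)) {
    message(sum(bad), " zero-mean voxel(s) excluded from mask")
    keep_idx <- which(!bad)
    mask <- data$mask
    mask[which(mask)[bad]] <- FALSE
    data$mask <- mask
    data$values <- data$values[keep_idx, , drop = FALSE]
    m <- m[keep_idx]
  }
  data$values <- data$values / m * 100
  data
}

#' MDL model-order selection from the eigenvalue spectrum
#'
#' Minimum-description-length criterion in the Wax–Kailath form, applied in
#' the spatial-ICA convention: voxels are the samples (n = V) and time points
#' the variables. For each candidate order k, the code term is
#' -n (T - k) log(geometric mean / arithmetic mean of the trailing
#' eigenvalues) and the penalty is k (2T - k) log(n) / 2; the estimated
#' order minimizes their sum. An equal-eigenvalue spectrum yields order 0.
#'
#' @param data V x T numeric matrix (or a `bold_dataset`)
#' @param eigenvalues optionally, a precomputed descending eigenvalue
#'   spectrum (then `data` is ignored except for the sample count `n`)
#' @param n sample count when `eigenvalues` is given
#' @return the estimated order (integer >= 0); the full criterion curve is
#'   attached as attribute `"mdl"`
#' @export
estimate_order_mdl <- function(data, eigenvalues = NULL, n = NULL) {
  if (is.null(eigenvalues)) {
    if (inherits(data, "bold_dataset")) data <- data$values
    stopifnot(is.matrix(data))
    if (ncol(data) < 3) stop("need at least 3 time points", call. = FALSE)
    n <- nrow(data)
    xc <- scale(data, center = TRUE, scale = FALSE)
    eigenvalues <- rev(eigen(crossprod(xc) / n, symmetric = TRUE,
                             only.values = TRUE)$values)
    eigenvalues <- sort(pmax(eigenvalues, .Machine$double.eps), decreasing = TRUE)
  } else {
    stopifnot(!is.null(n))
    eigenvalues <- sort(pmax(eigenvalues, .Machine$double.eps), decreasing = TRUE)
  }
  p <- length(eigenvalues)
  mdl <- numeric(p)                       # index k+1 holds order k
  for (k in 0:(p - 1)) {
    tail_ev <- eigenvalues[(k + 1):p]
    gm <- mean(log(tail_ev))
    am <- log(mean(tail_ev))
    mdl[k + 1] <- -n * (p - k) * (gm - am) + 0.5 * k * (2 * p - k) * log(n)
  }
  k_hat <- which.min(mdl) - 1L
  attr(k_hat, "mdl") <- mdl
  k_hat
}

#' PCA reduction with recorded projection
#'
#' Rows are treated as variables and columns as samples; rows are centered
#' and the data projected onto the top-k principal subspace. The orthonormal
#' projection, removed means and retained variance fraction are recorded so
#' the step can be inverted during back-reconstruction.
#'
#' @param data numeric matrix (variables x samples)
#' @param k target dimension, `1 <= k <= rank(data)`
#' @param level `"session"` or `"group"` (bookkeeping tag)
#' @return list with `reduced` (k x samples) and `step` (a `reduction_step`:
#'   `projection`, `retained_variance`, `means`, `level`)
#' @export
pca_reduce <- function(data, k, level = "session") {
  stopifnot(is.matrix(data), k >= 1)
  means <- rowMeans(data)
  xc <- data - means
  sv <- svd(xc, nu = min(dim(xc)), nv = 0)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank) {
    stop(sprintf("k = %d exceeds matrix rank %d", k, rank), call. = FALSE)
  }
  proj <- sv$u[, seq_len(k), drop = FALSE]
  step <- structure(list(projection = proj,
                         retained_variance = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2),
                         means = means, level = level),
                    class = "reduction_step")
  list(reduced = crossprod(proj, xc), step = step)
}

#' Concatenate session reductions and reduce at the group level
#'
#' Session-reduced matrices are stacked along the reduced-time axis and a
#' second PCA taken to the group dimension.
#'
#' @param session_reduced list of k_i x V matrices sharing the voxel dimension
#' @param k_group group target dimension
#' @return list with `reduced` (k_group x V), `step` (group
#'   `reduction_step`), and `blocks` (row ranges of each session in the
#'   concatenation)
#' @export
concat_group_reduce <- function(session_reduced, k_group) {
  Vs <- vapply(session_reduced, ncol, integer(1))
  if (length(unique(Vs)) != 1) stop("voxel dimensions differ across sessions", call. = FALSE)
  stacked <- do.call(rbind, session_reduced)
  rows <- vapply(session_reduced, nrow, integer(1))
  ends <- cumsum(rows)
  blocks <- Map(function(a, b) a:b, ends - rows + 1L, ends)
  out <- pca_reduce(stacked, k_group, level = "group")
  list(reduced = out$reduced, step = out$step, blocks = blocks)
}

#' Natural-gradient Infomax ICA
#'
#' Extended-free Infomax with the logistic nonlinearity, optimized by the
#' natural gradient over randomly permuted sample blocks, with learning-rate
#' annealing. The input is whitened internally; iteration stops when the
#' squared weight change per pass drops below `tol` or after `max_pass`
#' passes (the latter flags non-convergence). Sources are scaled to unit
#' (population) variance and sign-flipped so each source's largest-magnitude
#' sample is positive. With Gaussian-only sources the model is
#' rotation-invariant; the result is then flagged non-identifiable based on
#' the excess kurtosis of the recovered sources.
#'
#' @param reduced K x V numeric matrix (rows mix the sources)
#' @param seed integer seed for weight initialization and block permutations
#' @param lrate initial learning rate
#' @param max_pass maximum passes over the data
#' @param tol convergence tolerance on the squared weight change
#' @return list with `sources` (K x V, unit variance), `unmixing` (K x K,
#'   such that `unmixing %*% centered(reduced)` reproduces the sources),
#'   `converged`, and `non_identifiable`
#' @export
infomax_ica <- function(reduced, seed = 1, lrate = NULL, max_pass = 512L,
                        tol = 1e-6) {
  stopifnot(is.matrix(reduced), nrow(reduced) >= 2)
  K <- nrow(reduced); V <- ncol(reduced)
  withr_seed(seed)

  means <- rowMeans(reduced)
  xc <- reduced - means
  cv <- tcrossprod(xc) / V
  ec <- eigen(cv, symmetric = TRUE)
  wh <- diag(1 / sqrt(pmax(ec$values, 1e-12)), K) %*% t(ec$vectors)
  z <- wh %*% xc

  lrate <- lrate %||% (0.015 / log(K))
  block <- as.integer(min(V, max(8, floor(sqrt(V / 3)) * 8)))
  W <- qr.Q(qr(matrix(rnorm(K * K), K)))
  I_b <- diag(block, K)
  converged <- FALSE
  for (pass in seq_len(max_pass)) {
    W_old <- W
    perm <- sample.int(V)
    for (start in seq(1, V - block + 1, by = block)) {
      idx <- perm[start:(start + block - 1)]
      u <- W %*% z[, idx, drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + (lrate / block) * (I_b + (1 - 2 * y) %*% t(u)) %*% W
      if (!all(is.finite(W))) stop("Infomax diverged; lower the learning rate", call. = FALSE)
    }
    delta <- sum((W - W_old)^2)
    if (delta > 1e3) { lrate <- lrate * 0.5; W <- W_old; next }
    lrate <- lrate * 0.995
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("Infomax did not converge within max_pass passes", call. = FALSE)

  S <- W %*% z
  sds <- apply(S, 1, pop_sd)
  S <- S / sds
  unmix <- (W %*% wh) / sds
  # canonical sign: largest-|value| sample positive
  flips <- vapply(seq_len(K), function(k) sign(S[k, which.max(abs(S[k, ]))]), numeric(1))
  S <- S * flips
  unmix <- unmix * flips

  kurt <- apply(S, 1, function(s) mean(s^4) / mean(s^2)^2 - 3)
  structure(list(sources = S, unmixing = unmix, converged = converged,
                 non_identifiable = all(abs(kurt) < 0.5), kurtosis = kurt),
            class = "infomax_fit")
}

#' Icasso-style stability analysis
#'
#' Repeats Infomax from multiple random initializations, pools all resulting
#' sources, clusters them by absolute correlation (average linkage, K
#' clusters) and returns the cluster centrotypes as consensus sources
#' together with a per-component quality index (mean within-cluster minus
#' mean between-cluster similarity, clipped to [0, 1]).
#'
#' @param reduced K x V numeric matrix
#' @param n_runs number of restarts (>= 2)
#' @param seed base seed; run r uses `seed + r - 1` unless `seeds` is given
#' @param seeds optional explicit vector of per-run seeds
#' @return list with `sources` (consensus, K x V), `unmixing`, `quality`
#'   (length K), and `runs`
#' @export
icasso_stability <- function(reduced, n_runs = 10, seed = 1, seeds = NULL) {
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1
  if (length(seeds) < 2) stop("n_runs must be >= 2", call. = FALSE)
  K <- nrow(reduced)
  fits <- lapply(seeds, function(s) infomax_ica(reduced, seed = s))
  pooled <- do.call(rbind, lapply(fits, `[[`, "sources"))
  sim <- abs(cor(t(pooled)))
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim), method = "average"), k = K)

  quality <- numeric(K)
  centro_idx <- integer(K)
  for (g in seq_len(K)) {
    inside <- which(cl == g); outside <- which(cl != g)
    sim_in <- sim[inside, inside, drop = FALSE]
    w_in <- if (length(inside) > 1) {
      mean(sim_in[upper.tri(sim_in)])
    } else 1
    w_out <- if (length(outside)) mean(sim[inside, outside, drop = FALSE]) else 0
    quality[g] <- min(1, max(0, w_in - w_out))
    centro_idx[g] <- inside[which.max(rowSums(sim_in))]
  }
  sources <- pooled[centro_idx, , drop = FALSE]
  # coherent unmixing for the consensus set: regress sources on centered input
  xc <- reduced - rowMeans(reduced)
  unmix <- sources %*% t(xc) %*% solve(tcrossprod(xc))
  list(sources = sources, unmixing = unmix, quality = quality, runs = fits)
}

#' Group spatial ICA of multi-session BOLD data
#'
#' The full decomposition chain: per-session intensity normalization,
#' session-level PCA, concatenation and group-level PCA, Infomax with
#' Icasso-style stability, then deterministic ordering (descending explained
#' variance, ties broken by first-voxel sign then index) and canonical sign.
#'
#' @param datasets list of `bold_dataset` objects sharing the grid and mask
#' @param k_session session-level PCA dimension, or `"mdl"` to pick it by
#'   [estimate_order_mdl()] (the largest estimate across sessions)
#' @param k_group group dimension (number of components); defaults to
#'   `k_session`
#' @param n_runs Icasso restarts (set to 1 for a single Infomax fit)
#' @param seed integer seed
#' @param normalize intensity-normalize first (default TRUE)
#' @return a `group_ica` object: `group_maps` (K x V), `unmixing`,
#'   `session_steps`, `group_step`, `blocks`, `stability`, `mask`,
#'   `datasets_meta`
#' @export
group_ica <- function(datasets, k_session, k_group = NULL, n_runs = 10,
                      seed = 1, normalize = TRUE) {
  stopifnot(length(datasets) >= 1)
  if (normalize) datasets <- lapply(datasets, intensity_normalize)
  if (identical(k_session, "mdl")) {
    k_session <- max(vapply(datasets, function(d) {
      as.integer(estimate_order_mdl(d$values))
    }, integer(1)), 2L)
  }
  k_group <- k_group %||% k_session

  session_out <- lapply(datasets, function(d) pca_reduce(t(d$values), k_session))
  grp <- concat_group_reduce(lapply(session_out, `[[`, "reduced"), k_group)

  ic <- if (n_runs >= 2) {
    icasso_stability(grp$reduced, n_runs = n_runs, seed = seed)
  } else {
    fit <- infomax_ica(grp$reduced, seed = seed)
    list(sources = fit$sources, unmixing = fit$unmixing,
         quality = rep(NA_real_, k_group), runs = list(fit))
  }

  # order components by explained variance of their group-level contribution
  mixing <- solve(ic$unmixing)
  expvar <- colSums(mixing^2)
  ord <- order(-expvar, sign(ic$sources[, 1]), seq_along(expvar))
  sources <- ic$sources[ord, , drop = FALSE]
  unmix <- ic$unmixing[ord, , drop = FALSE]
  quality <- ic$quality[ord]
  flips <- vapply(seq_len(nrow(sources)),
                  function(k) sign(sources[k, which.max(abs(sources[k, ]))]),
                  numeric(1))
  flips[flips == 0] <- 1
  sources <- sources * flips
  unmix <- unmix * flips

  structure(list(group_maps = sources, unmixing = unmix,
                 session_steps = lapply(session_out, `[[`, "step"),
                 group_step = grp$step, blocks = grp$blocks,
                 group_reduced = grp$reduced,
                 stability = quality, mask = datasets[[1]]$mask,
                 tr_seconds = datasets[[1]]$tr_seconds,
                 datasets_meta = lapply(datasets, function(d) {
                   list(subject = d$subject, session = d$session,
                        n_scans = ncol(d$values))
                 }),
                 k_session = k_session, k_group = k_group, seed = seed),
            class = "group_ica")
}

#' @export
print.group_ica <- function(x, ...) {
  cat(sprintf("<group_ica> %d components, %d sessions, stability %s\n",
              nrow(x$group_maps), length(x$session_steps),
              paste(round(x$stability, 2), collapse = " ")))
  invisible(x)
}

#' GICA back-reconstruction of session-specific maps and time courses
#'
#' Session component maps and time courses are recovered by propagating the
#' group unmixing matrix back through the stored group- and session-level
#' PCA projections: with session block B_i of the group projection and group
#' mixing A, session maps solve B_i A S_i = X_i (least squares) and session
#' time courses are P_i B_i A. The product of time courses and maps
#' approximates the session's reduced data.
#'
#' @param decomp a `group_ica` object
#' @param datasets the same (normalized) datasets used for the decomposition;
#'   if omitted, only maps/time courses derivable from stored reductions are
#'   returned using the stored reduced data
#' @return a `component_set`: per session `maps` (K x V) and `time_courses`
#'   (T x K), plus mask/geometry metadata
#' @export
back_reconstruct <- function(decomp, datasets = NULL) {
  stopifnot(inherits(decomp, "group_ica"))
  K <- nrow(decomp$group_maps)
  A <- solve(decomp$unmixing)              # k_group x K mixing
  Pg <- decomp$group_step$projection       # (sum k_i) x k_group
  sessions <- vector("list", length(decomp$session_steps))
  for (i in seq_along(sessions)) {
    step_i <- decomp$session_steps[[i]]
    if (is.null(step_i)) stop("missing session reduction step", call. = FALSE)
    rows <- decomp$blocks[[i]]
    B <- Pg[rows, , drop = FALSE] %*% A    # k_i x K
    if (is.null(datasets)) stop("session data are required for back-reconstruction",
                                call. = FALSE)
    Xi <- crossprod(step_i$projection, t(datasets[[i]]$values) - step_i$means)
    maps_i <- qr.solve(B, Xi)              # K x V
    tc_i <- step_i$projection %*% B        # T x K
    sessions[[i]] <- list(maps = maps_i, time_courses = tc_i,
                          subject = decomp$datasets_meta[[i]]$subject,
                          session = decomp$datasets_meta[[i]]$session)
  }
  structure(list(sessions = sessions, mask = decomp$mask,
                 tr_seconds = decomp$tr_seconds, component_ids = seq_len(K)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d sessions x %d components\n",
              length(x$sessions), length(x$component_ids)))
  invisible(x)
}

#' Z-score component maps over in-mask voxels
#'
#' Standardizes each spatial map to mean 0, (population) variance 1 across
#' in-mask voxels — the scale on which labelling, group maps and overlap
#' analyses operate. Zero-variance maps are flagged and left unscaled.
#'
#' @param components a `component_set` (or a bare K x V matrix)
#' @return same type as the input, maps standardized; flagged components in
#'   attribute `"zero_variance"`
#' @export
zscore_components <- function(components) {
  z_mat <- function(m) {
    flagged <- integer(0)
    for (k in seq_len(nrow(m))) {
      if (pop_sd(m[k, ]) == 0) flagged <- c(flagged, k) else m[k, ] <- zscore_pop(m[k, ])
    }
    attr(m, "zero_variance") <- flagged
    m
  }
  if (is.matrix(components)) {
    out <- z_mat(components)
    if (length(attr(out, "zero_variance"))) {
      warning("zero-variance map(s) left unscaled: ",
              paste(attr(out, "zero_variance"), collapse = ", "), call. = FALSE)
    }
    return(out)
  }
  stopifnot(inherits(components, "component_set"))
  flagged <- integer(0)
  for (i in seq_along(components$sessions)) {
    m <- z_mat(components$sessions[[i]]$maps)
    flagged <- union(flagged, attr(m, "zero_variance"))
    attr(m, "zero_variance") <- NULL
    components$sessions[[i]]$maps <- m
  }
  if (length(flagged)) warning("zero-variance map(s) left unscaled: ",
                               paste(flagged, collapse = ", "), call. = FALSE)
  attr(components, "zero_variance") <- flagged
  components
}
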
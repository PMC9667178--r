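#' Ground truth for a simulated multi-network study
#'
#' Generates K sparse, smooth spatial network maps on a voxel grid (Gaussian
#' blobs thresholded to compact supports, giving super-Gaussian marginals —
#' the source class Infomax with a logistic nonlinearity identifies), a
#' K x C matrix of per-condition activity amplitudes, and a specification of
#' condition-modulated coupling between network pairs.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{n_networks}{K >= 2}
#'     \item{grid_shape}{integer vector of 3 dimensions}
#'     \item{conditions}{character vector of condition labels (non-empty)}
#'     \item{condition_betas}{optional K x C matrix; random sparse betas drawn
#'       when absent}
#'     \item{coupling}{list of `list(i, j, condition, strength)` entries
#'       (default none)}
#'     \item{noise_sd}{voxel noise standard deviation (default 1)}
#'     \item{tr_seconds}{repetition time (default 0.5)}
#'     \item{blob_sigma}{blob width in voxels (default 2)}
#'     \item{blob_threshold}{support cut as fraction of blob max (default 0.3)}
#'     \item{layout}{`"spread"` (jittered lattice, limited overlap) or
#'       `"disjoint"` (supports trimmed to be non-overlapping)}
#'   }
#' @param seed non-negative integer seed
#' @return a `ground_truth` object with fields `spatial_maps` (K x V),
#'   `condition_betas` (K x C), `coupling_spec`, `noise_sd`, `grid_shape`,
#'   `mask`, `tr_seconds`
#' @export
make_ground_truth <- function(config, seed = 1) {
  K <- config$n_networks
  grid_shape <- as.integer(config$grid_shape %||% c(20L, 20L, 10L))
  conditions <- config$conditions
  if (is.null(K) || K < 2) stop("invalid config: n_networks must be >= 2", call. = FALSE)
  if (is.null(conditions) || length(conditions) == 0) {
    stop("invalid config: empty condition set", call. = FALSE)
  }
  stopifnot(length(grid_shape) == 3)
  withr_seed(seed)

  sigma <- config$blob_sigma %||% 2
  thr <- config$blob_threshold %||% 0.3
  layout <- config$layout %||% "spread"
  V <- prod(grid_shape)
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))

  # blob centers on a jittered lattice so supports stay well separated
  n_side <- ceiling(sqrt(K))
  cx <- seq(0.5 / n_side, 1 - 0.5 / n_side, length.out = n_side)
  lattice <- as.matrix(expand.grid(cx, cx))[seq_len(K), , drop = FALSE]
  centers <- cbind(lattice[, 1] * grid_shape[1],
                   lattice[, 2] * grid_shape[2],
                   runif(K, 0.3, 0.7) * grid_shape[3])
  centers <- centers + matrix(runif(K * 3, -0.5, 0.5), K, 3)

  maps <- matrix(0, K, V)
  for (k in seq_len(K)) {
    d2 <- rowSums(sweep(coords, 2, centers[k, ])^2)
    blob <- exp(-d2 / (2 * sigma^2))
    blob[blob < thr * max(blob)] <- 0
    maps[k, ] <- blob
  }
  if (layout == "disjoint") {
    # each voxel kept only for its strongest network
    owner <- apply(maps, 2, which.max)
    for (k in seq_len(K)) maps[k, owner != k] <- 0
  }
  if (any(rowSums(abs(maps)) == 0)) {
    stop("degenerate ground truth: a network map has empty support", call. = FALSE)
  }

  C <- length(conditions)
  betas <- config$condition_betas
  if (is.null(betas)) {
    # each network loads strongly on a couple of conditions, weakly elsewhere
    betas <- matrix(runif(K * C, -0.3, 0.3), K, C)
    for (k in seq_len(K)) {
      picks <- sample(C, min(2L, C))
      betas[k, picks] <- runif(length(picks), 1, 2) * sample(c(-1, 1), length(picks),
                                                            replace = TRUE, prob = c(.25, .75))
    }
  }
  betas <- matrix(as.numeric(betas), K, C, dimnames = list(NULL, conditions))

  coupling <- config$coupling %||% list()
  for (cp in coupling) {
    stopifnot(cp$i != cp$j, is.finite(cp$strength))
    if (!cp$condition %in% conditions) {
      stop("coupling references unknown condition: ", cp$condition, call. = FALSE)
    }
  }

  structure(list(
    spatial_maps = maps,
    condition_betas = betas,
    coupling_spec = coupling,
    noise_sd = config$noise_sd %||% 1,
    grid_shape = grid_shape,
    mask = array(TRUE, grid_shape),
    tr_seconds = config$tr_seconds %||% 0.5,
    conditions = conditions,
    seed = seed
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d networks, grid %s, %d conditions, %d coupling entries\n",
              nrow(x$spatial_maps), paste(x$grid_shape, collapse = "x"),
              ncol(x$condition_betas), length(x$coupling_spec)))
  invisible(x)
}

#' Construct a BOLD dataset container
#'
#' Masked voxel x time matrix with grid geometry, TR and subject/session ids.
#'
#' @param values V x T numeric matrix (in-mask voxels by time points)
#' @param mask logical 3D array; `sum(mask)` must equal `nrow(values)`
#' @param tr_seconds repetition time
#' @param subject,session identifiers
#' @return a `bold_dataset` object
#' @export
bold_dataset <- function(values, mask, tr_seconds, subject = 1L, session = 1L) {
  stopifnot(is.matrix(values), sum(mask) == nrow(values), all(is.finite(values)))
  assert_scalar_pos(tr_seconds, "tr_seconds")
  structure(list(values = values, mask = mask, grid_shape = dim(mask),
                 tr_seconds = tr_seconds, subject = subject, session = session),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("<bold_dataset> sub %s ses %s: %d voxels x %d scans (TR = %gs)\n",
              x$subject, x$session, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

# nuisance bundle: linear drift + 6 AR(1) motion-like series + global signal
# + CSF/WM/aCompCor-like AR noise columns, named like a confound table
make_confounds <- function(n_scans) {
  ar <- function(rho = 0.95) as.numeric(stats::filter(rnorm(n_scans), rho, "recursive"))
  cols <- c(
    list(csf = ar(), wm = ar(), global = ar(0.8), drift = seq(-1, 1, length.out = n_scans)),
    setNames(lapply(1:6, function(i) ar()), paste0("compcor", 1:6)),
    setNames(lapply(1:6, function(i) ar()), paste0("motion", 1:6))
  )
  out <- do.call(cbind, cols)
  scale(out, center = TRUE, scale = apply(out, 2, pop_sd))[, , drop = FALSE]
}

#' Simulate a multi-subject, multi-session task-fMRI study
#'
#' For each subject and session, network time courses are built as the sum of
#' HRF-convolved condition regressors weighted by the ground-truth betas, a
#' condition-modulated shared latent signal for each coupled pair (the
#' interaction structure cPPI detects), and white noise. Voxel data are the
#' spatial mixture of those time courses plus voxel noise and nuisance
#' signals (drift, motion-like AR series, global signal), on top of a
#' constant baseline. The injected nuisance regressors are returned in each
#' session's confound table.
#'
#' @param truth a `ground_truth` object
#' @param n_subjects,n_sessions at least 1 each
#' @param events a single event table reused for every session, or a list of
#'   length `n_sessions`
#' @param seed master integer seed; every subject/session stream is derived
#'   from it
#' @param tc_noise_sd white-noise sd on network time courses (default 0.2)
#' @param nuisance_scale amplitude of injected nuisance signals (default 0.5)
#' @param baseline constant added to every voxel (default 1000, so intensity
#'   normalization to percent-of-mean is well posed)
#' @param coupling_signal_sd sd of the shared latent coupling signal
#' @return a `simulated_study`: list of sessions (`bold`, `events`,
#'   `confounds`, `network_tc`, subject/session ids), plus `truth` and `seed`
#' @export
simulate_study <- function(truth, n_subjects, n_sessions, events, seed = 1,
                           tc_noise_sd = 0.2, nuisance_scale = 0.5,
                           baseline = 1000, coupling_signal_sd = 1) {
  stopifnot(inherits(truth, "ground_truth"), n_subjects >= 1, n_sessions >= 1)
  events_list <- if (inherits(events, "data.frame")) {
    rep(list(events), n_sessions)
  } else events
  stopifnot(length(events_list) == n_sessions)
  for (ev in events_list) {
    unknown <- setdiff(unique(ev$trial_type), truth$conditions)
    if (length(unknown)) {
      stop("unknown condition in events: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  K <- nrow(truth$spatial_maps)
  V <- ncol(truth$spatial_maps)
  sessions <- list()
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(n_sessions)) {
      withr_seed(derive_seed(seed, sprintf("sub%03d_ses%03d", s, r)))
      ev <- events_list[[r]]
      # infer run length from the last event, rounded up to whole scans + tail
      n_scans <- ceiling((max(ev$onset + ev$duration) + 20) / truth$tr_seconds)
      X <- condition_regressors(ev, n_scans, truth$tr_seconds,
                                conditions = truth$conditions)
      tc <- X %*% t(truth$condition_betas)                       # T x K
      for (cp in truth$coupling_spec) {
        shared <- rnorm(n_scans, sd = coupling_signal_sd)
        gate <- X[, cp$condition]
        tc[, cp$i] <- tc[, cp$i] + cp$strength * gate * shared
        tc[, cp$j] <- tc[, cp$j] + cp$strength * gate * shared
      }
      tc <- tc + matrix(rnorm(n_scans * K, sd = tc_noise_sd), n_scans, K)

      conf <- make_confounds(n_scans)
      spat_w <- matrix(rnorm(ncol(conf) * V, sd = 0.1), ncol(conf), V)
      y <- crossprod(truth$spatial_maps, t(tc))                  # V x T
      y <- y + t(conf %*% spat_w) * nuisance_scale
      y <- y + matrix(rnorm(V * n_scans, sd = truth$noise_sd), V, n_scans)
      y <- y + baseline

      sessions[[length(sessions) + 1L]] <- list(
        bold = bold_dataset(y[as.vector(truth$mask), , drop = FALSE], truth$mask,
                            truth$tr_seconds, subject = s, session = r),
        events = ev,
        confounds = tibble::as_tibble(as.data.frame(conf)),
        network_tc = tc,
        subject = s, session = r
      )
    }
  }
  structure(list(sessions = sessions, truth = truth, seed = seed,
                 n_subjects = n_subjects, n_sessions = n_sessions),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d subjects x %d sessions (%d runs)\n",
              x$n_subjects, x$n_sessions, length(x$sessions)))
  invisible(x)
}

#' Toy binary masks from explicit voxel index sets
#'
#' Fixture helper: builds binary 3D maps with exactly the requested supports,
#' for hand-countable Jaccard / overlap / cluster tests.
#'
#' @param spec list of integer vectors of linear voxel indices
#' @param grid_shape integer vector of 3 dimensions
#' @return list of 0/1 arrays of dimension `grid_shape`
#' @export
make_toy_masks <- function(spec, grid_shape) {
  V <- prod(grid_shape)
  lapply(spec, function(idx) {
    idx <- as.integer(idx)
    if (length(idx) && (min(idx) < 1 || max(idx) > V)) {
      stop("voxel index out of range for grid", call. = FALSE)
    }
    m <- array(0, grid_shape)
    m[idx] <- 1
    m
  })
}
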
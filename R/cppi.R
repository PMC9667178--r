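#' Psychological contrast regressor
#'
#' Difference of the HRF-convolved target and control condition regressors,
#' mean-centered — the psychological term of a PPI for one task.
#'
#' @param design a `design_matrix` containing canonical condition columns
#' @param target,control condition column names
#' @param task optional task label carried along
#' @return a `psych_regressor`: numeric vector with attributes `task`,
#'   `contrast`
#' @export
psych_contrast <- function(design, target, control, task = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  for (nm in c(target, control)) {
    if (!nm %in% design$names) stop("condition not in design: ", nm, call. = FALSE)
  }
  v <- design$values[, target] - design$values[, control]
  v <- v - mean(v)
  if (all(v == 0)) stop("degenerate psychological regressor (identically zero)",
                        call. = FALSE)
  structure(v, task = task %||% paste(target, "vs", control),
            contrast = c(target = target, control = control),
            class = "psych_regressor")
}

#' PPI interaction term
#'
#' Element-wise product of the mean-centered neural time course and the
#' mean-centered psychological regressor.
#'
#' @param time_course numeric vector
#' @param psych numeric vector of equal length (centered internally)
#' @return numeric vector of the same length; an all-zero result carries
#'   attribute `degenerate = TRUE`
#' @export
ppi_term <- function(time_course, psych) {
  if (length(time_course) != length(psych)) {
    stop("time course and psychological regressor lengths differ", call. = FALSE)
  }
  out <- (time_course - mean(time_course)) * (psych - mean(psych))
  if (all(out == 0)) attr(out, "degenerate") <- TRUE
  out
}

#' Partial correlation of two vectors given controls
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the control
#' matrix plus an intercept; the p-value comes from
#' t = r sqrt(df / (1 - r^2)) with df = n - 2 - q controls, two-sided.
#'
#' @param x,y numeric vectors
#' @param controls numeric matrix (n x q) or NULL for a plain correlation
#' @return list with `r`, `p`, `df`
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(controls)) 0L else ncol(as.matrix(controls))
  if (n <= q + 2) stop("insufficient degrees of freedom for partial correlation",
                       call. = FALSE)
  if (q > 0) {
    Z <- cbind(1, as.matrix(controls))
    qz <- qr(Z)
    rx <- qr.resid(qz, x)
    ry <- qr.resid(qz, y)
    q <- qz$rank - 1L                     # effective controls after rank drop
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))
  df <- n - 2L - q
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(r = r, p = p, df = df)
}

#' cPPI network-interaction matrix for one subject and task
#'
#' For every unordered network pair (i, j), the partial correlation between
#' the two PPI terms (time course x psychological contrast), controlling for
#' all design-matrix columns, all confound columns, and the time courses of
#' the K - 2 remaining networks. Sessions should be concatenated beforehand.
#'
#' @param time_courses T x K matrix of network time courses
#'   (session-concatenated)
#' @param design a `design_matrix` (session-concatenated; its constant
#'   column is dropped from the controls, the residualization adds its own
#'   intercept)
#' @param confounds numeric matrix / data frame of confound columns or NULL
#' @param psych a `psych_regressor` from [psych_contrast()]
#' @param subject,task identifiers stored on the result
#' @return an `interaction_matrix`: `r` and `p` (K x K symmetric, NA
#'   diagonal), `subject`, `task`
#' @export
cppi_matrix <- function(time_courses, design, confounds, psych,
                        subject = NA, task = NULL) {
  stopifnot(is.matrix(time_courses))
  K <- ncol(time_courses)
  if (K < 3) stop("need at least 3 networks", call. = FALSE)
  if (!is.null(attr(ppi_term(time_courses[, 1], psych), "degenerate")) &&
      all(psych == 0)) stop("degenerate psychological regressor", call. = FALSE)
  X_design <- design$values[, design$roles != "constant", drop = FALSE]
  X_conf <- if (is.null(confounds)) NULL else as.matrix(confounds)
  ppi <- apply(time_courses, 2, ppi_term, psych = psych)

  R <- matrix(NA_real_, K, K); P <- matrix(NA_real_, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      ctrl <- cbind(X_design, X_conf, time_courses[, -c(i, j), drop = FALSE])
      pc <- partial_correlation(ppi[, i], ppi[, j], ctrl)
      R[i, j] <- R[j, i] <- pc$r
      P[i, j] <- P[j, i] <- pc$p
    }
  }
  structure(list(r = R, p = P, subject = subject,
                 task = task %||% attr(psych, "task")),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d networks, subject %s, task %s\n",
              nrow(x$r), x$subject, x$task))
  invisible(x)
}

#' Long-format view of interaction matrices
#'
#' @param matrices list of `interaction_matrix` objects
#' @return tibble: `subject`, `task`, `net_i`, `net_j`, `r`, `p` (upper
#'   triangle only)
#' @export
interaction_long <- function(matrices) {
  purrr::map(matrices, function(m) {
    K <- nrow(m$r)
    ut <- which(upper.tri(m$r), arr.ind = TRUE)
    tibble::tibble(subject = m$subject, task = m$task,
                   net_i = ut[, 1], net_j = ut[, 2],
                   r = m$r[ut], p = m$p[ut])
  }) |> dplyr::bind_rows()
}

#' Group-level significance of network interactions
#'
#' Per network pair, a one-sample two-sided t-test across subjects on the
#' Fisher-z transformed partial correlations, Bonferroni-corrected across
#' the task contrasts (factor 3 in the reference analysis). Reported mean
#' and SD are of the raw r values.
#'
#' @param matrices list of per-subject `interaction_matrix` for one task
#' @param n_tests Bonferroni factor (default 3)
#' @return tibble: `task`, `net_i`, `net_j`, `mean_r`, `sd_r`, `t`, `df`,
#'   `p`, `p_corrected`, `significant`
#' @export
group_interaction_tests <- function(matrices, n_tests = 3) {
  if (length(matrices) < 3) stop("need at least 3 subjects", call. = FALSE)
  long <- interaction_long(matrices)
  long |>
    dplyr::group_by(.data$task, .data$net_i, .data$net_j) |>
    dplyr::summarise(
      mean_r = mean(.data$r), sd_r = sd(.data$r),
      t = one_sample_t(atanh(pmax(pmin(.data$r, 1 - 1e-12), -1 + 1e-12)))$t,
      df = dplyr::n() - 1,
      p = one_sample_t(atanh(pmax(pmin(.data$r, 1 - 1e-12), -1 + 1e-12)))$p,
      .groups = "drop") |>
    dplyr::mutate(p_corrected = pmin(1, .data$p * n_tests),
                  significant = .data$p_corrected < 0.05)
}

# one-sample two-sided t with explicit zero-variance handling: identically
# zero samples give t = 0 / p = 1; a constant nonzero sample an infinite t
one_sample_t <- function(x) {
  n <- length(x)
  if (sd(x) == 0) {
    if (mean(x) == 0) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(x)), p = 0))
  }
  tstat <- mean(x) / (sd(x) / sqrt(n))
  list(t = tstat, p = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE))
}

#' Repeated-measures ANOVA of interactions across tasks
#'
#' Per network pair, a one-factor within-subject ANOVA of the Fisher-z
#' interaction values over task (numerator df = #tasks - 1), Bonferroni-
#' corrected over the 55 pairs; for significant pairs, post-hoc paired
#' t-tests between all task pairs at p < 0.05.
#'
#' @param matrices_by_task named list (task -> list of per-subject
#'   `interaction_matrix`), same subjects in the same order per task
#' @param n_tests Bonferroni factor over pairs (default: number of pairs)
#' @return list with `anova` (tibble: `net_i`, `net_j`, `F`, `df1`, `df2`,
#'   `p`, `p_corrected`, `significant`) and `posthoc` (tibble per significant
#'   pair and task pair: `t`, `df`, `p`, `mean_diff_r`)
#' @export
interaction_anova <- function(matrices_by_task, n_tests = NULL) {
  tasks <- names(matrices_by_task)
  stopifnot(length(tasks) >= 2)
  ns <- vapply(matrices_by_task, length, integer(1))
  if (length(unique(ns)) != 1) stop("unbalanced subjects across tasks", call. = FALSE)
  long <- purrr::imap(matrices_by_task, function(ms, tk) {
    dplyr::mutate(interaction_long(ms), task = tk)
  }) |> dplyr::bind_rows()
  long$z <- atanh(pmax(pmin(long$r, 1 - 1e-12), -1 + 1e-12))

  pairs <- dplyr::distinct(long, .data$net_i, .data$net_j)
  n_tests <- n_tests %||% nrow(pairs)

  anova_rows <- purrr::pmap(pairs, function(net_i, net_j) {
    d <- long[long$net_i == net_i & long$net_j == net_j, ]
    d$task <- factor(d$task); d$subject <- factor(d$subject)
    # identical values across tasks within every subject: no task effect
    if (max(abs(d$z - stats::ave(d$z, d$subject))) == 0) {
      return(tibble::tibble(net_i = net_i, net_j = net_j, F = 0,
                            df1 = length(tasks) - 1,
                            df2 = (length(tasks) - 1) * (nlevels(d$subject) - 1),
                            p = 1))
    }
    fit <- aov(z ~ task + Error(subject), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    tibble::tibble(net_i = net_i, net_j = net_j,
                   F = tab["task", "F value"],
                   df1 = tab["task", "Df"], df2 = tab["Residuals", "Df"],
                   p = tab["task", "Pr(>F)"])
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(F = ifelse(is.na(.data$F), 0, .data$F),
                  p = ifelse(is.na(.data$p), 1, .data$p),
                  p_corrected = pmin(1, .data$p * n_tests),
                  significant = .data$p_corrected < 0.05)

  task_pairs <- utils::combn(tasks, 2, simplify = FALSE)
  sig <- anova_rows[anova_rows$significant, c("net_i", "net_j")]
  posthoc <- purrr::pmap(sig, function(net_i, net_j) {
    purrr::map(task_pairs, function(tp) {
      a <- long[long$net_i == net_i & long$net_j == net_j & long$task == tp[1], ]
      b <- long[long$net_i == net_i & long$net_j == net_j & long$task == tp[2], ]
      b <- b[match(a$subject, b$subject), ]
      diffs <- a$z - b$z
      ht <- one_sample_t(diffs)
      tstat <- ht$t; pval <- ht$p; df <- length(diffs) - 1
      tibble::tibble(net_i = net_i, net_j = net_j,
                     task_a = tp[1], task_b = tp[2],
                     mean_diff_r = mean(a$r) - mean(b$r),
                     t = tstat, df = df, p = pval)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  list(anova = anova_rows, posthoc = posthoc)
}

#' Task-difference edge list
#'
#' Edges between networks whose interaction differs between two tasks:
#' pairs that are significant in the cross-task ANOVA and in the post-hoc
#' paired test for this task pair, weighted by the mean r difference
#' (task A minus task B), sign retained.
#'
#' @param anova_result output of [interaction_anova()]
#' @param task_a,task_b task labels (order sets the sign of the weight)
#' @param alpha post-hoc significance level (default 0.05)
#' @return tibble: `net_i`, `net_j`, `weight`
#' @export
difference_graph <- function(anova_result, task_a, task_b, alpha = 0.05) {
  ph <- anova_result$posthoc
  if (is.null(ph) || nrow(ph) == 0) {
    return(tibble::tibble(net_i = integer(), net_j = integer(), weight = numeric()))
  }
  sel <- ph[(ph$task_a == task_a & ph$task_b == task_b) |
              (ph$task_a == task_b & ph$task_b == task_a), ]
  sel <- sel[sel$p < alpha, ]
  if (nrow(sel) == 0) {
    return(tibble::tibble(net_i = integer(), net_j = integer(), weight = numeric()))
  }
  flip <- ifelse(sel$task_a == task_a, 1, -1)
  tibble::tibble(net_i = sel$net_i, net_j = sel$net_j,
                 weight = sel$mean_diff_r * flip)
}

#' Signed significance display scaling
#'
#' The matrix display convention: -sign(r) * log10(p), combining the sign
#' and strength of an interaction with its significance. p = 0 is clipped
#' to the smallest positive double with a warning.
#'
#' @param r correlation value(s)
#' @param p p-value(s) in (0, 1]
#' @return numeric vector
#' @export
display_scale <- function(r, p) {
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 clipped to machine minimum", call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  -sign(r) * log10(p)
}

#' Type-I error calibration of the per-pair group cPPI test
#'
#' Simulates null studies (network time courses with no condition-modulated
#' coupling), computes the per-subject cPPI partial correlation for one
#' network pair, and applies the group-level test actually used for
#' inference: a one-sample t-test across subjects on the Fisher-z
#' correlations. The observed rejection rate at `alpha` over many null
#' replicates measures calibration.
#'
#' The per-subject parametric p-value from [partial_correlation()] is known
#' to be anticonservative for PPI products (the shared psychological factor
#' makes the product series heteroscedastic), which is why group inference
#' across subjects — exact under the null by symmetry — is the calibrated
#' quantity.
#'
#' @param n_reps number of null replicates (default 1000)
#' @param n_scans series length per replicate (default 150)
#' @param n_subjects subjects per replicate entering the group test
#'   (default 8)
#' @param n_networks number of networks simulated (>= 3; the extra networks
#'   enter the controls)
#' @param alpha nominal level (default 0.05)
#' @param seed integer seed
#' @return observed rejection rate (proportion of replicates with group
#'   p < alpha)
#' @export
cppi_null_rejection_rate <- function(n_reps = 1000, n_scans = 150,
                                     n_subjects = 8, n_networks = 3,
                                     alpha = 0.05, seed = 1) {
  stopifnot(n_networks >= 3)
  ev <- simulate_events(c("tg", "ct"), n_scans, 0.5, trials_per_condition = 8,
                        duration = 2, seed = seed)
  dm <- build_design_matrix(ev, n_scans, 0.5, basis_kind = "canonical")
  psych <- psych_contrast(dm, "tg", "ct")
  X_design <- dm$values[, dm$roles != "constant", drop = FALSE]
  withr_seed(derive_seed(seed, "cppi-null"))
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    rs <- vapply(seq_len(n_subjects), function(s) {
      tc <- matrix(rnorm(n_scans * n_networks), n_scans, n_networks)
      ctrl <- cbind(X_design, tc[, -c(1, 2), drop = FALSE])
      partial_correlation(ppi_term(tc[, 1], psych),
                          ppi_term(tc[, 2], psych), ctrl)$r
    }, numeric(1))
    rej[r] <- one_sample_t(atanh(rs))$p < alpha
  }
  mean(rej)
}
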
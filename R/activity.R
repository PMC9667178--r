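#' Temporal sorting: regress a component time course on the design
#'
#' Multiple OLS regression of one component time course on all design-matrix
#' columns; returns the per-regressor betas and the model R-squared. The
#' design must be full column rank.
#'
#' @param time_course numeric vector of length T
#' @param design a `design_matrix` with T rows
#' @return a tibble with columns `regressor`, `role`, `beta`, and attribute
#'   `"r_squared"`
#' @export
temporal_sort <- function(time_course, design) {
  stopifnot(inherits(design, "design_matrix"),
            length(time_course) == nrow(design$values))
  X <- design$values
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, time_course)
  yc <- time_course - mean(time_course)
  r2 <- if (sum(yc^2) == 0) NA_real_ else 1 - sum(fit$residuals^2) / sum(yc^2)
  out <- tibble::tibble(regressor = colnames(X), role = design$roles,
                        beta = unname(fit$coefficients[colnames(X)]))
  attr(out, "r_squared") <- r2
  out
}

#' Temporal sorting for a whole study
#'
#' Runs [temporal_sort()] for every session and component of a
#' `component_set` against per-session designs.
#'
#' @param components a `component_set`
#' @param designs list of `design_matrix`, one per session in order
#' @return a `beta_table` tibble: `subject`, `session`, `component`,
#'   `regressor`, `role`, `beta`
#' @export
sort_components <- function(components, designs) {
  stopifnot(inherits(components, "component_set"),
            length(designs) == length(components$sessions))
  rows <- purrr::imap(components$sessions, function(ses, i) {
    tc <- ses$time_courses
    purrr::map(seq_len(ncol(tc)), function(k) {
      b <- temporal_sort(tc[, k], designs[[i]])
      dplyr::mutate(b, subject = ses$subject, session = ses$session,
                    component = k, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("beta_table", class(rows))
  rows
}

#' Average betas across sessions
#'
#' Session-level canonical-basis ("primary") betas are averaged per
#' (subject, component, condition); derivative, nuisance and constant
#' columns are excluded. Missing cells are dropped with a message.
#'
#' @param betas a `beta_table` from [sort_components()]
#' @return tibble: `subject`, `component`, `condition`, `beta`
#' @export
aggregate_betas <- function(betas) {
  prim <- dplyr::filter(betas, .data$role == "condition")
  n_sessions <- length(unique(prim$session))
  out <- prim |>
    dplyr::group_by(.data$subject, .data$component, condition = .data$regressor) |>
    dplyr::summarise(n = dplyr::n(), beta = mean(.data$beta), .groups = "drop")
  if (any(out$n < n_sessions)) {
    message(sum(out$n < n_sessions), " cell(s) missing sessions; averaged over available")
  }
  dplyr::select(out, -"n")
}

#' Paired condition contrast per component
#'
#' Two-sided paired t-test on per-subject session-averaged beta differences
#' (condition A minus condition B) for every component, Bonferroni-corrected
#' for `n_tests` tests (the study-wide family; 66 = 11 components x 6
#' contrasts in the reference analysis).
#'
#' @param betas session-averaged beta table from [aggregate_betas()]
#' @param condition_a,condition_b condition labels to contrast
#' @param n_tests Bonferroni family size (default 66)
#' @return tibble per component: `component`, `contrast`, `mean_diff`, `t`,
#'   `df`, `p`, `p_corrected`, `correction`, `sidedness`
#' @export
paired_contrast_test <- function(betas, condition_a, condition_b, n_tests = 66) {
  wide <- betas |>
    dplyr::filter(.data$condition %in% c(condition_a, condition_b)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "beta")
  if (!all(c(condition_a, condition_b) %in% names(wide))) {
    stop("conditions not found in beta table", call. = FALSE)
  }
  purrr::map(sort(unique(wide$component)), function(k) {
    d <- wide[wide$component == k, ]
    if (nrow(d) < 2) stop("need at least 2 subjects", call. = FALSE)
    if (nrow(d) == 2 && k == sort(unique(wide$component))[1]) {
      warning("only 2 subjects: paired tests have a single degree of freedom",
              call. = FALSE)
    }
    diffs <- d[[condition_a]] - d[[condition_b]]
    if (sd(diffs) == 0) {
      warning("zero-variance differences for component ", k, call. = FALSE)
      tstat <- if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs))
      pval <- if (mean(diffs) == 0) 1 else 0
      df <- length(diffs) - 1
    } else {
      ht <- t.test(diffs)
      tstat <- unname(ht$statistic); df <- unname(ht$parameter); pval <- ht$p.value
    }
    tibble::tibble(component = k,
                   contrast = paste(condition_a, "vs", condition_b),
                   mean_diff = mean(diffs), t = tstat, df = df, p = pval,
                   p_corrected = min(1, pval * n_tests),
                   correction = paste0("bonferroni-", n_tests),
                   sidedness = "two-sided")
  }) |> dplyr::bind_rows()
}
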
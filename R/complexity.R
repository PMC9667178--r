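#' Histogram bin probabilities on a fixed range
#'
#' Equal-width bins spanning `range` (default [0, 1]), left-closed /
#' right-open except the last bin, which also includes the right edge, so a
#' value of exactly 1 lands in bin m. Probabilities are counts normalized to
#' sum 1.
#'
#' @param values numeric vector (at least one value inside the range)
#' @param m number of bins (>= 2)
#' @param range length-2 numeric bin range
#' @return numeric vector of m probabilities summing to 1
#' @export
bin_probabilities <- function(values, m, range = c(0, 1)) {
  if (m < 2) stop("need at least 2 bins", call. = FALSE)
  if (length(values) == 0) stop("no values to bin (degenerate subject)", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = m + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  if (any(idx < 1 | idx > m)) stop("values outside the bin range", call. = FALSE)
  counts <- tabulate(idx, nbins = m)
  counts / sum(counts)
}

#' Functional complexity of a connectivity distribution
#'
#' C = 1 - (1/C_m) * sum over bins |p(bin) - 1/m|, with normalization
#' C_m = 2 (m - 1) / m, the maximal attainable total deviation from the
#' uniform distribution. C is 1 for exactly uniform bin occupancy and 0 when
#' all mass falls in a single bin; the result is clipped to [0, 1].
#'
#' @param values positive correlation values in the bin range
#' @param m number of bins
#' @param range histogram range (default [0, 1])
#' @return C in [0, 1]
#' @export
functional_complexity <- function(values, m, range = c(0, 1)) {
  p <- bin_probabilities(values, m, range)
  c_m <- 2 * (m - 1) / m
  C <- 1 - sum(abs(p - 1 / m)) / c_m
  min(1, max(0, C))
}

#' Complexity profile of an interaction matrix
#'
#' Extracts the positive upper-triangle partial correlations of a subject's
#' task-specific interaction matrix and evaluates functional complexity at
#' each requested bin count, plus the bin-averaged value.
#'
#' @param matrix an `interaction_matrix` (or bare symmetric matrix)
#' @param bins bin counts (default 10, 15, 20, 25, 30, 35, 40)
#' @param range histogram range (default [0, 1])
#' @return one-row tibble: `subject`, `task`, `n_positive`, one `C_m<bins>`
#'   column per bin count, and `C_mean`
#' @export
complexity_profile <- function(matrix, bins = c(10, 15, 20, 25, 30, 35, 40),
                               range = c(0, 1)) {
  if (inherits(matrix, "interaction_matrix")) {
    vals <- matrix$r[upper.tri(matrix$r)]
    subject <- matrix$subject; task <- matrix$task
  } else {
    vals <- matrix[upper.tri(matrix)]
    subject <- NA; task <- NA_character_
  }
  pos <- vals[!is.na(vals) & vals > 0]
  if (length(pos) == 0) stop("no positive interactions; subject excluded", call. = FALSE)
  Cs <- vapply(bins, function(m) functional_complexity(pos, m, range), numeric(1))
  out <- tibble::tibble(subject = subject, task = task, n_positive = length(pos))
  for (i in seq_along(bins)) out[[paste0("C_m", bins[i])]] <- Cs[i]
  out$C_mean <- mean(Cs)
  out
}

#' Complexity for a set of interaction matrices
#'
#' @param matrices list of `interaction_matrix` objects
#' @inheritParams complexity_profile
#' @return tibble with one row per matrix; subjects with no positive
#'   interactions are dropped with a message
#' @export
complexity_table <- function(matrices, bins = c(10, 15, 20, 25, 30, 35, 40),
                             range = c(0, 1)) {
  rows <- purrr::map(matrices, function(m) {
    tryCatch(complexity_profile(m, bins, range), error = function(e) NULL)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) message(dropped, " subject(s) with no positive interactions dropped")
  dplyr::bind_rows(rows)
}

#' Paired task comparisons of per-subject values
#'
#' Paired t-tests between tasks on per-subject scalar values (bin-averaged
#' complexity, or mean response times). One-sided by default with the
#' lower-tail convention p = P(T <= t) for the (task A - task B) difference,
#' i.e. testing whether task B exceeds task A.
#'
#' @param data tibble with columns `subject`, `task`, and the value column
#' @param value name of the value column (default `"C_mean"`)
#' @param sidedness `"one-sided"` (lower tail) or `"two-sided"`
#' @return tibble per task pair: `task_a`, `task_b`, `mean_diff`, `t`, `df`,
#'   `p`, `sidedness`
#' @export
compare_tasks <- function(data, value = "C_mean",
                          sidedness = c("one-sided", "two-sided")) {
  sidedness <- match.arg(sidedness)
  tasks <- unique(data$task)
  task_pairs <- utils::combn(tasks, 2, simplify = FALSE)
  purrr::map(task_pairs, function(tp) {
    a <- data[data$task == tp[1], c("subject", value)]
    b <- data[data$task == tp[2], c("subject", value)]
    if (!setequal(a$subject, b$subject) || anyDuplicated(a$subject)) {
      stop("unpaired subjects across tasks", call. = FALSE)
    }
    b <- b[match(a$subject, b$subject), ]
    diffs <- a[[value]] - b[[value]]
    n <- length(diffs); df <- n - 1
    tstat <- if (sd(diffs) == 0) 0 else mean(diffs) / (sd(diffs) / sqrt(n))
    p <- t_to_p(tstat, df, sidedness)
    tibble::tibble(task_a = tp[1], task_b = tp[2], mean_diff = mean(diffs),
                   t = tstat, df = df, p = p, sidedness = sidedness)
  }) |> dplyr::bind_rows()
}

#' Map a t statistic to a p-value
#'
#' The tail-area convention used for the complexity and response-time
#' comparisons: one-sided p is the lower-tail area P(T <= t) (a negative t
#' means the second task exceeds the first), two-sided the usual symmetric
#' tail area.
#'
#' @param t t statistic
#' @param df degrees of freedom
#' @param sidedness `"one-sided"` or `"two-sided"`
#' @return p-value
#' @export
t_to_p <- function(t, df, sidedness = c("one-sided", "two-sided")) {
  sidedness <- match.arg(sidedness)
  if (sidedness == "one-sided") pt(t, df) else 2 * pt(abs(t), df, lower.tail = FALSE)
}
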
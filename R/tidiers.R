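#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group ICA decomposition
#'
#' One row per component with its stability index and group-map summary
#' statistics.
#'
#' @param x a `group_ica` object
#' @param ... unused
#' @return tibble: `component`, `stability`, `map_max_z`, `map_positive_frac`
#' @method tidy group_ica
#' @export
tidy.group_ica <- function(x, ...) {
  K <- nrow(x$group_maps)
  tibble::tibble(
    component = seq_len(K),
    stability = x$stability,
    map_max_z = apply(x$group_maps, 1, function(v) max(abs(v))),
    map_positive_frac = apply(x$group_maps, 1, function(v) mean(v > 0))
  )
}

#' @rdname tidy.group_ica
#' @return for `glance`: one-row tibble with `n_components`, `n_sessions`,
#'   `k_session`, `k_group`, `retained_variance_group`, `min_stability`
#' @export
glance.group_ica <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$group_maps),
    n_sessions = length(x$session_steps),
    k_session = x$k_session,
    k_group = x$k_group,
    retained_variance_group = x$group_step$retained_variance,
    min_stability = if (all(is.na(x$stability))) NA_real_ else min(x$stability, na.rm = TRUE)
  )
}

#' Tidy an interaction matrix
#'
#' @param x an `interaction_matrix`
#' @param ... unused
#' @return long tibble: `subject`, `task`, `net_i`, `net_j`, `r`, `p`
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) interaction_long(list(x))

#' Heatmap of a cPPI interaction matrix
#'
#' Upper triangle shows partial correlations, lower triangle the signed
#' significance scaling -sign(r) log10(p).
#'
#' @param object an `interaction_matrix`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  K <- nrow(object$r)
  df <- expand.grid(i = seq_len(K), j = seq_len(K))
  df$value <- ifelse(df$i < df$j, object$r[cbind(df$i, df$j)],
                     ifelse(df$i > df$j,
                            display_scale(object$r[cbind(df$i, df$j)],
                                          pmax(object$p[cbind(df$i, df$j)],
                                               .Machine$double.xmin)),
                            NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r / -sign(r)log10(p)",
                  title = sprintf("cPPI interactions: %s", object$task)) +
    ggplot2::theme_minimal()
}

#' Per-subject complexity by task
#'
#' Points and group means of bin-averaged functional complexity by task.
#'
#' @param data a complexity tibble from [complexity_table()] (columns
#'   `subject`, `task`, `C_mean`)
#' @return a ggplot object
#' @export
plot_complexity <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$task, y = .data$C_mean)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = "functional complexity (bin-averaged C)") +
    ggplot2::theme_minimal()
}

#' Axial montage of a participation map
#'
#' @param object a `participation_map`
#' @param ... unused
#' @return a ggplot object (tile montage over slices)
#' @method autoplot participation_map
#' @export
autoplot.participation_map <- function(object, ...) {
  dims <- dim(object$counts)
  df <- do.call(rbind, lapply(seq_len(dims[3]), function(z) {
    g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
    g$z <- z; g$count <- as.vector(object$counts[, , z]); g
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$count))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z) +
    ggplot2::scale_fill_viridis_d(option = "B") +
    ggplot2::labs(fill = "networks", title = sprintf("%s (%s)", object$task, object$sign)) +
    ggplot2::theme_void()
}
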
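#' Event tables
#'
#' An event table is a tibble with columns `onset` (seconds), `duration`
#' (seconds) and `trial_type` (condition label), one row per stimulus.
#'
#' @param onset,duration numeric vectors (seconds, >= 0)
#' @param trial_type character vector of condition labels
#' @return a tibble with class checks applied
#' @export
event_table <- function(onset, duration, trial_type) {
  stopifnot(length(onset) == length(duration), length(onset) == length(trial_type))
  if (any(onset < 0) || any(duration < 0)) {
    stop("event onsets and durations must be non-negative", call. = FALSE)
  }
  tibble::tibble(onset = as.numeric(onset), duration = as.numeric(duration),
                 trial_type = as.character(trial_type))
}

#' Read / write BIDS-style events TSV
#'
#' Columns onset, duration, trial_type; seconds with decimal point.
#' @param path file path
#' @param events an event table
#' @return `read_events` returns a tibble; `write_events` returns `path`
#'   invisibly
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  event_table(ev$onset, ev$duration, ev$trial_type)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' Construct a design matrix object
#' @keywords internal
new_design_matrix <- function(values, roles, tr_seconds) {
  stopifnot(is.matrix(values), length(roles) == ncol(values))
  structure(list(values = values, names = colnames(values), roles = roles,
                 tr_seconds = tr_seconds),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d regressors (TR = %gs)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.design_matrix <- function(x, ...) as.data.frame(x$values)

#' Build a GLM design matrix from an event table
#'
#' One boxcar per condition (onset, duration) is built on a microtime grid
#' (16 bins per TR by default), convolved with each HRF basis kernel, and
#' decimated at scan acquisition times. Zero-duration events are modelled as
#' unit impulses. Nuisance columns and a constant column are appended.
#' Events extending past the end of the run are clipped with a warning.
#'
#' @param events an event table (see [event_table()])
#' @param n_scans number of volumes in the run
#' @param tr_seconds repetition time (seconds)
#' @param basis_kind `"canonical"` or `"canonical+derivatives"`
#' @param nuisance optional numeric matrix or data frame with `n_scans` rows
#'   of confound regressors
#' @param conditions optional character vector fixing the condition set and
#'   its column order (defaults to sorted unique trial types)
#' @param microtime sub-TR sampling factor
#' @return a `design_matrix` object: `values` (T x P), `names`, `roles`
#'   (condition / temporal-derivative / dispersion-derivative / nuisance /
#'   constant) and `tr_seconds`
#' @export
build_design_matrix <- function(events, n_scans, tr_seconds,
                                basis_kind = c("canonical+derivatives", "canonical"),
                                nuisance = NULL, conditions = NULL,
                                microtime = 16L) {
  basis_kind <- match.arg(basis_kind)
  if (!is.numeric(n_scans) || n_scans <= 0) stop("n_scans must be positive", call. = FALSE)
  assert_scalar_pos(tr_seconds, "tr_seconds")
  n_scans <- as.integer(n_scans)

  conditions <- conditions %||% sort(unique(events$trial_type))
  if (nrow(events) > 0 && !all(events$trial_type %in% conditions)) {
    bad <- setdiff(unique(events$trial_type), conditions)
    stop("events reference unknown conditions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  basis <- hrf_basis(tr_seconds, kind = basis_kind, microtime = microtime)
  dt <- attr(basis, "dt")
  n_micro <- n_scans * microtime
  run_end <- n_scans * tr_seconds

  if (nrow(events) > 0 && any(events$onset + events$duration > run_end + 1e-9)) {
    warning("events extending past the run end were clipped", call. = FALSE)
  }

  role_names <- c(canonical = "condition", tderiv = "temporal-derivative",
                  ddisp = "dispersion-derivative")
  cols <- list(); roles <- character()
  for (cond in conditions) {
    ev <- events[events$trial_type == cond, , drop = FALSE]
    stim <- numeric(n_micro)
    for (r in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset[r] / dt) + 1
      if (i0 > n_micro) next
      if (ev$duration[r] <= 0) {
        stim[i0] <- stim[i0] + 1
      } else {
        i1 <- min(n_micro, ceiling((ev$onset[r] + ev$duration[r]) / dt))
        stim[i0:i1] <- stim[i0:i1] + 1
      }
    }
    for (b in colnames(basis)) {
      reg <- convolve_stim(stim, basis[, b])[seq(1, n_micro, by = microtime)]
      nm <- if (b == "canonical") cond else paste0(cond, "_", b)
      cols[[nm]] <- reg
      roles <- c(roles, role_names[[b]])
    }
  }

  if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
    if (nrow(nuis) != n_scans) stop("nuisance rows must equal n_scans", call. = FALSE)
    if (is.null(colnames(nuis))) colnames(nuis) <- paste0("nuisance", seq_len(ncol(nuis)))
    for (j in seq_len(ncol(nuis))) {
      cols[[colnames(nuis)[j]]] <- nuis[, j]
      roles <- c(roles, "nuisance")
    }
  }
  cols[["constant"]] <- rep(1, n_scans)
  roles <- c(roles, "constant")

  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  new_design_matrix(values, roles, tr_seconds)
}

#' HRF-convolved condition regressors only
#'
#' Canonical-basis task regressors for each condition, without derivatives,
#' nuisance or constant columns. This is the exact regressor set the
#' synthetic generator drives network time courses with, so designs built
#' from generated events reproduce the generator's internals.
#'
#' @inheritParams build_design_matrix
#' @return T x C numeric matrix, one column per condition
#' @export
condition_regressors <- function(events, n_scans, tr_seconds, conditions = NULL,
                                 microtime = 16L) {
  dm <- build_design_matrix(events, n_scans, tr_seconds,
                            basis_kind = "canonical", conditions = conditions,
                            microtime = microtime)
  dm$values[, dm$roles == "condition", drop = FALSE]
}

#' Write a design matrix as TSV plus JSON sidecar
#'
#' @param design a `design_matrix`
#' @param path TSV path; a `.json` sidecar with roles and TR is written next
#'   to it
#' @return `path`, invisibly
#' @export
write_design_matrix <- function(design, path) {
  readr::write_tsv(tibble::as_tibble(design$values, .name_repair = "minimal"), path)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(roles = design$roles, names = design$names,
                            tr_seconds = design$tr_seconds),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Randomized event schedule for simulated runs
#'
#' Lays out trials for a declared condition set across a run: trial onsets are
#' drawn without overlap on a jittered grid, in randomized condition order,
#' emulating an event-related design.
#'
#' @param conditions character vector of condition labels
#' @param n_scans run length in volumes
#' @param tr_seconds repetition time (seconds)
#' @param trials_per_condition number of events per condition
#' @param duration event duration in seconds
#' @param seed integer seed
#' @return an event table sorted by onset
#' @export
simulate_events <- function(conditions, n_scans, tr_seconds,
                            trials_per_condition = 8, duration = 2, seed = 1) {
  stopifnot(length(conditions) >= 1)
  withr_seed(seed)
  n_ev <- length(conditions) * trials_per_condition
  run_len <- n_scans * tr_seconds
  slot <- (run_len - duration - 4) / n_ev
  if (slot <= duration) stop("run too short for requested events", call. = FALSE)
  onsets <- (seq_len(n_ev) - 1) * slot + runif(n_ev, 0, slot - duration)
  labels <- sample(rep(conditions, trials_per_condition))
  event_table(onset = sort(onsets), duration = rep(duration, n_ev),
              trial_type = labels)
}

# local seed without clobbering the caller's RNG state
withr_seed <- function(seed) {
  seed <- as.integer(seed %% 2147483647)
  set.seed(seed)
  invisible(seed)
}
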
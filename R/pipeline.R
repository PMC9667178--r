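#' Default pipeline configuration
#'
#' Every analysis threshold defaults to its reference value: FDR q = 0.05,
#' cluster minimum 20 voxels, template threshold fraction 0.20, Bonferroni
#' families 66 (activity), 55 (ANOVA over pairs) and 3 (task contrasts),
#' complexity bin counts 10..40 in steps of 5, Icasso restarts 50 (scaled
#' down to `icasso_runs` for desk use). The simulation block defines a
#' desk-scale study: 3 tasks x (target, control, rest) conditions, 5
#' networks on a 20 x 20 x 10 grid, 2 subjects x 2 sessions, TR 0.5 s.
#'
#' @param seed master seed; per-stage seeds are derived via [derive_seed()]
#' @return a nested configuration list
#' @export
default_config <- function(seed = 1) {
  tasks <- list(
    attention = c(target = "att_target", control = "att_control", rest = "att_rest"),
    semantics = c(target = "sem_target", control = "sem_control", rest = "sem_rest"),
    social = c(target = "soc_target", control = "soc_control", rest = "soc_rest")
  )
  conditions <- unname(unlist(lapply(tasks, function(t) t[c("target", "control", "rest")])))
  list(
    seed = seed,
    simulate = list(
      n_networks = 5, grid_shape = c(20, 20, 10), conditions = conditions,
      coupling = list(list(i = 1, j = 2, condition = "att_target", strength = 1.5)),
      noise_sd = 1, tr_seconds = 0.5, n_subjects = 2, n_sessions = 2,
      trials_per_condition = 6, event_duration = 2
    ),
    tasks = tasks,
    ica = list(k = 5, icasso_runs = 5),
    label = list(template_fraction = 0.20, component_threshold = 2,
                 noise_threshold = 0.5),
    activity = list(bonferroni = 66),
    overlap = list(fdr_q = 0.05, cluster_min_voxels = 20, connectivity = 6),
    cppi = list(bonferroni_tasks = 3, bonferroni_pairs = 55),
    complexity = list(bins = c(10, 15, 20, 25, 30, 35, 40), range = c(0, 1))
  )
}

#' Validate a pipeline configuration
#'
#' Schema-style validation of the configuration before any stage runs.
#'
#' @param config a configuration list (see [default_config()])
#' @return the config, invisibly; errors on the first violation
#' @export
validate_config <- function(config) {
  need <- c("seed", "simulate", "tasks", "ica", "label", "activity",
            "overlap", "cppi", "complexity")
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config missing sections: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  with(config$overlap, {
    if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0,1)", call. = FALSE)
    if (cluster_min_voxels < 1) stop("cluster_min_voxels must be >= 1", call. = FALSE)
  })
  if (config$simulate$n_networks < 2) stop("n_networks must be >= 2", call. = FALSE)
  if (length(config$simulate$conditions) == 0) stop("empty condition set", call. = FALSE)
  if (any(config$complexity$bins < 2)) stop("bin counts must be >= 2", call. = FALSE)
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, design, ICA, labelling, activity, overlap, cPPI
#' and complexity in dependency order, writing each stage's artifacts under
#' `out_dir` and a manifest JSON listing every artifact with its MD5 hash,
#' the resolved configuration and all derived seeds.
#'
#' @param config a configuration list (validated first)
#' @param out_dir output directory
#' @return the manifest (also written to `manifest.json`), invisibly a list
#'   with per-stage results under `$results`
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("netica_")) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), config = config)
  results <- list()
  log_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(
      name = name,
      artifacts = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
    )
  }

  ## 1. simulate -------------------------------------------------------------
  sim_cfg <- config$simulate
  truth <- make_ground_truth(sim_cfg, seed = derive_seed(config$seed, "truth"))
  tr <- truth$tr_seconds
  n_scans <- NULL
  events <- lapply(seq_len(sim_cfg$n_sessions), function(r) {
    simulate_events(sim_cfg$conditions,
                    n_scans = 600, tr_seconds = tr,
                    trials_per_condition = sim_cfg$trials_per_condition,
                    duration = sim_cfg$event_duration,
                    seed = derive_seed(config$seed, paste0("events", r)))
  })
  study <- simulate_study(truth, sim_cfg$n_subjects, sim_cfg$n_sessions, events,
                          seed = derive_seed(config$seed, "study"))
  sim_dir <- file.path(out_dir, "simulate")
  sim_files <- unlist(lapply(study$sessions, write_session, dir = sim_dir))
  log_stage("simulate", sim_files)
  results$study <- study

  ## 2. design ---------------------------------------------------------------
  n_scans <- vapply(study$sessions, function(s) ncol(s$bold$values), integer(1))
  designs <- purrr::imap(study$sessions, function(ses, i) {
    build_design_matrix(ses$events, ncol(ses$bold$values), tr,
                        basis_kind = "canonical+derivatives",
                        nuisance = NULL, conditions = truth$conditions)
  })
  des_dir <- file.path(out_dir, "design")
  dir.create(des_dir, showWarnings = FALSE)
  des_files <- purrr::imap_chr(designs, function(d, i) {
    f <- file.path(des_dir, sprintf("run-%02d_design.tsv", i))
    write_design_matrix(d, f); f
  })
  log_stage("design", c(des_files, sub("\\.tsv$", ".json", des_files)))
  results$designs <- designs

  ## 3. group ICA ------------------------------------------------------------
  datasets <- lapply(study$sessions, `[[`, "bold")
  decomp <- group_ica(datasets, k_session = config$ica$k, k_group = config$ica$k,
                      n_runs = config$ica$icasso_runs,
                      seed = derive_seed(config$seed, "ica"))
  comps <- zscore_components(back_reconstruct(decomp, lapply(datasets, intensity_normalize)))
  ica_dir <- file.path(out_dir, "ica")
  ica_files <- write_components(comps, ica_dir)
  meta_file <- file.path(ica_dir, "decomposition.json")
  jsonlite::write_json(list(k_session = decomp$k_session, k_group = decomp$k_group,
                            seed = decomp$seed, stability = decomp$stability,
                            retained_variance = decomp$group_step$retained_variance),
                       meta_file, auto_unbox = TRUE, digits = NA)
  log_stage("ica", c(ica_files, meta_file))
  results$decomposition <- decomp
  results$components <- comps

  ## 4. labelling ------------------------------------------------------------
  mask_vec <- rep(TRUE, sum(decomp$mask))
  K <- nrow(decomp$group_maps)
  group_z <- zscore_components(decomp$group_maps)
  atlas <- lapply(seq_len(nrow(truth$spatial_maps)), function(k) {
    as.numeric(truth$spatial_maps[k, which(decomp$mask)] > 0)
  })
  names(atlas) <- paste0("network", seq_along(atlas))
  noise <- flag_noise(group_z, mask_vec, config$label$noise_threshold)
  labels <- assign_labels(group_z, atlas,
                          component_threshold = config$label$component_threshold,
                          noise = noise)
  lab_file <- file.path(out_dir, "labels.tsv")
  readr::write_tsv(labels, lab_file)
  log_stage("label", lab_file)
  results$labels <- labels

  ## 5. activity -------------------------------------------------------------
  betas <- sort_components(comps, designs)
  beta_avg <- aggregate_betas(betas)
  contrasts <- purrr::imap(config$tasks, function(tk, name) {
    rbind(
      cbind(task = name, kind = "target_vs_rest",
            paired_contrast_test(beta_avg, tk[["target"]], tk[["rest"]],
                                 n_tests = config$activity$bonferroni)),
      cbind(task = name, kind = "target_vs_control",
            paired_contrast_test(beta_avg, tk[["target"]], tk[["control"]],
                                 n_tests = config$activity$bonferroni))
    )
  }) |> dplyr::bind_rows()
  act_dir <- file.path(out_dir, "activity")
  dir.create(act_dir, showWarnings = FALSE)
  act_files <- c(file.path(act_dir, "betas.tsv"), file.path(act_dir, "contrasts.tsv"))
  readr::write_tsv(beta_avg, act_files[1]); readr::write_tsv(contrasts, act_files[2])
  log_stage("activity", act_files)
  results$betas <- beta_avg
  results$contrasts <- contrasts

  ## 6. overlap --------------------------------------------------------------
  subj_ids <- vapply(comps$sessions, `[[`, numeric(1), "subject")
  subj_avg_maps <- lapply(seq_len(K), function(k) {
    lapply(unique(subj_ids), function(s) {
      ms <- lapply(comps$sessions[subj_ids == s], function(x) x$maps[k, ])
      Reduce(`+`, ms) / length(ms)
    })
  })
  thresh_maps <- lapply(subj_avg_maps, function(subject_maps) {
    tm <- group_t_map(subject_maps)
    full <- array(0, decomp$grid_shape %||% dim(decomp$mask))
    pfull <- rep(NA_real_, prod(dim(decomp$mask)))
    pfull[which(decomp$mask)] <- tm$p
    sig <- rep(FALSE, length(pfull))
    sig[which(decomp$mask)] <- fdr_threshold(tm$p, config$overlap$fdr_q)
    cluster_filter(array(as.numeric(sig), dim(decomp$mask)),
                   config$overlap$cluster_min_voxels, config$overlap$connectivity)
  })
  part_maps <- purrr::imap(config$tasks, function(tk, name) {
    sig_rows <- contrasts[contrasts$task == name & contrasts$kind == "target_vs_control" &
                            contrasts$p_corrected < 0.05, ]
    lapply(c(activating = 1, deactivating = -1), function(sgn) {
      ks <- sig_rows$component[sign(sig_rows$mean_diff) == sgn]
      if (length(ks) == 0) return(NULL)
      participation_map(thresh_maps[ks], task = name,
                        sign = if (sgn > 0) "activating" else "deactivating",
                        networks = paste0("IC", ks))
    })
  })
  ov_dir <- file.path(out_dir, "overlap")
  dir.create(ov_dir, showWarnings = FALSE)
  ov_files <- character(0)
  for (k in seq_len(K)) {
    f <- file.path(ov_dir, sprintf("IC%02d_groupmask.nii.gz", k))
    RNifti::writeNifti(thresh_maps[[k]], f)
    ov_files <- c(ov_files, f)
  }
  for (task in names(part_maps)) {
    for (sgn in names(part_maps[[task]])) {
      pm <- part_maps[[task]][[sgn]]
      if (is.null(pm)) next
      f <- file.path(ov_dir, sprintf("participation_%s_%s.nii.gz", task, sgn))
      RNifti::writeNifti(pm$counts, f)
      ov_files <- c(ov_files, f)
    }
  }
  log_stage("overlap", ov_files)
  results$group_masks <- thresh_maps
  results$participation <- part_maps

  ## 7. cPPI -----------------------------------------------------------------
  concat <- concat_subject_sessions(comps, designs, study)
  cppi_by_task <- purrr::imap(config$tasks, function(tk, name) {
    lapply(concat, function(subj) {
      psych <- psych_contrast(subj$design, tk[["target"]], tk[["control"]], task = name)
      cppi_matrix(subj$time_courses, subj$design, subj$confounds, psych,
                  subject = subj$subject, task = name)
    })
  })
  cppi_dir <- file.path(out_dir, "cppi")
  dir.create(cppi_dir, showWarnings = FALSE)
  cppi_files <- character(0)
  for (task in names(cppi_by_task)) {
    for (m in cppi_by_task[[task]]) {
      f <- file.path(cppi_dir, sprintf("sub-%02d_task-%s_cppi.tsv", m$subject, task))
      write_interaction_matrix(m, f)
      cppi_files <- c(cppi_files, f)
    }
  }
  long_file <- file.path(cppi_dir, "cppi_long.tsv")
  readr::write_tsv(interaction_long(unlist(cppi_by_task, recursive = FALSE)), long_file)
  log_stage("cppi", c(cppi_files, long_file))
  results$cppi <- cppi_by_task

  ## 8. complexity -----------------------------------------------------------
  cx <- complexity_table(unlist(cppi_by_task, recursive = FALSE),
                         bins = config$complexity$bins,
                         range = config$complexity$range)
  cx_file <- file.path(out_dir, "complexity.tsv")
  readr::write_tsv(cx, cx_file)
  cmp <- if (length(unique(cx$task)) >= 2 &&
             all(table(cx$task) >= 2)) compare_tasks(cx) else NULL
  cx_files <- cx_file
  if (!is.null(cmp)) {
    cmp_file <- file.path(out_dir, "complexity_tests.tsv")
    readr::write_tsv(cmp, cmp_file)
    cx_files <- c(cx_files, cmp_file)
  }
  log_stage("complexity", cx_files)
  results$complexity <- cx
  results$complexity_tests <- cmp

  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, digits = NA)
  out <- list(manifest = manifest, manifest_file = manifest_file,
              out_dir = out_dir, results = results)
  invisible(out)
}

# concatenate a subject's sessions: time courses, designs, confounds
concat_subject_sessions <- function(comps, designs, study) {
  subj_ids <- vapply(comps$sessions, `[[`, numeric(1), "subject")
  lapply(unique(subj_ids), function(s) {
    idx <- which(subj_ids == s)
    tc <- do.call(rbind, lapply(comps$sessions[idx], `[[`, "time_courses"))
    # block-diagonal-free concatenation: stack design values, keep one constant
    vals <- do.call(rbind, lapply(designs[idx], `[[`, "values"))
    dm <- new_design_matrix(vals, designs[[idx[1]]]$roles,
                            designs[[idx[1]]]$tr_seconds)
    conf <- do.call(rbind, lapply(study$sessions[idx],
                                  function(x) as.matrix(x$confounds)))
    list(subject = s, time_courses = tc, design = dm, confounds = conf)
  })
}
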
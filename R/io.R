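#' Write a BOLD dataset to NIfTI-1 plus TSVs
#'
#' The 4D volume (unmasked voxels zero-filled) and the 3D mask are written
#' as NIfTI-1 with the TR recorded in the header; events and confounds as
#' TSV.
#'
#' @param session a session entry from [simulate_study()] (fields `bold`,
#'   `events`, `confounds`)
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return named character vector of the files written, invisibly
#' @export
write_session <- function(session, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bold <- session$bold
  prefix <- prefix %||% sprintf("sub-%02d_ses-%02d", session$subject, session$session)
  vol <- array(0, c(bold$grid_shape, ncol(bold$values)))
  mask_idx <- which(bold$mask)
  V_all <- prod(bold$grid_shape)
  for (t in seq_len(ncol(bold$values))) {
    frame <- numeric(V_all)
    frame[mask_idx] <- bold$values[, t]
    vol[, , , t] <- frame
  }
  paths <- c(
    bold = file.path(dir, paste0(prefix, "_bold.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    events = file.path(dir, paste0(prefix, "_events.tsv")),
    confounds = file.path(dir, paste0(prefix, "_confounds.tsv"))
  )
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 1, bold$tr_seconds)
  RNifti::writeNifti(img, paths["bold"])
  RNifti::writeNifti(array(as.numeric(bold$mask), bold$grid_shape), paths["mask"])
  write_events(session$events, paths["events"])
  readr::write_tsv(session$confounds, paths["confounds"])
  invisible(paths)
}

#' Read a BOLD dataset written by [write_session()]
#'
#' @param bold_path 4D NIfTI path
#' @param mask_path 3D mask NIfTI path
#' @param tr_seconds repetition time; read from the header when omitted
#' @param subject,session identifiers
#' @return a `bold_dataset`
#' @export
read_bold <- function(bold_path, mask_path, tr_seconds = NULL,
                      subject = 1L, session = 1L) {
  vol <- RNifti::readNifti(bold_path)
  mask <- array(as.logical(RNifti::readNifti(mask_path) != 0), dim(vol)[1:3])
  tr_seconds <- tr_seconds %||% RNifti::pixdim(vol)[4]
  dm <- dim(vol)
  mat <- matrix(vol, prod(dm[1:3]), dm[4])[which(mask), , drop = FALSE]
  bold_dataset(mat, mask, tr_seconds, subject, session)
}

#' Write component maps as NIfTI volumes and time courses as TSV
#'
#' @param components a `component_set`
#' @param dir output directory
#' @return character vector of files written, invisibly
#' @export
write_components <- function(components, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  mask_idx <- which(components$mask)
  dims <- dim(components$mask)
  for (ses in components$sessions) {
    prefix <- sprintf("sub-%02d_ses-%02d", ses$subject, ses$session)
    K <- nrow(ses$maps)
    vol <- array(0, c(dims, K))
    for (k in seq_len(K)) {
      frame <- numeric(prod(dims)); frame[mask_idx] <- ses$maps[k, ]
      vol[, , , k] <- frame
    }
    f_map <- file.path(dir, paste0(prefix, "_components.nii.gz"))
    RNifti::writeNifti(vol, f_map)
    tc <- tibble::as_tibble(ses$time_courses, .name_repair = ~ paste0("IC", seq_len(K)))
    f_tc <- file.path(dir, paste0(prefix, "_timecourses.tsv"))
    readr::write_tsv(tc, f_tc)
    files <- c(files, f_map, f_tc)
  }
  invisible(files)
}

#' Write an interaction matrix as TSV
#' @param mat an `interaction_matrix`
#' @param path TSV path (K x K r values with network-name header)
#' @return `path`, invisibly
#' @export
write_interaction_matrix <- function(mat, path) {
  K <- nrow(mat$r)
  df <- tibble::as_tibble(mat$r, .name_repair = ~ paste0("net", seq_len(K)))
  readr::write_tsv(df, path)
  invisible(path)
}
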
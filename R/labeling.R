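#' Flag probable noise components
#'
#' A component is flagged as noise when too many of its peak voxels (the top
#' 1% by |Z|) fall outside the cortex mask — the automated counterpart of
#' rejecting components whose Z-score peaks sit in the ventricles or at the
#' brain edge. A manual override always wins.
#'
#' @param maps K x V matrix of Z-scored component maps (in-mask voxels)
#' @param cortex_mask logical/0-1 vector over the same V voxels (TRUE =
#'   cortex)
#' @param threshold_fraction flag when the outside fraction of peak voxels
#'   exceeds this (default 0.5)
#' @param peak_fraction fraction of voxels counted as peaks (default 0.01)
#' @param override optional logical vector of length K; non-NA entries
#'   replace the heuristic decision
#' @return logical vector of length K (TRUE = noise)
#' @export
flag_noise <- function(maps, cortex_mask, threshold_fraction = 0.5,
                       peak_fraction = 0.01, override = NULL) {
  stopifnot(is.matrix(maps))
  cortex_mask <- as.logical(cortex_mask)
  if (!any(cortex_mask)) stop("empty cortex mask", call. = FALSE)
  if (length(cortex_mask) != ncol(maps)) stop("mask length must match voxel count",
                                              call. = FALSE)
  K <- nrow(maps)
  n_peak <- max(1L, ceiling(peak_fraction * ncol(maps)))
  out <- vapply(seq_len(K), function(k) {
    peaks <- order(abs(maps[k, ]), decreasing = TRUE)[seq_len(n_peak)]
    mean(!cortex_mask[peaks]) > threshold_fraction
  }, logical(1))
  if (!is.null(override)) {
    stopifnot(length(override) == K)
    out[!is.na(override)] <- override[!is.na(override)]
  }
  out
}

#' Threshold an intensity template to a binary mask
#'
#' Retains positive voxels with value at least 20% of the volume maximum
#' (the standard template-preparation rule); already-binary maps pass
#' through unchanged.
#'
#' @param map numeric array or vector with a positive maximum
#' @param fraction threshold as a fraction of the maximum (default 0.20)
#' @return binary map (same shape), 1 where retained
#' @export
threshold_template <- function(map, fraction = 0.20) {
  mx <- max(map)
  if (mx <= 0) stop("template has no positive voxel", call. = FALSE)
  out <- map
  out[] <- as.numeric(map >= fraction * mx & map > 0)
  out
}

#' Jaccard similarity of two binary maps
#'
#' |a intersect b| / |a union b|, defined as 0 when the union is empty.
#'
#' @param a,b binary maps (same shape)
#' @return value in [0, 1]
#' @export
jaccard <- function(a, b) {
  if (length(a) != length(b)) stop("grid mismatch between masks", call. = FALSE)
  av <- as.logical(as.vector(a) != 0); bv <- as.logical(as.vector(b) != 0)
  uni <- sum(av | bv)
  if (uni == 0) return(0)
  sum(av & bv) / uni
}

#' Pearson spatial correlation of two maps
#'
#' @param a,b numeric maps (same shape)
#' @return correlation in [-1, 1]; `NA` with a warning when either map has
#'   zero variance
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("grid mismatch between maps", call. = FALSE)
  av <- as.vector(a); bv <- as.vector(b)
  if (pop_sd(av) == 0 || pop_sd(bv) == 0) {
    warning("spatial correlation undefined for zero-variance map", call. = FALSE)
    return(NA_real_)
  }
  cor(av, bv)
}

#' Label components by maximal Jaccard overlap with templates
#'
#' Each non-noise component is binarized (|Z| or positive-tail threshold)
#' and labelled with the template of maximal Jaccard similarity; the
#' runner-up is retained for auditing. Ties are broken by template
#' declaration order (with a message). Components whose thresholded map is
#' empty are left unlabelled with a warning.
#'
#' @param maps K x V matrix of Z-scored component maps
#' @param atlas named list of template maps (binary, or intensity maps which
#'   are thresholded via [threshold_template()]), each of length V
#' @param component_threshold Z threshold for component binarization
#'   (default 2)
#' @param tail `"positive"` (default) to binarize Z > threshold, or `"abs"`
#'   for |Z| > threshold
#' @param noise optional logical vector from [flag_noise()]
#' @return a tibble with one row per component: `component`, `status`,
#'   `label`, `jaccard`, `runner_up`, `runner_up_jaccard`
#' @export
assign_labels <- function(maps, atlas, component_threshold = 2,
                          tail = c("positive", "abs"), noise = NULL) {
  tail <- match.arg(tail)
  if (length(atlas) == 0) stop("empty template atlas", call. = FALSE)
  if (is.null(names(atlas)) || anyDuplicated(names(atlas))) {
    stop("atlas maps must have unique names", call. = FALSE)
  }
  K <- nrow(maps)
  noise <- noise %||% rep(FALSE, K)
  bin_templates <- lapply(atlas, function(m) {
    v <- as.vector(m)
    if (all(v %in% c(0, 1))) v else as.vector(threshold_template(v))
  })

  rows <- purrr::map(seq_len(K), function(k) {
    if (noise[k]) {
      return(tibble::tibble(component = k, status = "noise", label = NA_character_,
                            jaccard = NA_real_, runner_up = NA_character_,
                            runner_up_jaccard = NA_real_))
    }
    comp_bin <- if (tail == "positive") maps[k, ] > component_threshold else
      abs(maps[k, ]) > component_threshold
    if (!any(comp_bin)) {
      warning(sprintf("component %d empty after thresholding; left unlabelled", k),
              call. = FALSE)
      return(tibble::tibble(component = k, status = "unlabelled",
                            label = NA_character_, jaccard = NA_real_,
                            runner_up = NA_character_, runner_up_jaccard = NA_real_))
    }
    j <- vapply(bin_templates, function(tm) jaccard(comp_bin, tm), numeric(1))
    ord <- order(-j, seq_along(j))           # ties -> declaration order
    if (length(j) > 1 && j[ord[1]] == j[ord[2]] && j[ord[1]] > 0) {
      message(sprintf("component %d: Jaccard tie broken by template order", k))
    }
    tibble::tibble(component = k, status = "selected",
                   label = names(atlas)[ord[1]], jaccard = unname(j[ord[1]]),
                   runner_up = if (length(j) > 1) names(atlas)[ord[2]] else NA_character_,
                   runner_up_jaccard = if (length(j) > 1) unname(j[ord[2]]) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
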
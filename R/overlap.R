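#' Voxel-wise one-sample group t-map
#'
#' One-sided (positive) one-sample t-test across subjects at every in-mask
#' voxel of subject-averaged component maps. Voxels with zero variance
#' across subjects get t = Inf / p = 0 when the mean is positive and are
#' excluded (NA) otherwise.
#'
#' @param subject_maps list of numeric vectors/arrays (one per subject, same
#'   length), typically within-subject averages of session-level maps
#' @param mask optional logical vector restricting the test (default all)
#' @return list with vectors `t` and `p` (same length as the maps; NA
#'   outside the mask or where undefined)
#' @export
group_t_map <- function(subject_maps, mask = NULL) {
  n <- length(subject_maps)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n == 2) warning("only 2 subjects: voxel-wise t-tests have a single degree of freedom",
                      call. = FALSE)
  X <- do.call(cbind, lapply(subject_maps, as.vector))
  V <- nrow(X)
  mask <- if (is.null(mask)) rep(TRUE, V) else as.logical(as.vector(mask))
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (n - 1))
  tval <- mu / (s / sqrt(n))
  pval <- pt(tval, df = n - 1, lower.tail = FALSE)
  zero_var <- s == 0
  tval[zero_var & mu > 0] <- Inf
  pval[zero_var & mu > 0] <- 0
  tval[zero_var & mu <= 0] <- NA
  pval[zero_var & mu <= 0] <- NA
  tval[!mask] <- NA; pval[!mask] <- NA
  list(t = tval, p = pval, df = n - 1)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up procedure: sort p ascending, find the largest i with
#' p(i) <= i q / m, reject hypotheses 1..i.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, never rejected)
#' @param q FDR level in (0, 1), default 0.05
#' @return logical vector, TRUE where rejected
#' @export
fdr_threshold <- function(p, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (length(p) == 0) return(logical(0))
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH") <= q
  out
}

#' Remove small clusters from a binary 3D map
#'
#' Connected components are found under the chosen voxel adjacency
#' (face-only 6-connectivity by default) and components smaller than
#' `min_voxels` are removed.
#'
#' @param mask binary 3D array
#' @param min_voxels minimum cluster extent (default 20)
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners)
#' @return binary array of the same shape
#' @export
cluster_filter <- function(mask, min_voxels = 20, connectivity = 6) {
  stopifnot(min_voxels >= 1, connectivity %in% c(6, 18, 26))
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  lab <- cluster_label(mask, connectivity)
  if (max(lab) == 0) return(array(0, dims))
  keep <- which(tabulate(lab[lab > 0]) >= min_voxels)
  out <- array(0, dims)
  out[lab %in% keep] <- 1
  out
}

# connected-component labelling by flood fill over the voxel array
cluster_label <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  offs <- adjacency_offsets(connectivity)
  lab <- array(0L, dims)
  active <- which(mask != 0)
  current <- 0L
  idx_arr <- arrayInd(active, dims)
  in_mask <- array(FALSE, dims); in_mask[active] <- TRUE
  for (v in active) {
    if (lab[v] != 0L) next
    current <- current + 1L
    queue <- v
    lab[v] <- current
    while (length(queue)) {
      here <- queue[length(queue)]
      queue <- queue[-length(queue)]
      hc <- arrayInd(here, dims)
      for (o in seq_len(nrow(offs))) {
        nb <- hc + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        ni <- nb[1] + (nb[2] - 1L) * dims[1] + (nb[3] - 1L) * dims[1] * dims[2]
        if (in_mask[ni] && lab[ni] == 0L) {
          lab[ni] <- current
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

adjacency_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  man <- rowSums(abs(g))
  if (connectivity == 6) g[man == 1, , drop = FALSE]
  else if (connectivity == 18) g[man <= 2, , drop = FALSE]
  else g
}

#' Significance-thresholded group component map
#'
#' Applies BH-FDR over in-mask voxels of a group t-map, then cluster-extent
#' filtering, returning the binary significance map.
#'
#' @param tmap result of [group_t_map()]
#' @param grid_shape 3D dimensions to reshape the voxel vector into
#' @param q FDR level (default 0.05)
#' @param min_voxels cluster extent threshold (default 20)
#' @param connectivity cluster adjacency (default 6)
#' @return binary 3D array
#' @export
threshold_group_map <- function(tmap, grid_shape, q = 0.05, min_voxels = 20,
                                connectivity = 6) {
  sig <- fdr_threshold(tmap$p, q)
  arr <- array(as.numeric(sig), grid_shape)
  cluster_filter(arr, min_voxels, connectivity)
}

#' Network participation map
#'
#' Voxel-wise count of how many significantly (de)activating networks
#' include each voxel for a given task and sign.
#'
#' @param masks list of binary arrays on a common grid (the networks already
#'   selected as significantly activating or deactivating for the task)
#' @param task task label
#' @param sign `"activating"` or `"deactivating"`
#' @param networks optional character vector of contributing network names
#' @return a `participation_map`: `counts` (integer array), `task`, `sign`,
#'   `networks`
#' @export
participation_map <- function(masks, task = NA_character_,
                              sign = c("activating", "deactivating"),
                              networks = NULL) {
  sign <- match.arg(sign)
  if (length(masks) == 0) stop("no masks supplied", call. = FALSE)
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), dims)) stop("grid mismatch across masks", call. = FALSE)
  }
  counts <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m != 0), dims)))
  structure(list(counts = counts, task = task, sign = sign,
                 networks = networks %||% paste0("network", seq_along(masks))),
            class = "participation_map")
}

#' @export
print.participation_map <- function(x, ...) {
  cat(sprintf("<participation_map> task %s (%s), %d networks, max overlap %d\n",
              x$task, x$sign, length(x$networks), max(x$counts)))
  invisible(x)
}
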
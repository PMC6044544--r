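#' Grow a fixed-size searchlight region inside an ROI
#'
#' Volumetric region growing constrained by the ROI shape: the ROI voxels
#' are sorted by Euclidean distance (voxel units) from the center, with
#' distance ties broken by ascending linear index, and the nearest
#' `target` voxels taken. An ROI smaller than `target` yields the whole
#' ROI, flagged.
#'
#' @param roi_mask 3-D logical (or 0/1) array.
#' @param center Center voxel: length-3 ijk (1-based) or a single linear
#'   index into the array. Must lie inside the ROI.
#' @param target Region size in voxels (default 160).
#' @return List of class `voxel_region`: `center` (linear index),
#'   `members` (linear indices, sorted by distance), `saturated` flag.
#' @export
grow_region <- function(roi_mask, center, target = 160) {
  dims <- dim(roi_mask)
  stopifnot(length(dims) == 3)
  if (length(center) == 3) {
    center_lin <- center[1] + (center[2] - 1) * dims[1] +
      (center[3] - 1) * dims[1] * dims[2]
  } else center_lin <- center
  if (!roi_mask[center_lin]) stop("center voxel is outside the ROI")
  roi_lin <- which(roi_mask != 0)
  ijk <- arrayInd(roi_lin, .dim = dims)
  cijk <- arrayInd(center_lin, .dim = dims)
  d2 <- (ijk[, 1] - cijk[1])^2 + (ijk[, 2] - cijk[2])^2 +
    (ijk[, 3] - cijk[3])^2
  ord <- order(d2, roi_lin)
  saturated <- length(roi_lin) < target
  take <- min(target, length(roi_lin))
  structure(list(center = center_lin,
                 members = roi_lin[ord[seq_len(take)]],
                 saturated = saturated),
            class = "voxel_region")
}

#' Model-RSM agreement score of one searchlight region
#'
#' Builds the memory RSM from the region's voxels (cross-session trial
#' pair averaging, as in the whole-ROI analysis), vectorises the lower
#' triangle including the diagonal, and computes Spearman's rank
#' correlation with a model RSM of ones on the diagonal (within-memory)
#' and zeros off it. By default the two 8-memory sets get separate RSMs
#' and the two rho values are averaged; `rsm_mode = "full"` uses one RSM
#' over all memories.
#'
#' @param p Pattern matrix restricted to the region's voxels.
#' @param trials Filtered trial table.
#' @param rsm_mode `"per_set"` (default) or `"full"`.
#' @return Spearman rho, or `NA` when the RSM is degenerate (all entries
#'   equal).
#' @export
region_rsm_score <- function(p, trials, rsm_mode = c("per_set", "full")) {
  rsm_mode <- match.arg(rsm_mode)
  scor <- scorable_memories(trials)
  if (length(scor) < 2) stop("need >= 2 scorable memories in the region")
  groups <- if (rsm_mode == "per_set") {
    sets <- trials$set[match(scor, trials$memory_id)]
    split(scor, sets)
  } else list(scor)
  groups <- Filter(function(g) length(g) >= 2, groups)
  if (!length(groups)) stop("need >= 2 scorable memories per set")
  rhos <- vapply(groups, function(mems) {
    r <- memory_rsm(p, trials, memories = mems)
    v <- r[lower.tri(r, diag = TRUE)]
    model <- diag(length(mems))[lower.tri(r, diag = TRUE)]
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, model, method = "spearman")
  }, numeric(1))
  if (all(is.na(rhos))) NA_real_ else mean(rhos, na.rm = TRUE)
}

#' Searchlight map over an ROI
#'
#' One region is grown around every ROI voxel; each voxel's map value is
#' the mean region score over all regions it belongs to (missing region
#' scores excluded), giving a more representative per-voxel estimate of
#' informational content than center-only assignment.
#'
#' @param p Pattern matrix over all ROI voxels (columns in ascending
#'   linear-index order of the mask).
#' @param trials Filtered trial table.
#' @param roi_mask 3-D mask defining the voxel geometry.
#' @param target Region size (default 160).
#' @param rsm_mode Passed to [region_rsm_score()].
#' @return List of class `searchlight_map`: `values` (per-ROI-voxel mean
#'   rho, mask order), `mask`, `n_regions` per voxel.
#' @export
searchlight_map <- function(p, trials, roi_mask, target = 160,
                            rsm_mode = "per_set") {
  roi_lin <- which(roi_mask != 0)
  if (!length(roi_lin)) stop("empty ROI")
  stopifnot(ncol(p) == length(roi_lin))
  col_of <- integer(length(roi_mask)); col_of[roi_lin] <- seq_along(roi_lin)
  sums <- numeric(length(roi_lin)); counts <- integer(length(roi_lin))
  for (v in seq_along(roi_lin)) {
    reg <- grow_region(roi_mask, roi_lin[v], target)
    cols <- col_of[reg$members]
    rho <- region_rsm_score(p[, cols, drop = FALSE], trials, rsm_mode)
    if (!is.na(rho)) {
      sums[cols] <- sums[cols] + rho
      counts[cols] <- counts[cols] + 1L
    }
  }
  values <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(values = values, mask = roi_mask, n_regions = counts),
            class = "searchlight_map")
}

# 26-connected components of a voxel set (linear indices) in a 3-D grid.
# Returns an integer label per input voxel.
label_components <- function(lin, dims) {
  if (!length(lin)) return(integer(0))
  vol <- array(0L, dims)
  vol[lin] <- seq_along(lin)
  ijk <- arrayInd(lin, .dim = dims)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  labels <- integer(length(lin))
  cur <- 0L
  for (s in seq_along(lin)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- ijk[rep(v, nrow(off)), , drop = FALSE] + off
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nl <- nb[, 1] + (nb[, 2] - 1) * dims[1] +
        (nb[, 3] - 1) * dims[1] * dims[2]
      hit <- vol[nl]
      hit <- hit[hit > 0L]
      new <- hit[labels[hit] == 0L]
      labels[new] <- cur
      queue <- c(queue, new)
    }
  }
  labels
}

max_cluster_size <- function(lin, dims) {
  if (!length(lin)) return(0L)
  lab <- label_components(lin, dims)
  max(tabulate(lab))
}

# Per-permutation one-sample t statistics for sign-flipped subject maps.
# X: subjects x voxels; signs: n_perm x subjects (+/-1).
signflip_t <- function(X, signs) {
  n <- nrow(X)
  M <- (signs %*% X) / n
  ss <- matrix(colSums(X^2), nrow(signs), ncol(X), byrow = TRUE)
  v <- (ss - n * M^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  M / sqrt(v / n)
}

#' Sign-flip permutation cluster-level FWE test on subject maps
#'
#' Nonparametric one-sample group inference on searchlight maps in the
#' SnPM style: observed per-voxel one-sample t across subjects; clusters
#' are 26-connected components of voxels with t >= `t_thresh`; the null
#' distribution of the maximum cluster size is built from random
#' subject-wise whole-map sign flips (the identity flip included), and
#' each observed cluster's corrected p is the proportion of null maxima
#' at least as large.
#'
#' @param maps Subjects x ROI-voxels matrix (mask order), or a list of
#'   `searchlight_map`s sharing one mask.
#' @param roi_mask 3-D mask (required when `maps` is a matrix).
#' @param n_perm Number of permutations (default 10000). Fewer than 100
#'   triggers a warning but proceeds.
#' @param t_thresh Cluster-forming threshold in t units (default 3).
#' @param alpha Cluster-level FWE threshold (default 0.05).
#' @param seed Integer seed for the random flips.
#' @param exact Enumerate all `2^n` sign patterns instead of sampling
#'   (small groups only, n <= 16); p values are then exact proportions
#'   over the full permutation group and `n_perm` is ignored.
#' @return List of class `cluster_result`: `clusters` (data.frame
#'   cluster_id, n_voxels, peak_t, p_fwe, significant), `voxel_t`,
#'   `cluster_label` (per ROI voxel, 0 = subthreshold), `null_max_size`,
#'   `n_perm`, `t_thresh`.
#' @export
signflip_cluster_test <- function(maps, roi_mask = NULL, n_perm = 10000,
                                  t_thresh = 3, alpha = 0.05, seed = 1,
                                  exact = FALSE) {
  if (is.list(maps) && inherits(maps[[1]], "searchlight_map")) {
    roi_mask <- maps[[1]]$mask
    maps <- do.call(rbind, lapply(maps, function(m) m$values))
  }
  stopifnot(!is.null(roi_mask))
  X <- as.matrix(maps)
  if (nrow(X) < 6) stop("need >= 6 subjects for sign-flip inference")
  dims <- dim(roi_mask)
  roi_lin <- which(roi_mask != 0)
  stopifnot(ncol(X) == length(roi_lin))

  n <- nrow(X)
  if (exact) {
    if (n > 16) stop("exact enumeration limited to n <= 16 subjects")
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(signs) <- NULL
    n_perm <- nrow(signs)  # 2^n, identity pattern is row 1
  } else {
    if (n_perm < 100)
      warning("fewer than 100 permutations: p values are coarse")
    set.seed(as.integer(seed))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    signs[1, ] <- 1  # identity flip anchors the null
  }

  null_max <- integer(n_perm)
  chunk <- 2000L
  t_obs <- NULL
  for (start in seq(1L, n_perm, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_perm)
    Tm <- signflip_t(X, signs[idx, , drop = FALSE])
    if (start == 1L) t_obs <- Tm[1, ]
    for (r in seq_along(idx)) {
      supra <- roi_lin[Tm[r, ] >= t_thresh]
      null_max[idx[r]] <- max_cluster_size(supra, dims)
    }
  }

  supra_obs <- which(t_obs >= t_thresh)
  lab_roi <- integer(length(roi_lin))
  clusters <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                         peak_t = numeric(0), p_fwe = numeric(0),
                         significant = logical(0))
  if (length(supra_obs)) {
    lab <- label_components(roi_lin[supra_obs], dims)
    lab_roi[supra_obs] <- lab
    sizes <- tabulate(lab)
    clusters <- data.frame(
      cluster_id = seq_along(sizes),
      n_voxels = sizes,
      peak_t = vapply(seq_along(sizes), function(cl)
        max(t_obs[supra_obs[lab == cl]]), numeric(1)),
      p_fwe = vapply(sizes, function(sz) mean(null_max >= sz), numeric(1)))
    clusters$significant <- clusters$p_fwe < alpha
  }
  structure(list(clusters = clusters, voxel_t = t_obs,
                 cluster_label = lab_roi, null_max_size = null_max,
                 n_perm = n_perm, t_thresh = t_thresh, alpha = alpha),
            class = "cluster_result")
}
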
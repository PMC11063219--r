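#' Theoretical representational dissimilarity matrix
#'
#' Entry (i, j) is the Euclidean distance between the destinations of paths
#' i and j; the matrix is symmetric with a zero diagonal. Goals must come
#' from spaces of one dimensionality — Euclidean distance across
#' dimensionalities is undefined, so cross-space RDMs are computed per space
#' and their searchlight correlations averaged (see [searchlight_rsa()]).
#'
#' @param goals Numeric matrix of goal coordinates, one row per path.
#' @return `n x n` dissimilarity matrix.
#' @examples
#' theoretical_rdm(rbind(c(0, 0), c(3, 4)))[1, 2]  # 5
#' @export
theoretical_rdm <- function(goals) {
  if (is.list(goals)) {
    if (length(unique(lengths(goals))) != 1L)
      stop("goals mix dimensionalities; build one RDM per space")
    goals <- do.call(rbind, goals)
  }
  goals <- as.matrix(goals)
  as.matrix(stats::dist(goals))
}

#' Neural representational dissimilarity matrix
#'
#' Entry (i, j) is `1 - r`, the Pearson-correlation distance between the
#' voxel patterns of paths i and j.
#'
#' @param patterns Numeric matrix, one row per path, one column per voxel
#'   (>= 2 voxels with nonzero variance per pattern).
#' @return `n x n` dissimilarity matrix with entries in \[0, 2\].
#' @export
neural_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 3L) stop("need >= 3 paths for a neural RDM")
  if (ncol(patterns) < 2L) stop("patterns need >= 2 voxels")
  sds <- apply(patterns, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance pattern for path(s): ",
         paste(which(sds == 0), collapse = ", "))
  d <- 1 - stats::cor(t(patterns))
  diag(d) <- 0
  d
}

lower_tri <- function(m) m[lower.tri(m)]

#' Spearman correlation between two RDMs
#'
#' Rank correlation (average ranks for ties) over the strictly-lower-triangle
#' entries of the two matrices.
#'
#' @param neural,theoretical RDMs of identical dimension (n >= 3).
#' @return Spearman's rho, or `NA` with a warning when either triangle is
#'   constant (rank correlation undefined).
#' @export
rdm_spearman <- function(neural, theoretical) {
  if (!identical(dim(neural), dim(theoretical)))
    stop("RDM shapes differ")
  if (nrow(neural) < 3L) stop("need n >= 3 paths")
  a <- lower_tri(neural)
  b <- lower_tri(theoretical)
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) {
    warning("constant RDM triangle; Spearman correlation undefined")
    return(NA_real_)
  }
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

#' Fisher z transform of a correlation map
#'
#' `atanh` after clipping |rho| at `1 - 1e-7` (so degenerate rho = +/-1 maps
#' stay finite); missing values propagate.
#'
#' @param rho Numeric vector/array of correlations in \[-1, 1\].
#' @return Transformed values, same shape.
#' @export
fisher_z <- function(rho) {
  clip <- 1 - 1e-7
  atanh(pmin(pmax(rho, -clip), clip))
}

# linear indices of valid searchlight centers: full cube in-volume and
# entirely in-mask, subsampled by stride per axis
searchlight_centers <- function(shape, mask, cube_side, stride) {
  half <- (cube_side - 1L) %/% 2L
  ax <- lapply(shape, function(s) seq(half + 1L, s - half))
  if (any(lengths(ax) == 0L)) stop("cube does not fit inside the volume")
  ax <- lapply(ax, function(v) v[seq(1L, length(v), by = stride)])
  cent <- as.matrix(expand.grid(ax[[1L]], ax[[2L]], ax[[3L]]))
  offs <- as.matrix(expand.grid(-half:half, -half:half, -half:half))
  lin <- function(xyz) (xyz[, 1L]) + shape[1L] * ((xyz[, 2L] - 1L) +
                                                    shape[2L] * (xyz[, 3L] - 1L))
  cent_lin <- lin(cent)
  ok <- rep(TRUE, nrow(cent))
  mask_vec <- as.logical(mask)
  for (o in seq_len(nrow(offs))) {
    delta <- offs[o, 1L] + shape[1L] * (offs[o, 2L] + shape[2L] * offs[o, 3L])
    ok <- ok & mask_vec[cent_lin + delta]
  }
  if (!any(ok)) stop("no valid searchlight centers")
  list(centers_lin = cent_lin[ok], centers_xyz = cent[ok, , drop = FALSE],
       offsets_lin = offs[, 1L] + shape[1L] * (offs[, 2L] +
                                                 shape[2L] * offs[, 3L]))
}

# rows of the cube-pattern matrix for one volume: centers x cube voxels
extract_cube_patterns <- function(vol_vec, centers_lin, offsets_lin) {
  vapply(offsets_lin, function(d) vol_vec[centers_lin + d],
         numeric(length(centers_lin)))
}

# rowwise Pearson correlation of two centers x k matrices
rowwise_cor <- function(A, B) {
  k <- ncol(A)
  ma <- rowMeans(A); mb <- rowMeans(B)
  ca <- A - ma; cb <- B - mb
  num <- rowSums(ca * cb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Searchlight RSA over a PE map set
#'
#' Slides a cube of `cube_side` voxels (stride `stride` per axis) over the
#' volume; a center is valid when the whole cube lies in-volume and in-mask.
#' At each center, for each stage and each space with at least `min_paths`
#' paths in that stage, the cube patterns of those paths give a neural RDM
#' (1 - Pearson r) which is rank-correlated (Spearman) with the space's
#' theoretical goal-distance RDM; the per-space correlations are averaged
#' with equal weight and assigned to the center voxel. Invalid centers are
#' `NA`.
#'
#' @param pe A `pe_map_set` whose sidecar includes a `stage` column.
#' @param cube_side Searchlight cube side in voxels (default 3).
#' @param stride Center stride per axis (default 1).
#' @param min_paths Minimum paths per stage x space cell (default 3).
#' @return List of class `rho_maps`: `rho` (named list of 3-D arrays, one
#'   per stage), `z` (Fisher-transformed), `n_centers`, `centers_xyz`.
#' @export
searchlight_rsa <- function(pe, cube_side = 3L, stride = 1L, min_paths = 3L) {
  stopifnot(inherits(pe, "pe_map_set"), "stage" %in% names(pe$paths))
  shape <- pe$geometry$shape
  sl <- searchlight_centers(shape, pe$geometry$mask, cube_side, stride)
  n_cent <- length(sl$centers_lin)
  n_vol <- prod(shape)
  stages <- sort(unique(pe$paths$stage))
  rho_out <- list()
  for (stg in stages) {
    acc <- matrix(NA_real_, n_cent, 0L)
    for (lab in unique(pe$paths$space_label)) {
      sel <- which(pe$paths$stage == stg & pe$paths$space_label == lab)
      if (length(sel) < min_paths) next
      goals <- do.call(rbind, lapply(pe$paths$goal[sel], parse_location))
      theo <- lower_tri(theoretical_rdm(goals))
      if (length(unique(theo)) == 1L) next  # constant distances: rho undefined
      mats <- lapply(sel, function(i) {
        extract_cube_patterns(pe$data[(i - 1L) * n_vol + seq_len(n_vol)],
                              sl$centers_lin, sl$offsets_lin)
      })
      pairs <- utils::combn(length(sel), 2L)
      nd <- matrix(NA_real_, n_cent, ncol(pairs))
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1L, p]; j <- pairs[2L, p]
        nd[, p] <- 1 - rowwise_cor(mats[[i]], mats[[j]])
      }
      # Spearman per center: rank rows, Pearson against ranked theoretical;
      # pair order of nd matches lower_tri (combn column-major agreement)
      rb <- rank(theo)
      rb_c <- rb - mean(rb)
      rb_ss <- sqrt(sum(rb_c^2))
      ranks <- t(apply(nd, 1L, rank))
      rc <- ranks - rowMeans(ranks)
      den <- sqrt(rowSums(rc^2)) * rb_ss
      rho <- as.numeric(rc %*% rb_c) / den
      rho[den == 0 | apply(nd, 1L, function(r) anyNA(r))] <- NA_real_
      acc <- cbind(acc, rho)
    }
    if (ncol(acc) == 0L)
      stop("stage '", stg, "' has no space with >= ", min_paths, " paths")
    rho_mean <- rowMeans(acc)  # equal weight per space; NA propagates
    vol <- array(NA_real_, dim = shape)
    vol[sl$centers_lin] <- rho_mean
    rho_out[[stg]] <- vol
  }
  structure(list(rho = rho_out, z = lapply(rho_out, fisher_z),
                 n_centers = n_cent, centers_xyz = sl$centers_xyz,
                 cube_side = cube_side, stride = stride),
            class = "rho_maps")
}

#' Voxelwise paired t contrast between stage maps
#'
#' Per-subject difference maps (exploitation minus exploration) feed a
#' voxelwise paired t test; a voxel enters only if valid (non-missing) in
#' every subject.
#'
#' @param z_exploit,z_explore Lists (one 3-D array per subject) of
#'   Fisher-transformed searchlight maps.
#' @return List: `t_map` (3-D array, `NA` off the common valid set),
#'   `diff` (subjects x voxels matrix of differences), `valid`
#'   (logical array), `n_subjects`.
#' @export
stage_contrast <- function(z_exploit, z_explore) {
  n <- length(z_exploit)
  if (n < 2L || length(z_explore) != n)
    stop("need >= 2 subjects with both stage maps")
  shape <- dim(z_exploit[[1L]])
  diffs <- t(vapply(seq_len(n), function(i) {
    as.numeric(z_exploit[[i]]) - as.numeric(z_explore[[i]])
  }, numeric(prod(shape))))
  valid <- colSums(is.na(diffs)) == 0L
  t_vec <- rep(NA_real_, prod(shape))
  d <- diffs[, valid, drop = FALSE]
  m <- colMeans(d)
  s <- sqrt(pmax((colSums(d^2) - n * m^2) / (n - 1L), 0))
  tv <- m / (s / sqrt(n))
  tv[s == 0 & m == 0] <- 0  # identical maps in every subject
  t_vec[valid] <- tv
  list(t_map = array(t_vec, dim = shape),
       diff = diffs, valid = array(valid, dim = shape), n_subjects = n)
}

#' Threshold-free cluster enhancement
#'
#' Enhances each voxel by the integral over thresholds h of
#' `e(h)^E * h^H * dh`, where `e(h)` is the extent of the suprathreshold
#' connected component containing the voxel. Negative values are enhanced on
#' the negated map and returned with a negative sign; missing values count
#' as zero.
#'
#' @param stat_map 3-D numeric array (e.g. a t map).
#' @param H Height exponent (default 2).
#' @param E Extent exponent (default 0.5).
#' @param dh Threshold step (default 0.1).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Enhanced 3-D array (signed).
#' @export
tfce <- function(stat_map, H = 2, E = 0.5, dh = 0.1, connectivity = 6L) {
  shape <- dim(stat_map)
  stopifnot(length(shape) == 3L)
  x <- as.numeric(stat_map)
  x[is.na(x)] <- 0
  pos <- tfce_positive_cpp(pmax(x, 0), as.integer(shape), H, E, dh,
                           as.integer(connectivity))
  neg <- tfce_positive_cpp(pmax(-x, 0), as.integer(shape), H, E, dh,
                           as.integer(connectivity))
  array(pos - neg, dim = shape)
}

#' Sign-flip permutation inference with TFCE and FWE correction
#'
#' Group inference on per-subject difference maps. The observed paired t map
#' is TFCE-enhanced; under the null, subjects' difference maps are randomly
#' sign-flipped, the t map and its TFCE recomputed, and the volume-maximum
#' enhanced statistic collected. The FWE-corrected p of a voxel is the
#' proportion of permutation maxima at or above its observed enhancement
#' (with the +1/(n+1) correction for random permutations; exhaustive
#' enumeration of all 2^n sign patterns is used when it fits within
#' `n_perm`). Both signs are enhanced, and the null maximum is taken over
#' both, giving two-sided FWE control.
#'
#' @param diff_maps Subjects x voxels matrix (from [stage_contrast()]`$diff`)
#'   or list of 3-D arrays of per-subject differences.
#' @param shape Volume dimensions (required when `diff_maps` is a matrix).
#' @param n_perm Number of permutations (field default 10000; simulations in
#'   the test suite use 500).
#' @param seed Integer seed for the sign flips.
#' @param H,E,dh,connectivity TFCE parameters, see [tfce()].
#' @return List of class `group_result`: `t_map`, `tfce_map` (signed),
#'   `p_map` (FWE-corrected), `max_null` (permutation maxima), `n_perm`
#'   (permutations actually used), `exhaustive`, `seed`.
#' @export
permutation_fwe <- function(diff_maps, shape = NULL, n_perm = 10000L,
                            seed = 1L, H = 2, E = 0.5, dh = 0.1,
                            connectivity = 6L) {
  if (is.list(diff_maps)) {
    shape <- dim(diff_maps[[1L]])
    diff_maps <- t(vapply(diff_maps, as.numeric,
                          numeric(prod(shape))))
  }
  if (is.null(shape)) stop("shape required for matrix input")
  n <- nrow(diff_maps)
  if (n < 2L) stop("need >= 2 subjects")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  valid <- colSums(is.na(diff_maps)) == 0L
  D <- diff_maps
  D[, !valid] <- 0
  ss_fixed <- colSums(D^2)  # invariant under sign flips
  t_of_signs <- function(s) {
    m <- as.numeric(crossprod(s, D)) / n
    sd2 <- (ss_fixed - n * m^2) / (n - 1L)
    tv <- m / sqrt(sd2 / n)
    tv[sd2 <= 0 | !valid] <- 0
    tv
  }
  enhance <- function(tv) {
    tfce(array(tv, dim = shape), H = H, E = E, dh = dh,
         connectivity = connectivity)
  }
  t_obs <- t_of_signs(rep(1, n))
  tfce_obs <- enhance(t_obs)
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_used <- nrow(signs)
  } else {
    set.seed(as.integer(seed))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    n_perm, n)
    n_used <- n_perm
  }
  max_null <- vapply(seq_len(n_used), function(p) {
    e <- enhance(t_of_signs(signs[p, ]))
    max(abs(e))
  }, numeric(1L))
  obs_mag <- abs(as.numeric(tfce_obs))
  counts <- vapply(obs_mag, function(v) sum(max_null >= v), numeric(1L))
  p_vec <- if (exhaustive) counts / n_used else (1 + counts) / (n_used + 1)
  p_vec[!valid] <- NA_real_
  tmap <- rep(NA_real_, length(valid))
  tmap[valid] <- t_obs[valid]
  structure(list(t_map = array(tmap, dim = shape),
                 tfce_map = tfce_obs, p_map = array(p_vec, dim = shape),
                 max_null = max_null, n_perm = n_used,
                 exhaustive = exhaustive, seed = as.integer(seed)),
            class = "group_result")
}

#' Peak table of a group result
#'
#' @param result A `group_result`.
#' @param alpha FWE threshold (default 0.05).
#' @return data.frame of significant voxels: coordinates, t, TFCE, p,
#'   ordered by enhancement magnitude.
#' @export
peak_table <- function(result, alpha = 0.05) {
  sig <- which(!is.na(result$p_map) & result$p_map < alpha)
  if (!length(sig)) {
    return(data.frame(x = integer(), y = integer(), z = integer(),
                      t = numeric(), tfce = numeric(), p = numeric()))
  }
  xyz <- arrayInd(sig, dim(result$p_map))
  out <- data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    t = result$t_map[sig], tfce = result$tfce_map[sig],
                    p = result$p_map[sig])
  out[order(-abs(out$tfce)), ]
}
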
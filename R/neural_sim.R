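#' Volume geometry for synthetic pattern-estimate maps
#'
#' A regular voxel grid with an identity affine (nominal 2 mm voxels) and a
#' boolean brain mask. The default test geometry is a 20 x 20 x 20 grid with
#' everything in-mask.
#'
#' @param shape Integer vector of 3 grid sizes (each >= 3).
#' @param mask Logical array of dimension `shape` (default: all `TRUE`).
#' @param voxel_mm Nominal voxel size stored in written NIfTI headers.
#' @return List of class `volume_geometry`.
#' @export
volume_geometry <- function(shape = c(20L, 20L, 20L), mask = NULL,
                            voxel_mm = 2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L))
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  stopifnot(identical(dim(mask), shape), any(mask))
  structure(list(shape = shape, mask = mask, voxel_mm = voxel_mm),
            class = "volume_geometry")
}

#' Place a cubic region mask inside a volume
#'
#' @param geometry A `volume_geometry`.
#' @param corner 1-based lower corner of the cube.
#' @param side Cube side length in voxels.
#' @return Logical array marking the cube.
#' @export
cube_region <- function(geometry, corner, side) {
  corner <- as.integer(corner)
  stopifnot(all(corner >= 1L), all(corner + side - 1L <= geometry$shape))
  m <- array(FALSE, dim = geometry$shape)
  m[corner[1L]:(corner[1L] + side - 1L),
    corner[2L]:(corner[2L] + side - 1L),
    corner[3L]:(corner[3L] + side - 1L)] <- TRUE
  m
}

#' Generative model for stage-dependent destination coding
#'
#' Voxels inside the coding regions carry a linear readout of a goal
#' embedding (see [goal_embedding()]) plus stage-dependent noise; all other
#' in-mask voxels carry pure background noise. Exploration-stage maps get
#' more noise than exploitation-stage maps (`sigma_explore > sigma_exploit`),
#' planting the hypothesis that destinations are represented more accurately
#' during exploitation. Coding-voxel loadings are scaled so the noise-free
#' signal has unit RMS per voxel.
#'
#' @param regions List of logical region masks (e.g. from [cube_region()]).
#' @param bandwidth RBF bandwidth of the goal embedding, in location units.
#' @param sigma_explore,sigma_exploit Stage noise SDs
#'   (`sigma_explore > sigma_exploit >= 0`).
#' @param sigma_background Noise SD of non-coding in-mask voxels.
#' @param signal_scale Multiplier on the coding loadings; 0 removes the
#'   destination signal entirely (null simulations).
#' @return List of class `pattern_model`.
#' @export
pattern_model <- function(regions, bandwidth = 2,
                          sigma_explore = 0.8, sigma_exploit = 0.2,
                          sigma_background = 1, signal_scale = 1) {
  stopifnot(is.list(regions), length(regions) >= 1L,
            sigma_explore > sigma_exploit, sigma_exploit >= 0,
            signal_scale >= 0)
  structure(list(regions = regions, bandwidth = bandwidth,
                 sigma_explore = sigma_explore, sigma_exploit = sigma_exploit,
                 sigma_background = sigma_background,
                 signal_scale = signal_scale),
            class = "pattern_model")
}

#' Goal embedding with distance-determined similarity
#'
#' Embeds every location of a space so that the inner product of two
#' embeddings is exactly the radial-basis kernel of their Euclidean
#' distance, `exp(-d^2 / (2 * bandwidth^2))`: the features are rows of
#' `V %*% diag(sqrt(lambda))` from the eigendecomposition of the kernel Gram
#' matrix over all locations. Similarity therefore depends on goal distance
#' only and decreases strictly with it, so noise-free patterns built from
#' these features reproduce the theoretical dissimilarity structure exactly.
#'
#' @param space An `abstract_space`.
#' @param bandwidth Kernel bandwidth in location units.
#' @return List of class `goal_embedding`: `features` (locations x features),
#'   `locations` (matrix of coordinates), `bandwidth`.
#' @export
goal_embedding <- function(space, bandwidth = 2) {
  locs <- all_locations(space)
  d2 <- as.matrix(stats::dist(locs))^2
  K <- exp(-d2 / (2 * bandwidth^2))
  eig <- eigen(K, symmetric = TRUE)
  keep <- eig$values > 1e-10
  feats <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), sum(keep))
  structure(list(features = feats, locations = locs, bandwidth = bandwidth),
            class = "goal_embedding")
}

#' Look up the embedding vector of a goal
#'
#' @param embedding A `goal_embedding`.
#' @param goal Integer coordinate vector.
#' @return Numeric feature vector.
#' @export
embed_goal <- function(embedding, goal) {
  hit <- which(apply(embedding$locations, 1L,
                     function(l) all(l == as.integer(goal))))
  if (length(hit) != 1L) stop("goal not found in embedding: ",
                              paste(goal, collapse = ","))
  embedding$features[hit, ]
}

# column-centred orthonormal loading matrix, scaled to unit per-voxel RMS:
# columns orthogonal to the constant vector and to each other, so Pearson
# correlations between projected patterns equal embedding cosines exactly
coding_loadings <- function(n_vox, n_feat) {
  if (n_vox < n_feat + 1L)
    stop("coding region has ", n_vox, " voxels; needs > ", n_feat,
         " for an exact embedding readout")
  G <- matrix(stats::rnorm(n_vox * n_feat), n_vox, n_feat)
  G <- sweep(G, 2L, colMeans(G))
  qr.Q(qr(G)) * sqrt(n_vox)
}

#' Generate per-path parameter-estimate maps for one subject
#'
#' One 3-D map per path. In each coding region, each path's map carries the
#' region's linear readout of its goal embedding (per space) plus Gaussian
#' noise whose SD depends on the path's stage; background in-mask voxels get
#' `sigma_background` noise, and out-of-mask voxels are zero.
#'
#' @param staged A `staged_session` (needs `goal`, `space_label`, `n_dims`
#'   and `stage` per path).
#' @param geometry A `volume_geometry`.
#' @param model A `pattern_model`.
#' @param seed Integer seed; maps are a pure function of
#'   `(staged, geometry, model, seed)`.
#' @return List of class `pe_map_set`: `data` (4-D array, path-index last),
#'   `paths` (sidecar data.frame: subject, session_ordinal, space_label,
#'   goal, stage), `geometry`, `seed`.
#' @export
generate_pe_maps <- function(staged, geometry, model, seed = 1L) {
  stopifnot(inherits(staged, "staged_session"),
            inherits(geometry, "volume_geometry"),
            inherits(model, "pattern_model"))
  for (r in model$regions) {
    if (!identical(dim(r), geometry$shape))
      stop("region mask dimensions do not match the volume geometry")
    if (any(r & !geometry$mask))
      stop("coding region extends outside the brain mask")
  }
  set.seed(as.integer(seed))
  paths <- staged$paths
  n_path <- nrow(paths)
  shape <- geometry$shape
  dat <- array(0, dim = c(shape, n_path))
  mask_idx <- which(geometry$mask)
  coding_idx <- which(Reduce(`|`, model$regions))
  bg_idx <- setdiff(mask_idx, coding_idx)
  # per-dimensionality embeddings (spaces of equal n_dims share coordinates)
  embeds <- lapply(sort(unique(paths$n_dims)), function(nd) {
    sp_lab <- paths$space_label[match(nd, paths$n_dims)]
    goal_embedding(abstract_space(sp_lab), model$bandwidth)
  })
  names(embeds) <- sort(unique(paths$n_dims))
  # per region x space: seeded loading matrix
  n_vox_vol <- prod(shape)
  for (reg in model$regions) {
    reg_idx <- which(reg)
    for (lab in unique(paths$space_label)) {
      nd <- paths$n_dims[match(lab, paths$space_label)]
      emb <- embeds[[as.character(nd)]]
      W <- model$signal_scale * coding_loadings(length(reg_idx),
                                                ncol(emb$features))
      for (i in which(paths$space_label == lab)) {
        phi <- embed_goal(emb, parse_location(paths$goal[i]))
        sig_sd <- if (paths$stage[i] == "exploration") model$sigma_explore
                  else model$sigma_exploit
        dat[reg_idx + (i - 1L) * n_vox_vol] <-
          as.numeric(W %*% phi) + sig_sd * stats::rnorm(length(reg_idx))
      }
    }
  }
  for (i in seq_len(n_path)) {
    dat[bg_idx + (i - 1L) * n_vox_vol] <-
      model$sigma_background * stats::rnorm(length(bg_idx))
  }
  sidecar <- data.frame(
    subject = paths$subject, session_ordinal = paths$session_ordinal,
    space_label = paths$space_label, n_dims = paths$n_dims,
    goal = paths$goal, stage = as.character(paths$stage),
    stringsAsFactors = FALSE)
  structure(list(data = dat, paths = sidecar, geometry = geometry,
                 seed = as.integer(seed)),
            class = "pe_map_set")
}

#' Write / read a PE map set as NIfTI plus a CSV sidecar
#'
#' The 4-D map stack is written as one NIfTI file (identity orientation,
#' nominal voxel size from the geometry) and the per-path metadata as a CSV
#' sidecar next to it.
#'
#' @param pe A `pe_map_set`.
#' @param nifti_path Output `.nii` / `.nii.gz` path.
#' @param csv_path Sidecar path (default: `nifti_path` with `.csv`).
#' @return `nifti_path`, invisibly.
#' @export
write_pe_maps <- function(pe, nifti_path,
                          csv_path = sub("\\.nii(\\.gz)?$", ".csv",
                                         nifti_path)) {
  img <- RNifti::asNifti(pe$data,
                         pixdim = c(rep(pe$geometry$voxel_mm, 3L), 1))
  RNifti::writeNifti(img, nifti_path)
  utils::write.csv(pe$paths, csv_path, row.names = FALSE)
  invisible(nifti_path)
}

#' @rdname write_pe_maps
#' @param mask Optional logical mask for the rebuilt geometry (default all
#'   in-mask).
#' @return `read_pe_maps`: a `pe_map_set`.
#' @export
read_pe_maps <- function(nifti_path,
                         csv_path = sub("\\.nii(\\.gz)?$", ".csv",
                                        nifti_path),
                         mask = NULL) {
  img <- RNifti::readNifti(nifti_path)
  dat <- array(as.numeric(img), dim = dim(img))
  sidecar <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (dim(dat)[4L] != nrow(sidecar))
    stop("NIfTI has ", dim(dat)[4L], " volumes but sidecar has ",
         nrow(sidecar), " rows")
  geom <- volume_geometry(dim(dat)[1:3], mask)
  structure(list(data = dat, paths = sidecar, geometry = geom,
                 seed = NA_integer_),
            class = "pe_map_set")
}
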
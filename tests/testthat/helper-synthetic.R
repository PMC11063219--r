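# shared fixtures, all generated in code

# learning-level schedule with an abrupt change-point after path `cp` of
# every space: the planted exploration/exploitation split for recovery tests
change_point_level <- function(cp = 5L) {
  function(space_label, set_index, group_path_index, path_index)
    as.numeric(path_index > cp)
}

# a sharply separated change-point agent: exploration steps are always
# suboptimal and slow, exploitation steps always optimal and fast
change_point_agent <- function() {
  agent_config(q_min = 0, q_max = 1, beta_rt = 1.5, sigma_rt = 0.1)
}

planted_stage <- function(paths, cp = 5L) {
  factor(ifelse(paths$path_index > cp, "exploitation", "exploration"),
         levels = c("exploration", "exploitation"))
}

# staged_session with planted (not classifier-derived) stages, for tests
# that exercise the neural/RSA stack in isolation
fake_staged <- function(session, cp = 5L) {
  p <- session$paths
  p$stage <- planted_stage(p, cp)
  structure(list(paths = p, subject_id = p$subject[1L]),
            class = "staged_session")
}

# minimal pe_map_set built from an explicit 4-D array
manual_pe_set <- function(dat, goals_chr, space_label, n_dims,
                          stage = "exploitation", mask = NULL) {
  n <- dim(dat)[4L]
  structure(list(
    data = dat,
    paths = data.frame(subject = "s", session_ordinal = seq_len(n),
                       space_label = space_label, n_dims = n_dims,
                       goal = goals_chr, stage = stage,
                       stringsAsFactors = FALSE),
    geometry = volume_geometry(dim(dat)[1:3], mask),
    seed = NA_integer_), class = "pe_map_set")
}

# fully separable phase encodings: early = suboptimal and slow, late =
# optimal and fast; lengths vary so the classifier cannot rely on them alone
separable_encodings <- function(n_early, n_late, max_len = 20L) {
  mk <- function(ra, rt, k) {
    b <- rbind(matrix(c(ra, rt), k, 2L, byrow = TRUE),
               matrix(-1, max_len - k, 2L))
    as.numeric(t(b))
  }
  X <- rbind(
    t(vapply(seq_len(n_early), function(i) mk(0, 0.9, sample(3:8, 1L)),
             numeric(2L * max_len))),
    t(vapply(seq_len(n_late), function(i) mk(1, 0.1, sample(2:5, 1L)),
             numeric(2L * max_len))))
  Y <- cbind(rep(c(1, 0), c(n_early, n_late)),
             rep(c(0, 1), c(n_early, n_late)))
  list(X = X, Y = Y)
}

# direct simulation from the random-intercept mixed-model structure: one row
# per subject x dimensionality x path, two-level factor coded ref/cmp
simulate_lmm_table <- function(n_subj = 25, n_dims = 3, n_per = 10,
                               beta = -0.15, sd_cell = 0.05, sd_eps = 0.1,
                               intercept = 0.6) {
  rows <- expand.grid(subject = sprintf("s%02d", 1:n_subj),
                      n_dims = 1:n_dims, rep = 1:n_per)
  rows$x <- rep_len(c("ref", "cmp"), nrow(rows))
  cell <- interaction(rows$subject, rows$n_dims)
  u <- rnorm(nlevels(cell), 0, sd_cell)
  rows$RA_path <- intercept + beta * (rows$x == "ref") +
    u[as.integer(cell)] + rnorm(nrow(rows), 0, sd_eps)
  rows
}

# --- independent oracles -------------------------------------------------

# exact 1-D 2-means: clusters of an optimal 2-partition are intervals of the
# sorted values, so try every split point and take the minimum within-SS
exhaustive_two_means <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- NULL
  for (k in 1:(n - 1L)) {
    lo <- xs[1:k]; hi <- xs[(k + 1L):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || wss < best$wss) best <- list(wss = wss, k = k)
  }
  grp <- integer(n)
  grp[o] <- rep(1:2, c(best$k, n - best$k))
  list(wss = best$wss, cluster = grp)
}

# rank correlation from first principles (average ranks for ties)
spearman_oracle <- function(a, b) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  num / sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# TFCE of a single isolated suprathreshold voxel: extent is 1 at every
# threshold, so the enhancement is sum over h of h^H * dh
single_voxel_tfce <- function(height, H = 2, dh = 0.1) {
  ks <- seq_len(floor(height / dh + 1e-9))
  sum((ks * dh)^H * dh)
}
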
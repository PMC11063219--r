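#' Label learning phases within each space
#'
#' Within each 10-path space, the first three paths are labelled the early
#' learning phase, the last three the late learning phase, and the middle
#' four mid. Labels follow the path ordinal only; terminated paths keep their
#' ordinal label.
#'
#' @param session A `nav_session`.
#' @return The session's path table with a `phase` factor column
#'   (`early`/`mid`/`late`).
#' @export
label_phases <- function(session) {
  paths <- path_summaries(session)
  counts <- table(paths$space_label)
  if (any(counts != 10L))
    stop("phase labelling requires exactly 10 paths per space; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  phase <- rep("mid", nrow(paths))
  phase[paths$path_index <= 3L] <- "early"
  phase[paths$path_index >= 8L] <- "late"
  paths$phase <- factor(phase, levels = c("early", "mid", "late"))
  paths
}

#' Dimensionality groups of a session
#'
#' Spaces sharing a dimensionality are pooled and kept in session (time)
#' order: 1D = S1P then S1C, 2D = S2C then S2P, 3D = S3P. The phase
#' classifier and the exploration/exploitation split both operate per group.
#'
#' @param labeled_paths Path table from [label_phases()].
#' @return Named list (`"1"`, `"2"`, `"3"`) of path-table subsets, each in
#'   session order.
#' @export
dim_groups <- function(labeled_paths) {
  out <- split(labeled_paths, labeled_paths$n_dims)
  lapply(out, function(df) df[order(df$session_ordinal), ])
}

#' Encode paths as fixed-length classifier inputs
#'
#' Each path's step matrix B (one (RA, RT) row per step) becomes a
#' fixed-length vector: RT is min-max scaled to \[0, 1\] across all steps of
#' the subject, rows beyond `max_len` are dropped, shorter paths are padded
#' with sentinel rows (-1, -1), and the result is flattened row-major
#' (RA1, RT1, RA2, RT2, ...).
#'
#' @param session A `nav_session`.
#' @param ordinals Session ordinals of the paths to encode (in order).
#' @param max_len Maximum number of steps retained (default 20).
#' @return Numeric matrix, one row per path, `2 * max_len` columns.
#' @export
encode_paths <- function(session, ordinals, max_len = 20L) {
  stopifnot(max_len >= 1L)
  steps <- session$steps
  rt_min <- min(steps$RT)
  rt_rng <- max(steps$RT) - rt_min
  if (rt_rng == 0) rt_rng <- 1  # constant RT: scale to all-zero
  enc <- t(vapply(ordinals, function(o) {
    st <- steps[steps$session_ordinal == o, ]
    st <- st[order(st$step_index), ]
    b <- cbind(st$RA, (st$RT - rt_min) / rt_rng)
    n <- nrow(b)
    if (n > max_len) b <- b[seq_len(max_len), , drop = FALSE]
    if (n < max_len) b <- rbind(b, matrix(-1, max_len - n, 2L))
    as.numeric(t(b))
  }, numeric(2L * max_len)))
  if (length(ordinals) == 1L) enc <- matrix(enc, nrow = 1L)
  enc
}

#' Split labelled paths of a group into training and test sets
#'
#' Two early/late-labelled paths are withheld uniformly at random as the test
#' set; the remaining labelled paths train the classifier (10 paths in the
#' two-space 1D and 2D groups, 4 in the single-space 3D group). Mid-phase
#' paths enter neither set.
#'
#' @param group_paths One group from [dim_groups()].
#' @return List with data.frames `train` and `test`.
#' @export
split_train_test <- function(group_paths) {
  labeled <- group_paths[group_paths$phase %in% c("early", "late"), ]
  if (nrow(labeled) < 3L)
    stop("need at least 3 early/late paths to split; got ", nrow(labeled))
  test_i <- sample.int(nrow(labeled), 2L)
  list(train = labeled[-test_i, ], test = labeled[test_i, ])
}

# ---- feedforward phase classifier (dense 2*max_len -> 64 -> 32 -> 2) ------

#' Classifier architecture and training hyperparameters
#'
#' A feedforward network with two ReLU hidden layers (64 and 32 units) and a
#' 2-unit softmax output, trained full batch with categorical cross-entropy
#' and the Adam optimiser.
#'
#' @param input_len Input vector length (2 * max_len).
#' @param hidden Hidden-layer widths.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param init_scale Half-width of the uniform weight initialisation.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(input_len = 40L, hidden = c(64L, 32L),
                            lr = 0.001, epochs = 100L, init_scale = 0.1) {
  structure(list(sizes = c(input_len, hidden, 2L), lr = lr,
                 epochs = as.integer(epochs), init_scale = init_scale),
            class = "classifier_spec")
}

#' Chance-level test accuracy of the phase classifier
#'
#' With two equiprobable labels and a two-path test set scored per epoch, the
#' random baseline is 0.25 (= 0.5 / 2).
#' @return 0.25
#' @export
classifier_chance_level <- function() 0.5 / 2

mlp_init <- function(spec) {
  s <- spec$sizes
  params <- list()
  for (i in seq_len(length(s) - 1L)) {
    params[[paste0("W", i)]] <- matrix(
      stats::runif(s[i] * s[i + 1L], -spec$init_scale, spec$init_scale),
      s[i], s[i + 1L])
    params[[paste0("b", i)]] <- rep(0, s[i + 1L])
  }
  params
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns per-layer activations for backprop
mlp_forward <- function(params, X) {
  n_layers <- length(params) / 2L
  acts <- list(X)
  a <- X
  for (i in seq_len(n_layers)) {
    z <- a %*% params[[paste0("W", i)]] +
      rep(params[[paste0("b", i)]], each = nrow(a))
    a <- if (i < n_layers) pmax(z, 0) else softmax_rows(z)
    acts[[i + 1L]] <- a
  }
  list(probs = a, acts = acts)
}

# mean categorical cross-entropy
mlp_loss <- function(probs, Y) -mean(rowSums(Y * log(pmax(probs, 1e-12))))

# analytic gradients of the mean cross-entropy wrt all params
mlp_gradients <- function(params, acts, probs, Y) {
  n_layers <- length(params) / 2L
  n <- nrow(Y)
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  delta <- (probs - Y) / n        # d loss / d logits, softmax + CE
  for (i in rev(seq_len(n_layers))) {
    grads[[paste0("W", i)]] <- crossprod(acts[[i]], delta)
    grads[[paste0("b", i)]] <- colSums(delta)
    if (i > 1L) {
      delta <- (delta %*% t(params[[paste0("W", i)]])) * (acts[[i]] > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the phase classifier on one dimensionality group
#'
#' Full-batch gradient training with Adam for `spec$epochs` epochs. After
#' each epoch the test loss and test accuracy are recorded; the returned
#' parameters are those from the epoch with minimum test loss, and
#' `mean_test_accuracy` is the mean of the per-epoch test accuracies — the
#' quantity compared against the 0.25 chance baseline.
#'
#' @param X_train,Y_train Training inputs and one-hot labels (early, late).
#' @param X_test,Y_test Test inputs and labels.
#' @param spec A `classifier_spec`.
#' @return List of class `trained_classifier`: `params`, `mean_test_accuracy`,
#'   `test_loss`, `test_accuracy` (per-epoch traces), `best_epoch`.
#' @export
train_classifier <- function(X_train, Y_train, X_test, Y_test,
                             spec = classifier_spec(ncol(X_train))) {
  stopifnot(nrow(X_train) >= 1L, nrow(X_test) >= 1L,
            ncol(Y_train) == 2L, ncol(Y_test) == 2L)
  params <- mlp_init(spec)
  state <- adam_init(params)
  test_loss <- test_acc <- numeric(spec$epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (e in seq_len(spec$epochs)) {
    fw <- mlp_forward(params, X_train)
    if (!is.finite(mlp_loss(fw$probs, Y_train)))
      stop("non-finite training loss at epoch ", e)
    grads <- mlp_gradients(params, fw$acts, fw$probs, Y_train)
    upd <- adam_step(params, grads, state, spec$lr)
    params <- upd$params
    state <- upd$state
    te <- mlp_forward(params, X_test)
    test_loss[e] <- mlp_loss(te$probs, Y_test)
    test_acc[e] <- mean(max.col(te$probs) == max.col(Y_test))
    if (test_loss[e] < best$loss)
      best <- list(loss = test_loss[e], params = params, epoch = e)
  }
  structure(list(params = best$params, mean_test_accuracy = mean(test_acc),
                 test_loss = test_loss, test_accuracy = test_acc,
                 best_epoch = best$epoch, spec = spec),
            class = "trained_classifier")
}

#' Predict per-path learning levels
#'
#' Runs the trained classifier forward on the encoded paths and returns
#' P(early), the probability that a path belongs to the early learning
#' phase; this is the learning level used for staging (high P(early) =
#' unlearned behaviour).
#'
#' @param model A `trained_classifier`.
#' @param X Encoded path matrix (rows = paths).
#' @return Numeric vector of P(early) values in \[0, 1\].
#' @export
predict_learning_level <- function(model, X) {
  if (ncol(X) != model$spec$sizes[1L])
    stop("encoded length ", ncol(X), " does not match classifier input ",
         model$spec$sizes[1L])
  mlp_forward(model$params, X)$probs[, 1L]
}

one_hot_phase <- function(phase) {
  # column 1 = early, column 2 = late
  cbind(as.numeric(phase == "early"), as.numeric(phase == "late"))
}

#' Two-means clustering of scalar learning levels
#'
#' Lloyd's algorithm on one-dimensional data. Because an optimal 1-D
#' 2-partition is always a split of the sorted values, Lloyd iterations are
#' started from every sorted-split center pair (plus `n_restarts` seeded
#' random restarts), which attains the exact optimum of 2-means on scalars
#' (verified in the test suite against an exhaustive-split oracle). The
#' cluster with the higher mean P(early) is the exploration stage; the
#' other is exploitation.
#'
#' @param levels Numeric vector of P(early) values (length >= 2, not all
#'   identical).
#' @param n_restarts Additional random restarts of Lloyd's algorithm.
#' @return Factor of `"exploration"` / `"exploitation"` per value.
#' @export
kmeans_two <- function(levels, n_restarts = 10L) {
  if (length(levels) < 2L) stop("need at least 2 values")
  if (max(levels) == min(levels)) stop("degenerate input: all values identical")
  xs <- sort(levels)
  n <- length(xs)
  inits <- lapply(1:(n - 1L), function(k)
    c(mean(xs[1:k]), mean(xs[(k + 1L):n])))
  for (r in seq_len(n_restarts)) {
    centers <- sample(levels, 2L)
    while (centers[1L] == centers[2L]) centers <- sample(levels, 2L)
    inits[[length(inits) + 1L]] <- centers
  }
  best <- NULL
  for (centers in inits) {
    if (centers[1L] == centers[2L]) next
    for (it in 1:100) {
      assign <- ifelse(abs(levels - centers[1L]) <= abs(levels - centers[2L]),
                       1L, 2L)
      if (length(unique(assign)) < 2L) break
      new_centers <- c(mean(levels[assign == 1L]), mean(levels[assign == 2L]))
      if (all(new_centers == centers)) break
      centers <- new_centers
    }
    if (length(unique(assign)) < 2L) next
    wss <- sum((levels - centers[assign])^2)
    if (is.null(best) || wss < best$wss)
      best <- list(wss = wss, assign = assign, centers = centers)
  }
  if (is.null(best)) stop("2-means failed to find two nonempty clusters")
  m1 <- mean(levels[best$assign == 1L])
  m2 <- mean(levels[best$assign == 2L])
  if (m1 == m2) stop("cluster means tie exactly; staging undefined")
  explore_cluster <- if (m1 > m2) 1L else 2L
  factor(ifelse(best$assign == explore_cluster, "exploration", "exploitation"),
         levels = c("exploration", "exploitation"))
}

#' Stage all paths of one subject
#'
#' For each dimensionality group: label phases, encode the step matrices,
#' withhold two labelled paths as the test set, train the phase classifier,
#' predict P(early) for every path of the group, and split the paths into
#' exploration and exploitation by 2-means on P(early).
#'
#' @param session A `nav_session`.
#' @param seed Integer seed controlling the split, weight initialisation and
#'   clustering restarts.
#' @param spec A `classifier_spec` (input length must equal `2 * max_len`).
#' @param max_len Maximum encoded path length in steps.
#' @return List of class `staged_session`: `paths` (path table with
#'   `P_early` and `stage` columns), `group_summary` (per-dimensionality
#'   mean test accuracy, stage counts, best epoch).
#' @export
stage_session <- function(session, seed = 1L,
                          spec = classifier_spec(2L * max_len),
                          max_len = 20L) {
  set.seed(as.integer(seed))
  labeled <- label_phases(session)
  groups <- dim_groups(labeled)
  out_paths <- list()
  summaries <- list()
  for (g in names(groups)) {
    gp <- groups[[g]]
    sp <- split_train_test(gp)
    X_train <- encode_paths(session, sp$train$session_ordinal, max_len)
    X_test <- encode_paths(session, sp$test$session_ordinal, max_len)
    model <- train_classifier(X_train, one_hot_phase(sp$train$phase),
                              X_test, one_hot_phase(sp$test$phase), spec)
    X_all <- encode_paths(session, gp$session_ordinal, max_len)
    gp$P_early <- predict_learning_level(model, X_all)
    gp$stage <- kmeans_two(gp$P_early)
    out_paths[[g]] <- gp
    summaries[[g]] <- data.frame(
      n_dims = as.integer(g), n_train = nrow(sp$train), n_test = nrow(sp$test),
      mean_test_accuracy = model$mean_test_accuracy,
      best_epoch = model$best_epoch,
      n_exploration = sum(gp$stage == "exploration"),
      n_exploitation = sum(gp$stage == "exploitation"))
  }
  paths <- do.call(rbind, out_paths)
  paths <- paths[order(paths$session_ordinal), ]
  rownames(paths) <- NULL
  structure(list(paths = paths,
                 group_summary = do.call(rbind, c(summaries,
                                                  make.row.names = FALSE)),
                 subject_id = session$subject_id, seed = as.integer(seed)),
            class = "staged_session")
}

#' Stage every subject of a cohort
#'
#' @param sessions List of `nav_session` objects.
#' @param seed Master seed; per-subject staging seeds are derived from it.
#' @param ... Passed to [stage_session()].
#' @return List of `staged_session` objects.
#' @export
stage_cohort <- function(sessions, seed = 1L, ...) {
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(sessions))
  out <- Map(function(s, sd) stage_session(s, seed = sd, ...),
             sessions, sub_seeds)
  names(out) <- names(sessions)
  out
}

#' Combined path table of a staged cohort
#'
#' @param staged List of `staged_session` objects.
#' @return One data.frame with all subjects' staged paths.
#' @export
staged_path_table <- function(staged) {
  do.call(rbind, c(lapply(staged, `[[`, "paths"), make.row.names = FALSE))
}
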
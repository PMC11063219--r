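session_fixture <- function(seed = 101) simulate_session(agent_config(), seed)

test_that("phase labels follow the 3/4/3 ordinal rule", {
  s <- session_fixture()
  lab <- label_phases(s)
  for (sp in space_order()) {
    ph <- lab$phase[lab$space_label == sp][order(lab$path_index[lab$space_label == sp])]
    expect_equal(as.character(ph),
                 rep(c("early", "mid", "late"), c(3, 4, 3)))
  }
  # terminated paths keep their ordinal label
  term_late <- lab[lab$outcome == "terminated" & lab$path_index >= 8, ]
  if (nrow(term_late)) expect_true(all(term_late$phase == "late"))
  # wrong path count errors
  s9 <- s
  s9$paths <- s$paths[-1, ]
  expect_error(label_phases(s9), "10 paths")
})

test_that("dimensionality groups pool spaces in session order", {
  g <- dim_groups(label_phases(session_fixture()))
  expect_equal(names(g), c("1", "2", "3"))
  expect_equal(nrow(g[["1"]]), 20L)
  expect_equal(nrow(g[["2"]]), 20L)
  expect_equal(nrow(g[["3"]]), 10L)
  expect_equal(unique(g[["1"]]$space_label), c("S1P", "S1C"))
  expect_equal(unique(g[["2"]]$space_label), c("S2C", "S2P"))
  expect_true(all(diff(g[["2"]]$session_ordinal) > 0))
})

test_that("path encoding pads, truncates and scales as specified", {
  s <- session_fixture()
  n_steps <- s$paths$n_steps
  o_short <- s$paths$session_ordinal[which(n_steps == 3)[1]]
  enc <- encode_paths(s, o_short, max_len = 5L)
  expect_equal(dim(enc), c(1L, 10L))
  expect_equal(enc[1, 7:10], rep(-1, 4))   # two sentinel rows appended
  # RT scaled into [0,1] over the subject's steps
  rts <- enc[1, c(2, 4, 6)]
  expect_true(all(rts >= 0 & rts <= 1))
  st <- s$steps[s$steps$session_ordinal == o_short, ]
  expect_equal(rts, (st$RT - min(s$steps$RT)) / diff(range(s$steps$RT)))
  # truncation keeps the first max_len rows
  o_long <- s$paths$session_ordinal[which(n_steps >= 7)[1]]
  enc2 <- encode_paths(s, o_long, max_len = 5L)
  full <- encode_paths(s, o_long, max_len = 20L)
  expect_equal(enc2[1, ], full[1, 1:10])
  # exact-length path unchanged apart from scaling
  o3 <- s$paths$session_ordinal[which(n_steps == 3)[1]]
  enc3 <- encode_paths(s, o3, max_len = 3L)
  expect_equal(enc3[1, c(1, 3, 5)],
               s$steps$RA[s$steps$session_ordinal == o3])
})

test_that("train/test split withholds 2 labelled paths and keeps mid out", {
  g <- dim_groups(label_phases(session_fixture()))
  set.seed(5)
  sp1 <- split_train_test(g[["1"]])
  expect_equal(nrow(sp1$train), 10L)
  expect_equal(nrow(sp1$test), 2L)
  sp3 <- split_train_test(g[["3"]])
  expect_equal(nrow(sp3$train), 4L)
  both <- rbind(sp3$train, sp3$test)
  expect_setequal(both$session_ordinal,
                  g[["3"]]$session_ordinal[g[["3"]]$phase %in% c("early", "late")])
  expect_false(any(sp3$train$session_ordinal %in% sp3$test$session_ordinal))
  expect_true(all(both$phase %in% c("early", "late")))
  tiny <- g[["3"]][1:4, ]
  tiny$phase <- factor("mid", levels = levels(tiny$phase))
  expect_error(split_train_test(tiny), "at least 3")
})

test_that("forward pass conserves probability and is deterministic", {
  spec <- classifier_spec(10L, hidden = c(8L, 4L))
  set.seed(9)
  params <- abstractnav:::mlp_init(spec)
  X <- matrix(rnorm(50), 5, 10)
  fw <- abstractnav:::mlp_forward(params, X)
  expect_equal(rowSums(fw$probs), rep(1, 5))
  expect_true(all(fw$probs > 0))
  fw2 <- abstractnav:::mlp_forward(params, X)
  expect_identical(fw$probs, fw2$probs)
})

test_that("analytic gradients match central finite differences", {
  spec <- classifier_spec(6L, hidden = c(5L, 3L))
  set.seed(10)
  params <- abstractnav:::mlp_init(spec)
  # move biases off zero so no preactivation sits exactly on the ReLU kink,
  # where the two-sided difference quotient is ill-defined
  for (k in grep("^b", names(params), value = TRUE))
    params[[k]] <- runif(length(params[[k]]), 0.05, 0.2)
  X <- matrix(rnorm(24), 4, 6)
  Y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  fw <- abstractnav:::mlp_forward(params, X)
  grads <- abstractnav:::mlp_gradients(params, fw$acts, fw$probs, Y)
  loss_at <- function(p) {
    abstractnav:::mlp_loss(abstractnav:::mlp_forward(p, X)$probs, Y)
  }
  h <- 1e-6
  for (k in names(params)) {
    idx <- sample(length(params[[k]]), min(5L, length(params[[k]])))
    for (i in idx) {
      up <- params; up[[k]][i] <- up[[k]][i] + h
      dn <- params; dn[[k]][i] <- dn[[k]][i] - h
      fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
      expect_lt(abs(grads[[k]][i] - fd), 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("training separable phases beats the 0.25 chance baseline by far", {
  expect_equal(classifier_chance_level(), 0.25)
  accs <- vapply(1:20, function(sd) {
    set.seed(sd)
    tr <- separable_encodings(5, 5)
    te <- separable_encodings(1, 1)
    train_classifier(tr$X, tr$Y, te$X, te$Y)$mean_test_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
  expect_gt(mean(accs), classifier_chance_level())
})

test_that("shuffled labels leave test accuracy near the chance baseline", {
  accs <- vapply(1:20, function(sd) {
    set.seed(100 + sd)
    tr <- separable_encodings(5, 5)
    tr$Y <- tr$Y[sample(nrow(tr$Y)), ]
    te <- separable_encodings(1, 1)
    te$Y <- te$Y[sample(2), ]
    train_classifier(tr$X, tr$Y, te$X, te$Y)$mean_test_accuracy
  }, numeric(1))
  # noisy per-seed, but the average cannot sit far above chance
  expect_lt(mean(accs), 0.7)
})

test_that("an untrained classifier still returns valid probabilities", {
  set.seed(11)
  tr <- separable_encodings(5, 5)
  te <- separable_encodings(1, 1)
  m0 <- train_classifier(tr$X, tr$Y, te$X, te$Y,
                         classifier_spec(40L, epochs = 0L))
  expect_equal(m0$best_epoch, 0L)
  p <- predict_learning_level(m0, tr$X)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("predicted learning levels are probabilities and deterministic", {
  set.seed(12)
  tr <- separable_encodings(5, 5)
  te <- separable_encodings(1, 1)
  m <- train_classifier(tr$X, tr$Y, te$X, te$Y)
  probs <- abstractnav:::mlp_forward(m$params, tr$X)$probs
  expect_equal(rowSums(probs), rep(1, nrow(tr$X)))
  p1 <- predict_learning_level(m, tr$X)
  p2 <- predict_learning_level(m, tr$X)
  expect_identical(p1, p2)
  expect_equal(p1, probs[, 1])
  # an early-phase exemplar scores above 0.5
  expect_gt(p1[1], 0.5)
  expect_error(predict_learning_level(m, tr$X[, 1:10]), "does not match")
})

test_that("1-D 2-means equals the exhaustive split oracle on 1000 vectors", {
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(5:20, 1)
    x <- switch(1 + i %% 3,
                runif(n),
                c(runif(ceiling(n / 2), 0, 0.3), runif(floor(n / 2), 0.6, 1)),
                rbeta(n, 0.5, 0.5))
    if (max(x) == min(x)) next
    km <- kmeans_two(x)
    oracle <- exhaustive_two_means(x)
    got_wss <- sum((x[km == "exploration"] - mean(x[km == "exploration"]))^2) +
      sum((x[km == "exploitation"] - mean(x[km == "exploitation"]))^2)
    expect_equal(got_wss, oracle$wss, tolerance = 1e-12)
  }
})

test_that("2-means labels the high-P(early) cluster as exploration", {
  set.seed(14)
  st <- kmeans_two(c(0.95, 0.9, 0.85, 0.15, 0.1, 0.05))
  expect_equal(as.character(st),
               rep(c("exploration", "exploitation"), each = 3))
  st2 <- kmeans_two(c(0.8, 0.2))
  expect_equal(as.character(st2), c("exploration", "exploitation"))
  expect_error(kmeans_two(rep(0.4, 6)), "identical")
  expect_error(kmeans_two(0.5), "at least 2")
})

test_that("staging a session is reproducible and reports group summaries", {
  s <- session_fixture(707)
  g1 <- stage_session(s, seed = 15)
  g2 <- stage_session(s, seed = 15)
  expect_identical(g1$paths$stage, g2$paths$stage)
  expect_identical(g1$paths$P_early, g2$paths$P_early)
  expect_equal(g1$group_summary$n_train, c(10L, 10L, 4L))
  expect_equal(g1$group_summary$n_test, c(2L, 2L, 2L))
  expect_equal(g1$group_summary$n_exploration + g1$group_summary$n_exploitation,
               c(20L, 20L, 10L))
  expect_true(all(g1$paths$P_early >= 0 & g1$paths$P_early <= 1))
  expect_equal(nrow(g1$paths), 50L)
})

test_that("staging recovers a planted change-point in most paths", {
  sess <- simulate_cohort(8, change_point_agent(), seed = 16,
                          level_fn = change_point_level(5L))
  staged <- stage_cohort(sess, seed = 17)
  tab <- staged_path_table(staged)
  ok <- as.character(tab$stage) == as.character(planted_stage(tab, 5L))
  expect_gte(mean(ok), 0.85)
  # exploration paths behave worse than exploitation paths in most subjects
  worse <- vapply(staged, function(st) {
    mean(st$paths$RA_path[st$paths$stage == "exploration"]) <
      mean(st$paths$RA_path[st$paths$stage == "exploitation"])
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})
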
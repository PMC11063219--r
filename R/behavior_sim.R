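#' Agent configuration for the behavioral simulator
#'
#' The synthetic agent chooses a distance-minimising (optimal) option with
#' probability `q(L) = q_min + (q_max - q_min) * L`, where the latent learning
#' level `L` follows a logistic curve over the within-dimensionality path
#' index. Set-2 spaces start further along the curve by `transfer_offset`
#' paths, planting a transfer effect. Response times are lognormal with the
#' log-mean decreasing in `L`. After any suboptimal step the path terminates
#' with probability `p_terminate` (default 0.20, the task's rule for limiting
#' time spent on a path).
#'
#' @param q_min,q_max Probability of an optimal choice at zero / full learning.
#' @param k_learn Logistic slope of the learning curve per path.
#' @param t0 Logistic midpoint (within-dimensionality path index).
#' @param transfer_offset Path-index head start applied to Set-2 spaces.
#' @param mu_rt Baseline log response time (log seconds).
#' @param beta_rt Decrease in log RT per unit learning level.
#' @param sigma_rt Log RT noise SD (> 0).
#' @param p_terminate Termination probability after a suboptimal step.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(q_min = 0.35, q_max = 0.95, k_learn = 0.55, t0 = 8,
                         transfer_offset = 5, mu_rt = 0.6, beta_rt = 0.7,
                         sigma_rt = 0.25, p_terminate = 0.20) {
  stopifnot(q_min >= 0, q_max <= 1, q_min <= q_max, sigma_rt > 0,
            p_terminate >= 0, p_terminate <= 1)
  structure(list(q_min = q_min, q_max = q_max, k_learn = k_learn, t0 = t0,
                 transfer_offset = transfer_offset, mu_rt = mu_rt,
                 beta_rt = beta_rt, sigma_rt = sigma_rt,
                 p_terminate = p_terminate),
            class = "agent_config")
}

#' Latent learning level of the simulated agent
#'
#' @param agent An `agent_config`.
#' @param group_path_index 1-based path index within the dimensionality group
#'   (spaces of the same dimensionality concatenated in session order).
#' @param set_index 1 or 2; Set-2 spaces get the transfer head start.
#' @return Learning level in \[0, 1\], non-decreasing in the path index.
#' @export
true_learning_level <- function(agent, group_path_index, set_index = 1L) {
  t <- group_path_index + agent$transfer_offset * (set_index == 2L)
  stats::plogis(agent$k_learn * (t - agent$t0))
}

#' Simulate one navigation path
#'
#' Starting from `start`, the agent repeatedly receives an option set around
#' its current location; with probability `q(L)` it picks uniformly among the
#' flagged-optimal options, otherwise uniformly among the non-optimal ones
#' (or an optimal one if no alternative exists). Choosing the goal completes
#' the path; after a suboptimal step (RA = 0) the path terminates with
#' probability `p_terminate`. Terminated paths keep all their steps and enter
#' every downstream analysis.
#'
#' @param space An `abstract_space`.
#' @param agent An `agent_config`.
#' @param L Learning level in \[0, 1\] for this path.
#' @param start,goal Endpoint locations, `start != goal`.
#' @return List with `steps` (data.frame: step_index, current, goal, choice,
#'   RA, RT, n_options) and `outcome` (`"completed"` or `"terminated"`).
#' @export
simulate_path <- function(space, agent, L, start, goal) {
  q <- agent$q_min + (agent$q_max - agent$q_min) * L
  current <- .check_location(space, start)
  goal <- .check_location(space, goal)
  rows <- list()
  outcome <- NA_character_
  step <- 0L
  repeat {
    step <- step + 1L
    os <- generate_options(space, current, goal)
    pick_optimal <- stats::runif(1L) < q || all(os$optimal_flags)
    cand <- which(os$optimal_flags == pick_optimal)
    choice_i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    choice <- os$options[choice_i, ]
    ra <- as.integer(os$optimal_flags[choice_i])
    rt <- exp(agent$mu_rt - agent$beta_rt * L + agent$sigma_rt * stats::rnorm(1L))
    rows[[step]] <- data.frame(
      step_index = step, current = format_location(current),
      goal = format_location(goal), choice = format_location(choice),
      RA = ra, RT = rt, n_options = nrow(os$options),
      stringsAsFactors = FALSE)
    if (all(choice == goal)) { outcome <- "completed"; break }
    if (ra == 0L && stats::runif(1L) < agent$p_terminate) {
      outcome <- "terminated"; break
    }
    current <- choice
  }
  list(steps = do.call(rbind, rows), outcome = outcome)
}

#' Simulate a full five-space session for one subject
#'
#' The five spaces are visited in the fixed order S1P, S2C, S2P, S1C, S3P,
#' with 10 paths per space and freshly sampled endpoints per path. The
#' agent's learning level advances along the within-dimensionality path index
#' so that the second space of a dimensionality continues (and, with a
#' positive `transfer_offset`, jumps ahead on) the curve begun in the first.
#'
#' @param agent An `agent_config`.
#' @param seed Integer seed; the session is a pure function of
#'   `(agent, seed)`.
#' @param subject_id Identifier stored in the output tables.
#' @param n_paths Paths per space (default 10).
#' @param level_fn Optional override of the learning-level schedule: a
#'   function of `(space_label, set_index, group_path_index, path_index)`
#'   returning `L` in \[0, 1\]. Used e.g. to plant abrupt change-points for
#'   recovery tests; the default is the agent's logistic curve.
#' @return List of class `nav_session`: `steps` (long per-step data.frame),
#'   `paths` (per-path data.frame with RA_path, RT_path, outcome, phase
#'   metadata columns), `subject_id`, `seed`.
#' @export
simulate_session <- function(agent, seed, subject_id = "sub01", n_paths = 10L,
                             level_fn = NULL) {
  set.seed(as.integer(seed))
  step_rows <- list()
  path_rows <- list()
  ordinal <- 0L
  group_count <- c(`1` = 0L, `2` = 0L, `3` = 0L)
  for (lab in space_order()) {
    sp <- abstract_space(lab)
    dim_key <- as.character(sp$n_dims)
    for (p in seq_len(n_paths)) {
      ordinal <- ordinal + 1L
      group_count[dim_key] <- group_count[dim_key] + 1L
      L <- if (is.null(level_fn))
        true_learning_level(agent, group_count[dim_key], sp$set_index)
      else level_fn(lab, sp$set_index, group_count[[dim_key]], p)
      ep <- sample_endpoints(sp)
      res <- simulate_path(sp, agent, L, ep$start, ep$goal)
      st <- res$steps
      st$subject <- subject_id
      st$space_label <- lab
      st$set_index <- sp$set_index
      st$n_dims <- sp$n_dims
      st$path_index <- p
      st$session_ordinal <- ordinal
      st$outcome <- res$outcome
      step_rows[[ordinal]] <- st
      path_rows[[ordinal]] <- data.frame(
        subject = subject_id, space_label = lab, set_index = sp$set_index,
        n_dims = sp$n_dims, path_index = p, session_ordinal = ordinal,
        group_path_index = group_count[[dim_key]],
        start = format_location(ep$start), goal = format_location(ep$goal),
        n_steps = nrow(st), outcome = res$outcome,
        RA_path = mean(st$RA), RT_path = mean(st$RT),
        true_L = L, stringsAsFactors = FALSE)
    }
  }
  steps <- do.call(rbind, step_rows)
  cols <- c("subject", "space_label", "set_index", "n_dims", "path_index",
            "session_ordinal", "step_index", "current", "goal", "choice",
            "RA", "RT", "outcome")
  structure(list(steps = steps[, cols], paths = do.call(rbind, path_rows),
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "nav_session")
}

#' @export
print.nav_session <- function(x, ...) {
  cat(sprintf("<nav_session %s: %d paths, %d steps, seed %d>\n",
              x$subject_id, nrow(x$paths), nrow(x$steps), x$seed))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the whole cohort is reproducible from `(agent, n_subjects, seed)`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param agent An `agent_config`.
#' @param seed Master integer seed.
#' @param level_fn Optional learning-level override, see
#'   [simulate_session()].
#' @return List of `nav_session` objects named `sub01`, `sub02`, ...
#' @export
simulate_cohort <- function(n_subjects, agent = agent_config(), seed = 1L,
                            level_fn = NULL) {
  stopifnot(n_subjects >= 1L)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  out <- lapply(seq_len(n_subjects), function(i) {
    simulate_session(agent, sub_seeds[i], sprintf("sub%02d", i),
                     level_fn = level_fn)
  })
  names(out) <- vapply(out, `[[`, "", "subject_id")
  out
}

#' Per-path behavioral summaries
#'
#' Arithmetic means of step RA and RT per path. Terminated paths are included
#' like completed ones.
#'
#' @param session A `nav_session`.
#' @return The session's per-path data.frame (one row per path, with
#'   `RA_path` and `RT_path`).
#' @export
path_summaries <- function(session) {
  stopifnot(inherits(session, "nav_session"))
  session$paths
}

#' Write / read the long-format behavioral CSV
#'
#' One row per step; coordinates serialized as semicolon-joined integers.
#'
#' @param sessions A `nav_session` or list of them.
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_behavior_csv <- function(sessions, path) {
  if (inherits(sessions, "nav_session")) sessions <- list(sessions)
  steps <- do.call(rbind, lapply(sessions, `[[`, "steps"))
  utils::write.csv(steps, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @param drop_incomplete Error if a (subject, space) block has missing steps.
#' @return `read_behavior_csv`: a list of `nav_session` objects rebuilt from
#'   the step table.
#' @export
read_behavior_csv <- function(path, drop_incomplete = FALSE) {
  steps <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "space_label", "set_index", "n_dims", "path_index",
              "session_ordinal", "step_index", "current", "goal", "choice",
              "RA", "RT", "outcome")
  missing <- setdiff(needed, names(steps))
  if (length(missing)) stop("behavioral CSV lacks columns: ",
                            paste(missing, collapse = ", "))
  lapply(split(steps, steps$subject), session_from_steps)
}

# rebuild a nav_session (steps + path summaries) from a per-step table
session_from_steps <- function(steps) {
  steps <- steps[order(steps$session_ordinal, steps$step_index), ]
  by_path <- split(steps, steps$session_ordinal)
  group_count <- c(`1` = 0L, `2` = 0L, `3` = 0L)
  paths <- do.call(rbind, lapply(by_path, function(st) {
    dim_key <- as.character(st$n_dims[1L])
    group_count[dim_key] <<- group_count[dim_key] + 1L
    data.frame(
      subject = st$subject[1L], space_label = st$space_label[1L],
      set_index = st$set_index[1L], n_dims = st$n_dims[1L],
      path_index = st$path_index[1L], session_ordinal = st$session_ordinal[1L],
      group_path_index = group_count[[dim_key]],
      start = st$current[1L], goal = st$goal[1L], n_steps = nrow(st),
      outcome = st$outcome[1L], RA_path = mean(st$RA), RT_path = mean(st$RT),
      true_L = NA_real_, stringsAsFactors = FALSE)
  }))
  rownames(paths) <- NULL
  structure(list(steps = steps, paths = paths,
                 subject_id = steps$subject[1L], seed = NA_integer_),
            class = "nav_session")
}

#' Empirical termination rate of suboptimal steps
#'
#' Runs an agent until at least `min_steps` suboptimal (RA = 0) steps have
#' accumulated and reports the fraction of those immediately followed by
#' path termination — the empirical counterpart of `p_terminate`.
#'
#' @param agent An `agent_config`; use `q_min = q_max = 0` for an
#'   always-suboptimal agent.
#' @param min_steps Minimum number of suboptimal steps to accumulate.
#' @param seed Integer seed.
#' @param space Space simulated in (default the 2D space S2C).
#' @return List: `fraction` (terminations / suboptimal steps),
#'   `n_suboptimal`, `n_terminated`.
#' @export
termination_rate <- function(agent = agent_config(q_min = 0, q_max = 0),
                             min_steps = 10000L, seed = 1L,
                             space = abstract_space("S2C")) {
  set.seed(as.integer(seed))
  n_sub <- 0L
  n_term <- 0L
  while (n_sub < min_steps) {
    ep <- sample_endpoints(space)
    res <- simulate_path(space, agent, L = 0, ep$start, ep$goal)
    n_sub <- n_sub + sum(res$steps$RA == 0L)
    n_term <- n_term + as.integer(res$outcome == "terminated")
  }
  list(fraction = n_term / n_sub, n_suboptimal = n_sub, n_terminated = n_term)
}
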
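#' Training configuration for HP-model Q-learning
#'
#' Bundles the hyperparameters and protocol settings of the tabular Q-learning
#' optimizer. The defaults are the study protocol: step size `alpha = 0.01`,
#' exploration probability `epsilon = 0.5`, discount `gamma = 0.9`, 5 million
#' episodes per round with one learning-curve sample every 10,000 episodes.
#'
#' @param alpha Step size in (0, 1].
#' @param gamma Discount factor in \[0, 1\].
#' @param epsilon Exploration probability in \[0, 1\].
#' @param episodes Number of training episodes.
#' @param test_interval Episodes between curve samples; 0 disables sampling.
#' @param test_policy What the periodic sample records: `"sample"` (the
#'   default) logs the energy of the sampled *training* episode itself, so the
#'   curve reflects the epsilon-greedy behaviour policy — even a converged
#'   policy then hits the minimum only in a fraction of samples, which is the
#'   hit statistic the benchmark protocol counts; `"greedy"` instead runs one
#'   frozen epsilon = 0 rollout per sample, probing the target policy (a
#'   converged learner then hits on essentially every sample).
#' @param criterion `"rigid"` (overlapping placements are invalid and another
#'   action is taken instead) or `"flexible"` (allowed, penalised -10 per
#'   invalid step).
#' @param invalid_action How the rigid criterion handles an invalid action:
#'   `"reselect"` (the default) redraws a fresh epsilon-greedy action over the
#'   full action set until a valid one occurs, as the rigid rule prescribes;
#'   `"mask"` restricts selection to the valid subset up front (equivalent in
#'   the exploration branch, but greedier when the argmax action is blocked,
#'   which speeds convergence relative to the reference protocol). Ignored
#'   under the flexible criterion.
#' @param state_mode `"full3"`, `"full4"` (full prefix-tree state space with
#'   3 or 4 actions) or `"partial"` (compressed `1 + 4(n-1)` states, 4
#'   absolute actions).
#' @param action_geometry Geometric meaning of the actions: `"relative3"`
#'   (turn-left / straight / turn-right, the default for `full3`),
#'   `"absolute3"` (L/U/R fixed directions — partially directed walks only)
#'   or `"absolute4"` (L/U/R/D; forced for `full4` and `partial`).
#' @param seed RNG seed; every training run is bitwise reproducible given the
#'   seed and configuration.
#' @param pool_cap Maximum number of distinct minimum-energy conformations
#'   retained in the result output pool.
#' @param return_q Keep the learned Q table in the result (needed by
#'   [extract_pool()]).
#' @return Object of class `hp_train_config`.
#' @export
hp_train_config <- function(alpha = 0.01, gamma = 0.9, epsilon = 0.5,
                            episodes = 5e6, test_interval = 1e4,
                            criterion = c("rigid", "flexible"),
                            state_mode = c("full3", "full4", "partial"),
                            action_geometry = NULL,
                            invalid_action = c("reselect", "mask"),
                            test_policy = c("sample", "greedy"),
                            tie_break = c("random", "first"),
                            seed = 1L, pool_cap = 1000L, return_q = TRUE) {
  criterion <- match.arg(criterion)
  invalid_action <- match.arg(invalid_action)
  test_policy <- match.arg(test_policy)
  tie_break <- match.arg(tie_break)
  state_mode <- match.arg(state_mode)
  if (is.null(action_geometry)) {
    action_geometry <- switch(state_mode,
                              full3 = "relative3",
                              full4 = "absolute4",
                              partial = "absolute4")
  }
  action_geometry <- match.arg(action_geometry,
                               c("relative3", "absolute3", "absolute4"))
  if (state_mode == "full3" && action_geometry == "absolute4") {
    stop("full3 uses a 3-action geometry (relative3 or absolute3)", call. = FALSE)
  }
  if (state_mode %in% c("full4", "partial") && action_geometry != "absolute4") {
    stop(state_mode, " requires action_geometry = 'absolute4'", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma <= 1,
            epsilon >= 0, epsilon <= 1, episodes >= 0, test_interval >= 0,
            pool_cap >= 1)
  structure(list(alpha = alpha, gamma = gamma, epsilon = epsilon,
                 episodes = as.integer(episodes),
                 test_interval = as.integer(test_interval),
                 criterion = criterion, state_mode = state_mode,
                 action_geometry = action_geometry,
                 invalid_action = invalid_action, test_policy = test_policy,
                 tie_break = tie_break, seed = as.integer(seed),
                 pool_cap = as.integer(pool_cap), return_q = return_q),
            class = "hp_train_config")
}

#' @export
print.hp_train_config <- function(x, ...) {
  cat("<hp_train_config>\n")
  cat(sprintf("  %s criterion, %s states (%s actions)\n",
              x$criterion, x$state_mode, x$action_geometry))
  cat(sprintf("  alpha=%g gamma=%g epsilon=%g; %d episodes, sample every %d; seed %d\n",
              x$alpha, x$gamma, x$epsilon, x$episodes, x$test_interval, x$seed))
  cat(sprintf("  invalid actions: %s; samples: %s; ties: %s\n",
              x$invalid_action, x$test_policy, x$tie_break))
  invisible(x)
}

config_branching <- function(config) {
  if (config$action_geometry == "absolute4") 4L else 3L
}

#' Per-step reward
#'
#' The reward function of the two training criteria. Flexible: -10 when a
#' non-terminal residue is placed on an occupied cell, 0 on a free cell, and
#' |E| of the final folded structure at the terminal step. Rigid: 0 before
#' the terminal step and |E| at it (invalid placements never occur — they are
#' masked).
#'
#' @param criterion `"rigid"` or `"flexible"`.
#' @param placement_valid Was the residue placed on a free cell?
#' @param is_terminal Is this the placement of residue n?
#' @param E Terminal energy (required when `is_terminal`).
#' @return Numeric reward.
#' @export
step_reward <- function(criterion = c("rigid", "flexible"),
                        placement_valid, is_terminal, E = NULL) {
  criterion <- match.arg(criterion)
  if (is_terminal) {
    if (is.null(E)) stop("terminal reward needs the final energy E", call. = FALSE)
    return(abs(E))
  }
  if (criterion == "flexible" && !placement_valid) -10 else 0
}

# -- R-level sparse Q table (environment hash keyed by state index) ---------

#' Create an empty Q table
#'
#' Sparse mapping from (state, action) to value; unset entries read as exactly
#' 0. The R-level table backs the reference episode runner; large-scale
#' training keeps its table in native code and returns it as a data frame.
#'
#' @param b Number of actions per state.
#' @return Object of class `hp_qtable`.
#' @export
hp_qtable <- function(b = 3L) {
  structure(list(env = new.env(parent = emptyenv()), b = as.integer(b)),
            class = "hp_qtable")
}

#' Read a Q row
#' @param q An [hp_qtable()].
#' @param s State index.
#' @return Numeric vector of length `b` (zeros when unset).
#' @export
q_row <- function(q, s) {
  key <- sprintf("%.0f", s)
  v <- q$env[[key]]
  if (is.null(v)) numeric(q$b) else v
}

q_set <- function(q, s, a, value) {
  key <- sprintf("%.0f", s)
  v <- q$env[[key]]
  if (is.null(v)) v <- numeric(q$b)
  v[a] <- value
  assign(key, v, envir = q$env)
  invisible(q)
}

#' @export
print.hp_qtable <- function(x, ...) {
  cat("<hp_qtable>", length(ls(x$env)), "visited states,", x$b, "actions\n")
  invisible(x)
}

#' Convert an R-level Q table to the tabular form
#'
#' @param q An [hp_qtable()].
#' @return List with `state` (numeric vector) and `q` (matrix, one row per
#'   visited state), the same layout `train()` returns.
#' @export
qtable_as_matrix <- function(q) {
  keys <- ls(q$env)
  m <- do.call(rbind, lapply(keys, function(k) q$env[[k]]))
  if (is.null(m)) m <- matrix(numeric(), 0, q$b)
  list(state = as.numeric(keys), q = m)
}

#' Write or read a Q-table snapshot
#'
#' Serializes a learned table as a plain TSV: the state index as a decimal
#' string in the first column, one column per action value.
#'
#' @param q Q table (`$qtable` of a train result, or an [hp_qtable()]).
#' @param path File path.
#' @return `write_qtable`: the path, invisibly. `read_qtable`: a
#'   list(state, q) table.
#' @export
write_qtable <- function(q, path) {
  if (inherits(q, "hp_qtable")) q <- qtable_as_matrix(q)
  df <- data.frame(state = sprintf("%.0f", q$state))
  for (a in seq_len(ncol(q$q))) df[[paste0("q", a)]] <- q$q[, a]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qtable
#' @export
read_qtable <- function(path) {
  df <- utils::read.delim(path, colClasses = c(state = "character"))
  list(state = as.numeric(df$state),
       q = as.matrix(df[, -1, drop = FALSE]))
}

#' Build a training configuration from a config file
#'
#' Reads a YAML or JSON file whose keys mirror the arguments of
#' [hp_train_config()]; entries in `overrides` (e.g. parsed command-line
#' flags) take precedence over the file.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param overrides Named list of settings that win over the file's.
#' @return An [hp_train_config()].
#' @export
read_train_config <- function(path, overrides = list()) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config files require the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(hp_train_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(hp_train_config, vals)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon`, a uniform draw from `valid_actions`; otherwise
#' a uniform draw among the maximizers of `Q(s, .)` restricted to
#' `valid_actions`. Exactly two uniform variates are consumed per call (the
#' explore check, then the index draw — even for a single candidate), which
#' keeps the R and native training paths on identical RNG streams.
#'
#' @param q An [hp_qtable()].
#' @param s State index.
#' @param epsilon Exploration probability.
#' @param valid_actions Integer vector of selectable actions (nonempty).
#' @return The chosen action number.
#' @export
select_action <- function(q, s, epsilon, valid_actions,
                          tie_break = c("random", "first")) {
  tie_break <- match.arg(tie_break)
  m <- length(valid_actions)
  if (m == 0L) stop("no valid action to select (dead end)", call. = FALSE)
  u <- stats::runif(1)
  if (u < epsilon) {
    return(valid_actions[min(floor(stats::runif(1) * m) + 1, m)])
  }
  vals <- q_row(q, s)[valid_actions]
  ties <- valid_actions[vals == max(vals)]
  if (tie_break == "first") return(ties[1])
  ties[min(floor(stats::runif(1) * length(ties)) + 1, length(ties))]
}

#' One-step Q-learning update
#'
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') - Q(s,a))`; at a
#' terminal transition the bootstrap term is omitted (target = r), since
#' terminal states have no successors in the episodic process.
#'
#' @param q An [hp_qtable()], updated in place.
#' @param s,a Current state index and action.
#' @param r Reward received.
#' @param s_next Successor state index.
#' @param terminal Is the transition terminal?
#' @param alpha,gamma Step size and discount.
#' @return The updated table, invisibly.
#' @export
q_update <- function(q, s, a, r, s_next, terminal, alpha, gamma) {
  target <- if (terminal) r else r + gamma * max(q_row(q, s_next))
  old <- q_row(q, s)[a]
  q_set(q, s, a, old + alpha * (target - old))
}

#' Run a single training (or test) episode
#'
#' Reference implementation of one fold attempt: residue 1 at the origin,
#' then repeated action selection, placement, reward and (optionally)
#' Q-update until residue n is placed or — under the rigid criterion — no
#' valid action remains (a dead end, which terminates the episode with no
#' terminal bonus). This pure-R runner mirrors the native loop draw-for-draw
#' and is used for inspection and cross-validation; [train()] is the fast
#' path.
#'
#' @param seq An [hp_sequence()].
#' @param q An [hp_qtable()] (updated in place when `learn = TRUE`).
#' @param config An [hp_train_config()].
#' @param learn Apply Q-updates (`FALSE` for greedy test rollouts).
#' @param epsilon Exploration probability override (defaults to the config's;
#'   test rollouts use 0).
#' @return List: `conformation` ([hp_conformation()] of the placed residues),
#'   `energy` (terminal energy, NA if dead-ended), `complete`, `legal`,
#'   `moves` (absolute direction string), `invalid_steps`, and `trajectory`
#'   (data frame of state, action, reward, next state per step).
#' @export
run_episode <- function(seq, q, config, learn = TRUE, epsilon = config$epsilon) {
  seq <- hp_sequence(seq)
  n <- length(seq)
  b <- config_branching(config)
  rigid <- config$criterion == "rigid"
  geo <- config$action_geometry
  partial <- config$state_mode == "partial"

  xs <- integer(n); ys <- integer(n)
  occ <- new.env(parent = emptyenv())
  assign("0,0", TRUE, envir = occ)
  s <- 1; k <- 1; prev_dir <- 0L
  moves <- character(0)
  invalid_steps <- 0L
  overlapped <- FALSE
  traj <- vector("list", n - 1L)

  for (i in seq_len(n - 1L) + 1L) {
    dirs <- vapply(seq_len(b), function(l) action_direction(geo, l, prev_dir), integer(1))
    nxs <- xs[i - 1L] + .DIR_DX[dirs + 1L]
    nys <- ys[i - 1L] + .DIR_DY[dirs + 1L]
    occupied <- vapply(seq_len(b), function(l)
      isTRUE(occ[[paste0(nxs[l], ",", nys[l])]]), logical(1))
    if (rigid && all(occupied)) {
      return(list(conformation = hp_conformation(cbind(x = xs[1:(i - 1L)],
                                                       y = ys[1:(i - 1L)])),
                  energy = NA_integer_, complete = FALSE, legal = FALSE,
                  moves = paste(moves, collapse = ""),
                  invalid_steps = invalid_steps,
                  trajectory = do.call(rbind, traj[seq_len(i - 2L)])))
    }
    if (rigid && config$invalid_action == "reselect") {
      l <- NULL
      for (attempt in seq_len(32L)) {
        cand <- select_action(q, s, epsilon, seq_len(b), config$tie_break)
        if (!occupied[cand]) { l <- cand; break }
      }
      if (is.null(l)) {
        valid <- which(!occupied)
        l <- valid[min(floor(stats::runif(1) * length(valid)) + 1, length(valid))]
      }
    } else {
      valid <- if (rigid) which(!occupied) else seq_len(b)
      l <- select_action(q, s, epsilon, valid, config$tie_break)
    }
    d <- dirs[l]
    xs[i] <- nxs[l]; ys[i] <- nys[l]
    was_occupied <- occupied[l]
    if (was_occupied) { overlapped <- TRUE; invalid_steps <- invalid_steps + 1L }
    assign(paste0(xs[i], ",", ys[i]), TRUE, envir = occ)

    s_next <- if (partial) partial_state_of(i, l) else transfer(s, l, b)
    terminal <- i == n
    E <- if (terminal) energy(seq, hp_conformation(cbind(x = xs, y = ys))) else NULL
    r <- step_reward(config$criterion,
                     placement_valid = !was_occupied,
                     is_terminal = terminal, E = E)
    if (learn) q_update(q, s, l, r, s_next, terminal, config$alpha, config$gamma)
    traj[[i - 1L]] <- data.frame(step = i - 1L, state = s, action = l,
                                 reward = r, next_state = s_next,
                                 terminal = terminal, valid = !was_occupied)
    moves <- c(moves, c("R", "U", "L", "D")[d + 1L])
    s <- s_next
    prev_dir <- d
  }
  conf <- hp_conformation(cbind(x = xs, y = ys))
  list(conformation = conf, energy = energy(seq, conf), complete = TRUE,
       legal = !overlapped, moves = paste(moves, collapse = ""),
       invalid_steps = invalid_steps, trajectory = do.call(rbind, traj))
}

action_direction <- function(geometry, l, prev_dir) {
  switch(geometry,
         relative3 = (prev_dir + .REL3_TURN[l]) %% 4L,
         absolute3 = .ABS3_TO_DIR[l],
         absolute4 = .ABS4_TO_DIR[l])
}

#' Train the Q-learning folder on one sequence
#'
#' Runs the configured number of episodes with epsilon-greedy exploration and
#' one-step Q-updates; every `test_interval` episodes a greedy rollout
#' (epsilon = 0, learning frozen) probes the current policy, and its energy is
#' recorded in the learning curve. Distinct legal minimum-energy test
#' conformations are collected in the result output pool. Deterministic given
#' `config$seed`.
#'
#' @param seq An [hp_sequence()] (or H/P string).
#' @param config An [hp_train_config()].
#' @param target_energy Optional known minimum energy; enables
#'   `first_hit_episode` and hit counting.
#' @return Object of class `hp_train_result`: list with `curve` (data frame
#'   episode / test_energy / legal / cumulative_best), `best_energy`,
#'   `first_hit_episode`, `pool` (list of [hp_conformation()]), `pool_energy`,
#'   `dead_ends`, `n_states_visited`, `qtable` (list(state, q) or NULL) and
#'   the `config` echo.
#' @examples
#' cfg <- hp_train_config(episodes = 20000, test_interval = 2000, seed = 7)
#' fit <- train("HPPHHPH", cfg, target_energy = -2)
#' fit$best_energy
#' @export
train <- function(seq, config = hp_train_config(), target_energy = NULL) {
  seq <- hp_sequence(seq)
  stopifnot(inherits(config, "hp_train_config"))
  isH <- as.integer(hp_residues(seq) == "H")
  set.seed(config$seed)
  res <- cpp_train(isH, config$episodes, config$alpha, config$gamma,
                   config$epsilon, config$test_interval,
                   config$criterion == "rigid",
                   config$invalid_action == "reselect",
                   if (config$state_mode == "partial") "partial" else "full",
                   config$action_geometry,
                   config$test_policy == "sample",
                   config$tie_break == "first",
                   if (is.null(target_energy)) 0L else as.integer(target_energy),
                   !is.null(target_energy), config$return_q, config$pool_cap)
  finalize_train_result(res, seq, config, target_energy)
}

finalize_train_result <- function(res, seq, config, target_energy) {
  pool <- lapply(res$pool_moves, function(mv) decode_moves(mv, "absolute4"))
  curve <- res$curve
  hits <- NA_integer_
  if (!is.null(target_energy) && nrow(curve) > 0) {
    last <- utils::tail(curve, 100)
    hits <- sum(last$legal & !is.na(last$test_energy) &
                  last$test_energy <= target_energy)
  }
  structure(list(curve = curve,
                 best_energy = res$best_energy,
                 first_hit_episode = res$first_hit_episode,
                 hits_last_100 = hits,
                 pool = pool, pool_energy = res$pool_energy,
                 pool_truncated = res$pool_truncated,
                 dead_ends = res$dead_ends,
                 n_states_visited = res$n_states_visited,
                 q_absmax = res$q_absmax,
                 qtable = res$qtable,
                 sequence = seq, config = config,
                 target_energy = target_energy),
            class = "hp_train_result")
}

#' @export
print.hp_train_result <- function(x, ...) {
  cat("<hp_train_result>", as.character(x$sequence), "\n")
  cat(sprintf("  %s / %s, %d episodes (seed %d)\n", x$config$criterion,
              x$config$state_mode, x$config$episodes, x$config$seed))
  cat(sprintf("  best legal test energy: %s; first hit episode: %s\n",
              format(x$best_energy), format(x$first_hit_episode)))
  cat(sprintf("  pool: %d conformation(s) at E = %s; dead ends: %d\n",
              length(x$pool), format(x$pool_energy), x$dead_ends))
  invisible(x)
}

#' Pure-R training loop (reference implementation)
#'
#' Same protocol as [train()] but executed entirely through [run_episode()]
#' and the R-level Q table. Orders of magnitude slower; intended for
#' cross-validation of the native loop (identical seed and configuration give
#' bitwise-identical learning curves) and for step-by-step inspection.
#'
#' @inheritParams train
#' @return An `hp_train_result` (with `qtable` from [qtable_as_matrix()]).
#' @export
train_reference <- function(seq, config = hp_train_config(),
                            target_energy = NULL) {
  seq <- hp_sequence(seq)
  n <- length(seq)
  b <- config_branching(config)
  q <- hp_qtable(b)
  set.seed(config$seed)
  curve <- data.frame(episode = integer(), test_energy = integer(),
                      legal = logical(), cumulative_best = integer())
  best <- NA_integer_
  first_hit <- NA_integer_
  dead_ends <- 0L
  pool_E <- NA_integer_
  pool_moves <- character(0)
  for (ep in seq_len(config$episodes)) {
    out <- run_episode(seq, q, config, learn = TRUE)
    if (!out$complete) dead_ends <- dead_ends + 1L
    if (config$test_interval > 0 && ep %% config$test_interval == 0) {
      te <- if (config$test_policy == "sample") out else
        run_episode(seq, q, config, learn = FALSE, epsilon = 0)
      e <- if (te$complete) te$energy else NA_integer_
      if (te$legal) {
        if (is.na(best) || e < best) best <- e
        if (!is.null(target_energy) && is.na(first_hit) && e <= target_energy) {
          first_hit <- ep
        }
        if (is.na(pool_E) || e < pool_E) { pool_E <- e; pool_moves <- character(0) }
        if (e == pool_E && !(te$moves %in% pool_moves) &&
            length(pool_moves) < config$pool_cap) {
          pool_moves <- c(pool_moves, te$moves)
        }
      }
      curve <- rbind(curve, data.frame(episode = ep, test_energy = e,
                                       legal = te$legal,
                                       cumulative_best = best))
    }
  }
  qm <- qtable_as_matrix(q)
  res <- list(curve = curve, best_energy = best,
              first_hit_episode = first_hit, pool_moves = pool_moves,
              pool_energy = pool_E, pool_truncated = FALSE,
              dead_ends = dead_ends, n_states_visited = length(qm$state),
              q_absmax = if (length(qm$state)) max(abs(qm$q)) else 0,
              qtable = qm)
  finalize_train_result(res, seq, config, target_energy)
}

#' Decode the pool of optimal conformations from a converged Q table
#'
#' Expands the greedy policy depth-first, following *all* argmax-tied actions
#' at every state (up to `cap` leaves), then keeps the distinct legal
#' conformations of minimal energy among the completed leaves. Conformations
#' are translation-normalized by anchoring residue 1 at the origin.
#'
#' @param q Q table as returned by [train()] (`$qtable`: list(state, q)) or
#'   an [hp_qtable()].
#' @param seq The sequence the table was trained on.
#' @param config The training configuration (for state mode and geometry).
#' @param cap Leaf budget; exceeding it sets the `truncated` flag.
#' @return List with `pool` (list of [hp_conformation()]), `energy`,
#'   `moves` (absolute direction strings) and `truncated`.
#' @export
extract_pool <- function(q, seq, config, cap = 1000L) {
  seq <- hp_sequence(seq)
  if (inherits(q, "hp_qtable")) q <- qtable_as_matrix(q)
  if (is.null(q)) stop("no Q table: train with return_q = TRUE", call. = FALSE)
  isH <- as.integer(hp_residues(seq) == "H")
  res <- cpp_extract_pool(q$state, q$q, isH,
                          if (config$state_mode == "partial") "partial" else "full",
                          config$action_geometry, as.integer(cap))
  keep <- res$legal == 1L
  if (!any(keep)) {
    return(list(pool = list(), energy = NA_integer_, moves = character(0),
                truncated = res$truncated))
  }
  emin <- min(res$energy[keep])
  sel <- which(keep & res$energy == emin)
  mv <- unique(res$moves[sel])
  list(pool = lapply(mv, decode_moves, encoding = "absolute4"),
       energy = emin, moves = mv, truncated = res$truncated)
}
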
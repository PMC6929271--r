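#' Greedy folding of one episode
#'
#' The myopic contact-greedy baseline: residues are placed sequentially, and
#' each step chooses uniformly at random among the valid (unoccupied) moves
#' that create the largest number of new H-H contacts. Episodes carry no
#' memory — every call is statistically independent. A dead end (no valid
#' move before residue n) returns the partial fold flagged as failed.
#'
#' @param seq An [hp_sequence()] or H/P string.
#' @return List: `conformation`, `energy` (NA when failed), `complete`.
#' @export
greedy_fold <- function(seq) {
  seq <- hp_sequence(seq)
  res <- hp_residues(seq)
  n <- length(seq)
  xs <- integer(n); ys <- integer(n)
  occ <- new.env(parent = emptyenv())
  assign("0,0", 1L, envir = occ)
  for (i in seq_len(n - 1L) + 1L) {
    nx <- xs[i - 1L] + .DIR_DX
    ny <- ys[i - 1L] + .DIR_DY
    keys <- paste0(nx, ",", ny)
    valid <- which(vapply(keys, function(k) is.null(occ[[k]]), logical(1),
                          USE.NAMES = FALSE))
    if (length(valid) == 0L) {
      return(list(conformation = hp_conformation(cbind(x = xs[1:(i - 1L)],
                                                       y = ys[1:(i - 1L)])),
                  energy = NA_integer_, complete = FALSE))
    }
    gain <- vapply(valid, function(d) {
      if (res[i] != "H") return(0L)
      nbx <- nx[d] + .DIR_DX; nby <- ny[d] + .DIR_DY
      sum(vapply(seq_len(4), function(t) {
        j <- occ[[paste0(nbx[t], ",", nby[t])]]
        !is.null(j) && j != i - 1L && res[j] == "H"
      }, logical(1)))
    }, integer(1))
    best <- valid[gain == max(gain)]
    d <- best[min(floor(stats::runif(1) * length(best)) + 1, length(best))]
    xs[i] <- nx[d]; ys[i] <- ny[d]
    assign(keys[d], i, envir = occ)
  }
  conf <- hp_conformation(cbind(x = xs, y = ys))
  list(conformation = conf, energy = energy(seq, conf), complete = TRUE)
}

#' Repeated independent greedy folding
#'
#' Runs [greedy_fold()] for `episodes` independent attempts and aggregates a
#' curve comparable to the Q-learning learning curve (per-episode energies,
#' best so far, hits). Because episodes are independent, the method cannot
#' converge — optima are only found by luck.
#'
#' @param seq An [hp_sequence()] or H/P string.
#' @param episodes Number of independent attempts (>= 1).
#' @param seed RNG seed.
#' @param target_energy Optional known minimum for hit accounting.
#' @return List: `energies` (per episode, NA = dead end), `best_energy`,
#'   `first_hit_episode`, `hits_last_100`, `best_conformation`.
#' @export
greedy_search <- function(seq, episodes, seed = 1L, target_energy = NULL) {
  stopifnot(episodes >= 1)
  seq <- hp_sequence(seq)
  set.seed(seed)
  energies <- integer(episodes)
  best <- NA_integer_
  best_conf <- NULL
  first_hit <- NA_integer_
  for (ep in seq_len(episodes)) {
    out <- greedy_fold(seq)
    energies[ep] <- out$energy
    if (out$complete && (is.na(best) || out$energy < best)) {
      best <- out$energy
      best_conf <- out$conformation
    }
    if (!is.null(target_energy) && is.na(first_hit) &&
        out$complete && out$energy <= target_energy) {
      first_hit <- ep
    }
  }
  last <- utils::tail(energies, 100)
  hits <- if (is.null(target_energy)) NA_integer_ else
    sum(!is.na(last) & last <= target_energy)
  list(energies = energies, best_energy = best,
       first_hit_episode = first_hit, hits_last_100 = hits,
       best_conformation = best_conf)
}

#' Q-learning over the partial state space
#'
#' Identical training loop to [train()], but states are the compressed
#' `1 + 4(n - 1)` (residue index, last action) pairs with the 4 absolute
#' actions. Distinct action histories alias to the same state, so the
#' process is not Markov; the method solves short sequences but cannot
#' converge stably on longer ones.
#'
#' @inheritParams train
#' @param config An [hp_train_config()]; its `state_mode` is forced to
#'   `"partial"` (with `action_geometry = "absolute4"`).
#' @return An `hp_train_result`, as for [train()].
#' @export
train_partial <- function(seq, config = hp_train_config(), target_energy = NULL) {
  cfg <- hp_train_config(alpha = config$alpha, gamma = config$gamma,
                         epsilon = config$epsilon, episodes = config$episodes,
                         test_interval = config$test_interval,
                         criterion = config$criterion,
                         state_mode = "partial", action_geometry = "absolute4",
                         invalid_action = config$invalid_action,
                         test_policy = config$test_policy,
                         tie_break = config$tie_break,
                         seed = config$seed, pool_cap = config$pool_cap,
                         return_q = config$return_q)
  train(seq, cfg, target_energy = target_energy)
}
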
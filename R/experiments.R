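#' The sixteen-sequence benchmark suite
#'
#' Standard 2D-HP benchmark set: six classic literature sequences and ten
#' Uniref50-derived ones, lengths 7-21, with their known lowest energies.
#' Shipped as a packaged fixture.
#'
#' @return Data frame with columns `id`, `sequence`, `length`, `known_energy`.
#' @examples
#' head(hp_benchmark())
#' @export
hp_benchmark <- function() {
  path <- system.file("extdata", "table2_sequences.tsv", package = "hpfold",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nchar(df$sequence) == df$length)
  df
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme: each (method, sequence, round) cell of a
#' benchmark run gets `master * 1000 + counter` reduced modulo 2^31 - 1, so
#' rounds are independent yet the whole report is reproducible from one seed.
#'
#' @param master Master seed (integer).
#' @param counter Cell counter (>= 0).
#' @return Integer child seed.
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 1000 + counter) %% (2^31 - 1))
}

#' Desk-scale and paper-scale benchmark presets
#'
#' `desk` runs the two shortest sequences with the rigid full-state learner
#' for a few hundred thousand episodes — minutes on one CPU. `paper` is the
#' full protocol (all 16 sequences, 4 methods, 5 rounds of 5 million episodes
#' sampled every 10,000) and is a flagged long-running job (hours).
#'
#' @param scale `"desk"` or `"paper"`.
#' @return List with `sequence_ids`, `methods`, `episodes`, `test_interval`,
#'   `rounds`, and `flag_long_running`.
#' @export
benchmark_preset <- function(scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    list(sequence_ids = 1:2, methods = c("full_rigid", "greedy"),
         episodes = 5e5L, test_interval = 1e4L, rounds = 2L,
         flag_long_running = FALSE)
  } else {
    list(sequence_ids = 1:16,
         methods = c("full_rigid", "full_flexible", "partial", "greedy"),
         episodes = 5e6L, test_interval = 1e4L, rounds = 5L,
         flag_long_running = TRUE)
  }
}

#' Run the benchmark protocol
#'
#' Executes each requested method on each benchmark sequence for the given
#' number of independent rounds, with child seeds derived from the master
#' seed, and reports per-cell best energy, first-hit episode and the number
#' of minimum-energy hits among the last 100 test samples.
#'
#' Methods: `full_rigid` and `full_flexible` are full-state Q-learning
#' (3-action relative geometry) under the two reward criteria; `partial` is
#' the compressed-state learner (rigid); `greedy` is the independent-restart
#' contact-greedy baseline, run for `episodes / test_interval` attempts so
#' its sample count matches the learners' test count.
#'
#' @param suite Benchmark table as from [hp_benchmark()] (subset rows to
#'   restrict sequences).
#' @param methods Subset of `c("full_rigid", "full_flexible", "partial",
#'   "greedy")`.
#' @param episodes,test_interval,rounds Protocol scale.
#' @param seed Master seed.
#' @param alpha,gamma,epsilon Q-learning hyperparameters.
#' @return Data frame of class `hp_experiment_report`: one row per
#'   (sequence, method, round) with `best_energy`, `first_hit_episode`,
#'   `hits_last_100`, `known_energy`, `seed`.
#' @export
run_benchmark <- function(suite = hp_benchmark(),
                          methods = c("full_rigid", "greedy"),
                          episodes = 5e5, test_interval = 1e4, rounds = 5,
                          seed = 1L, alpha = 0.01, gamma = 0.9,
                          epsilon = 0.5) {
  methods <- match.arg(methods,
                       c("full_rigid", "full_flexible", "partial", "greedy"),
                       several.ok = TRUE)
  rows <- list()
  counter <- 0L
  for (m in methods) {
    for (r in seq_len(nrow(suite))) {
      sq <- suite$sequence[r]
      target <- suite$known_energy[r]
      for (round in seq_len(rounds)) {
        child <- derive_seed(seed, counter)
        counter <- counter + 1L
        if (episodes < 1) next
        if (m == "greedy") {
          g <- greedy_search(sq, episodes = max(1L, episodes %/% test_interval),
                             seed = child, target_energy = target)
          row <- data.frame(best_energy = g$best_energy,
                            first_hit_episode = g$first_hit_episode,
                            hits_last_100 = g$hits_last_100)
        } else {
          cfg <- hp_train_config(
            alpha = alpha, gamma = gamma, epsilon = epsilon,
            episodes = episodes, test_interval = test_interval,
            criterion = if (m == "full_flexible") "flexible" else "rigid",
            state_mode = if (m == "partial") "partial" else "full3",
            seed = child, return_q = FALSE)
          fit <- train(sq, cfg, target_energy = target)
          row <- data.frame(best_energy = fit$best_energy,
                            first_hit_episode = fit$first_hit_episode,
                            hits_last_100 = fit$hits_last_100)
        }
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(sequence_id = suite$id[r], sequence = sq,
                     method = m, round = round, known_energy = target,
                     seed = child),
          row)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = integer(), sequence = character(),
               method = character(), round = integer(),
               known_energy = integer(), seed = integer(),
               best_energy = integer(), first_hit_episode = integer(),
               hits_last_100 = integer())
  class(out) <- c("hp_experiment_report", class(out))
  out
}

#' Summarise a benchmark report
#'
#' Per (sequence, method) averages: best energy, mean hits in the last 100
#' samples per round, and the summed hits across rounds (both aggregations of
#' the hit statistic are exposed).
#'
#' @param report Output of [run_benchmark()].
#' @return Data frame with one row per sequence x method.
#' @export
summarise_benchmark <- function(report) {
  key <- interaction(report$sequence_id, report$method, drop = TRUE)
  do.call(rbind, lapply(split(report, key), function(g) {
    data.frame(sequence_id = g$sequence_id[1], method = g$method[1],
               known_energy = g$known_energy[1],
               best_energy = suppressWarnings(min(g$best_energy, na.rm = TRUE)),
               mean_first_hit = mean(g$first_hit_episode, na.rm = TRUE),
               mean_hits_last_100 = mean(g$hits_last_100),
               total_hits_last_100 = sum(g$hits_last_100),
               rounds = nrow(g))
  }))
}

#' Convergence experiment: episodes to first reach the known minimum
#'
#' Runs the convergence protocol on one sequence: several independent
#' rigid-criterion full-state training runs with default hyperparameters,
#' curve samples every `test_interval` episodes, each run recording the first
#' sampled episode whose fold achieves the exact minimum energy (computed by
#' the enumeration oracle at run time). A run that never hits within its
#' budget is counted at the full budget (a censored, conservative value).
#'
#' @param sequence H/P string.
#' @param max_episodes Episode budget per run.
#' @param runs Number of independent runs.
#' @param master_seed Master seed; run r uses `derive_seed(master_seed, r-1)`.
#' @param test_interval Episodes between curve samples.
#' @param config Base [hp_train_config()] whose protocol settings (criterion,
#'   state mode, geometry, hyperparameters) the runs inherit.
#' @return List: `first_hits` (per run), `mean_first_hit`, `target_energy`.
#' @export
convergence_experiment <- function(sequence, max_episodes, runs = 5,
                                   master_seed = 1L, test_interval = 1e4,
                                   config = hp_train_config()) {
  target <- enumerate_min_energy(sequence)$min_energy
  hits <- vapply(seq_len(runs), function(r) {
    cfg <- hp_train_config(alpha = config$alpha, gamma = config$gamma,
                           epsilon = config$epsilon,
                           episodes = max_episodes,
                           test_interval = test_interval,
                           criterion = config$criterion,
                           state_mode = config$state_mode,
                           action_geometry = config$action_geometry,
                           invalid_action = config$invalid_action,
                           test_policy = config$test_policy,
                           tie_break = config$tie_break,
                           seed = derive_seed(master_seed, r - 1L),
                           return_q = FALSE)
    fh <- train(sequence, cfg, target_energy = target)$first_hit_episode
    if (is.na(fh)) as.numeric(max_episodes) else as.numeric(fh)
  }, numeric(1))
  list(first_hits = hits, mean_first_hit = mean(hits), target_energy = target)
}

#' Generate random H/P fixture sequences
#'
#' Seeded random sequences with a requested hydrophobic fraction; used for
#' property tests and synthetic experiments. Deterministic: a fixed seed
#' reproduces the file byte-for-byte.
#'
#' @param n_range Integer vector of lengths to draw from (uniformly).
#' @param h_fraction Probability that a residue is H, in \[0, 1\].
#' @param count Number of sequences.
#' @param seed RNG seed.
#' @param path Optional output file (one sequence per line).
#' @return Character vector of H/P strings (invisibly when `path` is given).
#' @export
generate_fixtures <- function(n_range, h_fraction, count, seed = 1L,
                              path = NULL) {
  stopifnot(h_fraction >= 0, h_fraction <= 1, count >= 0)
  set.seed(seed)
  seqs <- character(count)
  for (i in seq_len(count)) {
    n <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
    seqs[i] <- paste(ifelse(stats::runif(n) < h_fraction, "H", "P"),
                     collapse = "")
  }
  if (!is.null(path)) {
    writeLines(seqs, path)
    return(invisible(seqs))
  }
  seqs
}
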
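# Shared helpers: random legal conformations and small sequence fixtures,
# generated in code under fixed seeds.

random_saw <- function(n, seed = NULL) {
  # rejection-sample a self-avoiding walk as a relative3 move string
  if (!is.null(seed)) set.seed(seed)
  repeat {
    conf <- decode_moves(sample(1:3, n - 1, replace = TRUE), "relative3")
    if (is_legal(conf)) return(conf)
  }
}

random_hp <- function(n, h_frac = 0.5) {
  paste(ifelse(stats::runif(n) < h_frac, "H", "P"), collapse = "")
}

fast_cfg <- function(...) {
  hp_train_config(..., return_q = TRUE)
}
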
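test_that("the enumerator solves the tiny worked cases", {
  expect_equal(enumerate_min_energy("HPPH")$min_energy, -1)
  expect_equal(enumerate_min_energy("HH")$min_energy, 0)
  expect_equal(enumerate_min_energy("H")$min_energy, 0)
  expect_equal(enumerate_min_energy("HPPHHPH")$min_energy, -2)
})

test_that("naive and pruned enumeration agree, including symmetry-class counts", {
  set.seed(21)
  cases <- c("HPPHHPH", "PPPPP", "HHHHHH", replicate(6, random_hp(7)))
  for (sq in cases) {
    naive <- naive_enumerate(sq, keep_optima = TRUE)
    fast <- enumerate_min_energy(sq)
    full <- enumerate_min_energy(sq, symmetry_reduce = FALSE)
    expect_identical(fast$min_energy, naive$min_energy)
    expect_identical(full$min_energy, naive$min_energy)
    # without symmetry reduction both enumerations see the same optimal walks
    expect_equal(full$optimum_count, naive$optimum_count)
    # with reduction, the count is one per symmetry class of optima
    classes <- unique(vapply(naive$optima, canonical_form, character(1)))
    expect_equal(fast$optimum_count, length(classes))
  }
})

test_that("pruning and symmetry reduction never change the minimum", {
  set.seed(33)
  for (n in c(8, 10, 12)) {
    for (rep in 1:3) {
      sq <- random_hp(n, h_frac = 0.6)
      base <- enumerate_min_energy(sq, symmetry_reduce = FALSE, bound_prune = FALSE)
      expect_identical(enumerate_min_energy(sq, bound_prune = FALSE)$min_energy,
                       base$min_energy)
      expect_identical(enumerate_min_energy(sq, symmetry_reduce = FALSE)$min_energy,
                       base$min_energy)
      expect_identical(enumerate_min_energy(sq)$min_energy, base$min_energy)
    }
  }
})

test_that("replacing H by P never deepens the minimum", {
  set.seed(55)
  for (rep in 1:8) {
    sq <- random_hp(10, h_frac = 0.7)
    e <- enumerate_min_energy(sq)$min_energy
    res <- hp_residues(sq)
    hpos <- which(res == "H")
    if (length(hpos) == 0) next
    res[sample(hpos, 1)] <- "P"
    e2 <- enumerate_min_energy(paste(res, collapse = ""))$min_energy
    expect_gte(e2, e)
  }
})

test_that("the node cap truncates loudly instead of lying", {
  res <- enumerate_min_energy("HPHPPHHPHPPHPHHPPHPH", node_cap = 50)
  expect_true(res$truncated)
  full <- enumerate_min_energy("HPPHHPH", node_cap = 1e6)
  expect_false(full$truncated)
  expect_equal(full$min_energy, -2)
})

test_that("naive enumeration refuses oversized inputs", {
  expect_error(naive_enumerate("HPHPHPHPHP"), "n <= 9")
})

test_that("the absolute3-restricted search is a strict subset of the full one", {
  # partially directed walks can miss the global minimum
  full <- enumerate_min_energy("HHPHPPHPHPHHPH")
  pd <- enumerate_min_energy("HHPHPPHPHPHHPH", restrict = "absolute3")
  expect_gte(pd$min_energy, full$min_energy)
  expect_equal(full$min_energy, -6)
  expect_equal(pd$min_energy, -4)
})
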
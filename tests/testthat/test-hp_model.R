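test_that("sequence validation accepts H/P strings and rejects others", {
  s <- hp_sequence("hpPhH")
  expect_s3_class(s, "hp_sequence")
  expect_equal(length(s), 5L)
  expect_equal(hp_residues(s), c("H", "P", "P", "H", "H"))
  expect_error(hp_sequence("HPX"), "invalid residue")
  expect_error(hp_sequence(""), "at least one residue")
  expect_error(hp_sequence(c("HP", "PH")), "single character string")
})

test_that("amino-acid mapping collapses to the two-letter alphabet", {
  expect_equal(as.character(aa_to_hp("GAVLIK")), "PHHHHP")
  expect_equal(as.character(aa_to_hp("AAA", hydrophobic = "G")), "PPP")
})

test_that("move decoding follows each encoding's geometry", {
  straight <- decode_moves("RRR", "absolute4")
  expect_equal(unname(straight$coords[, "x"]), 0:3)
  expect_equal(unname(straight$coords[, "y"]), rep(0L, 4))
  expect_true(is_legal(straight))

  back <- decode_moves("RL", "absolute4")
  expect_false(is_legal(back))
  expect_equal(unname(back$coords[3, ]), c(0L, 0L))

  rel_straight <- decode_moves(rep(2L, 5), "relative3")
  expect_equal(unname(rel_straight$coords[, "x"]), 0:5)
  expect_true(is_legal(rel_straight))

  # relative turns: left from +x heads +y, right heads -y
  expect_equal(unname(decode_moves(1L, "relative3")$coords[2, ]), c(0L, 1L))
  expect_equal(unname(decode_moves(3L, "relative3")$coords[2, ]), c(0L, -1L))
  # absolute3 can never step in -y
  for (mv in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
    expect_true(all(diff(decode_moves(mv, "absolute3")$coords[, "y"]) >= 0))
  }
  expect_error(decode_moves("RD", "absolute3"), "invalid move symbol")
  expect_error(decode_moves(c(1L, 4L), "relative3"), "action numbers")
})

test_that("legality requires unit steps and no overlap", {
  expect_true(is_legal(hp_conformation(cbind(c(0, 1, 1), c(0, 0, 1)))))
  expect_false(is_legal(hp_conformation(cbind(c(0, 1, 0), c(0, 0, 0)))))
  expect_error(hp_conformation(cbind(c(0, 2), c(0, 0))), "unit lattice distance")
})

test_that("energy and contacts match the contact-counting definition", {
  expect_equal(energy("HH", decode_moves("R", "absolute4")), 0)
  ufold <- decode_moves("RUL", "absolute4")
  expect_equal(energy("HPPH", ufold), -1)
  expect_equal(contacts("HPPH", ufold), data.frame(i = 1L, j = 4L))
  expect_equal(nrow(contacts("PPPP", ufold)), 0L)
  expect_error(energy("HPP", ufold), "residues but conformation")
  # energy is defined mechanically for overlapping chains
  over <- decode_moves("RURDLU", "absolute4")
  expect_false(is_legal(over))
  expect_lte(energy("HHHHHHH", over), 0)
})

test_that("energy is invariant under the 8 lattice symmetries and translation", {
  set.seed(42)
  for (rep in 1:20) {
    sq <- random_hp(9)
    conf <- random_saw(9)
    e <- energy(sq, conf)
    for (rf in c(FALSE, TRUE)) for (rot in 0:3) {
      im <- transform_conformation(conf, rot, rf)
      expect_identical(energy(sq, im), e)
      shifted <- hp_conformation(sweep(im$coords, 2, c(-3L, 7L)))
      expect_identical(energy(sq, shifted), e)
    }
  }
})

test_that("relative3 decoding round-trips through re-encoding for all short walks", {
  for (len in 1:7) {
    grid <- as.matrix(expand.grid(rep(list(1:3), len)))
    for (r in seq_len(nrow(grid))) {
      mv <- unname(grid[r, ])
      conf <- decode_moves(mv, "relative3")
      expect_identical(encode_moves(conf, "relative3"), as.integer(mv))
    }
  }
})

test_that("occupancy grid marks exactly the occupied cells of a legal fold", {
  conf <- random_saw(8, seed = 7)
  g <- occupancy_grid(conf)
  expect_equal(dim(g), c(15L, 15L))
  expect_equal(sum(g), 8L)
  org <- attr(g, "origin")
  expect_true(g[org[1], org[2]])  # residue 1 at the centre
  expect_error(occupancy_grid(conf, n = 3), "exceed")
})

test_that("a legal fold's contact count respects the hydrophobic bound", {
  set.seed(99)
  for (rep in 1:20) {
    sq <- random_hp(10)
    h <- sum(hp_residues(sq) == "H")
    conf <- random_saw(10)
    expect_lte(-energy(sq, conf), 2 * floor(h / 2))
  }
})

test_that("sequence files round-trip through plain text and FASTA", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "HPPH", "toy: HPHP", ""), tmp)
  seqs <- read_hp_sequences(tmp)
  expect_equal(names(seqs), c("seq1", "toy"))
  expect_equal(as.character(seqs$toy), "HPHP")

  skip_if_not_installed("seqinr")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "HPPH", ">b", "HPH", "P"), fa)
  seqs <- read_hp_sequences(fa)
  expect_equal(as.character(seqs$a), "HPPH")
  expect_equal(as.character(seqs$b), "HPHP")
})

test_that("conformation TSV output has one row per residue", {
  conf <- decode_moves("RUL", "absolute4")
  tmp <- tempfile(fileext = ".tsv")
  df <- write_conformation("HPPH", conf, tmp)
  back <- read.delim(tmp)
  expect_equal(back$residue, c("H", "P", "P", "H"))
  expect_equal(back$x, df$x)
})
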
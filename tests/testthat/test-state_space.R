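test_that("full state counts follow the geometric series", {
  expect_identical(full_state_count(2, 4), 5)
  expect_identical(full_state_count(3, 4), 21)
  expect_identical(full_state_count(1, 3), 1)
  expect_identical(full_state_count(5, 3), (3^5 - 1) / 2)
  expect_error(full_state_count(3, 5), "must be 3 or 4")
  # recurrence S(n) = 1 + b S(n-1) and exactness far beyond double range
  for (b in c(3, 4)) {
    for (n in 2:12) {
      expect_identical(full_state_count(n, b), 1 + b * full_state_count(n - 1, b))
    }
  }
  expect_identical(full_state_count(64, 4),
                   "113427455640312821154458202477256070485")
  expect_identical(full_state_count(64, 3),
                   "1716841910146256242328924544640")
})

test_that("transfer reproduces the worked successor indices", {
  expect_equal(transfer(1, 1, b = 4), 2)  # first child of the root
  expect_equal(transfer(2, 1, b = 4), 6)  # first depth-3 state
  expect_equal(transfer(1, 4, b = 4), 5)
  expect_equal(transfer(5, 4, b = 4), 21)
  expect_equal(transfer(1, 3, b = 3), 4)
  expect_error(transfer(1, 4, b = 3), "must lie in")
  expect_error(transfer(2, 1, b = 4, n = 2), "terminal")
})

test_that("transfer is a bijection onto each depth block (exhaustive, n <= 8)", {
  for (b in c(3, 4)) {
    n <- 8
    offs <- (b^(0:n) - 1) / (b - 1)
    for (depth in 1:(n - 1)) {
      parents <- (offs[depth] + 1):offs[depth + 1]
      kids <- unlist(lapply(parents, function(s) {
        vapply(1:b, function(l) transfer(s, l, b), numeric(1))
      }))
      expect_identical(sort(kids), as.numeric((offs[depth + 1] + 1):offs[depth + 2]))
    }
  }
})

test_that("state depth always grows by one and addresses invert the numbering", {
  for (b in c(3, 4)) {
    set.seed(b)
    for (rep in 1:50) {
      s <- sample.int(as.integer(full_state_count(7, b)), 1)
      addr <- state_address(s, b)
      expect_equal((b^(addr$depth - 1) - 1) / (b - 1) + addr$ordinal, s)
      if (addr$depth < 7) {
        l <- sample.int(b, 1)
        expect_equal(state_address(transfer(s, l, b), b)$depth, addr$depth + 1)
      }
    }
  }
})

test_that("prefix decoding inverts the transfer fold (exhaustive, n <= 6)", {
  for (b in c(3, 4)) {
    top <- as.integer(full_state_count(6, b))
    for (s in seq_len(top)) {
      expect_equal(prefix_to_state(state_to_prefix(s, b), b), s)
    }
  }
  expect_identical(state_to_prefix(1, 4), integer(0))
  expect_identical(state_to_prefix(6, 4), c(1L, 1L))
})

test_that("partial states number 1 + 4(n-1) with the stated layout", {
  expect_equal(partial_state_of(1), 1)
  expect_equal(partial_state_of(2, 1), 2)
  expect_equal(partial_state_of(3, 4), 9)
  expect_error(partial_state_of(2), "required")
  expect_equal(partial_state_count(14), 53)
  for (n in c(2, 5, 14)) {
    idx <- c(1, unlist(lapply(2:n, function(i)
      vapply(1:4, function(l) partial_state_of(i, l), numeric(1)))))
    expect_identical(sort(unique(idx)), as.numeric(seq_len(1 + 4 * (n - 1))))
  }
})
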
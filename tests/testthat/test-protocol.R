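test_that("operation sequences validate prefixes and parse from token text", {
  expect_s3_class(op_sequence(c("X", "Y", "pop", "pop")), "op_sequence")
  expect_error(op_sequence(c("pop", "X")), "more pops than records")
  expect_error(op_sequence(c("X", "b")), "invalid operation")
  ops <- parse_ops("X Y q q")
  expect_equal(as.vector(unclass(ops)), c("X", "Y", "pop", "pop"))
  expect_equal(format(ops), "X Y q q")
})

test_that("seqN generators produce periodic balanced 40-operation sequences", {
  s20 <- make_seqN(20, seed = 1)
  expect_equal(sum(unclass(s20) == "pop"), 20L)
  expect_equal(which(unclass(s20) == "pop"), 21:40) # all pops after all records
  s1 <- make_seqN(1, seed = 1)
  expect_equal(unclass(s1)[seq(2, 40, by = 2)], rep("pop", 20))
  expect_error(make_seqN(3), "divide 20")
  for (N in c(1, 2, 4, 5, 10, 20)) {
    s <- make_seqN(N, seed = 7)
    recs <- unclass(s)[unclass(s) != "pop"]
    expect_equal(length(recs), 20L)
    expect_lte(abs(sum(recs == "X") - sum(recs == "Y")), 1L)
    depth <- cumsum(ifelse(unclass(s) == "pop", -1L, 1L))
    expect_true(all(depth >= 0) && depth[40] == 0L) # finishes empty
  }
})

test_that("seqR is a prefix-valid seeded shuffle with balanced labels", {
  a <- make_seqR(seed = 1); b <- make_seqR(seed = 2)
  expect_false(identical(unclass(a), unclass(b)))
  for (s in list(a, b)) {
    ops <- unclass(s)
    expect_equal(sum(ops == "pop"), 20L)
    depth <- cumsum(ifelse(ops == "pop", -1L, 1L))
    expect_true(all(depth >= 0) && depth[40] == 0L)
    recs <- ops[ops != "pop"]
    expect_lte(abs(sum(recs == "X") - sum(recs == "Y")), 1L)
  }
  expect_identical(unclass(make_seqR(seed = 1)), unclass(a)) # seeded
})

test_that("ideal pops replay a textbook LIFO stack exactly", {
  expect_equal(ideal_pops(op_sequence(c("X", "Y", "pop", "pop"))), c("Y", "X"))
  set.seed(31)
  for (s in c(lapply(c(1, 5, 10, 20), make_seqN, seed = 5),
              list(make_seqR(seed = 5)))) {
    expect_equal(ideal_pops(s), textbook_pops(unclass(s)))
  }
})

test_that("compilation expands records and pops to chemistry stages", {
  st <- compile_operations(op_sequence(c("X", "pop")))
  expect_equal(st$token, c("s", "p", "X", "r", "q"))
  expect_equal(st$readout, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_true(all(st$wash_after))
  expect_equal(attr(st, "expected_pops"), "X")
  expect_equal(unique(st$conc), 300e-9)
  expect_equal(unique(st$wait), 1800)

  expect_equal(nrow(compile_operations(make_seqN(5, seed = 1))), 81L)
  empty <- compile_operations(op_sequence(character(0)))
  expect_equal(empty$token, "s")

  low_read <- compile_operations(op_sequence(c("X", "pop")), read_conc = 50e-9)
  expect_equal(low_read$conc[low_read$token == "r"], 50e-9)

  # deterministic given sequence and defaults
  expect_identical(compile_operations(make_seqN(5, seed = 2)),
                   compile_operations(make_seqN(5, seed = 2)))
})
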
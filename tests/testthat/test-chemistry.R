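test_that("monomer table validates completeness and lengths", {
  m <- define_monomers()
  expect_equal(nrow(m), 9L)
  expect_equal(m$length_nt[m$token == "X"], 107L)
  expect_equal(m$length_nt[m$token == "Y"], 137L)
  expect_equal(m$length_nt[m$token == "p"], 56L)

  partial <- m[m$token != "z", ]
  expect_error(define_monomers(partial), "missing monomer: z")
  bad <- m; bad$length_nt[1] <- 0
  expect_error(define_monomers(bad), "positive")
  expect_error(define_monomers(data.frame(token = "v", length_nt = 10)),
               "unknown monomer")
})

test_that("species grammar accepts stack and off-target complexes, rejects junk", {
  expect_s3_class(species_from_tokens(c("k", "s", "p", "X")), "stack_species")
  expect_equal(unclass(species_from_tokens(c("p", "w", "p"))), "p.w.p")
  for (ok in list(c("w", "p", "w"), c("s", "p", "X", "p"), c("k", "z"),
                  c("p", "q"), c("X", "r"), c("k", "s", "r"), "q", "z"))
    expect_silent(species_from_tokens(ok))
  for (bad in list(c("s", "s"), c("s", "X"), c("k", "p"), c("p", "p"),
                   c("X", "Y"), c("s", "p", "q"), c("k", "s", "z"),
                   c("p", "X", "r"), c("z", "k")))
    expect_error(species_from_tokens(bad), "invalid species")
  expect_error(species_from_tokens(c("k", "s", "p"), tethered = FALSE),
               "tethered")
})

test_that("exposed sites follow the elongation order", {
  expect_equal(exposed_sites("k.s.p")$tail, "beta_open")
  expect_equal(exposed_sites("k.s.p.X")$tail, "alpha_open")
  expect_equal(exposed_sites("k.s")$tail, "alpha_open")
  expect_equal(exposed_sites("X.r")$tail, "none")
  expect_equal(exposed_sites("X.r")$head_binds, "none")
  expect_equal(exposed_sites("k")$tail, "linker_open")
  expect_equal(exposed_sites("p.w")$head_binds, "alpha_open")
  expect_equal(exposed_sites("w.p")$head_binds, "beta_open")
  expect_true(is_inert("p.q"))
  expect_false(is_inert("k.s.p"))
  expect_true(is_tethered("k.z"))
  expect_false(is_tethered("s.p.w"))
})

test_that("total nucleotides sums monomer lengths", {
  expect_equal(total_nucleotides(c("s", "p", "w")), 168L)
  expect_equal(total_nucleotides("X.r"), 163L)
  m <- define_monomers()
  m$length_nt[m$token == "s"] <- 40L
  expect_equal(total_nucleotides(c("s", "p"), m), 96L)
})

test_that("enumeration matches the brute-force rule oracle on random states", {
  pool <- species_pool()
  set.seed(421)
  for (rep in 1:60) {
    keys <- sample(pool, sample(2:6, 1))
    got <- enumerate_reactions(keys)
    want <- oracle_reactions(keys)
    expect_equal(reaction_keyset(got), reaction_keyset(want),
                 info = paste(keys, collapse = " "))
  }
})

test_that("enumeration is order-independent and covers the named examples", {
  # nucleation: a single reaction for {s free, k on bead}
  rx <- enumerate_reactions(c("s", "k"))
  expect_equal(nrow(rx), 1L)
  expect_equal(rx$product1, "k.s")

  # signal elongation plus solution-phase joins
  rx <- enumerate_reactions(c("k.s.p", "w", "p"))
  expect_setequal(rx$product1, c("k.s.p.w", "p.w", "w.p"))

  # read displacement retains the stack below the popped signal
  rx <- enumerate_reactions(c("k.s.p.X", "r"))
  expect_equal(nrow(rx), 1L)
  expect_setequal(c(rx$product1, rx$product2), c("k.s.p", "X.r"))

  a <- enumerate_reactions(c("k.s", "p", "w", "r", "X.r"))
  b <- enumerate_reactions(rev(c("k.s", "p", "w", "r", "X.r")))
  expect_setequal(reaction_keyset(a), reaction_keyset(b))

  expect_error(enumerate_reactions(c("k.s", "s.s")), "invalid")
})

test_that("no reaction is generated between inert duplexes", {
  rx <- enumerate_reactions(c("X.r", "Y.r", "p.q", "k.z", "s.r", "w.r"))
  expect_equal(nrow(rx), 0L)
})

test_that("rule switches remove the corresponding channels", {
  opts <- rule_options(r_free_signal = FALSE, q_free_push = FALSE,
                       cap_start = FALSE)
  rx <- enumerate_reactions(c("X", "p", "k.s", "r", "q"), options = opts)
  expect_false("X.r" %in% rx$product1)      # no read + free signal
  expect_false("p.q" %in% rx$product1)      # no pop + free push
  expect_false("k.s.r" %in% rx$product1)    # no capping of a bare start
  off2 <- rule_options(rules = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  rx2 <- enumerate_reactions(c("k.s.p", "w"), options = off2)
  expect_equal(nrow(rx2), 0L)               # R2 disabled
})

test_that("apply_reaction conserves tokens and checks stoichiometry", {
  counts <- c(k.s = 5, p = 3)
  rx <- enumerate_reactions(names(counts))
  out <- apply_reaction(counts, rx[1, ])
  expect_equal(out[["k.s"]], 4)
  expect_equal(out[["p"]], 2)
  expect_equal(out[["k.s.p"]], 1)
  expect_error(apply_reaction(c(k.s = 0, p = 1), rx[1, ]), "insufficient")

  # token conservation over a random reaction walk
  set.seed(99)
  counts <- c(k = 50, s = 40, p = 60, X = 30, Y = 20, r = 25, q = 25, z = 10)
  census0 <- dnastack:::token_census(counts)
  for (step in 1:40) {
    rx <- enumerate_reactions(names(counts)[counts > 0])
    # keep only reactions whose stoichiometry the state can support
    feasible <- vapply(seq_len(nrow(rx)), function(i) {
      need <- table(c(rx$reactant1[i], rx$reactant2[i]))
      all(counts[names(need)] >= need)
    }, TRUE)
    rx <- rx[feasible, , drop = FALSE]
    if (!nrow(rx)) break
    counts <- apply_reaction(counts, rx[sample(nrow(rx), 1), ])
    counts <- counts[counts > 0]
  }
  expect_equal(dnastack:::token_census(counts), census0)
})
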
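test_that("initial state and strand additions convert concentration to copies", {
  st <- init_state() # 0.15 pl, 200 nM linker
  expect_equal(unname(st$counts["k"]), round(200e-9 * 0.15e-12 * 6.02214076e23))
  expect_equal(unname(st$counts["k"]), 18066)
  expect_equal(st$bead_fraction, 1)
  expect_equal(st$wash_index, 0L)
  expect_error(init_state(volume = 0), "positive")

  st <- add_strand(st, "p", 300e-9)
  expect_equal(unname(st$counts["p"]), 27100)
  st <- add_strand(st, "r", 50e-9)
  expect_equal(unname(st$counts["r"]), 4517)
  expect_error(add_strand(st, "v", 1e-9), "unknown token")
})

test_that("pipetting noise draws are truncated at zero and never error", {
  set.seed(7)
  # noise wider than the nominal concentration: negative draws truncate to 0
  zeros <- 0L
  for (i in 1:60) {
    st <- add_strand(init_state(), "p", 100e-9, eta = 300e-9)
    expect_gte(unname(st$counts["p"]), 0)
    if (st$counts[["p"]] == 0) zeros <- zeros + 1L
  }
  expect_gt(zeros, 0L)
  # eta = 0 is exact
  st <- add_strand(init_state(), "p", 300e-9, eta = 0)
  expect_equal(unname(st$counts["p"]), 27100)
})

test_that("advancing a state with no possible reactions only moves the clock", {
  st <- init_state(linker_conc = 0)
  st$counts <- c(X.r = 100, p.q = 50)
  for (backend in c("ssa", "ode")) {
    out <- advance(st, 123, backend = backend)
    expect_equal(out$time, 123)
    expect_equal(sort(out$counts), sort(st$counts))
  }
  expect_error(advance(st, -1), "non-negative")
})

test_that("SSA matches closed-form bimolecular kinetics within 3 standard errors", {
  # irreversible A+B -> C realised as linker + start nucleation
  vol <- 2e-15
  n0 <- round(200e-9 * vol * 6.02214076e23) # ~241 copies each
  c0 <- n0 / (vol * 6.02214076e23)
  k <- 3e4
  t_half <- 1 / (k * c0)
  set.seed(2024)
  prod <- replicate(200, {
    st <- init_state(volume = vol, linker_conc = 0)
    st$counts <- c(k = n0, s = n0)
    out <- advance(st, t_half, backend = "ssa")
    if ("k.s" %in% names(out$counts)) out$counts[["k.s"]] else 0
  })
  expected <- bimolecular_product(c0, k, t_half) * vol * 6.02214076e23
  se <- sd(prod) / sqrt(length(prod))
  expect_lt(abs(mean(prod) - expected), 3 * se + 1e-9)
})

test_that("stage kinetics at standard conditions are near-complete in 30 min", {
  # s + p at 300 nM each: half-completion at ~1/(k c0) ~ 111 s
  vol <- 0.15e-12
  n0 <- round(300e-9 * vol * 6.02214076e23)
  st <- init_state(volume = vol, linker_conc = 0)
  st$counts <- c(s = n0, p = n0)
  out <- advance(st, 1800, backend = "ode")
  frac <- out$counts[["s.p"]] / n0
  expect_gt(frac, 0.9)
  half <- advance(st, 111, backend = "ode")
  expect_equal(half$counts[["s.p"]] / n0, 0.5, tolerance = 0.02)
})

test_that("washing follows the mu / phi_n algebra", {
  st <- init_state()
  st$counts <- c(k.s.p = 10000, w = 10000, s = 5000)
  w1 <- wash_params("W1")
  expect_equal(w1$mu, 0.1); expect_equal(w1$phi0, 0.33)
  expect_equal(wash_params("W2")[c("mu", "phi0")], list(mu = 0.05, phi0 = 0.15))
  expect_equal(wash_params("W3")[c("mu", "phi0")], list(mu = 0.02, phi0 = 0.05))
  expect_error(wash_params(1.2, 0.1), "\\[0, 1\\]")

  # deterministic: first W1 wash keeps 90% of tethered, 33% of supernatant
  out <- wash(st, w1, stochastic = FALSE)
  expect_equal(unname(out$counts["k.s.p"]), 9000)
  expect_equal(unname(out$counts["w"]), 3300)
  expect_equal(out$bead_fraction, 0.9)

  # successive washes: supernatant survival phi0 * phi1 * phi2, beads (1-mu)^3
  st3 <- st
  for (i in 1:3) st3 <- wash(st3, w1, stochastic = FALSE)
  expect_equal(st3$bead_fraction, 0.9^3)
  expect_equal(unname(st3$counts["w"]) / 10000, 0.33^3 * 0.9^(0 + 1 + 2),
               tolerance = 1e-12)
  expect_equal(unname(st3$counts["k.s.p"]) / 10000, 0.9^3)

  # perfect wash empties the supernatant, keeps every tethered copy
  perfect <- wash(st, wash_params(0, 0), stochastic = TRUE)
  expect_equal(unname(perfect$counts["k.s.p"]), 10000)
  expect_false("w" %in% names(perfect$counts))

  # stochastic thinning is binomial in expectation
  set.seed(5)
  kept <- replicate(300, {
    s <- st; s$counts <- c(w = 1000)
    out <- wash(s, w1, stochastic = TRUE)
    if ("w" %in% names(out$counts)) out$counts[["w"]] else 0
  })
  expect_equal(mean(kept), 330, tolerance = 0.03)
})

test_that("token conservation holds over reaction intervals without washing", {
  st <- init_state()
  st <- add_strand(st, "s", 300e-9)
  st <- add_strand(st, "p", 300e-9)
  st <- add_strand(st, "w", 150e-9)
  census0 <- dnastack:::token_census(st$counts)
  set.seed(11)
  out <- advance(st, 1800, backend = "ssa")
  expect_equal(dnastack:::token_census(out$counts), census0)
})

test_that("identical seeds reproduce identical SSA trajectories", {
  s5 <- make_seqN(5, seed = 3)
  stages <- compile_operations(s5)[1:8, ]
  run <- function() {
    set.seed(42)
    run_protocol(init_state(), stages, wash = wash_params("W1"),
                 backend = "ssa", trace = FALSE)
  }
  a <- run(); b <- run()
  expect_identical(a$state$counts, b$state$counts)
  expect_identical(a$readouts, b$readouts)
})

test_that("SSA and ODE backends agree on early write-protocol stages", {
  stages <- compile_operations(op_sequence(c("w", "pop")))[1:2, ]
  ode <- run_protocol(init_state(), stages, wash = wash_params("W1"),
                      backend = "ode", trace = TRUE)
  set.seed(8)
  ssa <- run_protocol(init_state(), stages, wash = wash_params("W1"),
                      backend = "ssa", trace = TRUE)
  for (sg in 1:2) {
    o <- ode$trace[ode$trace$stage == sg, ]
    s <- ssa$trace[ssa$trace$stage == sg, ]
    big <- o$species[o$conc_nM >= 10]
    for (sp in big) {
      so <- o$conc_nM[o$species == sp]
      ss <- s$conc_nM[s$species == sp]
      expect_equal(length(ss), 1L, info = sp)
      expect_lt(abs(so - ss) / so, 0.05)
    }
  }
})
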
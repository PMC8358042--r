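test_that("pop limit scans consecutive correct pops under the 10 nM rule", {
  r <- data.frame(expected = c("X", "Y"), Xr_nM = c(120, 8), Yr_nM = c(5, 9),
                  wr_nM = 0)
  expect_equal(pop_limit(r), 1L)
  expect_equal(pop_limit(r[0, ]), 0L)

  # wrong majority fails even when distinguishable
  r2 <- data.frame(expected = c("Y"), Xr_nM = 50, Yr_nM = 10, wr_nM = 0)
  expect_equal(pop_limit(r2), 0L)

  # a failed pop stops the scan; signals_retrieved keeps counting
  r3 <- data.frame(expected = c("X", "Y", "X"), Xr_nM = c(120, 9, 40),
                   Yr_nM = c(5, 8, 10), wr_nM = 0)
  expect_equal(pop_limit(r3), 1L)
  expect_equal(signals_retrieved(r3), 2L)

  # single-signal runs use the wr detection floor
  rw <- data.frame(expected = c("w", "w"), Xr_nM = 0, Yr_nM = 0,
                   wr_nM = c(25, 6))
  expect_equal(pop_limit(rw), 1L)
})

test_that("band patterns bin species by nucleotide content", {
  st <- init_state()
  st$counts <- c(k.s.p.w = 1000) # single species -> single band
  bp <- band_pattern(st, "tethered")
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$size_nt, 28L + 56L + 56L + 56L)

  # intensity is nt-weighted concentration; faint bands fall below threshold
  st$counts <- c(k.s.p.w = 1000, k.s = 5, w = 5000)
  bp <- band_pattern(st, "tethered")
  expect_equal(nrow(bp), 1L) # k.s is ~0.05 nM * 84 nt, below 1000 nM*nt
  expect_equal(band_pattern(st, "supernatant")$size_nt, 56L)
  expect_equal(nrow(band_pattern(st, "all")), 2L)
})

test_that("band order error follows the pairwise disagreement convention", {
  expect_equal(band_order_error(c(100, 200, 300), c(100, 200, 300)), 0)
  expect_equal(band_order_error(c(100, 200, 300, 400), c(400, 300, 200, 100)), 1)
  expect_equal(band_order_error(c(100, 200), c(100, 200, 300)), 2 / 3)
  expect_error(band_order_error(c(100), numeric(0)), "empty")

  # premetric properties: symmetric, zero iff identical over shared support
  set.seed(17)
  for (i in 1:25) {
    a <- sample(seq(100, 900, by = 100), sample(2:6, 1))
    b <- sample(seq(100, 900, by = 100), sample(2:6, 1))
    eab <- band_order_error(a, b)
    expect_equal(eab, band_order_error(b, a))
    expect_gte(eab, 0); expect_lte(eab, 1)
    expect_equal(band_order_error(a, a), 0)
    if (eab == 0) expect_identical(sort(a), sort(b))
  }
})

test_that("off-target bands above the target stack require supernatant carry-over", {
  lanes <- write_lane_experiments(3)
  lane7 <- lanes[["lane7_w"]] # three write signals recorded
  target_nt <- total_nucleotides(c("k", "s", "p", "w", "p", "w", "p", "w"))

  st_w1 <- dnastack:::simulate_lane(lane7, wash_params("W1"))
  bp_w1 <- band_pattern(st_w1, "tethered")
  expect_gt(nrow(bp_w1), 1L)
  expect_true(any(bp_w1$size_nt > target_nt))

  st_clean <- dnastack:::simulate_lane(lane7, wash_params(0.1, 0))
  bp_clean <- band_pattern(st_clean, "tethered")
  expect_false(any(bp_clean$size_nt > target_nt))
})

test_that("fixtures at p_swap = 0 reproduce predicted rankings; mu = 1 is degenerate", {
  lanes <- write_lane_experiments(1)
  fx <- make_fit_fixture(0.05, 0.1, lanes)
  for (i in seq_along(lanes)) {
    st <- dnastack:::simulate_lane(lanes[[i]], wash_params(0.05, 0.1))
    expect_identical(fx[[i]], band_pattern(st, "tethered")$size_nt)
  }
  expect_false(isTRUE(attr(fx, "degenerate")))
  fx1 <- make_fit_fixture(1, 0.1, lanes)
  expect_true(attr(fx1, "degenerate"))
})

test_that("washing calibration recovers known parameters from fixtures", {
  lanes <- write_lane_experiments(3)[c(3, 5, 7, 9, 13)]
  mu_grid <- seq(0, 0.2, by = 0.05)
  phi0_grid <- seq(0, 0.44, by = 0.11)

  fx <- make_fit_fixture(0.1, 0.33, lanes)
  fit <- fit_wash_params(lanes, fx, mu_grid, phi0_grid)
  expect_lte(abs(fit$mu - 0.1), 0.05 + 1e-9)
  expect_lte(abs(fit$phi0 - 0.33), 0.11 + 1e-9)

  # self-consistency at the perfect-washing corner
  fx0 <- make_fit_fixture(0, 0, lanes)
  fit0 <- fit_wash_params(lanes, fx0, c(0, 0.05, 0.1), c(0, 0.11, 0.22))
  expect_equal(c(fit0$mu, fit0$phi0), c(0, 0))
  expect_equal(fit0$error, 0)

  # rank noise: truth still within two grid cells
  fxs <- make_fit_fixture(0.1, 0.33, lanes, seed = 5, p_swap = 0.1)
  fits <- fit_wash_params(lanes, fxs, mu_grid, phi0_grid)
  expect_lte(abs(fits$mu - 0.1), 0.1 + 1e-9)
  expect_lte(abs(fits$phi0 - 0.33), 0.22 + 1e-9)
})

test_that("seq1 pop limit is insensitive to increasing phi0 at small mu", {
  mean_pl <- function(phi0) {
    mean(sapply(1:6, function(sd) {
      pop_limit(simulate_sequence(make_seqN(1, seed = sd),
                                  wash = wash_params(0.02, phi0),
                                  seed = 400 + sd, trace = FALSE))
    }))
  }
  lo <- mean_pl(0); hi <- mean_pl(0.4)
  expect_gte(hi, lo - 0.5) # no degradation with rising carry-over
})
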
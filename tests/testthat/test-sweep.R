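test_that("wash sweeps run one seeded simulation per grid cell", {
  ops <- parse_ops("X Y q q")
  sw <- sweep_wash(ops, mu = c(0, 0.1), phi0 = c(0, 0.33), seed = 9)
  expect_equal(nrow(sw), 4L)
  expect_setequal(names(sw), c("mu", "phi0", "seed", "pop_limit"))
  # the perfect-washing cell achieves every pop
  expect_equal(sw$pop_limit[sw$mu == 0 & sw$phi0 == 0], 2L)
  sw2 <- sweep_wash(ops, mu = c(0, 0.1), phi0 = c(0, 0.33), seed = 9)
  expect_identical(as.data.frame(sw), as.data.frame(sw2)) # seed-deterministic
})

test_that("concentration/wait sweeps report the axes in working units", {
  ops <- parse_ops("X q")
  sw <- sweep_conc_wait(ops, gamma = c(300e-9), t_wait = c(600, 1800),
                        wash = "W1", seed = 4)
  expect_equal(nrow(sw), 2L)
  expect_equal(sort(unique(sw$t_wait_min)), c(10, 30))
  expect_equal(unique(sw$gamma_nM), 300)
  expect_true(all(sw$pop_limit >= 0))
})

test_that("noise sweeps expose replicate statistics and the onset scan", {
  ops <- parse_ops("X q")
  sw <- sweep_noise(ops, eta = c(0, 100e-9), n = 4, wash = "W1", seed = 6)
  expect_equal(nrow(sw), 8L)
  s <- summary(sw)
  expect_equal(s$n, c(4, 4))
  on <- noise_onset(sw)
  expect_true(is.list(on) && all(c("eta_onset_nM", "floor_nM", "flat") %in% names(on)))
  # replicate k is reproducible in isolation through derived seeds
  sw2 <- sweep_noise(ops, eta = c(0, 100e-9), n = 4, wash = "W1", seed = 6)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})
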
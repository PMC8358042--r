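## Parameter sweeps: washing heatmaps, concentration x wait-time heatmaps
## and pipetting-noise Monte Carlo curves, all reporting the pop limit.

#' Washing-efficiency sweep
#'
#' Pop limit of an operation sequence over a `(mu, phi0)` grid, one
#' simulation per cell with a seed derived from the master seed.
#'
#' @param opseq An `op_sequence`.
#' @param mu,phi0 Grid axes (defaults: mu in \[0, 0.2\] x phi0 in \[0, 0.6\],
#'   11 x 13 cells).
#' @param backend,seed,... Passed to [simulate_sequence()].
#' @return A `stack_sweep` data frame with columns `mu`, `phi0`, `seed`,
#'   `pop_limit`.
#' @export
sweep_wash <- function(opseq, mu = seq(0, 0.2, length.out = 11),
                       phi0 = seq(0, 0.6, length.out = 13),
                       backend = "ssa", seed = 1, ...) {
  grid <- expand.grid(mu = mu, phi0 = phi0)
  grid$seed <- vapply(seq_len(nrow(grid)), function(g) derive_seed(seed, g), 1L)
  grid$pop_limit <- vapply(seq_len(nrow(grid)), function(g) {
    run <- simulate_sequence(opseq, wash = wash_params(grid$mu[g], grid$phi0[g]),
                             backend = backend, seed = grid$seed[g], ...)
    as.integer(pop_limit(run))
  }, 1L)
  structure(grid, class = c("stack_sweep", "data.frame"), plan = "wash",
            opseq = opseq)
}

#' Concentration x wait-time sweep
#'
#' Pop limit over a grid of standard strand concentration `gamma` and stage
#' wait `t_wait` at fixed washing parameters (log-scaled axes by default,
#' the standard operating point 300 nM / 30 min lying on the grid).
#'
#' @param opseq An `op_sequence`.
#' @param gamma Concentration axis in M.
#' @param t_wait Wait axis in seconds.
#' @param wash Washing parameters or preset name.
#' @param backend,seed,... Passed to [simulate_sequence()].
#' @return A `stack_sweep` data frame with columns `gamma_nM`, `t_wait_min`,
#'   `seed`, `pop_limit`.
#' @export
sweep_conc_wait <- function(opseq,
                            gamma = c(30, 100, 300, 1000, 3000) * 1e-9,
                            t_wait = c(5, 10, 30, 60, 120) * 60,
                            wash = "W1", backend = "ssa", seed = 1, ...) {
  if (is.character(wash)) wash <- wash_params(wash)
  grid <- expand.grid(gamma = gamma, t_wait = t_wait)
  grid$seed <- vapply(seq_len(nrow(grid)), function(g) derive_seed(seed, g), 1L)
  grid$pop_limit <- vapply(seq_len(nrow(grid)), function(g) {
    run <- simulate_sequence(opseq, wash = wash, backend = backend,
                             seed = grid$seed[g], gamma = grid$gamma[g],
                             t_wait = grid$t_wait[g], ...)
    as.integer(pop_limit(run))
  }, 1L)
  out <- data.frame(gamma_nM = round(grid$gamma * 1e9, 6),
                    t_wait_min = round(grid$t_wait / 60, 6),
                    seed = grid$seed, pop_limit = grid$pop_limit)
  structure(out, class = c("stack_sweep", "data.frame"), plan = "conc_wait",
            opseq = opseq, wash = wash)
}

#' Pipetting-noise Monte Carlo sweep
#'
#' Mean and spread of the pop limit under uniform pipetting noise
#' `U(gamma - eta, gamma + eta)` for a range of noise half-widths, with `n`
#' independent stochastic replicates per noise value.
#'
#' @param opseq An `op_sequence`.
#' @param eta Noise half-widths in M (default 0 to 300 nM in 25 nM steps).
#' @param n Replicates per noise value.
#' @param wash Washing parameters or preset name.
#' @param seed Master seed; replicate `k` at noise index `i` is reproducible
#'   in isolation via a derived seed.
#' @param ... Passed to [simulate_sequence()].
#' @return A `stack_sweep` data frame with columns `eta_nM`, `rep`, `seed`,
#'   `pop_limit`; `summary()` gives per-eta mean and sd.
#' @export
sweep_noise <- function(opseq, eta = seq(0, 300, by = 25) * 1e-9, n = 25,
                        wash = "W1", seed = 1, ...) {
  if (is.character(wash)) wash <- wash_params(wash)
  grid <- expand.grid(rep = seq_len(n), eta = eta)[, c("eta", "rep")]
  grid$seed <- vapply(seq_len(nrow(grid)), function(g)
    derive_seed(seed, match(grid$eta[g], eta) * 1000L + grid$rep[g]), 1L)
  grid$pop_limit <- vapply(seq_len(nrow(grid)), function(g) {
    run <- simulate_sequence(opseq, wash = wash, backend = "ssa",
                             seed = grid$seed[g], eta = grid$eta[g], ...)
    as.integer(pop_limit(run))
  }, 1L)
  out <- data.frame(eta_nM = round(grid$eta * 1e9, 6), rep = grid$rep,
                    seed = grid$seed, pop_limit = grid$pop_limit)
  structure(out, class = c("stack_sweep", "data.frame"), plan = "noise",
            opseq = opseq, wash = wash)
}

#' Run a sweep by plan name
#'
#' Dispatcher over [sweep_wash()], [sweep_conc_wait()] and [sweep_noise()].
#'
#' @param opseq An `op_sequence`.
#' @param plan One of `"wash"`, `"conc_wait"`, `"noise"`.
#' @param ... Passed to the corresponding sweep function.
#' @return A `stack_sweep` data frame.
#' @export
run_sweep <- function(opseq, plan = c("wash", "conc_wait", "noise"), ...) {
  plan <- match.arg(plan)
  switch(plan,
         wash = sweep_wash(opseq, ...),
         conc_wait = sweep_conc_wait(opseq, ...),
         noise = sweep_noise(opseq, ...))
}

#' @export
summary.stack_sweep <- function(object, ...) {
  plan <- attr(object, "plan")
  if (identical(plan, "noise")) {
    agg <- stats::aggregate(pop_limit ~ eta_nM, data = object,
                            FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                                n = length(x)))
    out <- data.frame(eta_nM = agg$eta_nM, mean = agg$pop_limit[, "mean"],
                      sd = agg$pop_limit[, "sd"], n = agg$pop_limit[, "n"])
    return(out)
  }
  summary.data.frame(object, ...)
}

#' @export
plot.stack_sweep <- function(x, ...) {
  plan <- attr(x, "plan")
  if (identical(plan, "noise")) {
    s <- summary(x)
    graphics::plot(s$eta_nM, s$mean, type = "b", pch = 16,
                   ylim = range(c(s$mean - s$sd, s$mean + s$sd)),
                   xlab = expression(eta ~ "(nM)"), ylab = "pop limit", ...)
    graphics::arrows(s$eta_nM, s$mean - s$sd, s$eta_nM, s$mean + s$sd,
                     angle = 90, code = 3, length = 0.03, col = "grey50")
  } else {
    ax <- if (identical(plan, "wash")) c("mu", "phi0") else c("gamma_nM", "t_wait_min")
    xv <- x[[ax[1]]]; yv <- x[[ax[2]]]
    lab <- ax
    if (identical(plan, "conc_wait")) { # log-scaled axes
      xv <- log10(xv); yv <- log10(yv)
      lab <- paste0("log10 ", ax)
    }
    xs <- sort(unique(xv)); ys <- sort(unique(yv))
    z <- matrix(NA_real_, length(xs), length(ys))
    z[cbind(match(xv, xs), match(yv, ys))] <- x$pop_limit
    graphics::image(xs, ys, z, xlab = lab[1], ylab = lab[2], ...)
  }
  invisible(x)
}
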
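## Calibration of washing parameters (mu, phi0) from ranked gel band
## orderings, and synthetic fixtures for testing the calibration.

#' Single-signal lane experiments for calibration
#'
#' Builds the stage lists of a set of gel lanes from an `n`-record /
#' `n`-pop run with the linear signal `w`: lane `k` is the protocol truncated
#' after its `k`-th stage, so the lane set mirrors a record/pop PAGE series
#' (start, push, signal, ..., read, pop, ...).
#'
#' @param n_records Number of `w` records (and pops).
#' @param gamma,t_wait Standard concentration (M) and wait (s).
#' @return A named list of stage data frames, one per lane.
#' @export
write_lane_experiments <- function(n_records = 3, gamma = 300e-9,
                                   t_wait = 1800) {
  ops <- op_sequence(c(rep("w", n_records), rep("pop", n_records)))
  stages <- compile_operations(ops, gamma = gamma, t_wait = t_wait)
  lanes <- lapply(seq_len(nrow(stages)), function(k) stages[seq_len(k), , drop = FALSE])
  names(lanes) <- paste0("lane", seq_along(lanes), "_", stages$token)
  lanes
}

simulate_lane <- function(stages, wash, backend = "ode", seed = NULL,
                          L_max = 24L, network = NULL, ...) {
  run <- with_seed(seed, {
    state <- init_state(...)
    # the lane is sampled at the end of its final reaction interval: no
    # trailing wash
    stages$wash_after[nrow(stages)] <- FALSE
    run_protocol(state, stages, wash = wash, backend = backend, trace = FALSE,
                 L_max = L_max, network = network)
  })
  run$state
}

# one shared truncated network for a set of lane experiments
lane_network <- function(experiments, L_max = 24L, rates = rate_constants(),
                         options = rule_options()) {
  toks <- unique(c("k", unlist(lapply(experiments, function(e) e$token))))
  build_ode_network(toks, rates = rates, options = options, L_max = L_max)
}

#' Synthetic observed band orderings at known washing parameters
#'
#' Simulates each lane experiment at the given `(mu, phi0)` and reports the
#' ranked band sizes, optionally corrupted by adjacent rank swaps. Used to
#' validate [fit_wash_params()] by parameter recovery, which stands in for
#' calibration against real gel data.
#'
#' @param mu,phi0 True washing parameters in \[0, 1\].
#' @param experiments List of stage data frames (see
#'   [write_lane_experiments()]).
#' @param seed Seed for rank noise (and the simulation, if stochastic).
#' @param p_swap Probability of swapping each adjacent rank pair.
#' @param backend Simulation backend (deterministic `"ode"` by default).
#' @param threshold Band detection threshold (nM x nt).
#' @param L_max Truncation order for the deterministic backend.
#' @param ... Passed to [init_state()].
#' @return A list of ranked band-size vectors (one per lane), with attribute
#'   `degenerate = TRUE` if every lane is empty (e.g. `mu = 1`).
#' @export
make_fit_fixture <- function(mu, phi0, experiments = write_lane_experiments(),
                             seed = NULL, p_swap = 0, backend = "ode",
                             threshold = 1000, L_max = 24L, ...) {
  wp <- wash_params(mu, phi0)
  network <- if (backend == "ode") lane_network(experiments, L_max = L_max) else NULL
  rankings <- lapply(seq_along(experiments), function(i) {
    st <- simulate_lane(experiments[[i]], wp, backend = backend,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                        L_max = L_max, network = network, ...)
    band_pattern(st, "tethered", threshold = threshold)$size_nt
  })
  names(rankings) <- names(experiments)
  if (p_swap > 0) {
    rankings <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 0L), {
      lapply(rankings, function(rk) {
        if (length(rk) < 2L) return(rk)
        for (i in seq_len(length(rk) - 1L)) {
          if (stats::runif(1) < p_swap) rk[c(i, i + 1L)] <- rk[c(i + 1L, i)]
        }
        rk
      })
    })
  }
  # degenerate when every lane that saw at least one wash comes out empty
  # (e.g. mu = 1 strips the beads at the first wash)
  washed <- vapply(experiments, function(e)
    sum(utils::head(e$wash_after, -1)) > 0, TRUE)
  attr(rankings, "degenerate") <-
    any(washed) && all(lengths(rankings[washed]) == 0L)
  attr(rankings, "truth") <- c(mu = mu, phi0 = phi0)
  rankings
}

#' Fit washing parameters from band orderings
#'
#' Grid search over `(mu, phi0)`: every lane experiment is simulated
#' (deterministic mass-action backend by default) at each grid cell, the
#' predicted band ordering is compared with the observed one via
#' [band_order_error()], and the cell minimising the mean error over lanes
#' is returned together with the full error surface. Cells whose simulation
#' fails are excluded with a warning.
#'
#' @param experiments List of stage data frames, one per lane.
#' @param observed List of ranked band-size vectors, parallel to
#'   `experiments`.
#' @param mu_grid,phi0_grid Grid values in \[0, 1\].
#' @param backend Simulation backend.
#' @param threshold Band detection threshold (nM x nt).
#' @param L_max Truncation order for the deterministic backend.
#' @param ... Passed to [init_state()].
#' @return An object of class `wash_fit`: list with `mu`, `phi0`, `error`
#'   (at the optimum) and `surface` (data frame `mu`, `phi0`, `error`).
#' @export
fit_wash_params <- function(experiments, observed,
                            mu_grid = seq(0, 0.2, by = 0.05),
                            phi0_grid = seq(0, 0.6, by = 0.1),
                            backend = "ode", threshold = 1000, L_max = 24L,
                            ...) {
  if (length(experiments) != length(observed))
    stop("experiments and observed rankings must have equal length")
  if (any(mu_grid < 0 | mu_grid > 1) || any(phi0_grid < 0 | phi0_grid > 1))
    stop("grid must cover a sub-rectangle of [0, 1]^2")
  network <- if (backend == "ode") lane_network(experiments, L_max = L_max) else NULL
  grid <- expand.grid(mu = mu_grid, phi0 = phi0_grid)
  grid$error <- NA_real_
  for (g in seq_len(nrow(grid))) {
    wp <- wash_params(grid$mu[g], grid$phi0[g])
    errs <- rep(NA_real_, length(experiments))
    bad <- FALSE
    for (i in seq_along(experiments)) {
      st <- tryCatch(simulate_lane(experiments[[i]], wp, backend = backend,
                                   L_max = L_max, network = network, ...),
                     error = function(e) e)
      if (inherits(st, "error")) {
        warning(sprintf("cell (mu=%.3g, phi0=%.3g) excluded: %s",
                        grid$mu[g], grid$phi0[g], conditionMessage(st)))
        bad <- TRUE
        break
      }
      pred <- band_pattern(st, "tethered", threshold = threshold)$size_nt
      errs[i] <- if (length(observed[[i]]))
        band_order_error(pred, observed[[i]])
      else if (length(pred)) 1 else 0
    }
    if (!bad) grid$error[g] <- mean(errs)
  }
  if (all(is.na(grid$error))) stop("all grid cells failed to simulate")
  best <- which.min(grid$error)
  structure(list(mu = grid$mu[best], phi0 = grid$phi0[best],
                 error = grid$error[best], surface = grid,
                 mu_grid = mu_grid, phi0_grid = phi0_grid),
            class = "wash_fit")
}

#' @export
print.wash_fit <- function(x, ...) {
  cat("<wash_fit> lowest mean band-order error", signif(x$error, 4),
      "at mu =", x$mu, ", phi0 =", x$phi0, "\n")
  cat("  grid:", length(x$mu_grid), "x", length(x$phi0_grid), "cells\n")
  invisible(x)
}

#' @export
plot.wash_fit <- function(x, ...) {
  z <- matrix(x$surface$error, nrow = length(x$mu_grid),
              dimnames = list(x$mu_grid, x$phi0_grid))
  graphics::image(x$mu_grid, x$phi0_grid, z, xlab = expression(mu),
                  ylab = expression(phi[0]), main = "mean band-order error",
                  ...)
  graphics::points(x$mu, x$phi0, pch = 21, bg = "white", cex = 1.4)
  invisible(x)
}
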
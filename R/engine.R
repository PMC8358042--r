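## Staged protocol engine: strand addition, timed reaction intervals
## (stochastic or deterministic), and discrete washing events.

AVOGADRO <- 6.02214076e23

#' Convert concentration to copy number and back
#'
#' @param conc Concentration in M.
#' @param n Copy number.
#' @param volume Volume in litres.
#' @return `conc_to_copies` gives c*V*NA (unrounded); `copies_to_nM` gives
#'   the concentration in nM.
#' @export
conc_to_copies <- function(conc, volume) conc * volume * AVOGADRO

#' @rdname conc_to_copies
#' @export
copies_to_nM <- function(n, volume) n / (volume * AVOGADRO) * 1e9

#' Initialise the system state
#'
#' Creates a state holding bead-borne linker `k` at the given concentration
#' (rounded half-to-even to copies for the stochastic backend), full bead
#' mass, and zeroed wash counter and clock.
#'
#' @param volume Reaction volume in litres (default 0.15 pl).
#' @param linker_conc Linker concentration in M (default 200 nM).
#' @param rates Rate constants, see [rate_constants()].
#' @param monomers Monomer table, see [define_monomers()].
#' @param options Rule switches, see [rule_options()].
#' @return An object of class `stack_state`: a list with `counts` (named
#'   numeric vector of copies per species key), `volume`, `bead_fraction`,
#'   `wash_index`, `time`, plus the chemistry configuration.
#' @export
#' @examples
#' st <- init_state()
#' st$counts  # ~18066 copies of tethered linker
init_state <- function(volume = 0.15e-12, linker_conc = 200e-9,
                       rates = rate_constants(), monomers = default_monomers(),
                       options = rule_options()) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  if (linker_conc < 0) stop("linker concentration must be non-negative")
  counts <- c(k = round(conc_to_copies(linker_conc, volume)))
  structure(list(
    counts = counts, volume = volume, bead_fraction = 1,
    wash_index = 0L, time = 0,
    rates = rates, monomers = monomers, options = options
  ), class = "stack_state")
}

#' @export
print.stack_state <- function(x, ...) {
  cat("<stack_state> t =", format(x$time), "s, wash_index =", x$wash_index,
      ", bead_fraction =", signif(x$bead_fraction, 4), "\n")
  cat(" ", length(x$counts), "species,",
      format(sum(x$counts), big.mark = ","), "molecules in",
      format(x$volume * 1e12), "pl\n")
  top <- sort(x$counts, decreasing = TRUE)
  top <- top[top > 0]
  show <- utils::head(top, 8L)
  for (i in seq_along(show))
    cat(sprintf("  %-16s %12.0f copies  (%8.2f nM)\n", names(show)[i],
                show[i], copies_to_nM(show[i], x$volume)))
  if (length(top) > length(show)) cat("  ...\n")
  invisible(x)
}

#' Add a strand to the system
#'
#' Increments the free monomer count by `round(c' * V * NA)` where `c'` is
#' the pipetted concentration, optionally perturbed by uniform pipetting
#' noise `c' ~ U(conc - eta, conc + eta)` truncated at zero.
#'
#' @param state A `stack_state`.
#' @param token Monomer token to add.
#' @param conc Nominal concentration in M.
#' @param eta Half-width of the uniform pipetting noise in M (0 = exact).
#' @return The updated state; the realised concentration is recorded in
#'   `state$last_added`.
#' @export
add_strand <- function(state, token, conc, eta = 0) {
  if (!token %in% TOKENS) stop("unknown token: ", token)
  if (conc < 0 || eta < 0) stop("concentration and noise must be non-negative")
  cprime <- if (eta > 0) max(0, stats::runif(1, conc - eta, conc + eta)) else conc
  n <- round(conc_to_copies(cprime, state$volume))
  key <- token
  state$counts[key] <- (if (key %in% names(state$counts)) state$counts[[key]] else 0) + n
  state$last_added <- c(token = token, conc = cprime)
  state
}

#' Advance the chemistry for a time interval
#'
#' `backend = "ssa"` runs the Gillespie direct method on the jump process
#' whose channels are re-enumerated just-in-time as new species appear
#' (compiled core); propensities are `k * n_i * n_j / (V * NA)` for
#' bimolecular channels, halved for identical reactants. `backend = "ode"`
#' integrates the mass-action rate equations on the species set closed under
#' the rules up to `L_max` monomers per complex (see [advance_ode()]).
#'
#' @param state A `stack_state`.
#' @param duration Interval in seconds (>= 0).
#' @param backend `"ssa"` or `"ode"`.
#' @param max_steps Cap on SSA firings per call.
#' @param L_max Truncation order for the ODE backend.
#' @param network Optional precomputed [build_ode_network()] (ODE backend).
#' @return The updated state.
#' @export
advance <- function(state, duration, backend = c("ssa", "ode"),
                    max_steps = 5e7, L_max = 16L, network = NULL) {
  backend <- match.arg(backend)
  if (duration < 0) stop("duration must be non-negative")
  if (duration == 0 || !length(state$counts)) {
    state$time <- state$time + duration
    return(state)
  }
  state$counts <- state$counts[state$counts > 0]
  if (!length(state$counts)) {
    state$time <- state$time + duration
    return(state)
  }
  if (backend == "ssa") {
    ids <- lapply(names(state$counts), function(k) tokens_to_ids(key_tokens(k)))
    res <- ssa_advance_cpp(ids, unname(state$counts),
                           state$rates$k_A, state$rates$k_BC,
                           state$volume, duration, max_steps, state$options)
    keys <- vapply(res$tokens, function(iv) species_key(ids_to_tokens(iv)), "")
    state$counts <- stats::setNames(res$counts, keys)
    state$time <- state$time + duration
    state
  } else {
    advance_ode(state, duration, L_max = L_max, network = network)
  }
}

#' Wash the system
#'
#' Models one centrifugation/supernatant-removal event. Bead mass is reduced
#' by the loss fraction `mu`; tethered species are thinned by `(1 - mu)` and
#' supernatant species by the carry-over fraction `phi_n = phi0 * (1 - mu)^n`
#' (with `n` the number of washes already performed), which decays with
#' successive washes as the bead mass available for non-specific binding
#' shrinks. The stochastic backend thins counts binomially so copy numbers
#' stay integral; the deterministic backend multiplies exactly.
#'
#' @param state A `stack_state`.
#' @param wash Washing parameters from [wash_params()].
#' @param stochastic Logical: binomial thinning (TRUE, for SSA runs) or exact
#'   multiplication (FALSE, for ODE runs).
#' @return The updated state with `wash_index` incremented.
#' @export
wash <- function(state, wash = wash_params("W1"), stochastic = TRUE) {
  mu <- wash$mu; phi0 <- wash$phi0
  phi_n <- min(1, phi0 * (1 - mu)^state$wash_index)
  if (length(state$counts)) {
    teth <- vapply(names(state$counts), function(k) key_tokens(k)[1] == "k", TRUE)
    keep_p <- ifelse(teth, 1 - mu, phi_n)
    if (stochastic) {
      thinned <- stats::rbinom(length(state$counts), round(state$counts), keep_p)
      state$counts <- stats::setNames(as.numeric(thinned), names(state$counts))
    } else {
      state$counts <- state$counts * keep_p
    }
    state$counts <- state$counts[state$counts > 0]
  }
  state$bead_fraction <- state$bead_fraction * (1 - mu)
  state$wash_index <- state$wash_index + 1L
  state
}

#' Washing parameters
#'
#' `mu` is the fraction of beads lost per wash; `phi0` the fraction of
#' supernatant species non-specifically transferred through the first wash.
#' Presets: `W1` (0.1, 0.33) -- the calibrated experimental protocol --
#' `W2` (0.05, 0.15) and `W3` (0.02, 0.05).
#'
#' @param mu Either a preset name (`"W1"`, `"W2"`, `"W3"`) or a numeric bead
#'   loss fraction in \[0, 1\].
#' @param phi0 Supernatant transfer fraction in \[0, 1\] (ignored when a
#'   preset name is given).
#' @return A list with elements `mu` and `phi0`.
#' @export
#' @examples
#' wash_params("W1")
#' wash_params(0.02, 0.01)
wash_params <- function(mu, phi0 = NULL) {
  presets <- list(W1 = c(0.1, 0.33), W2 = c(0.05, 0.15), W3 = c(0.02, 0.05))
  if (is.character(mu)) {
    if (!mu %in% names(presets)) stop("unknown washing preset: ", mu)
    v <- presets[[mu]]
    return(list(mu = v[1], phi0 = v[2], preset = mu))
  }
  if (is.null(phi0)) stop("phi0 required when mu is numeric")
  if (mu < 0 || mu > 1 || phi0 < 0 || phi0 > 1)
    stop("washing parameters must lie in [0, 1]")
  list(mu = mu, phi0 = phi0, preset = NA_character_)
}

#' Run a compiled staged protocol
#'
#' Executes `add -> wait -> (readout) -> (wash)` for each stage, recording a
#' per-stage trace and the supernatant read-signal measurements taken at the
#' end of every read stage (before its wash), which are the raw material of
#' the pop-limit statistic.
#'
#' @param state Initial state from [init_state()].
#' @param stages Stage table from [compile_operations()] (columns `token`,
#'   `conc`, `wait`, `wash_after`, `readout`).
#' @param wash Washing parameters, see [wash_params()].
#' @param backend `"ssa"` or `"ode"`.
#' @param eta Pipetting noise half-width in M, applied to every stage
#'   addition.
#' @param trace Logical: keep the full per-stage species trace (turn off for
#'   large sweeps).
#' @param ... Passed to [advance()].
#' @return An object of class `stack_run`: list with the final `state`,
#'   `readouts` (data frame: pop index, expected token, `Xr_nM`, `Yr_nM`,
#'   `wr_nM`) and, if requested, `trace` (long data frame: stage, species,
#'   compartment, copies, conc_nM).
#' @export
run_protocol <- function(state, stages, wash = wash_params("W1"),
                         backend = c("ssa", "ode"), eta = 0, trace = TRUE, ...) {
  backend <- match.arg(backend)
  stochastic <- backend == "ssa"
  expected <- attr(stages, "expected_pops")
  readouts <- list()
  rows <- list()
  pop_i <- 0L
  for (i in seq_len(nrow(stages))) {
    st <- stages[i, ]
    state <- add_strand(state, st$token, st$conc, eta = eta)
    state <- advance(state, st$wait, backend = backend, ...)
    if (isTRUE(st$readout)) {
      pop_i <- pop_i + 1L
      sup <- supernatant_nM(state)
      readouts[[pop_i]] <- data.frame(
        pop = pop_i,
        expected = if (!is.null(expected) && pop_i <= length(expected))
          expected[pop_i] else NA_character_,
        Xr_nM = sup_get(sup, "X.r"), Yr_nM = sup_get(sup, "Y.r"),
        wr_nM = sup_get(sup, "w.r"), stringsAsFactors = FALSE)
    }
    if (isTRUE(st$wash_after)) state <- wash(state, wash, stochastic = stochastic)
    if (trace) rows[[i]] <- state_snapshot(state, stage = i, token = st$token)
  }
  out <- list(
    state = state,
    readouts = if (length(readouts)) do.call(rbind, readouts) else
      data.frame(pop = integer(), expected = character(),
                 Xr_nM = numeric(), Yr_nM = numeric(), wr_nM = numeric()),
    trace = if (trace) do.call(rbind, rows) else NULL,
    stages = stages, wash = wash, backend = backend, eta = eta
  )
  class(out) <- "stack_run"
  out
}

supernatant_nM <- function(state) {
  if (!length(state$counts)) return(numeric(0))
  teth <- vapply(names(state$counts), function(k) key_tokens(k)[1] == "k", TRUE)
  copies_to_nM(state$counts[!teth], state$volume)
}

sup_get <- function(sup, key) if (key %in% names(sup)) unname(sup[[key]]) else 0

state_snapshot <- function(state, stage, token) {
  if (!length(state$counts))
    return(data.frame(stage = integer(), token = character(),
                      species = character(), compartment = character(),
                      copies = numeric(), conc_nM = numeric()))
  teth <- vapply(names(state$counts), function(k) key_tokens(k)[1] == "k", TRUE)
  data.frame(
    stage = stage, token = token, species = names(state$counts),
    compartment = ifelse(teth, "tethered", "supernatant"),
    copies = unname(state$counts),
    conc_nM = unname(copies_to_nM(state$counts, state$volume)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.stack_run <- function(x, ...) {
  cat("<stack_run> backend =", x$backend, "|", nrow(x$stages), "stages |",
      nrow(x$readouts), "pops\n")
  if (nrow(x$readouts)) {
    cat("pop limit:", pop_limit(x), "\n")
    print(utils::head(x$readouts, 10))
  }
  invisible(x)
}
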
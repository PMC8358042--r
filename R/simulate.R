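## One-call simulation of an operation sequence.

#' Simulate a stack operation sequence
#'
#' Convenience wrapper that compiles an operation sequence to stages,
#' initialises the bead-linker state and runs the staged protocol under the
#' given washing parameters.
#'
#' @param opseq An `op_sequence` (see [make_seqN()], [make_seqR()],
#'   [parse_ops()]).
#' @param wash Washing parameters or preset name (see [wash_params()]).
#' @param backend `"ssa"` (stochastic, default) or `"ode"` (deterministic
#'   mass action).
#' @param seed Seed for the stochastic backend (`NULL` = current RNG state).
#' @param eta Pipetting noise half-width in M.
#' @param gamma Standard strand concentration in M.
#' @param t_wait Stage wait in seconds.
#' @param read_conc Read-strand concentration in M (defaults to `gamma`).
#' @param volume Reaction volume in litres.
#' @param linker_conc Linker concentration in M.
#' @param rates,monomers,options Chemistry configuration, see
#'   [rate_constants()], [define_monomers()], [rule_options()].
#' @param trace Keep the full per-stage trace?
#' @param ... Passed to [advance()] (e.g. `L_max` for the ODE backend).
#' @return A `stack_run`; apply [pop_limit()] for the performance statistic.
#' @export
#' @examples
#' \donttest{
#' run <- simulate_sequence(parse_ops("X Y q q"), wash = "W1", seed = 7)
#' pop_limit(run)
#' }
simulate_sequence <- function(opseq, wash = "W1", backend = c("ssa", "ode"),
                              seed = NULL, eta = 0, gamma = 300e-9,
                              t_wait = 1800, read_conc = gamma,
                              volume = 0.15e-12, linker_conc = 200e-9,
                              rates = rate_constants(),
                              monomers = default_monomers(),
                              options = rule_options(), trace = FALSE, ...) {
  backend <- match.arg(backend)
  if (is.character(wash)) wash <- wash_params(wash)
  stages <- compile_operations(opseq, gamma = gamma, t_wait = t_wait,
                               read_conc = read_conc)
  with_seed(seed, {
    state <- init_state(volume = volume, linker_conc = linker_conc,
                        rates = rates, monomers = monomers, options = options)
    run_protocol(state, stages, wash = wash, backend = backend, eta = eta,
                 trace = trace, ...)
  })
}
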
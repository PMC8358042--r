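## Monomer alphabet and strand definitions.

# fixed token order; integer ids used by the compiled core follow this order
TOKENS <- c("s", "p", "X", "Y", "w", "r", "q", "k", "z")
SIGNAL_TOKENS <- c("X", "Y", "w")

TOKEN_ROLES <- c(
  s = "start", p = "push", X = "signal", Y = "signal", w = "signal",
  r = "read", q = "pop", k = "linker", z = "releaser"
)

#' Default monomer table
#'
#' The nine single-stranded DNA species that operate the stack. Signal strands
#' `X` (107 nt) and `Y` (137 nt) carry information in hairpin loops; `w` is
#' the linear single-signal variant used for gel work. `p` spans the 28 nt A
#' domain plus the 28 nt BC overhang (56 nt). Lengths of the remaining strands
#' are not uniquely determined by the domain architecture and are package
#' assumptions: two-domain strands (`s`, `r`, `q`, `w`) default to 56 nt,
#' single-domain strands (`k`, `z`) to 28 nt.
#'
#' @return A data frame with columns `token`, `length_nt` and `role`.
#' @export
#' @examples
#' default_monomers()
default_monomers <- function() {
  data.frame(
    token = TOKENS,
    length_nt = c(56L, 56L, 107L, 137L, 56L, 56L, 56L, 28L, 28L),
    role = unname(TOKEN_ROLES[TOKENS]),
    stringsAsFactors = FALSE
  )
}

#' Validate a monomer configuration
#'
#' Checks that a monomer table names all nine strands of the chemistry with
#' positive lengths. Roles are fixed by the token identity and filled in if
#' absent.
#'
#' @param config A data frame with columns `token` and `length_nt` (and
#'   optionally `role`), or a named list/vector of lengths. `NULL` gives the
#'   defaults.
#' @return A validated monomer data frame (one row per token, in canonical
#'   token order).
#' @export
#' @examples
#' define_monomers(list(X = 107, Y = 137, s = 56, p = 56, w = 56,
#'                      r = 56, q = 56, k = 28, z = 28))
define_monomers <- function(config = NULL) {
  if (is.null(config)) return(default_monomers())
  if (!is.data.frame(config)) {
    lens <- unlist(config)
    config <- data.frame(token = names(lens), length_nt = as.numeric(lens),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("token", "length_nt") %in% names(config)))
    stop("monomer config needs columns 'token' and 'length_nt'")
  unknown <- setdiff(config$token, TOKENS)
  if (length(unknown))
    stop("unknown monomer token(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(config$token))
    stop("duplicated monomer token(s) in config")
  missing <- setdiff(TOKENS, config$token)
  if (length(missing))
    stop("missing monomer: ", paste(missing, collapse = ", "))
  if (any(!is.finite(config$length_nt)) || any(config$length_nt <= 0))
    stop("monomer lengths must be positive")
  out <- config[match(TOKENS, config$token), c("token", "length_nt"), drop = FALSE]
  out$length_nt <- as.integer(out$length_nt)
  out$role <- unname(TOKEN_ROLES[out$token])
  rownames(out) <- NULL
  out
}

#' Kinetic rate constants
#'
#' The chemistry reduces to two bimolecular hybridisation rate constants:
#' `k_A` for reactions nucleated at an exposed A-type (alpha) domain and
#' `k_BC` for reactions nucleated at an exposed BC-type (beta) overhang.
#' Strand-displacement steps inherit the rate of their toehold-binding
#' domain. Defaults are the UV-absorbance estimates, 3e4 /M/s for both.
#'
#' @param k_A,k_BC Bimolecular rate constants in M^-1 s^-1; both must be
#'   positive.
#' @return A named list with elements `k_A` and `k_BC`.
#' @export
rate_constants <- function(k_A = 3e4, k_BC = 3e4) {
  if (!is.finite(k_A) || !is.finite(k_BC) || k_A <= 0 || k_BC <= 0)
    stop("rate constants must be positive")
  list(k_A = k_A, k_BC = k_BC)
}

#' Reaction-rule switches
#'
#' Individual rule classes can be disabled for sensitivity analyses. `rules`
#' toggles the five principal classes (elongation by push, elongation by
#' signal, read displacement, pop displacement, nucleation/release). The
#' remaining switches control degenerate instances: read capping of a bare
#' start, read hybridising a free signal monomer, pop hybridising a free push
#' monomer, and whether start-headed complexes (not just free start strands)
#' may nucleate on a bead linker.
#'
#' @param rules Logical vector of length 5, master switches for rule classes
#'   R1..R5.
#' @param cap_start,r_free_signal,q_free_push,chain_nucleation Logical
#'   switches for the degenerate rule instances described above.
#' @return A list consumed by [enumerate_reactions()] and the simulation
#'   backends.
#' @export
rule_options <- function(rules = rep(TRUE, 5), cap_start = TRUE,
                         r_free_signal = TRUE, q_free_push = TRUE,
                         chain_nucleation = TRUE) {
  stopifnot(is.logical(rules), length(rules) == 5L)
  list(rules = rules, cap_start = isTRUE(cap_start),
       r_free_signal = isTRUE(r_free_signal),
       q_free_push = isTRUE(q_free_push),
       chain_nucleation = isTRUE(chain_nucleation))
}

tokens_to_ids <- function(tokens) {
  ids <- match(tokens, TOKENS)
  if (anyNA(ids)) stop("unknown token(s): ",
                       paste(tokens[is.na(ids)], collapse = ", "))
  as.integer(ids)
}

ids_to_tokens <- function(ids) TOKENS[ids]
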
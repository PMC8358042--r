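## Deterministic mass-action backend on a truncated polymer species set.

# Close a species set under the reaction rules, truncating complexes at
# L_max monomers. Returns list(species = keys, reactions = data frame).
close_network <- function(species, rates, options, L_max = 16L) {
  set <- unique(species)
  repeat {
    rx <- enumerate_reactions(set, rates = rates, options = options)
    if (nrow(rx)) {
      too_big <- function(k) !is.na(k) & lengths(strsplit(k, ".", fixed = TRUE)) > L_max
      rx <- rx[!too_big(rx$product1) & !(!is.na(rx$product2) & too_big(rx$product2)), ,
               drop = FALSE]
    }
    prods <- unique(stats::na.omit(c(rx$product1, rx$product2)))
    new <- setdiff(prods, set)
    if (!length(new)) return(list(species = set, reactions = rx))
    set <- c(set, new)
  }
}

#' Precompute a truncated mass-action network
#'
#' Closes a species universe (typically the monomers a protocol will add,
#' plus the bead linker) under the reaction rules up to `L_max` monomers per
#' complex and assembles the stoichiometry used by the deterministic
#' backend. Building the network once and passing it to [advance()] or
#' [run_protocol()] avoids re-deriving it at every stage, which is what
#' makes grid calibrations practical.
#'
#' @param species Character vector of seed species keys (e.g. the monomer
#'   tokens used by a protocol).
#' @param rates,options Chemistry configuration.
#' @param L_max Maximum monomers per complex.
#' @return An object of class `ode_network`.
#' @export
build_ode_network <- function(species, rates = rate_constants(),
                              options = rule_options(), L_max = 16L) {
  net <- close_network(species, rates, options, L_max = L_max)
  spp <- net$species
  rx <- net$reactions
  n_rx <- nrow(rx)
  i_idx <- match(rx$reactant1, spp)
  j_idx <- match(rx$reactant2, spp)
  S <- matrix(0, nrow = length(spp), ncol = n_rx)
  if (n_rx) for (c in seq_len(n_rx)) {
    S[i_idx[c], c] <- S[i_idx[c], c] - 1
    S[j_idx[c], c] <- S[j_idx[c], c] - 1
    p1 <- match(rx$product1[c], spp)
    S[p1, c] <- S[p1, c] + 1
    if (!is.na(rx$product2[c])) {
      p2 <- match(rx$product2[c], spp)
      S[p2, c] <- S[p2, c] + 1
    }
  }
  structure(list(species = spp, reactions = rx, i = i_idx, j = j_idx,
                 S = S, k = rx$rate, L_max = L_max,
                 sizes = lengths(strsplit(spp, ".", fixed = TRUE))),
            class = "ode_network")
}

#' @export
print.ode_network <- function(x, ...) {
  cat("<ode_network>", length(x$species), "species,", nrow(x$reactions),
      "reactions, L_max =", x$L_max, "\n")
  invisible(x)
}

#' Advance the chemistry deterministically
#'
#' Mass-action rate equations are built on the species set reachable from the
#' current state under the reaction rules, truncated at `L_max` monomers per
#' complex, and integrated with `deSolve::lsoda`. If more than
#' `boundary_tol` of the total monomer mass ends up in complexes at the
#' truncation boundary the integration aborts with a diagnostic, since the
#' truncated network is then distorting the kinetics.
#'
#' @param state A `stack_state`.
#' @param duration Interval in seconds.
#' @param L_max Maximum number of monomers per complex (default 16).
#' @param rtol,atol Integration tolerances passed to `deSolve::lsoda`.
#' @param boundary_tol Maximum tolerated fraction of monomer tokens residing
#'   in complexes of `L_max - 1` or more monomers at the end of the interval.
#' @param network Optional precomputed [build_ode_network()] result; it must
#'   contain every species present in the state.
#' @return The updated state (counts may be fractional).
#' @export
advance_ode <- function(state, duration, L_max = 16L, rtol = 1e-8,
                        atol = 1e-12, boundary_tol = 1e-3, network = NULL) {
  counts <- state$counts[state$counts > 0]
  if (!length(counts) || duration == 0) {
    state$time <- state$time + duration
    return(state)
  }
  if (is.null(network)) {
    network <- build_ode_network(names(counts), state$rates, state$options,
                                 L_max = L_max)
  } else {
    missing <- setdiff(names(counts), network$species)
    if (length(missing))
      stop("precomputed network lacks species: ", paste(missing, collapse = ", "))
  }
  spp <- network$species
  y0 <- stats::setNames(numeric(length(spp)), spp)
  y0[names(counts)] <- counts / (state$volume * AVOGADRO) # copies -> M
  if (!nrow(network$reactions)) {
    state$time <- state$time + duration
    return(state)
  }
  i_idx <- network$i; j_idx <- network$j; S <- network$S; kvec <- network$k
  derivs <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- kvec * y[i_idx] * y[j_idx]
    list(as.vector(S %*% v))
  }
  sol <- deSolve::lsoda(y = y0, times = c(0, duration), func = derivs,
                        parms = NULL, rtol = rtol, atol = atol)
  yT <- pmax(sol[nrow(sol), -1], 0)
  counts_T <- yT * state$volume * AVOGADRO
  # truncation diagnostic: token mass near the boundary
  sizes <- network$sizes
  tok_mass <- sizes * counts_T
  if (sum(tok_mass) > 0) {
    frac <- sum(tok_mass[sizes >= network$L_max - 1L]) / sum(tok_mass)
    if (frac > boundary_tol)
      stop(sprintf(paste0("ODE truncation overflow: %.2g of monomer mass in ",
                          "complexes of >= %d monomers (tolerance %.2g); ",
                          "raise L_max"), frac, network$L_max - 1L, boundary_tol))
  }
  keep <- counts_T > atol * state$volume * AVOGADRO
  state$counts <- stats::setNames(counts_T[keep], spp[keep])
  state$time <- state$time + duration
  state
}
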
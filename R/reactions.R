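## Reaction enumeration (just-in-time) and bookkeeping.

RULE_LABELS <- c(
  "1" = "R1", "2" = "R2", "3" = "R3", "32" = "R3-cap", "33" = "R3-free",
  "4" = "R4", "43" = "R4-free", "51" = "R5-nucleate", "52" = "R5-release",
  "53" = "R5-cap"
)

#' Enumerate all reactions applicable to a species multiset
#'
#' Instantiates the rule set by pattern matching on exposed sites, once per
#' distinct ordered (target, attacker) pair of currently present species:
#' elongation by push at an alpha-open end (R1, rate `k_A`), elongation by
#' signal at a beta-open end (R2, rate `k_BC`), read displacement of a
#' terminal signal (R3, `k_A`), pop displacement of a terminal push (R4,
#' `k_BC`), and nucleation/release on the bead linker (R5, `k_A`).
#' Polymer-polymer joins are included whenever one partner's head matches the
#' other's exposed end. Degenerate instances (read capping a bare start, read
#' or pop hybridising free signal/push monomers) are controlled by
#' [rule_options()].
#'
#' @param species Character vector of species keys (or list of token
#'   vectors) present in the system.
#' @param rates Rate constants from [rate_constants()].
#' @param options Rule switches from [rule_options()].
#' @return A data frame with one row per concrete reaction: columns
#'   `reactant1`, `reactant2`, `product1`, `product2` (`NA` if single
#'   product), `rate` (M^-1 s^-1) and `rule`.
#' @export
#' @examples
#' enumerate_reactions(c("k", "s"))  # single nucleation reaction
enumerate_reactions <- function(species, rates = rate_constants(),
                                options = rule_options()) {
  keys <- vapply(species, function(s) species_key(as_species_tokens(s)), "")
  if (anyDuplicated(keys)) stop("duplicate species in multiset")
  tok_lists <- lapply(keys, key_tokens)
  ok <- vapply(tok_lists, valid_species_tokens, TRUE)
  if (any(!ok))
    stop("unknown or invalid species: ", paste(keys[!ok], collapse = ", "))
  ids <- lapply(tok_lists, tokens_to_ids)
  res <- ssa_enumerate_cpp(ids, rates$k_A, rates$k_BC, options)
  n <- length(res$rate)
  key_of <- function(iv) if (is.null(iv)) NA_character_ else
    species_key(ids_to_tokens(iv))
  data.frame(
    reactant1 = vapply(res$reactant1, key_of, ""),
    reactant2 = vapply(res$reactant2, key_of, ""),
    product1 = vapply(res$product1, key_of, ""),
    product2 = vapply(res$product2, key_of, NA_character_),
    rate = res$rate,
    rule = unname(RULE_LABELS[as.character(res$rule)]),
    stringsAsFactors = FALSE
  )
}

#' Apply one reaction to a species count table
#'
#' Decrements reactant counts and increments product counts; monomer tokens
#' are conserved and tether flags propagate through the species keys
#' themselves.
#'
#' @param counts Named numeric vector of species counts (names are species
#'   keys).
#' @param reaction One row of the data frame returned by
#'   [enumerate_reactions()] (or a list with the same fields).
#' @return The updated named count vector (zero-count entries retained).
#' @export
apply_reaction <- function(counts, reaction) {
  reactants <- c(reaction$reactant1, reaction$reactant2)
  reactants <- reactants[!is.na(reactants)]
  products <- c(reaction$product1, reaction$product2)
  products <- products[!is.na(products)]
  for (sp in unique(reactants)) {
    need <- sum(reactants == sp)
    have <- if (sp %in% names(counts)) counts[[sp]] else 0
    if (have < need)
      stop("insufficient reactants: need ", need, " of ", sp, ", have ", have)
  }
  for (sp in reactants) counts[[sp]] <- counts[[sp]] - 1
  for (sp in products) {
    counts[[sp]] <- (if (sp %in% names(counts)) counts[[sp]] else 0) + 1
  }
  counts
}

# multiset of monomer tokens over a count table (for conservation checks)
token_census <- function(counts) {
  if (!length(counts)) return(integer(0))
  toks <- unlist(mapply(function(k, n) rep(key_tokens(k), n),
                        names(counts), counts, SIMPLIFY = FALSE))
  table(factor(toks, levels = TOKENS))
}
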
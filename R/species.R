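## Polymer species: grammar, canonical identity, exposed sites, size.

# Species are identified by their token sequence joined with "." (fixed 5'->3'
# orientation along the assembly axis), e.g. "k.s.p.X". A species is tethered
# to a bead iff its first token is the linker k. Inert duplexes and caps are
# sequences ending in r, q or z ("X.r", "p.q", "k.z", "s.r", "k.s.r").

species_key <- function(tokens) paste(tokens, collapse = ".")

key_tokens <- function(key) strsplit(key, ".", fixed = TRUE)[[1]]

#' Construct a canonical polymer species from monomer tokens
#'
#' Validates the complex grammar: an optional leading linker `k`, then `s`,
#' then alternating (`p`, signal) pairs with an optional trailing `p`.
#' Solution-phase complexes obey the same strict p/signal alternation without
#' requiring `s` (e.g. `p.w`, `w.p`, `p.w.p`). Inert duplexes (`X.r`, `Y.r`,
#' `w.r`, `p.q`, `k.z`, `s.r`) and read-capped stacks (`k.s.r`) are the only
#' sequences containing `r`, `q` or `z`.
#'
#' @param tokens Character vector of monomer tokens, in order.
#' @param tethered Optional logical; if supplied it must agree with the
#'   presence of a leading `k` (tethering is implied by the linker).
#' @return The canonical species key (a string) with class `stack_species`.
#' @export
#' @examples
#' species_from_tokens(c("k", "s", "p", "X"))
#' species_from_tokens(c("p", "w", "p"))
species_from_tokens <- function(tokens, tethered = NULL) {
  if (!length(tokens)) stop("invalid species: empty token list")
  tokens_to_ids(tokens) # rejects unknown tokens
  if (!valid_species_tokens(tokens))
    stop("invalid species: [", paste(tokens, collapse = ","),
         "] violates the complex grammar")
  if (!is.null(tethered) && isTRUE(tethered) != (tokens[1] == "k"))
    stop("tethered flag inconsistent with token sequence (tethered iff ",
         "the complex starts with linker k)")
  structure(species_key(tokens), class = "stack_species")
}

# grammar check on a token character vector
valid_species_tokens <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(tokens %in% TOKENS) # every free monomer is a species
  is_sig <- tokens %in% SIGNAL_TOKENS
  # positional constraints
  if (any(tokens[-1] == "k")) return(FALSE)
  if (any(which(tokens == "s") > if (tokens[1] == "k") 2L else 1L)) return(FALSE)
  if (tokens[1] == "k" && n > 1L && !(tokens[2] %in% c("s", "z"))) return(FALSE)
  # r: only terminal, after s, or after a leading signal (2-token duplex)
  rpos <- which(tokens == "r")
  if (length(rpos)) {
    if (length(rpos) > 1L || rpos != n || n < 2L) return(FALSE)
    prev <- tokens[n - 1L]
    if (!(prev == "s" || (is_sig[n - 1L] && n == 2L))) return(FALSE)
  }
  # q: only the p.q duplex; z: only the k.z duplex
  if (any(tokens == "q") && !identical(tokens, c("p", "q"))) return(FALSE)
  if (any(tokens == "z") && !identical(tokens, c("k", "z"))) return(FALSE)
  # successor relation over the remaining chain
  for (i in seq_len(n - 1L)) {
    a <- tokens[i]; b <- tokens[i + 1L]
    ok <- switch(a,
      k = b %in% c("s", "z"),
      s = b %in% c("p", "r"),
      p = b %in% SIGNAL_TOKENS || b == "q",
      r = FALSE, q = FALSE, z = FALSE,
      # signals
      b %in% c("p", "r")
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

as_species_tokens <- function(species) {
  if (inherits(species, "stack_species") || is.character(species) && length(species) == 1L)
    key_tokens(unclass(species))
  else as.character(species)
}

#' Is a species tethered to a bead?
#' @param species A species key or token vector.
#' @return Logical.
#' @export
is_tethered <- function(species) {
  as_species_tokens(species)[1] == "k"
}

#' Is a species inert?
#'
#' Inert species (blunt duplexes and capped complexes) expose no reactive
#' site and take part in no further reaction.
#' @param species A species key or token vector.
#' @return Logical.
#' @export
is_inert <- function(species) {
  toks <- as_species_tokens(species)
  toks[length(toks)] %in% c("r", "q", "z")
}

#' Exposed single-stranded interfaces of a complex
#'
#' Reports the reactive site at the growing (3') end of a complex and, for
#' solution-phase complexes, the site its head attaches to when it joins
#' another complex. End sites are `alpha_open` (exposed 28 nt A-type domain:
#' a bare start or a terminal signal), `beta_open` (exposed 28 nt BC
#' overhang: a terminal push), `linker_open` (an unused bead linker) or
#' `none` (inert).
#'
#' @param species A species key (from [species_from_tokens()]) or a token
#'   vector.
#' @return A list with elements `tail` (site exposed at the growing end) and
#'   `head_binds` (site the head would attach to; `none` for tethered or
#'   inert species).
#' @export
#' @examples
#' exposed_sites(species_from_tokens(c("k", "s", "p")))$tail   # beta_open
#' exposed_sites(species_from_tokens(c("k", "s", "p", "X")))$tail # alpha_open
#' exposed_sites(species_from_tokens(c("X", "r")))$tail        # none
exposed_sites <- function(species) {
  toks <- as_species_tokens(species)
  if (!valid_species_tokens(toks))
    stop("invalid species: [", paste(toks, collapse = ","), "]")
  n <- length(toks)
  last <- toks[n]
  tail <- if (last %in% c("r", "q", "z")) "none"
    else if (n == 1L && last == "k") "linker_open"
    else if (last == "s" || last %in% SIGNAL_TOKENS) "alpha_open"
    else if (last == "p") "beta_open"
    else "none"
  first <- toks[1]
  head_binds <- if (last %in% c("r", "q", "z")) "none" # fully duplexed
    else if (first == "k") "none"
    else if (first == "p") "alpha_open"
    else if (first %in% SIGNAL_TOKENS) "beta_open"
    else if (first == "s") "linker_open"
    else "none"
  list(tail = tail, head_binds = head_binds)
}

#' Total nucleotide content of a complex
#'
#' Sum of monomer lengths over the token sequence; both backbones of the
#' nicked duplex count, which is the quantity gel migration is proportional
#' to.
#'
#' @param species A species key or token vector.
#' @param monomers A monomer table from [define_monomers()].
#' @return Integer number of nucleotides.
#' @export
#' @examples
#' total_nucleotides(c("s", "p", "w")) # 168 with default lengths
total_nucleotides <- function(species, monomers = default_monomers()) {
  toks <- as_species_tokens(species)
  if (!length(toks) || identical(toks, character(0))) return(0L)
  lens <- monomers$length_nt[match(toks, monomers$token)]
  if (anyNA(lens)) stop("unknown token(s) in species")
  as.integer(sum(lens))
}

#' @export
print.stack_species <- function(x, ...) {
  toks <- key_tokens(unclass(x))
  cat("<species> ", unclass(x),
      if (toks[1] == "k") "  [tethered]" else "  [solution]",
      if (is_inert(toks)) " [inert]" else "", "\n", sep = "")
  invisible(x)
}
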
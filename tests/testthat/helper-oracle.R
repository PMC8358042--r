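# Independent oracles used across the suite. These re-derive expected
# behaviour from first principles (brute force / closed form) and must not
# call into the package's enumeration or simulation internals.

SIGS <- c("X", "Y", "w")

# Brute-force reaction enumeration: test every ordered (target, attacker)
# pair of species against each abstract rule, written directly from the rule
# statements.
oracle_reactions <- function(keys) {
  toks <- strsplit(keys, ".", fixed = TRUE)
  rows <- list()
  add <- function(r1, r2, p1, p2, rate) {
    rows[[length(rows) + 1L]] <<- data.frame(
      reactant1 = r1, reactant2 = r2, product1 = p1,
      product2 = if (is.null(p2)) NA_character_ else p2,
      rate = rate, stringsAsFactors = FALSE)
  }
  jn <- function(v) paste(v, collapse = ".")
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    A <- toks[[i]]; B <- toks[[j]] # A = target, B = attacker
    if (B[1] == "k") next                       # attacker must be in solution
    a_last <- A[length(A)]
    a_inert <- a_last %in% c("r", "q", "z")
    b_inert <- B[length(B)] %in% c("r", "q", "z")
    # join rules R1/R2/R5-nucleation: head of B matches exposed end of A
    if (!a_inert && !b_inert) {
      tail_site <- if (length(A) == 1L && a_last == "k") "L"
        else if (a_last %in% c("s", SIGS)) "A"
        else if (a_last == "p") "B" else NA
      head_site <- if (B[1] == "p") "A"
        else if (B[1] %in% SIGS) "B"
        else if (B[1] == "s") "L" else NA
      if (!is.na(tail_site) && !is.na(head_site) && tail_site == head_site)
        add(keys[i], keys[j], jn(c(A, B)), NULL,
            if (tail_site == "B") 3e4 else 3e4)
    }
    if (length(B) == 1L) {
      if (B == "r" && !a_inert) {
        if (a_last %in% SIGS) { # R3: read removes the terminal signal
          if (length(A) == 1L) add(keys[i], keys[j], paste0(a_last, ".r"), NULL, 3e4)
          else add(keys[i], keys[j], jn(A[-length(A)]), paste0(a_last, ".r"), 3e4)
        } else if (a_last == "s") { # degenerate: cap a bare start
          add(keys[i], keys[j], jn(c(A, "r")), NULL, 3e4)
        }
      }
      if (B == "q" && !a_inert && a_last == "p") { # R4: pop removes push
        if (length(A) == 1L) add(keys[i], keys[j], "p.q", NULL, 3e4)
        else add(keys[i], keys[j], jn(A[-length(A)]), "p.q", 3e4)
      }
      if (B == "z" && A[1] == "k") { # R5: release / cap linker
        if (length(A) == 1L) add(keys[i], keys[j], "k.z", NULL, 3e4)
        else if (A[2] == "s") add(keys[i], keys[j], "k.z", jn(A[-1]), 3e4)
      }
    }
  }
  if (!length(rows))
    return(data.frame(reactant1 = character(), reactant2 = character(),
                      product1 = character(), product2 = character(),
                      rate = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# canonical comparable form of a reaction table
reaction_keyset <- function(df) {
  if (!nrow(df)) return(character(0))
  prods <- mapply(function(a, b) paste(sort(c(a, if (!is.na(b)) b)), collapse = "+"),
                  df$product1, df$product2)
  sort(paste(df$reactant1, df$reactant2, prods, sep = " | "))
}

# a pool of valid species to draw random states from
species_pool <- function() {
  c("s", "p", "X", "Y", "w", "r", "q", "k", "z",
    "k.s", "k.s.p", "k.s.p.X", "k.s.p.w", "k.s.p.Y.p", "k.s.p.X.p.Y",
    "s.p", "s.p.w", "p.w", "w.p", "p.w.p", "w.p.w", "p.X", "X.p.Y",
    "X.r", "Y.r", "w.r", "p.q", "k.z", "s.r", "k.s.r")
}

# textbook LIFO stack used to verify the ideal-operation oracle
textbook_pops <- function(ops) {
  stack <- list()
  out <- character(0)
  for (op in ops) {
    if (op == "pop") {
      out <- c(out, stack[[length(stack)]])
      stack[[length(stack)]] <- NULL
    } else {
      stack[[length(stack) + 1L]] <- op
    }
  }
  out
}

# closed-form irreversible bimolecular kinetics, equal initial
# concentrations: [C](t) = c0 * k c0 t / (1 + k c0 t)
bimolecular_product <- function(c0, k, t) c0 * (k * c0 * t) / (1 + k * c0 * t)
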
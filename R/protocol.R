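## Stack-level operation sequences and their compilation to staged protocols.

# run a function with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# deterministic substream seeds below 2^31 from one master seed
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 2654435) %% 2147483587) + 1L
}

#' Operation sequences over {record X, record Y, record w, pop}
#'
#' An operation sequence is a character vector whose elements are a signal
#' token (`"X"`, `"Y"`, `"w"`) for a record operation or `"pop"` for a pop.
#' A sequence is valid for ideal operation iff no prefix contains more pops
#' than records.
#'
#' @param ops Character vector of operations.
#' @param name Optional label.
#' @return An object of class `op_sequence`.
#' @export
#' @examples
#' op_sequence(c("X", "Y", "pop", "pop"))
op_sequence <- function(ops, name = NULL) {
  bad <- setdiff(ops, c(SIGNAL_TOKENS, "pop"))
  if (length(bad)) stop("invalid operation(s): ", paste(bad, collapse = ", "))
  depth <- cumsum(ifelse(ops == "pop", -1L, 1L))
  if (any(depth < 0))
    stop("invalid operation sequence: a prefix has more pops than records")
  structure(as.character(ops), class = "op_sequence",
            name = if (is.null(name)) "ops" else name)
}

#' Parse an operation sequence from token text
#'
#' Records are written as their signal letter and pops as `q`
#' (e.g. `"X Y q q"`).
#'
#' @param text A whitespace-separated token string.
#' @param name Optional label.
#' @return An `op_sequence`.
#' @export
parse_ops <- function(text, name = NULL) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[toks == "q"] <- "pop"
  op_sequence(toks, name = if (is.null(name)) text else name)
}

#' @export
format.op_sequence <- function(x, ...) {
  paste(ifelse(unclass(x) == "pop", "q", unclass(x)), collapse = " ")
}

#' @export
print.op_sequence <- function(x, ...) {
  cat("<op_sequence> ", attr(x, "name"), ": ", format(x), "\n", sep = "")
  invisible(x)
}

# balanced X/Y labels for n record slots, |#X - #Y| <= 1, seeded shuffle
balanced_labels <- function(n) {
  lab <- rep(c("X", "Y"), length.out = n + n %% 2)[seq_len(n)]
  sample(lab)
}

#' Periodic benchmark sequences seqN
#'
#' `seqN` consists of periodic blocks of `N` records followed by `N` pops,
#' repeated until 20 records and 20 pops have been issued. X/Y signal labels
#' are assigned by a seeded shuffle with `|#X - #Y| <= 1` overall.
#'
#' @param N Block size; must divide 20.
#' @param seed Seed for the label shuffle (`NULL` = current RNG state).
#' @return An `op_sequence` named `seqN`.
#' @export
#' @examples
#' make_seqN(5, seed = 1)
make_seqN <- function(N, seed = NULL) {
  if (!N %in% c(1L, 2L, 4L, 5L, 10L, 20L))
    stop("N must divide 20 (one of 1, 2, 4, 5, 10, 20)")
  labels <- with_seed(seed, balanced_labels(20L))
  ops <- character(0)
  used <- 0L
  for (b in seq_len(20L / N)) {
    ops <- c(ops, labels[used + seq_len(N)], rep("pop", N))
    used <- used + N
  }
  op_sequence(ops, name = paste0("seq", N))
}

#' Random benchmark sequence seqR
#'
#' Arranges 20 record and 20 pop operations uniformly at random,
#' rejection-sampled until every prefix has at least as many records as pops;
#' X/Y labels are balanced as in [make_seqN()].
#'
#' @param seed Seed (`NULL` = current RNG state).
#' @return An `op_sequence` named `seqR`.
#' @export
make_seqR <- function(seed = NULL) {
  ops <- with_seed(seed, {
    repeat {
      kind <- sample(rep(c("rec", "pop"), each = 20L))
      depth <- cumsum(ifelse(kind == "pop", -1L, 1L))
      if (all(depth >= 0)) break
    }
    labels <- balanced_labels(20L)
    out <- kind
    out[kind == "rec"] <- labels
    out
  })
  op_sequence(ops, name = "seqR")
}

#' Expected pop outputs under ideal stack semantics
#'
#' Replays the operation sequence against an ideal last-in first-out stack
#' and returns, for each pop, the signal token it should emit.
#'
#' @param opseq An `op_sequence`.
#' @return Character vector, one signal token per pop operation.
#' @export
#' @examples
#' ideal_pops(op_sequence(c("X", "Y", "pop", "pop")))  # "Y" "X"
ideal_pops <- function(opseq) {
  stack <- character(0)
  out <- character(0)
  for (op in unclass(opseq)) {
    if (op == "pop") {
      out <- c(out, stack[length(stack)])
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, op)
    }
  }
  out
}

#' Compile an operation sequence to chemistry-level stages
#'
#' Each record of signal `sigma` becomes a push stage followed by a `sigma`
#' stage; each pop becomes a read stage (with a supernatant readout taken
#' before its wash) followed by a pop-strand stage. A single start stage is
#' prepended (the linker is assumed pre-bound by [init_state()]). Every
#' stage uses the standard concentration and wait and is followed by a wash.
#'
#' @param opseq An `op_sequence`.
#' @param gamma Standard strand concentration in M (default 300 nM).
#' @param t_wait Reaction wait per stage in seconds (default 30 min).
#' @param read_conc Concentration of the read strand in M (defaults to
#'   `gamma`; the optimised experimental protocol used 50 nM).
#' @return A data frame of stages (columns `token`, `conc`, `wait`,
#'   `wash_after`, `readout`) with attributes `expected_pops` (from
#'   [ideal_pops()]) and `opseq`.
#' @export
#' @examples
#' nrow(compile_operations(make_seqN(5, seed = 1)))  # 81 stages
compile_operations <- function(opseq, gamma = 300e-9, t_wait = 1800,
                               read_conc = gamma) {
  if (!inherits(opseq, "op_sequence")) opseq <- op_sequence(opseq)
  if (gamma < 0 || t_wait < 0 || read_conc < 0)
    stop("concentrations and wait times must be non-negative")
  tok <- "s"; conc <- gamma; readout <- FALSE
  for (op in unclass(opseq)) {
    if (op == "pop") {
      tok <- c(tok, "r", "q")
      conc <- c(conc, read_conc, gamma)
      readout <- c(readout, TRUE, FALSE)
    } else {
      tok <- c(tok, "p", op)
      conc <- c(conc, gamma, gamma)
      readout <- c(readout, FALSE, FALSE)
    }
  }
  stages <- data.frame(token = tok, conc = conc, wait = t_wait,
                       wash_after = TRUE, readout = readout,
                       stringsAsFactors = FALSE)
  attr(stages, "expected_pops") <- ideal_pops(opseq)
  attr(stages, "opseq") <- opseq
  stages
}
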
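## Observables: pop-limit statistic, gel band-pattern prediction and the
## band-ordering error used for washing calibration.

#' Pop limit of a run
#'
#' The consecutive number of correct pop operations before the popped
#' signals become indistinguishable. For two-signal runs a pop is correct
#' iff the supernatant read-duplex concentrations satisfy
#' `|[Xr] - [Yr]| >= threshold` (10 nM by default; below that the signals
#' are indistinguishable) and the majority duplex matches the signal an
#' ideal stack would have emitted. For single-signal (`w`-only) runs, where
#' only `wr` exists, a pop is correct iff `[wr] >= threshold`. Scanning
#' stops at the first failure.
#'
#' @param x A `stack_run` from [run_protocol()], or a readout data frame
#'   with columns `expected`, `Xr_nM`, `Yr_nM`, `wr_nM` in operation order.
#' @param threshold Indistinguishability threshold in nM.
#' @return Integer count of correct pops before the first failure.
#' @export
#' @examples
#' r <- data.frame(expected = c("X", "Y"), Xr_nM = c(120, 8),
#'                 Yr_nM = c(5, 9), wr_nM = 0)
#' pop_limit(r)  # 1
pop_limit <- function(x, threshold = 10) {
  readouts <- if (inherits(x, "stack_run")) x$readouts else x
  if (is.null(readouts) || !nrow(readouts)) return(0L)
  limit <- 0L
  for (i in seq_len(nrow(readouts))) {
    expected <- readouts$expected[i]
    ok <- if (!is.na(expected) && expected == "w") {
      readouts$wr_nM[i] >= threshold
    } else {
      xr <- readouts$Xr_nM[i]; yr <- readouts$Yr_nM[i]
      majority <- if (xr >= yr) "X" else "Y"
      abs(xr - yr) >= threshold && !is.na(expected) && majority == expected
    }
    if (!ok) break
    limit <- limit + 1L
  }
  limit
}

#' Predicted gel band pattern of a compartment
#'
#' Species are binned by total nucleotide content (gel migration is linearly
#' proportional to nucleotides for the nicked-duplex polymers) and each
#' bin's intensity is the stain-proportional, nucleotide-weighted
#' concentration `sum(conc_nM * nt)`. Bins below the detection threshold are
#' dropped and bands are returned in descending intensity order.
#'
#' @param state A `stack_state` (or a `stack_run`, whose final state is
#'   used).
#' @param compartment `"tethered"`, `"supernatant"` or `"all"`.
#' @param monomers Monomer table used for nucleotide lengths.
#' @param threshold Detection threshold on intensity in nM x nt (default
#'   1000, i.e. 1 nM of a 1 kb band).
#' @return A data frame of class `band_pattern` with columns `size_nt`,
#'   `intensity` and `rank`, ordered by decreasing intensity.
#' @export
band_pattern <- function(state, compartment = c("tethered", "supernatant", "all"),
                         monomers = NULL, threshold = 1000) {
  compartment <- match.arg(compartment)
  if (inherits(state, "stack_run")) state <- state$state
  if (is.null(monomers)) monomers <- state$monomers
  counts <- state$counts[state$counts > 0]
  empty <- data.frame(size_nt = integer(), intensity = numeric(),
                      rank = integer())
  if (!length(counts)) return(structure(empty, class = c("band_pattern", "data.frame")))
  teth <- vapply(names(counts), function(k) key_tokens(k)[1] == "k", TRUE)
  keep <- switch(compartment, tethered = teth, supernatant = !teth,
                 all = rep(TRUE, length(counts)))
  counts <- counts[keep]
  if (!length(counts)) return(structure(empty, class = c("band_pattern", "data.frame")))
  nt <- vapply(names(counts), total_nucleotides, 0L, monomers = monomers)
  conc <- copies_to_nM(counts, state$volume)
  agg <- tapply(conc * nt, nt, sum)
  out <- data.frame(size_nt = as.integer(names(agg)),
                    intensity = as.numeric(agg))
  out <- out[out$intensity >= threshold, , drop = FALSE]
  out <- out[order(-out$intensity, out$size_nt), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("band_pattern", "data.frame"))
}

#' @export
print.band_pattern <- function(x, ...) {
  cat("<band_pattern> ", nrow(x), " band(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Rank-order disagreement between two band patterns
#'
#' Normalised pairwise rank disagreement (Kendall-type) between the
#' predicted and observed intensity orderings, computed over the union of
#' band sizes. A pair of bands disagrees if their relative order differs; a
#' pair involving a band absent from one of the two patterns counts as
#' maximal disagreement. The result is the disagreeing fraction of all
#' pairs: 0 for identical orderings, 1 for a fully reversed ordering of the
#' same bands.
#'
#' @param predicted A `band_pattern`, or a vector of band sizes ranked by
#'   decreasing intensity.
#' @param observed A ranked vector of band sizes (nt), most intense first,
#'   or a `band_pattern`.
#' @return Error in \[0, 1\].
#' @export
#' @examples
#' band_order_error(c(100, 200, 300), c(100, 200, 300))  # 0
#' band_order_error(c(100, 200), c(100, 200, 300))       # 2/3
band_order_error <- function(predicted, observed) {
  rank_of <- function(x) {
    if (inherits(x, "band_pattern") || is.data.frame(x)) x <- x$size_nt
    x <- as.numeric(x)
    if (anyDuplicated(x)) stop("band sizes within one pattern must be unique")
    stats::setNames(seq_along(x), x)
  }
  pr <- rank_of(predicted)
  ob <- rank_of(observed)
  if (!length(ob)) stop("observed band list is empty")
  all_sizes <- union(names(pr), names(ob))
  m <- length(all_sizes)
  if (m < 2L) return(if (setequal(names(pr), names(ob))) 0 else 1)
  npairs <- m * (m - 1) / 2
  bad <- 0
  for (a in seq_len(m - 1L)) for (b in seq((a + 1L), m)) {
    sa <- all_sizes[a]; sb <- all_sizes[b]
    in_pr <- sa %in% names(pr) && sb %in% names(pr)
    in_ob <- sa %in% names(ob) && sb %in% names(ob)
    if (!in_pr || !in_ob) {
      bad <- bad + 1
    } else if (sign(pr[sa] - pr[sb]) != sign(ob[sa] - ob[sb])) {
      bad <- bad + 1
    }
  }
  bad / npairs
}

#' Total signals retrieved in a run
#'
#' Counts every pop whose readout is correct (same criterion as
#' [pop_limit()]), without requiring the correct pops to be consecutive.
#' This is the "signals retrievable" measure: a run may fail one pop in the
#' middle and still recover later signals.
#'
#' @inheritParams pop_limit
#' @return Integer count of correct pops over the whole run.
#' @export
signals_retrieved <- function(x, threshold = 10) {
  readouts <- if (inherits(x, "stack_run")) x$readouts else x
  if (is.null(readouts) || !nrow(readouts)) return(0L)
  ok <- vapply(seq_len(nrow(readouts)), function(i) {
    expected <- readouts$expected[i]
    if (!is.na(expected) && expected == "w") {
      readouts$wr_nM[i] >= threshold
    } else {
      xr <- readouts$Xr_nM[i]; yr <- readouts$Yr_nM[i]
      majority <- if (xr >= yr) "X" else "Y"
      abs(xr - yr) >= threshold && !is.na(expected) && majority == expected
    }
  }, TRUE)
  sum(ok)
}

#' Pipetting-noise degradation onset
#'
#' Scans a noise sweep (see [sweep_noise()]) for the smallest noise
#' half-width at which the mean pop limit drops significantly below the
#' noise-free mean (one-sided Welch t-test), and reports the corresponding
#' instantaneous concentration floor `gamma - eta_onset`. If no tested
#' noise level degrades performance the onset is `NA` and the floor is
#' reported as the lowest floor shown not to degrade.
#'
#' @param sweep A `stack_sweep` from [sweep_noise()].
#' @param gamma_nM Nominal concentration in nM (default 300).
#' @param alpha Significance level for the one-sided test.
#' @return A list with `eta_onset_nM` (possibly `NA`), `floor_nM`, `flat`
#'   (logical: no degradation found on the grid) and the per-eta summary
#'   table.
#' @export
noise_onset <- function(sweep, gamma_nM = 300, alpha = 0.05) {
  etas <- sort(unique(sweep$eta_nM))
  if (length(etas) < 2L || etas[1] != 0)
    stop("sweep must contain eta = 0 and at least one positive eta")
  base <- sweep$pop_limit[sweep$eta_nM == 0]
  tab <- summary(sweep)
  onset <- NA_real_
  for (e in etas[-1]) {
    x <- sweep$pop_limit[sweep$eta_nM == e]
    p <- if (stats::sd(x) == 0 && stats::sd(base) == 0) {
      if (mean(x) < mean(base)) 0 else 1
    } else {
      stats::t.test(x, base, alternative = "less")$p.value
    }
    if (is.finite(p) && p < alpha) { onset <- e; break }
  }
  flat <- is.na(onset)
  floor_nM <- if (flat) gamma_nM - max(etas) else gamma_nM - onset
  list(eta_onset_nM = onset, floor_nM = floor_nM, flat = flat, summary = tab)
}
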
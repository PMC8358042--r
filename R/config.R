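## Configuration loading, validation and result serialisation.

config_defaults <- function() {
  list(
    wash = "W1",
    volume_pl = 0.15,
    gamma_nM = 300,
    t_wait_min = 30,
    read_nM = NULL, # defaults to gamma
    linker_nM = 200,
    k_A = 3e4,
    k_BC = 3e4,
    backend = "ssa",
    eta_nM = 0,
    seed = 0,
    ops = NULL,      # inline token string, e.g. "X Y q q"
    sequence = NULL, # generator name: "seq1","seq5","seq10","seq20","seqR"
    monomers = NULL  # named lengths, optional
  )
}

#' Load and resolve a run configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration, fills in
#' the standard defaults (300 nM strands, 30 min waits, 0.15 pl volume,
#' k_A = k_BC = 3e4 /M/s, 200 nM linker, washing preset W1, seed 0) and
#' validates every field, naming the offending key on failure.
#'
#' @param path Path to the configuration file, or a list with the same
#'   fields (useful programmatically).
#' @return A fully resolved configuration of class `run_config`, with
#'   derived elements `wash_params`, `rates`, `monomer_table`, `opseq` (if
#'   `ops`/`sequence` given) and SI-unit values under `si`.
#' @export
#' @examples
#' cfg <- load_config(list(wash = "W1"))
#' cfg$wash_params
load_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else
      yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, raw, keep.null = TRUE)

  num_ok <- function(key, lo = 0, hi = Inf, strict_lo = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < lo || v > hi || (strict_lo && v <= lo))
      stop("invalid config value for '", key, "'")
    v
  }
  num_ok("volume_pl", strict_lo = TRUE)
  num_ok("gamma_nM")
  num_ok("t_wait_min")
  num_ok("linker_nM")
  num_ok("eta_nM")
  num_ok("k_A", strict_lo = TRUE)
  num_ok("k_BC", strict_lo = TRUE)
  num_ok("seed", lo = -.Machine$integer.max, hi = .Machine$integer.max)
  if (is.null(cfg$read_nM)) cfg$read_nM <- cfg$gamma_nM else num_ok("read_nM")
  if (!cfg$backend %in% c("ssa", "ode"))
    stop("invalid config value for 'backend' (use \"ssa\" or \"ode\")")

  cfg$wash_params <- if (is.character(cfg$wash)) {
    wash_params(cfg$wash)
  } else {
    if (!is.list(cfg$wash) || is.null(cfg$wash$mu) || is.null(cfg$wash$phi0))
      stop("invalid config value for 'wash' (preset name or {mu, phi0})")
    tryCatch(wash_params(cfg$wash$mu, cfg$wash$phi0),
             error = function(e) stop("invalid config value for 'wash': ",
                                      conditionMessage(e)))
  }
  cfg$rates <- rate_constants(cfg$k_A, cfg$k_BC)
  cfg$monomer_table <- define_monomers(cfg$monomers)
  cfg$opseq <- if (!is.null(cfg$ops)) {
    parse_ops(cfg$ops)
  } else if (!is.null(cfg$sequence)) {
    if (identical(cfg$sequence, "seqR")) make_seqR(seed = cfg$seed)
    else if (grepl("^seq[0-9]+$", cfg$sequence))
      make_seqN(as.integer(sub("seq", "", cfg$sequence)), seed = cfg$seed)
    else stop("invalid config value for 'sequence'")
  } else NULL
  cfg$si <- list(volume = cfg$volume_pl * 1e-12, gamma = cfg$gamma_nM * 1e-9,
                 t_wait = cfg$t_wait_min * 60, read = cfg$read_nM * 1e-9,
                 linker = cfg$linker_nM * 1e-9, eta = cfg$eta_nM * 1e-9)
  structure(cfg, class = "run_config")
}

resolved_params <- function(cfg) {
  list(wash = cfg$wash_params[c("mu", "phi0")], volume_pl = cfg$volume_pl,
       gamma_nM = cfg$gamma_nM, t_wait_min = cfg$t_wait_min,
       read_nM = cfg$read_nM, linker_nM = cfg$linker_nM, k_A = cfg$k_A,
       k_BC = cfg$k_BC, backend = cfg$backend, eta_nM = cfg$eta_nM,
       seed = cfg$seed,
       ops = if (!is.null(cfg$opseq)) format(cfg$opseq) else NULL)
}

#' Write simulation artefacts to disk
#'
#' Serialises a `stack_run` (per-stage trace CSV, readouts CSV), a
#' `stack_sweep` (long-format CSV) or a `wash_fit` (error-surface CSV),
#' together with a JSON sidecar holding the resolved parameters and seed so
#' a run can be reproduced byte-identically.
#'
#' @param x A `stack_run`, `stack_sweep` or `wash_fit`.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @param meta Optional list of resolved parameters (e.g. from
#'   [load_config()]) for the JSON sidecar.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(x, dir, name = "stack", meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, suffix) {
    p <- file.path(dir, paste0(name, "_", suffix, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(x, "stack_run")) {
    if (!is.null(x$trace)) wr(x$trace, "trace")
    wr(x$readouts, "readouts")
    meta$pop_limit <- pop_limit(x)
  } else if (inherits(x, "stack_sweep")) {
    wr(as.data.frame(x), "sweep")
    meta$plan <- attr(x, "plan")
  } else if (inherits(x, "wash_fit")) {
    wr(x$surface, "fit_surface")
    meta$fit <- list(mu = x$mu, phi0 = x$phi0, error = x$error)
  } else {
    stop("don't know how to serialise objects of class ", class(x)[1])
  }
  mp <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, mp)
  invisible(paths)
}

#' Read and write ranked gel-lane band tables
#'
#' Lane tables are CSVs with columns `lane_id`, `rank`, `apparent_size_nt`;
#' each lane's bands are listed most intense first.
#'
#' @param path CSV path.
#' @param rankings Named list of ranked band-size vectors.
#' @return `read_lanes` returns a named list of ranked size vectors.
#' @export
read_lanes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "rank", "apparent_size_nt")
  if (!all(need %in% names(df)))
    stop("lane table needs columns: ", paste(need, collapse = ", "))
  lanes <- split(df, df$lane_id)
  lapply(lanes, function(d) d$apparent_size_nt[order(d$rank)])
}

#' @rdname read_lanes
#' @export
write_lanes <- function(rankings, path) {
  rows <- lapply(names(rankings), function(id) {
    rk <- rankings[[id]]
    if (!length(rk)) return(NULL)
    data.frame(lane_id = id, rank = seq_along(rk), apparent_size_nt = rk,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(lane_id = character(), rank = integer(),
                     apparent_size_nt = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
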
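config_keys <- c(
  "n", "m", "r", "eta", "mu", "a", "b", "c", "sale_rule", "recovery_target",
  "disease", "r0", "h", "protected_frac", "kappa0", "init", "reps", "seed",
  "max_steps", "eq_tol", "eq_window", "landless_eps", "equity_fraction",
  "record_every"
)

#' Read a simulation configuration file
#'
#' Reads a flat YAML key-value file into a validated [sim_config()],
#' filling unspecified keys with the package defaults (rates 0.5,
#' utilities `c = 3 > b = 2 > a = 1`, complement sale rule). Unknown
#' keys and out-of-range values are rejected with a descriptive error.
#'
#' @param path Path to a YAML file, e.g. `{n: 64, m: 64, r0: 2}`.
#' @return A [sim_config()] object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines("n: 16\nm: 16\nseed: 7", f)
#' read_sim_config(f)
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "latifundia_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  # quote flat keys so YAML 1.1 boolean-like names ("n", "y") survive
  lines <- sub("^([A-Za-z_][A-Za-z0-9_]*)([ \t]*):", '"\\1"\\2:', lines)
  raw <- yaml::yaml.load(paste(lines, collapse = "\n"))
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "latifundia_config_error")
  }
  config_from_list(raw)
}

# build a sim_config from a flat named list (missing keys -> defaults)
config_from_list <- function(raw) {
  gv <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  params <- land_params(
    r = gv("r", 0.5), eta = gv("eta", 0.5), mu = gv("mu", 0.5),
    a = gv("a", 1), b = gv("b", 2), c = gv("c", 3),
    sale_rule = gv("sale_rule", "complement"),
    recovery_target = gv("recovery_target", "forest")
  )
  disease_on <- isTRUE(gv("disease", FALSE)) || !is.null(raw$r0) ||
    !is.null(raw$protected_frac)
  if (isFALSE(raw$disease)) disease_on <- FALSE
  disease <- disease_params(
    r0 = gv("r0", 2), h = gv("h", 1),
    protected_frac = gv("protected_frac", 0),
    kappa0 = raw$kappa0, enabled = disease_on
  )
  m <- gv("m", 64)
  sim_config(
    n = gv("n", 64), m = m, params = params, disease = disease,
    init = gv("init", "random"), reps = gv("reps", 20L),
    seed = gv("seed", 1L), max_steps = gv("max_steps", 1e5),
    eq_tol = gv("eq_tol", 1e-9 * m), eq_window = gv("eq_window", 10L),
    landless_eps = gv("landless_eps", 1e-3),
    equity_fraction = gv("equity_fraction", 0.9),
    record_every = gv("record_every", 0L)
  )
}

#' Write a simulation configuration file
#'
#' Serialises a [sim_config()] to flat YAML so that
#' `read_sim_config(write_sim_config(cfg, path))` round-trips.
#'
#' @param config A [sim_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  d <- config$disease
  flat <- list(
    n = config$n, m = config$m,
    r = p$r, eta = p$eta, mu = p$mu, a = p$a, b = p$b, c = p$c,
    sale_rule = p$sale_rule, recovery_target = p$recovery_target,
    disease = d$enabled, r0 = d$r0, h = d$h,
    protected_frac = d$protected_frac,
    init = config$init, reps = config$reps, seed = config$seed,
    max_steps = config$max_steps, eq_tol = config$eq_tol,
    eq_window = config$eq_window, landless_eps = config$landless_eps,
    equity_fraction = config$equity_fraction,
    record_every = config$record_every
  )
  if (!is.null(d$kappa0)) flat$kappa0 <- d$kappa0
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write simulation or sweep results to CSV
#'
#' For a `latifundia_sim`: writes the one-row summary to
#' `<stem>_summary.csv` and, when a trajectory was recorded,
#' `<stem>_trajectory.csv` (columns `step`, `owner`, `x`, `y`, `z`,
#' `infected`, `utility`). For a `latifundia_sweep`: writes the
#' aggregated per-cell table to `<stem>_cells.csv` and the
#' per-replicate rows to `<stem>_replicates.csv`. Row order is
#' deterministic, so identical seeds give byte-identical files.
#'
#' @param result A `latifundia_sim` or `latifundia_sweep` object.
#' @param stem Output path stem (directories are created).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if (inherits(result, "latifundia_sim")) {
    f <- paste0(stem, "_summary.csv")
    readr::write_csv(glance(result), f)
    written <- f
    if (!is.null(result$trajectory)) {
      f2 <- paste0(stem, "_trajectory.csv")
      readr::write_csv(result$trajectory, f2)
      written <- c(written, f2)
    }
  } else if (inherits(result, "latifundia_sweep")) {
    f <- paste0(stem, "_cells.csv")
    readr::write_csv(as_tibble(result), f)
    f2 <- paste0(stem, "_replicates.csv")
    readr::write_csv(tidy(result), f2)
    written <- c(f, f2)
  } else {
    abort("`result` must be a latifundia_sim or latifundia_sweep.",
          class = "latifundia_config_error")
  }
  invisible(written)
}
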
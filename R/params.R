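#' Land-use and trade parameters
#'
#' Bundles the parameters of the land-use Markov chain and of the
#' pre-capitalist trade rule. Land parcels cycle through three uses:
#' forest (`F`), agriculture (`A`) and post-agricultural / empty land in
#' recovery (`E`). Deforestation moves land F -> A at rate `r` per year,
#' degradation A -> E at rate `eta`, and recovery returns E land at rate
#' `mu` -- by default to forest, or to agriculture when
#' `recovery_target = "agriculture"`.
#'
#' Utilities `a`, `b`, `c` are the per-parcel values of forest,
#' agricultural and empty land: `a` captures ecosystem services, `b` crop
#' revenue net of management costs, and `c` the value attributed to land
#' in recovery (the only land that can be traded). The default ordering
#' `c = 3 > b = 2 > a = 1` is the configuration least prone to
#' spontaneous ownership concentration and is the reference configuration
#' for the disease experiments.
#'
#' @param r Deforestation rate (F to A), probability per year in `[0, 1]`.
#' @param eta Degradation rate (A to E), probability per year in `[0, 1]`.
#' @param mu Recovery rate out of E, probability per year in `[0, 1]`.
#' @param a,b,c Per-parcel utilities of forest, agricultural and empty
#'   land; non-negative.
#' @param sale_rule How sale pressure is computed from owner utilities:
#'   `"complement"` (V = 1 - P, the default), `"mean"` (sell all E land
#'   when below the population mean utility) or `"median"` (below the
#'   population median).
#' @param recovery_target Destination of recovering E land, `"forest"`
#'   (default) or `"agriculture"` (the literal one-way cascade, under
#'   which forest is never regenerated).
#'
#' @return An object of class `land_params` (a named list).
#' @examples
#' land_params()
#' land_params(r = 0.2, eta = 0.4, mu = 0.4)
#' @export
land_params <- function(r = 0.5, eta = 0.5, mu = 0.5,
                        a = 1, b = 2, c = 3,
                        sale_rule = c("complement", "mean", "median"),
                        recovery_target = c("forest", "agriculture")) {
  sale_rule <- match.arg(sale_rule)
  recovery_target <- match.arg(recovery_target)
  for (nm in c("r", "eta", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single rate in [0, 1], got %s.", nm,
                    deparse(v)), class = "latifundia_config_error")
    }
  }
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("utility `%s` must be a single non-negative number.", nm),
            class = "latifundia_config_error")
    }
  }
  structure(
    list(r = r, eta = eta, mu = mu, a = a, b = b, c = c,
         sale_rule = sale_rule, recovery_target = recovery_target),
    class = "land_params"
  )
}

#' @export
print.land_params <- function(x, ...) {
  cat("<land_params>\n")
  cat(sprintf("  rates:      r = %g (F->A), eta = %g (A->E), mu = %g (E->%s)\n",
              x$r, x$eta, x$mu,
              if (x$recovery_target == "forest") "F" else "A"))
  cat(sprintf("  utilities:  a = %g (F), b = %g (A), c = %g (E)\n",
              x$a, x$b, x$c))
  cat(sprintf("  sale rule:  %s\n", x$sale_rule))
  invisible(x)
}

#' Disease parameters
#'
#' Parameters of the frequency-dependent susceptible-infected-susceptible
#' (SIS) process coupled to the land model. Each year the force of
#' infection is `lambda = min(1, R0 * kappa / n)`, with `kappa` the number
#' of owners infected the previous year. Infection lasts one year; owners
#' recover the following year and become exposable again the year after.
#' An infected owner's land utility is multiplied by the discount `h`
#' for that year, shrinking both purchasing power and the incentive to
#' keep land.
#'
#' @param r0 Basic reproductive number, non-negative. `r0 = 1` is the
#'   epidemic regime, `r0 = 2` the endemic regime.
#' @param h Utility discount factor for infected owners in `[0, 1]`;
#'   `h = 0` removes all productivity while sick, `h = 1` makes the
#'   disease economically neutral.
#' @param protected_frac Fraction of owners immune to infection, in
#'   `[0, 1]`. `ceiling(protected_frac * n)` owners are sampled once at
#'   the start of each replicate and stay protected for the whole run.
#' @param kappa0 Initially infected count, or `NULL` (default) to seed at
#'   the deterministic SIS endemic level `max(1, round(n * (1 - 1/r0)))`:
#'   an endemically established disease for `r0 > 1`, a single introduced
#'   case for `r0 <= 1`.
#' @param enabled Logical; `FALSE` gives a disease-free model (the other
#'   fields are ignored).
#'
#' @return An object of class `disease_params`.
#' @examples
#' disease_params(r0 = 2, h = 0, protected_frac = 0.2)
#' disease_params(enabled = FALSE)
#' @export
disease_params <- function(r0 = 2, h = 1, protected_frac = 0,
                           kappa0 = NULL, enabled = TRUE) {
  if (!is.numeric(r0) || length(r0) != 1L || is.na(r0) || r0 < 0) {
    abort("`r0` must be a single non-negative number.",
          class = "latifundia_config_error")
  }
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 || h > 1) {
    abort("`h` must be a single number in [0, 1].",
          class = "latifundia_config_error")
  }
  if (!is.numeric(protected_frac) || length(protected_frac) != 1L ||
      is.na(protected_frac) || protected_frac < 0 || protected_frac > 1) {
    abort("`protected_frac` must be a single number in [0, 1].",
          class = "latifundia_config_error")
  }
  if (!is.null(kappa0) &&
      (!is.numeric(kappa0) || length(kappa0) != 1L || kappa0 < 0)) {
    abort("`kappa0` must be NULL or a single non-negative count.",
          class = "latifundia_config_error")
  }
  structure(
    list(r0 = r0, h = h, protected_frac = protected_frac,
         kappa0 = if (is.null(kappa0)) NULL else as.integer(kappa0),
         enabled = isTRUE(enabled)),
    class = "disease_params"
  )
}

#' @export
print.disease_params <- function(x, ...) {
  cat("<disease_params>\n")
  if (!x$enabled) {
    cat("  disabled\n")
    return(invisible(x))
  }
  cat(sprintf("  R0 = %g, discount h = %g, protected fraction = %g\n",
              x$r0, x$h, x$protected_frac))
  cat(sprintf("  initial infected: %s\n",
              if (is.null(x$kappa0)) "endemic level (max(1, n(1 - 1/R0)))"
              else as.character(x$kappa0)))
  invisible(x)
}

#' Simulation configuration
#'
#' Assembles everything a simulation run needs: the landscape size, the
#' land/trade parameters, the disease parameters, the stopping rule and
#' the outcome classification thresholds.
#'
#' A run iterates yearly steps until the landscape is at a steady state:
#' every owner's holdings match those of two years earlier within
#' `eq_tol` for `eq_window` consecutive years. The two-year lag makes the
#' test period-aware: under sustained transmission the SIS process
#' alternates owners between infected and susceptible years, so the
#' attractor is generically a period-two orbit of which a fixed point is
#' the special case. An owner survives if their total land exceeds
#' `landless_eps * m`; the outcome is `"equity"` when at least
#' `equity_fraction * n` owners survive and `"latifundia"` otherwise.
#'
#' @param n Number of landowners (at least 2).
#' @param m Parcels per owner at the start (positive; parcels are
#'   continuous and divisible).
#' @param params A [land_params()] object.
#' @param disease A [disease_params()] object; default disabled.
#' @param init Initial landscape: `"random"` (each owner's land split at
#'   random with mean m/3 per use, see [init_landscape()]) or `"equal"`
#'   (perfect equity: every owner holds exactly m/3 in each use).
#' @param reps Number of replicates for drivers that run several.
#' @param seed Integer root seed; all randomness (initial landscapes,
#'   protected sets, infection draws) derives from it.
#' @param max_steps Cap on the number of yearly iterations.
#' @param eq_tol Steady-state tolerance on per-owner holdings (parcels).
#' @param eq_window Consecutive years the tolerance must hold.
#' @param landless_eps Ownership extinction threshold as a fraction of m.
#' @param equity_fraction Minimum surviving fraction of owners for the
#'   `"equity"` label.
#' @param record_every Trajectory thinning: keep every k-th year
#'   (`0` disables trajectory recording).
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n = 8, m = 8, seed = 1)
#' run_simulation(cfg)
#' @export
sim_config <- function(n = 64, m = 64,
                       params = land_params(),
                       disease = disease_params(enabled = FALSE),
                       init = c("random", "equal"),
                       reps = 20L, seed = 1L,
                       max_steps = 1e5, eq_tol = 1e-9 * m, eq_window = 10L,
                       landless_eps = 1e-3, equity_fraction = 0.9,
                       record_every = 0L) {
  init <- match.arg(init)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.",
          class = "latifundia_config_error")
  }
  if (!is.numeric(m) || length(m) != 1L || m <= 0) {
    abort("`m` must be a single positive number.",
          class = "latifundia_config_error")
  }
  if (!inherits(params, "land_params")) {
    abort("`params` must be a land_params() object.",
          class = "latifundia_config_error")
  }
  if (!inherits(disease, "disease_params")) {
    abort("`disease` must be a disease_params() object.",
          class = "latifundia_config_error")
  }
  if (!is.numeric(equity_fraction) || equity_fraction <= 0 ||
      equity_fraction > 1) {
    abort("`equity_fraction` must be in (0, 1].",
          class = "latifundia_config_error")
  }
  stopifnot(max_steps >= 1, eq_tol > 0, eq_window >= 1, landless_eps > 0,
            reps >= 1)
  structure(
    list(n = as.integer(n), m = m, params = params, disease = disease,
         init = init, reps = as.integer(reps), seed = as.integer(seed),
         max_steps = as.integer(max_steps), eq_tol = eq_tol,
         eq_window = as.integer(eq_window), landless_eps = landless_eps,
         equity_fraction = equity_fraction,
         record_every = as.integer(record_every)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d owners x m = %g parcels, init = %s\n",
              x$n, x$m, x$init))
  print(x$params)
  print(x$disease)
  cat(sprintf("  reps = %d, seed = %d, max_steps = %d\n",
              x$reps, x$seed, x$max_steps))
  cat(sprintf("  steady state: |change over 2 years| < %g for %d years\n",
              x$eq_tol, x$eq_window))
  cat(sprintf("  landless below %g * m; equity if >= %g of owners survive\n",
              x$landless_eps, x$equity_fraction))
  invisible(x)
}
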
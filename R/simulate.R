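#' Random initial landscape
#'
#' Gives every owner exactly `m` parcels, split at random over the three
#' uses: two uses are drawn from Uniform(0, 2m/3) -- mean m/3 each --
#' and the third takes the remainder, redrawing until the remainder is
#' non-negative. Which use takes the remainder is itself drawn uniformly
#' per owner, so no use is systematically favoured.
#'
#' @param n Number of owners.
#' @param m Parcels per owner.
#' @return A tibble with columns `owner`, `x`, `y`, `z`; each row sums
#'   to `m`.
#' @examples
#' set.seed(1)
#' init_landscape(4, 12)
#' @export
init_landscape <- function(n, m) {
  stopifnot(n >= 2, m > 0)
  H <- matrix(0, n, 3)
  rest <- sample.int(3, n, replace = TRUE)
  for (i in seq_len(n)) {
    repeat {
      d <- runif(2, 0, 2 * m / 3)
      if (sum(d) <= m) break
    }
    H[i, -rest[i]] <- d
    H[i, rest[i]] <- m - sum(d)
  }
  tibble(owner = seq_len(n), x = H[, 1], y = H[, 2], z = H[, 3])
}

# one model year on bare vectors: infection draw, discounted utilities,
# pooled trade, land-use transition. `M` is the landuse matrix.
year_step <- function(x, y, z, inf, kappa, cfg, M, protected) {
  n <- cfg$n
  p <- cfg$params
  dis <- cfg$disease
  if (dis$enabled) {
    lam <- force_of_infection(kappa, n, dis$r0)
    inf <- sample_infections(lam, n, protected, recovering = inf)
    kappa <- sum(inf)
  }
  U <- (p$a * x + p$b * y + p$c * z)
  if (dis$enabled) U <- ifelse(inf, dis$h, 1) * U
  P <- purchasing_power(U)
  V <- sale_pressure(U, P, p$sale_rule)
  pool <- sum(V * z)
  z <- (1 - V) * z + P * pool
  xn <- M[1, 1] * x + M[1, 2] * y + M[1, 3] * z
  yn <- M[2, 1] * x + M[2, 2] * y + M[2, 3] * z
  zn <- M[3, 1] * x + M[3, 2] * y + M[3, 3] * z
  list(x = xn, y = yn, z = zn, inf = inf, kappa = kappa, utility = U)
}

#' One simulated year
#'
#' Advances a landscape by one year in the order the model prescribes:
#' (1) last year's infecteds recover and new infections are drawn from
#' the force of infection; (2) utilities are computed, discounted by `h`
#' for the infected, giving purchasing power and sale pressure; (3) the
#' pooled empty land is traded; (4) land uses transition. Trade happens
#' before the land transition is realised, and the composite step
#' conserves total land.
#'
#' @param landscape Per-owner holdings tibble (columns `x`, `y`, `z`).
#' @param config A [sim_config()] object (its `n` must match the
#'   landscape).
#' @param infected Logical vector of owners infected last year.
#' @param kappa Infected count of the previous year (defaults to
#'   `sum(infected)`).
#' @param protected Indices of protected owners.
#' @return A list with elements `landscape` (updated tibble), `infected`,
#'   `kappa` and `utility`.
#' @examples
#' cfg <- sim_config(n = 4, m = 12, seed = 1)
#' ls0 <- init_landscape(4, 12)
#' sim_step(ls0, cfg)$landscape
#' @export
sim_step <- function(landscape, config, infected = rep(FALSE, nrow(landscape)),
                     kappa = sum(infected), protected = integer()) {
  landscape <- check_landscape(landscape)
  if (nrow(landscape) != config$n) {
    abort("landscape has a different number of owners than `config$n`.",
          class = "latifundia_state_error")
  }
  M <- landuse_matrix(config$params)
  s <- year_step(landscape$x, landscape$y, landscape$z,
                 infected, kappa, config, M, protected)
  landscape$x <- s$x
  landscape$y <- s$y
  landscape$z <- s$z
  list(landscape = landscape, infected = s$inf, kappa = s$kappa,
       utility = s$utility)
}

#' Run one simulation replicate
#'
#' Iterates yearly steps from a fresh initial landscape until the
#' steady-state rule of the configuration is met (holdings constant over
#' a two-year lag within `eq_tol` for `eq_window` years) or `max_steps`
#' is reached. The replicate's randomness is derived from the root seed:
#' replicate `k` uses a deterministic child seed for the initial
#' landscape and protected set, and a second stream seeded from it for
#' the yearly infection draws, so disease-free runs and `h = 1` runs see
#' identical landscapes.
#'
#' @param config A [sim_config()] object.
#' @param replicate Replicate index (1-based); selects the child seed.
#' @return A `latifundia_sim` object: a list with the final landscape,
#'   the (thinned) trajectory if `record_every > 0`, convergence
#'   information and the equity/latifundia classification. Use [tidy()]
#'   for the trajectory and [glance()] for the one-row summary.
#' @examples
#' res <- run_simulation(sim_config(n = 8, m = 8, seed = 42))
#' glance(res)
#' @export
run_simulation <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  m <- config$m
  dis <- config$disease
  child <- child_seed(config$seed, replicate)
  set.seed(child)

  if (config$init == "random") {
    ls0 <- init_landscape(n, m)
  } else {
    ls0 <- tibble(owner = seq_len(n), x = m / 3, y = m / 3, z = m / 3)
  }
  protected <- integer()
  if (dis$enabled && dis$protected_frac > 0) {
    protected <- sample_indices(seq_len(n), ceiling(dis$protected_frac * n))
  }
  # separate stream for the infection process
  set.seed(child_seed(child, 977L))
  inf <- seed_infections(n, dis, protected)
  kappa <- sum(inf)

  M <- landuse_matrix(config$params)
  x <- ls0$x; y <- ls0$y; z <- ls0$z
  tot1 <- tot2 <- x + y + z
  ok <- 0L
  t <- 0L
  rec <- list()
  U <- owner_utility(ls0, config$params, inf, if (dis$enabled) dis$h else 1)
  if (config$record_every > 0) {
    rec[[1]] <- tibble(step = 0L, owner = ls0$owner, x = x, y = y, z = z,
                       infected = inf, utility = U)
  }
  while (t < config$max_steps) {
    t <- t + 1L
    s <- year_step(x, y, z, inf, kappa, config, M, protected)
    x <- s$x; y <- s$y; z <- s$z; inf <- s$inf; kappa <- s$kappa
    tot <- x + y + z
    ok <- if (max(abs(tot - tot2)) < config$eq_tol) ok + 1L else 0L
    tot2 <- tot1
    tot1 <- tot
    if (config$record_every > 0 && t %% config$record_every == 0L) {
      rec[[length(rec) + 1L]] <-
        tibble(step = t, owner = ls0$owner, x = x, y = y, z = z,
               infected = inf, utility = s$utility)
    }
    if (ok >= config$eq_window) break
  }
  total <- x + y + z
  owners_final <- sum(total > config$landless_eps * m)
  structure(
    list(
      final = tibble(owner = ls0$owner, x = x, y = y, z = z, total = total,
                     infected = inf,
                     surviving = total > config$landless_eps * m),
      trajectory = if (length(rec)) bind_rows(rec) else NULL,
      converged = ok >= config$eq_window,
      steps = t,
      owners_initial = n,
      owners_final = owners_final,
      ratio = owners_final / n,
      outcome = if (owners_final >= config$equity_fraction * n) "equity"
                else "latifundia",
      protected = protected,
      replicate = as.integer(replicate),
      seed = child,
      config = config
    ),
    class = "latifundia_sim"
  )
}

#' Run all replicates of a configuration
#'
#' Runs `config$reps` independent replicates (deterministic child seeds
#' from the root seed) and returns their one-row summaries stacked.
#'
#' @param config A [sim_config()] object.
#' @param keep_sims Also return the `latifundia_sim` objects (as the
#'   `"sims"` attribute)?
#' @return A tibble with one row per replicate (the [glance()] columns).
#' @examples
#' run_replicates(sim_config(n = 8, m = 8, seed = 1, reps = 3))
#' @export
run_replicates <- function(config, keep_sims = FALSE) {
  sims <- map(seq_len(config$reps), ~ run_simulation(config, .x))
  out <- map_dfr(sims, glance)
  if (keep_sims) attr(out, "sims") <- sims
  out
}

# deterministic 32-bit child seed derivation (never relies on global RNG)
child_seed <- function(root, k) {
  as.integer((as.double(root) * 2654435761 + as.double(k) * 40503) %%
               2147483629)
}

#' @export
print.latifundia_sim <- function(x, ...) {
  cat(sprintf(
    "<latifundia_sim> %d owners, %s after %d years (%s)\n",
    x$owners_initial, x$outcome, x$steps,
    if (x$converged) "steady state" else "step cap reached"))
  cat(sprintf("  surviving owners: %d/%d (ratio %.3f)\n",
              x$owners_final, x$owners_initial, x$ratio))
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x A `latifundia_sim` object.
#' @param ... Unused.
#' @return The recorded trajectory as a tibble (`step`, `owner`, `x`,
#'   `y`, `z`, `infected`, `utility`), or the final state when no
#'   trajectory was recorded.
#' @exportS3Method generics::tidy
tidy.latifundia_sim <- function(x, ...) {
  if (!is.null(x$trajectory)) {
    x$trajectory
  } else {
    mutate(x$final, step = x$steps, .before = 1)
  }
}

#' One-row summary of a simulation result
#'
#' @param x A `latifundia_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `converged`, `steps`,
#'   `owners_initial`, `owners_final`, `ratio`, `outcome`.
#' @exportS3Method generics::glance
glance.latifundia_sim <- function(x, ...) {
  tibble(replicate = x$replicate, converged = x$converged, steps = x$steps,
         owners_initial = x$owners_initial, owners_final = x$owners_final,
         ratio = x$ratio, outcome = x$outcome)
}

#' Plot the ownership trajectory of a run
#'
#' Each line is one owner's total land through time; requires the run to
#' have been made with `record_every > 0`.
#'
#' @param object A `latifundia_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.latifundia_sim <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("no trajectory recorded; rerun with `record_every > 0`.")
  }
  d <- mutate(object$trajectory, total = .data$x + .data$y + .data$z)
  ggplot(d, aes(.data$step, .data$total,
                group = .data$owner, colour = factor(.data$owner))) +
    geom_line(show.legend = FALSE) +
    labs(x = "year", y = "total land (parcels)",
         title = sprintf("Ownership trajectory (%s)", object$outcome)) +
    theme_minimal()
}
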
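#' @noRd
new_sweep <- function(cells, replicates, sweep_type) {
  structure(cells, replicates = replicates, sweep_type = sweep_type,
            class = c("latifundia_sweep", class(cells)))
}

# run one sweep cell: reps replicates of `config`, summarised
run_cell <- function(config, cell_info) {
  runs <- run_replicates(config)
  rep_rows <- bind_rows(lapply(seq_len(nrow(runs)), function(i) {
    dplyr::bind_cols(cell_info, runs[i, ])
  }))
  agg <- dplyr::bind_cols(
    cell_info,
    tibble(
      reps = nrow(runs),
      p_equity = mean(runs$outcome == "equity"),
      owner_ratio = mean(runs$ratio),
      mean_steps = mean(runs$steps),
      all_converged = all(runs$converged)
    )
  )
  list(agg = agg, reps = rep_rows)
}

utility_orderings <- function() {
  perms <- list(c(3, 2, 1), c(3, 1, 2), c(2, 3, 1),
                c(1, 3, 2), c(2, 1, 3), c(1, 2, 3))
  map_dfr(perms, function(p) {
    nm <- c("a", "b", "c")
    tibble(ordering = paste(nm[order(-p)], collapse = ">"),
           a = p[1], b = p[2], c = p[3])
  })
}

#' Sweep system size and utility orderings
#'
#' Monte-Carlo sweep over landscape sizes (`n = 2^k1` owners, `m = 2^k2`
#' parcels each) crossed with the six orderings of the utility values
#' `{3, 2, 1}` over forest, agriculture and empty land, estimating the
#' probability of an equity outcome per cell. Transition rates default
#' to `r = eta = mu = 0.5`.
#'
#' @param k_n,k_m Integer exponents: owners `n = 2^k_n`, parcels
#'   `m = 2^k_m` (vectors define the grid).
#' @param orderings Data frame of utility assignments with columns
#'   `ordering`, `a`, `b`, `c`; defaults to all six permutations of
#'   `(3, 2, 1)`.
#' @param reps Replicates per cell.
#' @param seed Root seed; replicate child seeds are shared across cells
#'   so cells are seed-paired.
#' @param params Base [land_params()]; utilities are overwritten per
#'   cell.
#' @param max_steps Yearly iteration cap per run.
#' @return A `latifundia_sweep` tibble with one aggregated row per cell
#'   (`p_equity`, `owner_ratio`, ...); the per-replicate rows are in
#'   `attr(, "replicates")`.
#' @examples
#' \donttest{
#' sw <- sweep_size_utilities(k_n = 2:3, k_m = 2:3, reps = 5, seed = 1)
#' }
#' @export
sweep_size_utilities <- function(k_n = 1:6, k_m = 1:6,
                                 orderings = utility_orderings(),
                                 reps = 20, seed = 1,
                                 params = land_params(),
                                 max_steps = 5000) {
  grid <- tidyr::expand_grid(
    orderings,
    k_n = as.integer(k_n), k_m = as.integer(k_m)
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- land_params(r = params$r, eta = params$eta, mu = params$mu,
                     a = g$a, b = g$b, c = g$c,
                     sale_rule = params$sale_rule,
                     recovery_target = params$recovery_target)
    cfg <- sim_config(n = 2^g$k_n, m = 2^g$k_m, params = p,
                      reps = reps, seed = seed, max_steps = max_steps)
    run_cell(cfg, dplyr::mutate(g, n = 2^g$k_n, m = 2^g$k_m))
  })
  new_sweep(map_dfr(out, "agg"), map_dfr(out, "reps"), "size_utilities")
}

#' Sweep the land-use transition rates
#'
#' Sensitivity of the equity probability to the deforestation (`r`),
#' degradation (`eta`) and recovery (`mu`) rates on a grid, at fixed
#' system size and utilities (`n = m = 64`, `c = 3 > b = 2 > a = 1` by
#' default).
#'
#' @param rates Numeric vector of rate values; the grid is their full
#'   crossing over `(mu, eta, r)`. Alternatively pass a data frame with
#'   columns `r`, `eta`, `mu` for an explicit grid.
#' @param n,m System size.
#' @param reps,seed,max_steps As in [sweep_size_utilities()].
#' @param params Base [land_params()]; rates are overwritten per cell.
#' @return A `latifundia_sweep` tibble (aggregated rows; per-replicate
#'   rows in `attr(, "replicates")`).
#' @examples
#' \donttest{
#' sw <- sweep_transition_rates(rates = c(0.1, 0.9), n = 8, m = 8,
#'                              reps = 5, seed = 1)
#' }
#' @export
sweep_transition_rates <- function(rates = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                   n = 64, m = 64, reps = 20, seed = 1,
                                   params = land_params(),
                                   max_steps = 5000) {
  grid <- if (is.data.frame(rates)) {
    as_tibble(rates)
  } else {
    tidyr::expand_grid(mu = rates, eta = rates, r = rates)
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- land_params(r = g$r, eta = g$eta, mu = g$mu,
                     a = params$a, b = params$b, c = params$c,
                     sale_rule = params$sale_rule,
                     recovery_target = params$recovery_target)
    cfg <- sim_config(n = n, m = m, params = p, reps = reps, seed = seed,
                      max_steps = max_steps)
    run_cell(cfg, g)
  })
  new_sweep(map_dfr(out, "agg"), map_dfr(out, "reps"), "transition_rates")
}

#' Disease scenario experiment
#'
#' Reproduces the disease experiments: for each basic reproductive
#' number (epidemic `r0 = 1`, endemic `r0 = 2`), utility discount `h`
#' and protected fraction, runs replicates from a perfect-equity
#' landscape with the disease seeded at its endemic level, and records
#' the ratio of final to initial landowners. A disease-free `"ND"`
#' control row (no latifundia can form from perfect equity) is included.
#'
#' @param r0_values Basic reproductive numbers to scan.
#' @param h_values Utility discount factors to scan (`h = 1` no
#'   discount, `h = 0` full discount, `h = 0.01` a 99% discount; the
#'   intermediate regime defaults to `0.1` and `0.5`).
#' @param protected_fractions Fractions of the population immune to
#'   infection.
#' @param n,m System size (64 x 64 by default, the reference
#'   configuration).
#' @param reps,seed,max_steps As in [sweep_size_utilities()].
#' @param params [land_params()] for the land model (reference
#'   utilities `c = 3 > b = 2 > a = 1`, rates 0.5).
#' @param init Initial landscape for the disease runs (default
#'   `"equal"`: disease is introduced into a perfectly equitable
#'   population, conditions under which latifundia cannot otherwise
#'   form).
#' @return A `latifundia_sweep` tibble with per-cell mean owner ratio
#'   and equity probability; per-replicate rows in
#'   `attr(, "replicates")`.
#' @examples
#' \donttest{
#' de <- disease_experiment(r0_values = 2, h_values = 0,
#'                          protected_fractions = c(0, 0.2),
#'                          n = 16, m = 16, reps = 3, seed = 1)
#' }
#' @export
disease_experiment <- function(r0_values = c(1, 2),
                               h_values = c(1, 0, 0.01, 0.1, 0.5),
                               protected_fractions = c(0, 0.1, 0.2),
                               n = 64, m = 64, reps = 20, seed = 1,
                               params = land_params(),
                               max_steps = 5000,
                               init = c("equal", "random")) {
  init <- match.arg(init)
  grid <- tidyr::expand_grid(r0 = r0_values, h = h_values,
                             protected = protected_fractions)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- sim_config(
      n = n, m = m, params = params,
      disease = disease_params(r0 = g$r0, h = g$h,
                               protected_frac = g$protected),
      init = init, reps = reps, seed = seed, max_steps = max_steps
    )
    run_cell(cfg, dplyr::mutate(g, scenario = sprintf(
      "R0=%g, h=%g, %g%% protected", g$r0, g$h, 100 * g$protected)))
  })
  nd_cfg <- sim_config(n = n, m = m, params = params,
                       disease = disease_params(enabled = FALSE),
                       init = "equal", reps = reps, seed = seed,
                       max_steps = max_steps)
  nd <- run_cell(nd_cfg, tibble(r0 = NA_real_, h = NA_real_,
                                protected = NA_real_, scenario = "ND"))
  new_sweep(bind_rows(map_dfr(out, "agg"), nd$agg),
            bind_rows(map_dfr(out, "reps"), nd$reps),
            "disease")
}

#' @export
print.latifundia_sweep <- function(x, ...) {
  cat(sprintf("<latifundia_sweep: %s> %d cells x %d reps\n",
              attr(x, "sweep_type"), nrow(x),
              if (nrow(x)) x$reps[1] else 0L))
  NextMethod()
}

#' Per-replicate rows of a sweep
#'
#' @param x A `latifundia_sweep` object.
#' @param ... Unused.
#' @return A tibble with one row per cell and replicate.
#' @exportS3Method generics::tidy
tidy.latifundia_sweep <- function(x, ...) {
  attr(x, "replicates")
}

#' Plot a sweep result
#'
#' Heatmaps of the per-cell equity probability (size and rate sweeps,
#' faceted by ordering or recovery rate) or bar panels of the mean
#' final/initial owner ratio (disease experiment).
#'
#' @param object A `latifundia_sweep` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.latifundia_sweep <- function(object, ...) {
  type <- attr(object, "sweep_type")
  d <- as_tibble(object)
  if (identical(type, "size_utilities")) {
    ggplot(d, aes(.data$k_n, .data$k_m, fill = .data$p_equity)) +
      geom_tile() +
      facet_wrap(~ordering) +
      scale_fill_viridis_c(limits = c(0, 1)) +
      labs(x = expression(log[2] ~ "owners (n)"),
           y = expression(log[2] ~ "parcels per owner (m)"),
           fill = "P(equity)") +
      theme_minimal()
  } else if (identical(type, "transition_rates")) {
    ggplot(d, aes(.data$eta, .data$r, fill = .data$p_equity)) +
      geom_tile() +
      facet_wrap(~mu, labeller = "label_both") +
      scale_fill_viridis_c(limits = c(0, 1)) +
      labs(x = expression(eta ~ "(degradation)"),
           y = "r (deforestation)", fill = "P(equity)") +
      theme_minimal()
  } else {
    d$label <- ifelse(is.na(d$protected), "ND",
                      sprintf("%g%%", 100 * d$protected))
    ggplot(d, aes(.data$label, .data$owner_ratio)) +
      geom_col() +
      facet_grid(rows = dplyr::vars(.data$r0), cols = dplyr::vars(.data$h),
                 labeller = "label_both") +
      labs(x = "protected owners", y = "final / initial landowners") +
      theme_minimal()
  }
}
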
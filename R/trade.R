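#' Total land utility per owner
#'
#' An owner's utility is the value of their holdings,
#' `a x + b y + c z`, multiplied by the discount `h` in years the owner
#' is infected (a sick owner works the land less productively; `h = 1`
#' for healthy owners).
#'
#' @param landscape Per-owner holdings (columns `x`, `y`, `z`).
#' @param params A [land_params()] object supplying utilities `a, b, c`.
#' @param infected Logical vector flagging infected owners, or `NULL`
#'   for none.
#' @param h Utility discount applied to infected owners, in `[0, 1]`.
#' @return A numeric vector of per-owner utilities.
#' @examples
#' ls0 <- tibble::tibble(x = 1, y = 1, z = 1)
#' owner_utility(ls0, land_params(a = 1, b = 2, c = 3))         # 6
#' owner_utility(ls0, land_params(a = 1, b = 2, c = 3), TRUE, 0) # 0
#' @export
owner_utility <- function(landscape, params, infected = NULL, h = 1) {
  landscape <- check_landscape(landscape)
  stopifnot(h >= 0, h <= 1)
  u <- params$a * landscape$x + params$b * landscape$y + params$c * landscape$z
  if (!is.null(infected)) {
    infected <- rep_len(as.logical(infected), length(u))
    u <- ifelse(infected, h, 1) * u
  }
  u
}

#' Purchasing power
#'
#' Each owner's probability-like weight for acquiring land: their utility
#' relative to the total utility of all owners, `P_i = U_i / sum(U)`.
#' Weights are non-negative and sum to one, and are invariant to scaling
#' all utilities by a positive constant. If every utility is zero (all
#' land worthless, e.g. full discount of a fully infected population) the
#' weights fall back to the uniform `1/n`.
#'
#' @param utility Numeric vector of non-negative per-owner utilities.
#' @return Numeric vector of weights summing to one.
#' @examples
#' purchasing_power(c(3, 1))  # 0.75 0.25
#' @export
purchasing_power <- function(utility) {
  if (any(utility < 0)) {
    abort("utilities must be non-negative.", class = "latifundia_state_error")
  }
  s <- sum(utility)
  if (s > 0) utility / s else rep(1 / length(utility), length(utility))
}

#' Sale pressure
#'
#' The propensity of each owner to put their empty-state land on sale.
#' Three rules:
#' * `"complement"`: `V_i = 1 - P_i` -- owners with high purchasing power
#'   hold on to their land (the richer-conquers assumption);
#' * `"mean"`: sell everything when the owner's utility is below the
#'   population mean, otherwise nothing;
#' * `"median"`: the same with the population median as threshold.
#'
#' @param utility Per-owner utilities.
#' @param power Per-owner purchasing power; computed from `utility` when
#'   omitted.
#' @param rule One of `"complement"`, `"mean"`, `"median"`.
#' @return Numeric vector of sale pressures in `[0, 1]`.
#' @examples
#' sale_pressure(c(3, 1))                      # 0.25 0.75
#' sale_pressure(1:4, rule = "median")         # 1 1 0 0
#' @export
sale_pressure <- function(utility, power = purchasing_power(utility),
                          rule = c("complement", "mean", "median")) {
  rule <- match.arg(rule)
  switch(rule,
    complement = 1 - power,
    mean = as.numeric(utility < mean(utility)),
    median = as.numeric(utility < median(utility))
  )
}

#' Trade state of a landscape
#'
#' Computes, for each owner, the quantities that drive one year of land
#' trade: the (possibly disease-discounted) utility `U`, the purchasing
#' power `P`, the sale pressure `V` under the configured rule, and the
#' pooled empty land on sale `T = sum(V * z)`.
#'
#' @inheritParams owner_utility
#' @return A tibble with columns `owner`, `utility`, `power`, `pressure`
#'   and attribute `pool` (also exposed as column `pool` repeated per
#'   owner is avoided; use `attr(, "pool")` or [trade_step()]).
#' @examples
#' ls0 <- init_landscape(4, 12)
#' trade_state(ls0, land_params())
#' @export
trade_state <- function(landscape, params, infected = NULL, h = 1) {
  landscape <- check_landscape(landscape)
  U <- owner_utility(landscape, params, infected, h)
  P <- purchasing_power(U)
  V <- sale_pressure(U, P, params$sale_rule)
  out <- tibble(owner = landscape$owner, utility = U, power = P, pressure = V)
  attr(out, "pool") <- sum(V * landscape$z)
  out
}

#' One year of land trade
#'
#' Pools the empty-state land on sale, `T = sum(V_j z_j)`, and
#' redistributes it according to purchasing power:
#' `z'_i = (1 - V_i) z_i + P_i T`. Forest and agricultural land do not
#' change hands; total land and total empty land are conserved exactly
#' (the weights `P` sum to one). Owners without empty land participate as
#' buyers only -- there is no borrowing and no negative holding.
#'
#' @param landscape Per-owner holdings (columns `x`, `y`, `z`).
#' @param trade A [trade_state()] tibble (columns `power`, `pressure`),
#'   or `NULL` to compute it from `landscape`, `params`.
#' @param params,infected,h Used only when `trade` is `NULL`.
#' @return The landscape tibble with updated `z`.
#' @examples
#' ls0 <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(10, 10))
#' ts <- tibble::tibble(power = c(0.75, 0.25), pressure = c(0.25, 0.75))
#' trade_step(ls0, ts)  # z becomes 15, 5
#' @export
trade_step <- function(landscape, trade = NULL, params = NULL,
                       infected = NULL, h = 1) {
  landscape <- check_landscape(landscape)
  if (is.null(trade)) {
    if (is.null(params)) {
      abort("supply either `trade` or `params`.",
            class = "latifundia_config_error")
    }
    trade <- trade_state(landscape, params, infected, h)
  }
  P <- trade$power
  V <- trade$pressure
  stopifnot(length(P) == nrow(landscape), length(V) == nrow(landscape))
  if (abs(sum(P) - 1) > 1e-8 || any(V < 0) || any(V > 1)) {
    abort("trade state invalid: P must sum to 1 and V lie in [0, 1].",
          class = "latifundia_state_error")
  }
  pool <- sum(V * landscape$z)
  landscape$z <- (1 - V) * landscape$z + P * pool
  landscape
}
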
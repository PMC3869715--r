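#' Two-owner steady state under fixed purchasing power
#'
#' The two-owner system admits an analytic treatment when purchasing
#' power is frozen: owner i buys with probability `p_fixed`, owner j with
#' `1 - p_fixed`, and each sale pressure is the complement of the
#' owner's purchasing power. The pairwise trade rates
#' `t_ij = (1 - P_i) P_j` coincide with the pooled mechanism when
#' `P_i + P_j = 1`, so this iterates the pooled trade plus land-use maps
#' from an equal split until the shares stop moving, and returns the
#' long-run share of total land held by each owner.
#'
#' Equal shares arise only at `p_fixed = 0.5`; for `p_fixed > 0.5` land
#' spends ever more time in owner i's hands, and at `p_fixed = 1` all
#' land ends up with owner i.
#'
#' @param p_fixed Owner i's fixed purchasing power, in `[0, 1]`.
#' @param params A [land_params()] object (its `sale_rule` is ignored:
#'   the fixed-power analysis uses the complement rule).
#' @param m Parcels per owner in the initial equal split.
#' @param max_steps Iteration cap.
#' @param tol Convergence tolerance on the share of owner i.
#' @return A tibble with columns `owner` (`"i"`, `"j"`) and `share`.
#' @examples
#' two_owner_steady_state(0.5)$share   # 0.5 0.5
#' two_owner_steady_state(1)$share     # 1 0
#' @export
two_owner_steady_state <- function(p_fixed, params = land_params(), m = 64,
                                   max_steps = 1e5, tol = 1e-12) {
  stopifnot(p_fixed >= 0, p_fixed <= 1)
  P <- c(p_fixed, 1 - p_fixed)
  V <- 1 - P
  M <- landuse_matrix(params)
  x <- y <- z <- rep(m / 3, 2)
  share <- 0.5
  for (t in seq_len(max_steps)) {
    pool <- sum(V * z)
    z <- (1 - V) * z + P * pool
    xn <- M[1, 1] * x + M[1, 2] * y + M[1, 3] * z
    yn <- M[2, 1] * x + M[2, 2] * y + M[2, 3] * z
    z <- M[3, 1] * x + M[3, 2] * y + M[3, 3] * z
    x <- xn
    y <- yn
    tot <- x + y + z
    new_share <- tot[1] / sum(tot)
    if (abs(new_share - share) < tol && t > 10) {
      share <- new_share
      break
    }
    share <- new_share
  }
  tibble(owner = c("i", "j"), share = c(share, 1 - share))
}
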
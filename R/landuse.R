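#' Yearly land-use transition matrix
#'
#' The single-parcel Markov chain over the three land uses, as a
#' column-stochastic matrix: column j holds the probabilities that one
#' parcel currently in use j is in each use next year. Deforestation
#' takes F to A at rate `r`, degradation A to E at rate `eta`, and
#' recovery moves E land at rate `mu` to forest (default) or, under the
#' literal one-way reading, back to agriculture.
#'
#' @param params A [land_params()] object.
#' @return A 3x3 matrix with dimnames `c("x", "y", "z")` (forest,
#'   agriculture, empty).
#' @examples
#' landuse_matrix(land_params(r = 0.2, eta = 0.4, mu = 0.4))
#' @export
landuse_matrix <- function(params) {
  stopifnot(inherits(params, "land_params"))
  with(params, {
    M <- if (recovery_target == "forest") {
      rbind(c(1 - r, 0,       mu),
            c(r,     1 - eta, 0),
            c(0,     eta,     1 - mu))
    } else {
      rbind(c(1 - r, 0,       0),
            c(r,     1 - eta, mu),
            c(0,     eta,     1 - mu))
    }
    dimnames(M) <- list(c("x", "y", "z"), c("x", "y", "z"))
    M
  })
}

#' Stationary land-use distribution
#'
#' Long-run fractions of land in each use under the yearly transition
#' chain, i.e. the unit eigenvector of [landuse_matrix()] for eigenvalue
#' one. With recovery to forest and all rates positive these are
#' proportional to `(1/r, 1/eta, 1/mu)`.
#'
#' @param params A [land_params()] object.
#' @return A tibble with columns `use` (`"x"`, `"y"`, `"z"`) and
#'   `fraction`.
#' @examples
#' landuse_stationary(land_params(r = 0.2, eta = 0.4, mu = 0.4))
#' @export
landuse_stationary <- function(params) {
  M <- landuse_matrix(params)
  e <- eigen(M)
  i <- which.min(abs(e$values - 1))
  f <- Re(e$vectors[, i])
  f <- f / sum(f)
  tibble(use = c("x", "y", "z"), fraction = f)
}

#' One year of land-use change
#'
#' Applies the deterministic expected-flow update of the land-use chain
#' to every owner's holdings. Parcels are continuous, so the rates act as
#' proportions: with recovery to forest,
#' `x' = (1 - r) x + mu z`, `y' = r x + (1 - eta) y`,
#' `z' = eta y + (1 - mu) z`. Each owner's total is unchanged -- trade is
#' the only mechanism that moves land between owners.
#'
#' @param landscape A data frame with one row per owner and numeric
#'   columns `x`, `y`, `z` (forest, agricultural and empty land).
#' @param params A [land_params()] object.
#' @return A tibble shaped like `landscape` with updated `x`, `y`, `z`.
#' @examples
#' ls0 <- init_landscape(4, 12)
#' landuse_step(ls0, land_params())
#' @export
landuse_step <- function(landscape, params) {
  landscape <- check_landscape(landscape)
  M <- landuse_matrix(params)
  H <- t(M %*% t(as.matrix(landscape[, c("x", "y", "z")])))
  landscape$x <- unname(H[, 1])
  landscape$y <- unname(H[, 2])
  landscape$z <- unname(H[, 3])
  landscape
}

# validate a per-owner holdings table
check_landscape <- function(landscape) {
  if (!is.data.frame(landscape) ||
      !all(c("x", "y", "z") %in% names(landscape))) {
    abort("`landscape` must be a data frame with columns x, y, z.",
          class = "latifundia_state_error")
  }
  h <- as.matrix(landscape[, c("x", "y", "z")])
  if (!is.numeric(h) || anyNA(h)) {
    abort("holdings must be numeric and non-missing.",
          class = "latifundia_state_error")
  }
  if (any(h < 0)) {
    abort("negative land amounts: invalid landscape state.",
          class = "latifundia_state_error")
  }
  if (!("owner" %in% names(landscape))) {
    landscape$owner <- seq_len(nrow(landscape))
  }
  as_tibble(landscape[, c("owner", "x", "y", "z")])
}
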
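#' Force of infection
#'
#' Frequency-dependent yearly infection probability,
#' `lambda = min(1, R0 * kappa / n)`, where `kappa` is the number of
#' owners infected in the previous year and `n` the population size. The
#' cap at one keeps `lambda` a probability when `R0 > 1`.
#'
#' @param kappa Infected count in the previous year, `0 <= kappa <= n`.
#' @param n Population size.
#' @param r0 Basic reproductive number.
#' @return A probability in `[0, 1]`.
#' @examples
#' force_of_infection(0, 64, 2)   # 0
#' force_of_infection(32, 64, 2)  # 1
#' @export
force_of_infection <- function(kappa, n, r0) {
  stopifnot(n >= 1, kappa >= 0, kappa <= n, r0 >= 0)
  min(1, r0 * kappa / n)
}

#' Draw one year of infections
#'
#' Rejection sampling of new SIS infections: every exposable owner is
#' infected independently when a uniform draw falls below `lambda`.
#' Protected owners are never infected. Owners infected in the previous
#' year recover during the current year and are not exposable again
#' until the following one; without that one-year refractory period a
#' saturated force of infection (`lambda = 1`) would lock the whole
#' unprotected population in the infected state and erase the
#' between-owner variation the trade dynamics feed on.
#'
#' @param lambda Infection probability for the year, in `[0, 1]`.
#' @param n Population size.
#' @param protected Integer indices of owners immune to infection.
#' @param recovering Logical vector (length `n`) of owners infected in
#'   the previous year, or `NULL` for none.
#' @return Logical vector of this year's infections.
#' @examples
#' set.seed(1)
#' sample_infections(1, 6, protected = c(1, 2))
#' @export
sample_infections <- function(lambda, n, protected = integer(),
                              recovering = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  inf <- rep(FALSE, n)
  eligible <- setdiff(seq_len(n), protected)
  if (!is.null(recovering)) {
    eligible <- setdiff(eligible, which(as.logical(recovering)))
  }
  if (length(eligible) > 0 && lambda > 0) {
    inf[eligible] <- runif(length(eligible)) < lambda
  }
  inf
}

# initial infected set: endemically established for r0 > 1, a single
# introduction otherwise (kappa0 overrides)
seed_infections <- function(n, disease, protected = integer()) {
  inf <- rep(FALSE, n)
  if (!disease$enabled) {
    return(inf)
  }
  k0 <- disease$kappa0
  if (is.null(k0)) {
    k0 <- max(1L, as.integer(round(n * (1 - 1 / max(disease$r0, 1)))))
  }
  unprot <- setdiff(seq_len(n), protected)
  k0 <- min(k0, length(unprot))
  if (k0 > 0) {
    inf[sample_indices(unprot, k0)] <- TRUE
  }
  inf
}

# sample() without the length-1 surprise
sample_indices <- function(pool, k) {
  if (length(pool) == 1L) {
    return(pool[seq_len(min(k, 1L))])
  }
  sample(pool, k)
}
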
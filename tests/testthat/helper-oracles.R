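# independent oracles used across tests

# stationary distribution of the 3-state land-use chain, written out by
# hand (column-stochastic matrix) and solved by eigen-decomposition
oracle_stationary <- function(r, eta, mu, recovery = "forest") {
  M <- if (recovery == "forest") {
    rbind(c(1 - r, 0, mu),
          c(r, 1 - eta, 0),
          c(0, eta, 1 - mu))
  } else {
    rbind(c(1 - r, 0, 0),
          c(r, 1 - eta, mu),
          c(0, eta, 1 - mu))
  }
  e <- eigen(M)
  f <- Re(e$vectors[, which.min(abs(e$values - 1))])
  f / sum(f)
}

# dominant eigenvector of the 6-dimensional linear two-owner system with
# frozen purchasing power: long-run land share of owner i
oracle_two_owner_share <- function(p_fixed, r = 0.5, eta = 0.5, mu = 0.5) {
  P <- c(p_fixed, 1 - p_fixed)
  V <- 1 - P
  # state (x1, y1, z1, x2, y2, z2); trade then land use, both linear
  Tr <- diag(6)
  Tr[3, 3] <- (1 - V[1]) + P[1] * V[1]
  Tr[3, 6] <- P[1] * V[2]
  Tr[6, 6] <- (1 - V[2]) + P[2] * V[2]
  Tr[6, 3] <- P[2] * V[1]
  A1 <- rbind(c(1 - r, 0, mu), c(r, 1 - eta, 0), c(0, eta, 1 - mu))
  L <- matrix(0, 6, 6)
  L[1:3, 1:3] <- A1
  L[4:6, 4:6] <- A1
  J <- L %*% Tr
  e <- eigen(J)
  v <- Re(e$vectors[, which.max(Mod(e$values))])
  v <- v / sum(v)
  sum(v[1:3])
}

# equal-split landscape used by several tests
equal_landscape <- function(n, m) {
  tibble::tibble(owner = seq_len(n), x = m / 3, y = m / 3, z = m / 3)
}
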
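# Shared fixture builders (everything generated in code).

# multivariate normal draws with a given precision matrix
rmvn_prec <- function(n, omega) {
  P <- ncol(omega)
  R <- chol(omega)
  z <- t(backsolve(R, matrix(rnorm(n * P), P, n)))
  dimnames(z) <- list(sprintf("s%03d", seq_len(n)), sprintf("t%02d", seq_len(P)))
  z
}

# chain 1-2-3 embedded among independent taxa
chain_precision <- function(P = 10, diag_val = 1.5, off = -0.6) {
  omega <- diag(diag_val, P)
  omega[1, 2] <- omega[2, 1] <- off
  omega[2, 3] <- omega[3, 2] <- off
  dimnames(omega) <- list(paste0("t", 1:P), paste0("t", 1:P))
  omega
}

# disjoint strong pairs: partial correlation ~ strength/(strength + margin)
pair_precision <- function(P = 30, strength = 1, margin = 0.05) {
  om <- diag(strength + margin, P)
  for (i in seq(1, P - 1, by = 2)) om[i, i + 1] <- om[i + 1, i] <- -strength
  dimnames(om) <- list(sprintf("t%02d", 1:P), sprintf("t%02d", 1:P))
  om
}

# small abundance fixture with ids
toy_counts <- function(n = 4, p = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * p, 20), n, p,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:p)))
  m
}

# exact robustness distribution by exhaustive enumeration of removal orders
enumerate_robustness <- function(g) {
  P <- igraph::vcount(g)
  stopifnot(P <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  orders <- perms(seq_len(P))
  vapply(orders, function(ord) {
    sigma <- numeric(P)
    for (i in seq_len(P)) {
      remaining <- setdiff(seq_len(P), ord[seq_len(i)])
      sigma[i] <- if (length(remaining) == 0) 0 else {
        sub <- igraph::induced_subgraph(g, remaining)
        max(igraph::components(sub)$csize) / P
      }
    }
    mean(sigma)
  }, numeric(1))
}
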
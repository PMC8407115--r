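test_that("precision-to-partial matches the textbook identity", {
  omega <- matrix(c(2, -1, -1, 2), 2, 2)
  pc <- precision_to_partial(omega)
  expect_equal(pc$rho[1, 2], 0.5)
  expect_equal(diag(pc$rho), c(1, 1), ignore_attr = TRUE)

  # diagonal precision -> no associations
  pc0 <- precision_to_partial(diag(c(1, 2, 3)))
  expect_equal(pc0$rho, diag(3), ignore_attr = TRUE)

  # dense random SPD, checked against an independent base-R route (cov2cor)
  set.seed(10)
  for (i in 1:10) {
    A <- matrix(rnorm(36), 6, 6)
    om <- crossprod(A) + diag(6)
    expected <- -stats::cov2cor(om)
    diag(expected) <- 1
    got <- precision_to_partial(om)$rho
    expect_equal(unname(got), unname(expected), tolerance = 1e-10)
  }
})

test_that("partial correlations are scale-invariant and reject bad diagonals", {
  set.seed(11)
  A <- matrix(rnorm(25), 5, 5)
  om <- crossprod(A) + diag(5)
  expect_equal(precision_to_partial(om)$rho,
               precision_to_partial(om * 7.3)$rho, tolerance = 1e-12)
  om2 <- om; om2[1, 1] <- -1
  expect_error(precision_to_partial(om2), "diagonal")
})

test_that("inference rejects constant columns and degenerate inputs", {
  x <- rmvn_prec(30, diag(1.5, 4))
  x[, 2] <- 5
  expect_error(estimate_precision(x, selection = "fixed", lambda = 0.2), "t02")
  expect_error(estimate_precision(x[1:2, ], selection = "fixed", lambda = 0.2),
               "3 samples")
})

test_that("two-taxon case reduces to thresholded simple correlation", {
  set.seed(12)
  om <- matrix(c(1.5, -0.9, -0.9, 1.5), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  x <- rmvn_prec(300, om)
  r <- cor(x[, 1], x[, 2])  # strongly positive
  hi <- estimate_precision(x, selection = "fixed", lambda = abs(r) + 0.05)
  expect_false(hi$support[1, 2])
  lo <- estimate_precision(x, selection = "fixed", lambda = abs(r) / 2)
  expect_true(lo$support[1, 2])
  expect_gt(precision_to_partial(lo)$rho[1, 2], 0)
})

test_that("independent columns yield an empty or near-empty selected graph", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(500 * 6), 500, 6,
                dimnames = list(paste0("s", 1:500), paste0("t", 1:6)))
    est <- estimate_precision(x, selection = "stars")
    hits <- hits + sum(est$support) / 2
  }
  expect_lte(hits / (10 * choose(6, 2)), 0.1)
})

test_that("chain-structured data recovers its two true edges, not the shortcut", {
  rec <- 0; short <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- rmvn_prec(500, chain_precision(10))
    est <- estimate_precision(x, selection = "stars")
    rec <- rec + (est$support[1, 2] + est$support[2, 3]) / 2
    short <- short + est$support[1, 3]
  }
  expect_gte(rec / 10, 0.9)
  expect_lte(short / 10, 0.2)
})

test_that("support recall is non-decreasing with sample size", {
  recall_at <- function(n, seeds = 15) {
    mean(vapply(seq_len(seeds), function(s) {
      set.seed(1000 + s)
      x <- rmvn_prec(n, chain_precision(8))
      est <- estimate_precision(x, selection = "fixed", lambda = 0.15)
      (est$support[1, 2] + est$support[2, 3]) / 2
    }, numeric(1)))
  }
  r <- c(recall_at(50), recall_at(200), recall_at(800))
  expect_true(all(diff(r) >= -0.05))
  expect_gte(r[3], r[1])
})

test_that("graphical-lasso backend approaches the dense inverse at tiny penalty", {
  set.seed(13)
  x <- rmvn_prec(400, chain_precision(5))
  est <- estimate_precision(x, selection = "fixed", lambda = 1e-4,
                            method = "glasso")
  S <- cov(scale(x)) * 399 / 400
  direct <- solve(S)
  expect_equal(unname(precision_to_partial(est)$rho),
               unname(precision_to_partial(direct)$rho), tolerance = 0.02)
})

test_that("graphical-lasso and neighborhood selection agree on clear structure", {
  set.seed(14)
  x <- rmvn_prec(500, chain_precision(6))
  mb <- estimate_precision(x, selection = "fixed", lambda = 0.2)
  gl <- estimate_precision(x, selection = "fixed", lambda = 0.2,
                           method = "glasso")
  expect_true(gl$support[1, 2] && gl$support[2, 3])
  expect_true(mb$support[1, 2] && mb$support[2, 3])
})

test_that("population network drops isolated taxa and keeps rho as weights", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- -0.4
  sup <- matrix(FALSE, 3, 3); sup[1, 2] <- sup[2, 1] <- TRUE
  taxa <- c("a", "b", "c")
  dimnames(rho) <- dimnames(sup) <- list(taxa, taxa)
  pcm <- structure(list(taxon_ids = taxa, rho = rho, support = sup, n = 10),
                   class = "partial_correlation")
  g <- build_mnp(pcm)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, -0.4)

  empty <- pcm
  empty$support[] <- FALSE
  empty$rho <- diag(3); dimnames(empty$rho) <- list(taxa, taxa)
  expect_equal(igraph::vcount(build_mnp(empty)), 0)
})

test_that("emitted MNP edge weights equal the partial-correlation entries", {
  set.seed(15)
  x <- rmvn_prec(300, chain_precision(6))
  pcm <- precision_to_partial(estimate_precision(x, selection = "fixed",
                                                 lambda = 0.15))
  g <- build_mnp(pcm)
  el <- igraph::as_data_frame(g)
  for (k in seq_len(nrow(el)))
    expect_equal(el$weight[k], pcm$rho[el$from[k], el$to[k]], tolerance = 1e-12)
})
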
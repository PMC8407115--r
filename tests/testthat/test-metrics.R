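test_that("connectivity metrics match hand enumeration on small graphs", {
  tri <- igraph::make_full_graph(3)
  m <- connectivity(tri)
  expect_equal(m$node_number, 3)
  expect_equal(m$edge_number, 3)
  expect_equal(m$mean_degree, 2)
  expect_equal(m$average_path, 1)

  path3 <- igraph::make_graph(~ a - b, b - c)
  m2 <- connectivity(path3)
  expect_equal(m2$mean_degree, 4 / 3)
  expect_equal(m2$average_path, 4 / 3)  # pairs at distances (1, 1, 2)

  two_edges <- igraph::make_graph(~ a - b, c - d)
  expect_equal(connectivity(two_edges)$average_path, 1)  # cross pairs excluded

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  m3 <- connectivity(empty)
  expect_equal(m3$node_number, 0)
  expect_true(is.na(m3$average_path))
})

test_that("robustness closed forms hold exactly", {
  set.seed(30)
  k4 <- robustness(igraph::make_full_graph(4), n_repeats = 25)
  expect_equal(k4$robustness, 0.375)  # (P-1)/(2P) for complete graphs
  expect_equal(k4$collapse_curve$giant_fraction, c(3, 2, 1, 0) / 4)

  for (P in c(3, 5, 8)) {
    edgeless <- igraph::make_empty_graph(P, directed = FALSE)
    expect_equal(robustness(edgeless, n_repeats = 10)$robustness,
                 (P - 1) / P^2)
  }

  single <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(robustness(single, n_repeats = 5)$robustness, 0)
})

test_that("simulated robustness matches exhaustive order enumeration", {
  graphs <- list(igraph::make_graph(~ a - b, b - c, c - d),          # path P4
                 igraph::make_graph(~ a - b, b - c, c - a, c - d),   # tadpole
                 igraph::make_ring(5))
  for (g in graphs) {
    exact <- enumerate_robustness(g)
    set.seed(31)
    sim <- robustness(g, n_repeats = 2001)
    expect_equal(sim$robustness, median(exact), tolerance = 0.02)
    # simulated per-repeat values only take enumerated values
    nearest <- apply(abs(outer(sim$R_repeats, exact, "-")), 1, min)
    expect_true(all(nearest < 1e-12))
  }
})

test_that("adding edges does not lower robustness beyond noise", {
  diffs <- numeric(20)
  for (s in 1:20) {
    set.seed(600 + s)
    g <- igraph::sample_gnp(10, 0.2)
    comp <- igraph::complementer(g)
    add <- igraph::as_edgelist(comp)
    add <- add[sample(nrow(add), min(5, nrow(add))), , drop = FALSE]
    g2 <- igraph::add_edges(g, t(add))
    set.seed(600 + s)
    r1 <- robustness(g, 301)$robustness
    set.seed(600 + s)
    r2 <- robustness(g2, 301)$robustness
    diffs[s] <- r2 - r1
  }
  expect_gte(mean(diffs), 0)
  expect_gte(min(diffs), -0.02)
})

test_that("mean degree identity holds for every emitted metric set", {
  set.seed(32)
  for (i in 1:10) {
    g <- igraph::sample_gnp(sample(4:15, 1), runif(1, 0.1, 0.6))
    m <- network_metrics(g, n_repeats = 20)
    if (m$node_number > 0)
      expect_equal(m$mean_degree, 2 * m$edge_number / m$node_number)
    expect_gte(m$robustness, 0)
    expect_lte(m$robustness, 1)
    expect_true(all(diff(m$collapse_curve$giant_fraction) <= 1e-12))
  }
})

test_that("group comparison reports medians and pairwise rank tests", {
  met <- data.frame(edge_number = c(1, 2, 3, 4, 10, 11, 12, 13, 5, 6, 7, 8))
  grp <- rep(c("a", "b", "c"), each = 4)
  out <- compare_groups(met, grp)
  expect_equal(nrow(out), 3)  # 3 pairwise tests for the single metric
  ab <- out[out$group1 == "a" & out$group2 == "b", ]
  expect_equal(ab$median1, 2.5)
  expect_equal(ab$median2, 11.5)
  expect_lt(ab$p_value, 0.05)

  same <- data.frame(x = rep(1, 8))
  out2 <- suppressWarnings(compare_groups(same, rep(c("a", "b"), each = 4)))
  expect_gte(out2$p_value, 0.99)

  expect_warning(out3 <- compare_groups(met, c(rep("a", 6), rep("b", 5),
                                               "tiny")), "tiny")
  expect_setequal(unique(c(out3$group1, out3$group2)), c("a", "b"))
})

test_that("denser random networks have larger edge-number medians", {
  wins <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    dense <- replicate(15, igraph::ecount(igraph::sample_gnp(30, 0.30)))
    sparse <- replicate(15, igraph::ecount(igraph::sample_gnp(30, 0.10)))
    if (median(dense) > median(sparse)) wins <- wins + 1
  }
  expect_gte(wins / 20, 0.95)
})

test_that("degree matrix row sums equal twice the edge numbers", {
  set.seed(33)
  x <- rmvn_prec(15, chain_precision(6))
  fit <- mni(x, selection = "fixed", lambda = 0.2)
  D <- degree_matrix(fit)
  ec <- vapply(fit$results, function(r) igraph::ecount(r$network), numeric(1))
  expect_equal(unname(rowSums(D)), unname(2 * ec))
})

test_that("Bray-Curtis behaves as a bounded dissimilarity on degree rows", {
  expect_equal(as.numeric(vegan::vegdist(rbind(c(1, 0), c(0, 1)), "bray")), 1)
  expect_equal(as.numeric(vegan::vegdist(rbind(c(2, 3), c(2, 3)), "bray")), 0)
  set.seed(34)
  D <- matrix(rpois(60, 3), 10, 6)
  d <- as.numeric(vegan::vegdist(D + 1, "bray"))  # +1 avoids zero rows
  expect_true(all(d >= 0 & d <= 1))
})

test_that("well-separated planted groups ordinate to perfect label agreement", {
  set.seed(35)
  base <- list(c(8, 8, 8, 0, 0, 0, 0, 0), c(0, 0, 0, 8, 8, 8, 0, 0),
               c(0, 0, 8, 0, 0, 0, 8, 8), c(4, 0, 0, 0, 4, 0, 0, 4))
  D <- do.call(rbind, lapply(1:4, function(g)
    t(replicate(6, pmax(base[[g]] + rpois(8, 1) - 1, 0)))))
  rownames(D) <- paste0("s", 1:24)
  colnames(D) <- paste0("t", 1:8)
  grp <- rep(letters[1:4], each = 6)
  ord <- degree_ordination(D, group = grp)
  expect_equal(ord$ari, 1)
  expect_equal(nrow(ord$points), 24)
})

test_that("all-zero degree rows are excluded with a warning", {
  D <- rbind(a = c(2, 1, 0), b = c(0, 0, 0), c = c(1, 2, 0), d = c(2, 0, 1))
  colnames(D) <- paste0("t", 1:3)
  expect_warning(ord <- degree_ordination(D, group = c(1, 2, 1, 1)), "b")
  expect_equal(nrow(ord$points), 3)
})

test_that("Shannon entropy matches hand-computed values", {
  expect_equal(shannon(rep(25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "positive")
})
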
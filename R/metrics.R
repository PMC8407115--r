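# Connectivity and fragility statistics for association networks (population
# or individual), group comparison, and degree-matrix ordination.

#' Network connectivity metrics
#'
#' Node number, edge number, mean degree (2|E|/|V|) and average shortest-path
#' length. The average path is taken over connected node pairs only, so it
#' stays defined for fragmented networks; an empty graph yields node_number 0
#' and `NA` paths rather than an error.
#'
#' @param g an undirected [igraph::igraph] graph.
#' @return list of class `network_metrics` with fields `node_number`,
#'   `edge_number`, `mean_degree`, `average_path`.
#' @export
connectivity <- function(g) {
  stopifnot(inherits(g, "igraph"))
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  mean_deg <- if (nv > 0) 2 * ne / nv else NA_real_
  avg_path <- if (nv > 1 && ne > 0)
    igraph::mean_distance(g, weights = NA, directed = FALSE, unconnected = TRUE)
  else NA_real_
  structure(list(node_number = nv, edge_number = ne,
                 mean_degree = mean_deg, average_path = avg_path),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("nodes %d, edges %d, mean degree %.3g, average path %.3g",
              x$node_number, x$edge_number, x$mean_degree, x$average_path))
  if (!is.null(x$robustness)) cat(sprintf(", robustness %.4g", x$robustness))
  cat("\n")
  invisible(x)
}

#' Network fragility by random node removal
#'
#' Simulates ecological collapse: all P nodes are removed one by one in a
#' uniformly random order and, after each removal, the fractional size of
#' the largest connected component relative to the original P is recorded.
#' A single removal order yields `R = (1/P) * sum_i sigma(i/P)`; the
#' reported robustness is the median of R over `n_repeats` orders, and the
#' collapse curve is the per-position median of the curves. Randomness comes
#' from the session RNG (`set.seed()` makes it reproducible).
#'
#' @param g an undirected [igraph::igraph] graph with at least one node.
#' @param n_repeats number of random removal orders (>= 1); 1,000 by default.
#' @return list of class `network_metrics` with fields `robustness`,
#'   `collapse_curve` (data.frame: `fraction_removed`, `giant_fraction`),
#'   `R_repeats` (per-order values).
#' @export
robustness <- function(g, n_repeats = 1000) {
  stopifnot(inherits(g, "igraph"))
  P <- igraph::vcount(g)
  if (P < 1) stop("robustness needs at least one node")
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  sim <- robustness_sim_cpp(el - 1L, P, as.integer(n_repeats))
  curve <- apply(sim$curves, 2, stats::median)
  structure(list(robustness = stats::median(sim$R),
                 collapse_curve = data.frame(fraction_removed = seq_len(P) / P,
                                             giant_fraction = curve),
                 R_repeats = sim$R),
            class = "network_metrics")
}

#' All connectivity and fragility metrics of one network
#'
#' @inheritParams robustness
#' @return `network_metrics` with both connectivity and fragility fields.
#' @export
network_metrics <- function(g, n_repeats = 1000) {
  con <- connectivity(g)
  if (con$node_number > 0) {
    fr <- robustness(g, n_repeats)
    con$robustness <- fr$robustness
    con$collapse_curve <- fr$collapse_curve
    con$R_repeats <- fr$R_repeats
  } else {
    con$robustness <- NA_real_
    con$collapse_curve <- data.frame(fraction_removed = numeric(0),
                                     giant_fraction = numeric(0))
  }
  con
}

#' Per-sample metrics table for an MNI fit
#'
#' @param fit an `mni_fit`.
#' @param n_repeats removal orders for the robustness simulation.
#' @return data.frame with one row per sample: node_number, edge_number,
#'   mean_degree, average_path, robustness.
#' @export
mni_metrics <- function(fit, n_repeats = 1000) {
  stopifnot(inherits(fit, "mni_fit"))
  rows <- lapply(fit$results, function(r) {
    m <- network_metrics(r$network, n_repeats)
    data.frame(sample_id = r$sample_id, node_number = m$node_number,
               edge_number = m$edge_number, mean_degree = m$mean_degree,
               average_path = m$average_path, robustness = m$robustness)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-sample network metrics between groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests per metric, with per-group
#' medians so orderings across groups can be read off. Exact p-values are
#' used when both groups have at most 25 samples and no ties; the normal
#' approximation with continuity correction otherwise. No multiplicity
#' correction is applied across the metric panel.
#'
#' @param metrics data.frame of per-sample metrics (numeric columns are
#'   tested); must not contain a column named `group`.
#' @param group group label per row (>= 2 groups with >= 2 samples each;
#'   smaller groups are dropped with a warning).
#' @return data.frame of class `group_comparison`: metric, group1, group2,
#'   median1, median2, statistic, p_value.
#' @export
compare_groups <- function(metrics, group) {
  stopifnot(is.data.frame(metrics), length(group) == nrow(metrics))
  group <- as.character(group)
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with fewer than 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    metrics <- metrics[keep, , drop = FALSE]
    group <- group[keep]
  }
  glev <- sort(unique(group))
  if (length(glev) < 2) stop("need at least 2 groups with 2+ samples")
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  pairs <- utils::combn(glev, 2)
  rows <- list()
  for (m in num) {
    for (k in seq_len(ncol(pairs))) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      v1 <- metrics[[m]][group == g1]; v2 <- metrics[[m]][group == g2]
      v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
      exact <- length(v1) <= 25 && length(v2) <= 25 &&
        !anyDuplicated(c(v1, v2))
      if (length(unique(c(v1, v2))) == 1) {
        wt <- list(statistic = length(v1) * length(v2) / 2, p.value = 1)
      } else {
        wt <- suppressWarnings(
          stats::wilcox.test(v1, v2, exact = exact, correct = TRUE))
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, group1 = g1, group2 = g2,
        median1 = stats::median(v1), median2 = stats::median(v2),
        statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Degree matrix of an MNI fit
#'
#' Rows are samples, columns the shared taxon universe; entries are the node
#' degrees in each individual network (0 for taxa absent from a network).
#' Row sums therefore equal twice the per-network edge numbers.
#'
#' @param fit an `mni_fit` (or list of `mni_result` with a `taxon_ids`
#'   attribute supplied via `taxon_ids`).
#' @param taxon_ids taxon universe (defaults to the fit's).
#' @return integer matrix, samples x taxa.
#' @export
degree_matrix <- function(fit, taxon_ids = NULL) {
  results <- if (inherits(fit, "mni_fit")) fit$results else fit
  if (is.null(taxon_ids)) taxon_ids <- fit$taxon_ids
  D <- matrix(0L, length(results), length(taxon_ids),
              dimnames = list(vapply(results, `[[`, "", "sample_id"),
                              taxon_ids))
  for (i in seq_along(results)) {
    g <- results[[i]]$network
    if (igraph::vcount(g) > 0) {
      d <- igraph::degree(g)
      D[i, names(d)] <- as.integer(d)
    }
  }
  D
}

#' Ordination of individual networks by node degree
#'
#' Bray-Curtis dissimilarity between the rows of the degree matrix, then
#' classical PCoA (eigendecomposition of the double-centered squared
#' distance matrix; negative eigenvalues truncated at zero, no correction).
#' When group labels are given, a k-medoids clustering (k = number of
#' groups) on the first two axes is compared to the labels by the adjusted
#' Rand index.
#'
#' @param fit an `mni_fit`, or a degree matrix (samples x taxa).
#' @param group optional group labels per sample.
#' @param k number of clusters (defaults to the number of groups).
#' @param n_axes number of ordination axes to return.
#' @return list of class `degree_ordination`: `points` (samples x axes),
#'   `eig` (eigenvalues), `ari`, `clustering`, `excluded` (all-zero rows).
#' @export
degree_ordination <- function(fit, group = NULL, k = NULL, n_axes = 2) {
  D <- if (inherits(fit, "mni_fit")) degree_matrix(fit) else as.matrix(fit)
  if (nrow(D) < 3) stop("ordination needs at least 3 samples")
  zero <- rowSums(D) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " sample(s) with all-zero degree rows: ",
            paste(rownames(D)[zero], collapse = ", "))
    D <- D[!zero, , drop = FALSE]
    if (!is.null(group)) group <- group[!zero]
  }
  d <- vegan::vegdist(D, method = "bray")
  n_axes <- min(n_axes, nrow(D) - 1)
  pc <- stats::cmdscale(d, k = n_axes, eig = TRUE)
  eig <- pmax(pc$eig, 0)
  ari <- NA_real_; clus <- NULL
  if (!is.null(group)) {
    if (is.null(k)) k <- length(unique(group))
    if (k >= 2 && k < nrow(D)) {
      clus <- cluster::pam(pc$points[, 1:min(2, ncol(pc$points)), drop = FALSE],
                           k = k, cluster.only = TRUE)
      ari <- mclust::adjustedRandIndex(clus, group)
    }
  }
  structure(list(points = pc$points, eig = eig, ari = ari,
                 clustering = clus, excluded = names(zero)[zero]),
            class = "degree_ordination")
}

#' @export
print.degree_ordination <- function(x, ...) {
  cat(sprintf("PCoA of degree matrix: %d samples, %d axes",
              nrow(x$points), ncol(x$points)))
  if (!is.na(x$ari)) cat(sprintf(", ARI = %.3f", x$ari))
  cat("\n")
  invisible(x)
}

#' Shannon alpha diversity of one sample
#'
#' Natural-log Shannon entropy of the nonzero proportions.
#'
#' @param abundances nonnegative vector with positive sum (counts or
#'   relative abundances; normalized internally).
#' @return Shannon entropy (nats).
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0) || sum(abundances) <= 0)
    stop("abundances must be nonnegative with a positive sum")
  p <- abundances / sum(abundances)
  p <- p[p > 0]
  -sum(p * log(p))
}
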
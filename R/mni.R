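# Microbiome network of individual (MNI): per-sample direct-association
# networks by leave-one-out interpolation of the population partial
# correlations. With r(N) the population partial correlation and r(N/q) the
# estimate with sample q held out, the sample-specific edge score is
#
#     l(q) = N * r(N) - (N - 1) * r(N/q)
#
# so that the average of l(q) over samples returns (approximately) r(N),
# and a sample whose removal strengthens an association is flagged as
# weak on that edge.

#' Leave-one-out partial correlations
#'
#' Re-runs the inference with sample `q` removed, under identical settings
#' as the full fit. When `support` is given (the default route inside
#' [mni()]), the population topology is held fixed and only the edge
#' magnitudes are refit on the remaining N - 1 samples, so the leave-one-out
#' estimate is a smooth function of the data and score differences are
#' attributable to the held-out sample. Otherwise edge selection is redone
#' at the supplied penalty.
#'
#' @param clr CLR matrix, samples x taxa.
#' @param q sample index (or sample identifier) to hold out.
#' @param lambda penalty for re-selection (ignored when `support` given).
#' @param support optional fixed symmetric support (logical matrix).
#' @param ... further arguments passed to [estimate_precision()].
#' @return a `partial_correlation` on the same taxon universe.
#' @export
loo_partial <- function(clr, q, lambda = NULL, support = NULL, ...) {
  if (is.character(q)) q <- match(q, rownames(clr))
  if (is.na(q) || q < 1 || q > nrow(clr)) stop("sample index q out of range")
  if (!is.null(support))
    return(refit_partial(clr[-q, , drop = FALSE], support))
  if (is.null(lambda)) stop("either lambda or support must be supplied")
  est <- estimate_precision(clr[-q, , drop = FALSE], selection = "fixed",
                            lambda = lambda, ...)
  precision_to_partial(est)
}

#' Refit partial correlations on a fixed support
#'
#' Unpenalized node-wise regressions restricted to the given topology,
#' assembled into a precision estimate and converted to partial
#' correlations.
#'
#' @param clr CLR matrix, samples x taxa.
#' @param support symmetric logical adjacency (zero diagonal) on the same
#'   taxon universe.
#' @return a `partial_correlation`.
#' @export
refit_partial <- function(clr, support) {
  if (!identical(dim(support), c(ncol(clr), ncol(clr))))
    stop("support dimensions do not match the taxon universe")
  xs <- scale(clr)
  omega <- .refit_omega(xs, support)
  taxa <- colnames(clr)
  dimnames(omega) <- list(taxa, taxa)
  est <- structure(list(taxon_ids = taxa, omega_inv = omega,
                        support = support, lambda_used = NA_real_,
                        method = "refit", n = nrow(clr)),
                   class = "precision_estimate")
  precision_to_partial(est)
}

#' Per-sample edge scores from full and leave-one-out partial correlations
#'
#' Computes `l = N * r_full - (N - 1) * r_loo` entrywise; the diagonal is
#' set to 0 by convention.
#'
#' @param r_full `partial_correlation` from all N samples.
#' @param r_loo `partial_correlation` with one sample held out.
#' @param N number of samples in the full fit.
#' @param sample_id identifier of the held-out sample.
#' @return object of class `mni_edge_matrix`: list with `sample_id`,
#'   `taxon_ids`, `l` (symmetric score matrix, zero diagonal), `r_full`,
#'   `r_loo`, `N`.
#' @export
mni_scores <- function(r_full, r_loo, N, sample_id = NA_character_) {
  stopifnot(inherits(r_full, "partial_correlation"),
            inherits(r_loo, "partial_correlation"))
  if (!identical(r_full$taxon_ids, r_loo$taxon_ids))
    stop("full and leave-one-out fits are on different taxon universes")
  if (N < 2) stop("N must be at least 2")
  l <- N * r_full$rho - (N - 1) * r_loo$rho
  diag(l) <- 0
  structure(list(sample_id = sample_id, taxon_ids = r_full$taxon_ids,
                 l = l, r_full = r_full, r_loo = r_loo, N = N),
            class = "mni_edge_matrix")
}

#' Threshold an edge-score matrix into an individual network
#'
#' Candidate edges are, by default, the union of the full-data and
#' leave-one-out supports; an edge enters the individual's network when its
#' absolute score meets the threshold `tau`. The default `tau = "auto"`
#' anchors to the population fit: the smallest absolute partial correlation
#' retained by the population network, so an individual keeps an edge only
#' if it is at least as strong (for them) as the weakest population edge.
#' Isolated nodes are dropped, so node number varies between individuals.
#'
#' @param edge_matrix an `mni_edge_matrix`.
#' @param tau nonnegative threshold on `|l|`, or `"auto"`.
#' @param candidates `"union"` (full-data plus leave-one-out supports) or
#'   `"population"` (full-data support only).
#' @return object of class `mni_result`: list with `sample_id`, `edge_matrix`,
#'   `network` (weighted igraph), `tau`.
#' @export
mni_network <- function(edge_matrix, tau = "auto",
                        candidates = c("union", "population")) {
  stopifnot(inherits(edge_matrix, "mni_edge_matrix"))
  candidates <- match.arg(candidates)
  sup_full <- edge_matrix$r_full$support
  cand <- if (candidates == "union") sup_full | edge_matrix$r_loo$support
          else sup_full
  if (identical(tau, "auto")) {
    vals <- abs(edge_matrix$r_full$rho[sup_full])
    tau <- if (length(vals)) min(vals) else 0
  }
  if (!is.numeric(tau) || tau < 0) stop("tau must be a nonnegative number")
  w <- edge_matrix$l
  w[!cand | abs(w) < tau] <- 0
  g <- graph_from_weights(w, edge_matrix$taxon_ids)
  structure(list(sample_id = edge_matrix$sample_id,
                 edge_matrix = edge_matrix, network = g, tau = tau),
            class = "mni_result")
}

#' @export
print.mni_result <- function(x, ...) {
  cat(sprintf("MNI for sample '%s': %d nodes, %d edges (tau = %.4g)\n",
              x$sample_id, igraph::vcount(x$network),
              igraph::ecount(x$network), x$tau))
  invisible(x)
}

#' Fit individual microbiome networks for every sample
#'
#' The main fitting function: one population inference plus N leave-one-out
#' inferences, interpolated into one network per sample. By default
#' (`loo_mode = "reuse"`) the leave-one-out fits keep the population fit's
#' selected penalty and topology, refitting only the edge magnitudes on the
#' remaining samples, so score differences are attributable to the sample
#' rather than to selection jitter; `"fixed-lambda"` redoes edge selection
#' per fold at the population penalty, and `"reselect"` redoes the full
#' selection including the penalty.
#'
#' @param clr CLR matrix, samples x taxa (N >= 4).
#' @param lambda_min,n_lambda,selection,lambda,method,sym,stars_reps,stars_thresh,subsample_ratio
#'   passed to [estimate_precision()] for the population fit.
#' @param tau edge threshold for [mni_network()].
#' @param candidates candidate-edge rule for [mni_network()].
#' @param loo_mode `"reuse"` (default), `"fixed-lambda"`, or `"reselect"`.
#' @return object of class `mni_fit`: list with `full` (the population
#'   `precision_estimate`), `r_full`, `mnp` (population network), `results`
#'   (list of `mni_result`, one per sample), `N`, `taxon_ids`, `settings`.
#' @export
mni <- function(clr,
                lambda_min = 0.01, n_lambda = 20,
                selection = c("stars", "fixed"), lambda = NULL,
                method = c("mb", "glasso"), sym = c("or", "and"),
                stars_reps = 20, stars_thresh = 0.05, subsample_ratio = NULL,
                tau = "auto", candidates = c("union", "population"),
                loo_mode = c("reuse", "fixed-lambda", "reselect")) {
  selection <- match.arg(selection); method <- match.arg(method)
  sym <- match.arg(sym); candidates <- match.arg(candidates)
  loo_mode <- match.arg(loo_mode)
  N <- nrow(clr)
  if (N < 4) stop("need at least 4 samples for leave-one-out inference")
  if (is.null(rownames(clr))) rownames(clr) <- paste0("s", seq_len(N))

  full <- estimate_precision(clr, lambda_min = lambda_min, n_lambda = n_lambda,
                             selection = selection, lambda = lambda,
                             method = method, sym = sym,
                             stars_reps = stars_reps,
                             stars_thresh = stars_thresh,
                             subsample_ratio = subsample_ratio)
  r_full <- precision_to_partial(full)
  results <- vector("list", N)
  for (q in seq_len(N)) {
    r_loo <- switch(loo_mode,
      "reuse" = loo_partial(clr, q, support = full$support),
      "fixed-lambda" = loo_partial(clr, q, lambda = full$lambda_used,
                                   lambda_min = lambda_min,
                                   n_lambda = n_lambda, method = method,
                                   sym = sym),
      "reselect" = {
        est <- estimate_precision(clr[-q, , drop = FALSE],
                                  lambda_min = lambda_min,
                                  n_lambda = n_lambda,
                                  selection = selection, lambda = lambda,
                                  method = method, sym = sym,
                                  stars_reps = stars_reps,
                                  stars_thresh = stars_thresh,
                                  subsample_ratio = subsample_ratio)
        precision_to_partial(est)
      })
    em <- mni_scores(r_full, r_loo, N, sample_id = rownames(clr)[q])
    results[[q]] <- mni_network(em, tau = tau, candidates = candidates)
  }
  names(results) <- rownames(clr)
  structure(list(full = full, r_full = r_full, mnp = build_mnp(r_full),
                 results = results, N = N, taxon_ids = full$taxon_ids,
                 settings = list(lambda_min = lambda_min, n_lambda = n_lambda,
                                 selection = selection, method = method,
                                 sym = sym, tau = tau, candidates = candidates,
                                 loo_mode = loo_mode,
                                 lambda_used = full$lambda_used)),
            class = "mni_fit")
}

#' @rdname mni
#' @param ... arguments passed on to [mni()].
#' @export
mni_all <- function(clr, ...) mni(clr, ...)

#' @export
print.mni_fit <- function(x, ...) {
  cat(sprintf("MNI fit: %d samples, %d taxa, lambda = %.4g (%s)\n",
              x$N, length(x$taxon_ids), x$settings$lambda_used,
              x$settings$selection))
  cat(sprintf("Population network: %d nodes, %d edges\n",
              igraph::vcount(x$mnp), igraph::ecount(x$mnp)))
  ec <- vapply(x$results, function(r) igraph::ecount(r$network), numeric(1))
  cat(sprintf("Individual networks: edge number median %g (range %g-%g)\n",
              stats::median(ec), min(ec), max(ec)))
  invisible(x)
}

#' @export
summary.mni_fit <- function(object, ...) {
  tab <- data.frame(
    sample_id = names(object$results),
    node_number = vapply(object$results,
                         function(r) igraph::vcount(r$network), numeric(1)),
    edge_number = vapply(object$results,
                         function(r) igraph::ecount(r$network), numeric(1)),
    row.names = NULL)
  structure(list(table = tab, N = object$N,
                 lambda_used = object$settings$lambda_used),
            class = "summary.mni_fit")
}

#' @export
print.summary.mni_fit <- function(x, ...) {
  cat(sprintf("MNI fit of %d samples (lambda = %.4g)\n", x$N, x$lambda_used))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("... (", nrow(x$table) - 10, " more)\n", sep = "")
  invisible(x)
}

#' @export
plot.mni_fit <- function(x, sample = 1, ...) {
  r <- if (is.character(sample)) x$results[[sample]] else x$results[[sample]]
  if (is.null(r)) stop("no such sample")
  g <- r$network
  if (igraph::vcount(g) == 0) {
    graphics::plot.new()
    graphics::title(main = paste("MNI", r$sample_id, "(empty)"))
    return(invisible(x))
  }
  igraph::plot.igraph(g, edge.width = abs(igraph::E(g)$weight) * 3,
                      edge.color = ifelse(igraph::E(g)$weight > 0,
                                          "steelblue", "firebrick"),
                      main = paste("MNI", r$sample_id), ...)
  invisible(x)
}
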
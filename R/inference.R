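# Sparse inverse-covariance (direct association) network inference on CLR data.
#
# The default engine is neighborhood selection: one lasso regression per taxon
# on all other taxa, edges where the coefficient is nonzero, OR/AND
# symmetrization. Edge magnitudes are then refit without penalty on the
# selected support (each node regressed on its selected neighbors), and the
# coefficients and residual variances are assembled into a symmetric
# precision estimate through the regression/precision identity
# omega_ii = 1/s2_i, omega_ij = -beta_ij / s2_i (symmetrized by averaging),
# which is exact for full-conditional regressions. The refit magnitudes are
# smooth functions of the data for a fixed support — a property the
# per-sample network extraction relies on.

#' Estimate a sparse precision (inverse covariance) matrix
#'
#' @param clr CLR-transformed matrix, samples x taxa (see [clr_transform()]).
#' @param lambda_min smallest penalty on the regularization path.
#' @param n_lambda number of log-spaced penalties on the path.
#' @param selection `"stars"` for StARS stability selection over the path
#'   (uses the session RNG), or `"fixed"` to use `lambda` directly.
#' @param lambda penalty for `selection = "fixed"`.
#' @param method `"mb"` (neighborhood selection) or `"glasso"`
#'   (block-coordinate graphical lasso, mainly for cross-checking).
#' @param sym symmetrization rule for neighborhood selection: `"or"` keeps
#'   an edge if either regression selects it, `"and"` requires both.
#' @param stars_reps number of StARS subsamples.
#' @param stars_thresh StARS edge-instability threshold.
#' @param subsample_ratio StARS subsample size as a fraction of N; default
#'   `min(10 * sqrt(N), 0.8 * N) / N`.
#' @param refit refit edge magnitudes on the selected support by unpenalized
#'   node-wise regressions (default TRUE); FALSE keeps the penalized
#'   coefficients.
#' @return object of class `precision_estimate`: list with `taxon_ids`,
#'   `omega_inv`, `support` (logical adjacency, zero diagonal),
#'   `lambda_used`, `lambda_path`, `method`, `instability` (StARS only).
#' @export
estimate_precision <- function(clr,
                               lambda_min = 0.01,
                               n_lambda = 20,
                               selection = c("stars", "fixed"),
                               lambda = NULL,
                               method = c("mb", "glasso"),
                               sym = c("or", "and"),
                               stars_reps = 20,
                               stars_thresh = 0.05,
                               subsample_ratio = NULL,
                               refit = TRUE) {
  selection <- match.arg(selection)
  method <- match.arg(method)
  sym <- match.arg(sym)
  if (!is.matrix(clr) || !is.numeric(clr)) stop("clr must be a numeric matrix")
  n <- nrow(clr); p <- ncol(clr)
  if (n < 3) stop("need at least 3 samples for network inference")
  if (p < 2) stop("need at least 2 taxa")
  if (lambda_min <= 0) stop("lambda_min must be positive")
  sds <- apply(clr, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(clr)[sds == 0], collapse = ", "))
  xs <- scale(clr)  # standardized working matrix

  path <- .lambda_path(xs, lambda_min, n_lambda)
  instab <- NULL
  if (selection == "fixed") {
    if (is.null(lambda)) stop("selection = 'fixed' requires lambda")
    lambda_used <- lambda
  } else {
    if (is.null(subsample_ratio)) {
      b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
      b <- max(b, 3)
    } else b <- max(3, floor(subsample_ratio * n))
    instab <- .stars_instability(xs, path, b, stars_reps, method, sym)
    dbar <- cummax(instab)               # path runs from large to small lambda
    ok <- which(dbar <= stars_thresh)
    lambda_used <- path[if (length(ok)) max(ok) else 1L]
  }

  fit <- if (method == "mb") .mb_fit(xs, lambda_used, sym)
         else .glasso_fit(xs, lambda_used)
  if (refit && method == "mb") {
    ref <- .refit_omega(xs, fit$support)
    fit$omega <- ref
  }
  taxa <- colnames(clr)
  dimnames(fit$omega) <- list(taxa, taxa)
  dimnames(fit$support) <- list(taxa, taxa)
  structure(list(taxon_ids = taxa,
                 omega_inv = fit$omega,
                 support = fit$support,
                 lambda_used = lambda_used,
                 lambda_path = path,
                 method = method,
                 sym = sym,
                 instability = instab,
                 n = n),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- length(x$taxon_ids)
  ne <- sum(x$support[upper.tri(x$support)])
  cat(sprintf("Sparse precision estimate (%s): %d taxa, %d edges, lambda = %.4g\n",
              x$method, p, ne, x$lambda_used))
  invisible(x)
}

# log-spaced lambda path from the empirical lambda_max down to lambda_min
.lambda_path <- function(xs, lambda_min, n_lambda) {
  n <- nrow(xs)
  r <- stats::cov(xs) * (n - 1) / n
  diag(r) <- 0
  lmax <- max(abs(r))
  if (!is.finite(lmax) || lmax <= lambda_min) lmax <- lambda_min * 10
  exp(seq(log(lmax), log(lambda_min), length.out = n_lambda))
}

# Lasso coefficients of node regressions at every lambda on the path.
# Returns list(beta = array p x p x L (beta[i, j, ]: predictor j in the
# regression of node i), s2 = matrix p x L of residual variances).
.mb_path_fit <- function(xs, path) {
  n <- nrow(xs); p <- ncol(xs); L <- length(path)
  beta <- array(0, dim = c(p, p, L))
  s2 <- matrix(1, p, L)
  for (i in seq_len(p)) {
    y <- xs[, i]
    X <- xs[, -i, drop = FALSE]
    if (p == 2) {
      # single predictor: closed-form lasso on standardized data
      r <- sum(X[, 1] * y) / n
      for (l in seq_len(L)) {
        b <- sign(r) * max(abs(r) - path[l], 0)
        beta[i, -i, l] <- b
        s2[i, l] <- mean((y - X[, 1] * b)^2)
      }
    } else {
      fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = path,
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-9)
      bmat <- as.matrix(fit$beta)  # (p-1) x length(fit$lambda)
      # glmnet may drop trailing lambdas; map back onto the requested path
      idx <- match(round(path, 10), round(fit$lambda, 10))
      for (l in seq_len(L)) {
        bl <- if (is.na(idx[l])) {
          # refit single lambda (rare)
          as.numeric(glmnet::glmnet(X, y, lambda = path[l], standardize = FALSE,
                                    intercept = FALSE, thresh = 1e-9)$beta)
        } else bmat[, idx[l]]
        beta[i, -i, l] <- bl
        s2[i, l] <- mean((y - X %*% bl)^2)
      }
    }
  }
  list(beta = beta, s2 = s2)
}

# Assemble a symmetric precision estimate from node-wise coefficients.
.mb_assemble <- function(beta, s2, sym) {
  p <- nrow(beta)
  sel <- beta != 0
  support <- if (sym == "or") (sel | t(sel)) else (sel & t(sel))
  diag(support) <- FALSE
  s2 <- pmax(s2, 1e-12)
  omega <- -(beta / s2 + t(beta / s2)) / 2
  omega[!support] <- 0
  diag(omega) <- 1 / s2
  list(omega = omega, support = support)
}

.mb_fit <- function(xs, lambda, sym) {
  pf <- .mb_path_fit(xs, lambda)
  .mb_assemble(pf$beta[, , 1], pf$s2[, 1, drop = TRUE], sym)
}

# Unpenalized node-wise refit of magnitudes on a fixed symmetric support:
# each node regressed (OLS) on its supported neighbors; omega assembled via
# omega_ii = 1/s2_i, omega_ij = -(b_ij/s2_i + b_ji/s2_j)/2. Smooth in the
# data for fixed support.
.refit_omega <- function(xs, support) {
  n <- nrow(xs); p <- ncol(xs)
  beta <- matrix(0, p, p)
  s2 <- numeric(p)
  for (i in seq_len(p)) {
    nb <- which(support[i, ])
    y <- xs[, i]
    if (length(nb) == 0) {
      s2[i] <- mean(y^2)
    } else {
      X <- xs[, nb, drop = FALSE]
      b <- qr.coef(qr(X), y)
      b[is.na(b)] <- 0
      beta[i, nb] <- b
      s2[i] <- mean((y - X %*% b)^2)
    }
  }
  s2 <- pmax(s2, 1e-10)
  omega <- -(beta / s2 + t(beta / s2)) / 2
  omega[!support] <- 0
  diag(omega) <- 1 / s2
  omega
}

# StARS: mean edge instability 2*theta*(1-theta) per lambda across subsamples.
.stars_instability <- function(xs, path, b, reps, method, sym) {
  n <- nrow(xs); p <- ncol(xs); L <- length(path)
  counts <- array(0, dim = c(p, p, L))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, b)
    xsub <- scale(xs[idx, , drop = FALSE])
    if (any(!is.finite(xsub))) next
    if (method == "mb") {
      pf <- .mb_path_fit(xsub, path)
      for (l in seq_len(L)) {
        a <- .mb_assemble(pf$beta[, , l], pf$s2[, l], sym)
        counts[, , l] <- counts[, , l] + a$support
      }
    } else {
      for (l in seq_len(L)) {
        g <- .glasso_fit(xsub, path[l])
        counts[, , l] <- counts[, , l] + g$support
      }
    }
  }
  theta <- counts / reps
  xi <- 2 * theta * (1 - theta)
  ut <- upper.tri(matrix(0, p, p))
  vapply(seq_len(L), function(l) mean(xi[, , l][ut]), numeric(1))
}

# Block-coordinate graphical lasso (Friedman-style), small-p implementation.
.glasso_fit <- function(xs, rho, maxit = 200, tol = 1e-5) {
  n <- nrow(xs); p <- ncol(xs)
  S <- stats::cov(xs) * (n - 1) / n
  W <- S + rho * diag(p)
  B <- matrix(0, p, p)  # column j: lasso coefficients for block j
  for (it in seq_len(maxit)) {
    Wold <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      bj <- B[-j, j]
      # coordinate descent on: minimize 1/2 b' W11 b - s12' b + rho ||b||_1
      for (sweep in 1:50) {
        bold <- bj
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, ] * bj) + W11[k, k] * bj[k]
          bj[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(bj - bold)) < tol * 1e-2) break
      }
      B[-j, j] <- bj
      W[-j, j] <- W11 %*% bj
      W[j, -j] <- W[-j, j]
    }
    if (mean(abs(W - Wold)) < tol * mean(abs(S))) break
  }
  omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    denom <- W[j, j] - sum(W[-j, j] * B[-j, j])
    omega[j, j] <- 1 / denom
    omega[-j, j] <- -B[-j, j] * omega[j, j]
  }
  omega <- (omega + t(omega)) / 2
  support <- abs(omega) > 1e-8
  diag(support) <- FALSE
  omega[!support & row(omega) != col(omega)] <- 0
  list(omega = omega, support = support)
}

#' Convert a precision estimate to partial correlations
#'
#' Off-diagonal partial correlation `rho_ij = -omega_ij / sqrt(omega_ii *
#' omega_jj)`; diagonal 1. For a `precision_estimate` input the sparsity
#' support is carried through and `rho` is zero off-support.
#'
#' @param est a `precision_estimate`, or a symmetric numeric matrix with
#'   strictly positive diagonal.
#' @return object of class `partial_correlation`: list with `taxon_ids`,
#'   `rho` (symmetric, unit diagonal), `support`, `n`.
#' @export
precision_to_partial <- function(est) {
  if (inherits(est, "precision_estimate")) {
    omega <- est$omega_inv; support <- est$support
    taxa <- est$taxon_ids; n <- est$n
  } else {
    omega <- est
    if (!is.matrix(omega) || nrow(omega) != ncol(omega))
      stop("est must be a precision_estimate or a square matrix")
    support <- abs(omega) > 0
    diag(support) <- FALSE
    taxa <- colnames(omega)
    if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(omega)))
    n <- NA_integer_
  }
  d <- diag(omega)
  if (any(d <= 0)) stop("precision matrix has nonpositive diagonal entries")
  rho <- -omega / sqrt(tcrossprod(d))
  rho[!support] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(taxa, taxa)
  structure(list(taxon_ids = taxa, rho = rho, support = support, n = n),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  ne <- sum(x$support[upper.tri(x$support)])
  cat(sprintf("Partial correlation matrix: %d taxa, %d supported edges\n",
              length(x$taxon_ids), ne))
  invisible(x)
}

#' Build the population network (MNP) from partial correlations
#'
#' Nodes are taxa with at least one supported edge (isolated taxa are
#' excluded, so node number varies between networks); edges carry the
#' partial correlation as weight.
#'
#' @param pcm a `partial_correlation` object.
#' @return an undirected weighted [igraph::igraph] graph.
#' @export
build_mnp <- function(pcm) {
  stopifnot(inherits(pcm, "partial_correlation"))
  graph_from_weights(pcm$rho * pcm$support, pcm$taxon_ids)
}

# weighted adjacency (0 = no edge) -> igraph with isolated nodes dropped
graph_from_weights <- function(w, taxa) {
  w[lower.tri(w, diag = TRUE)] <- 0
  idx <- which(w != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  el <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                   weight = w[idx], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}
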
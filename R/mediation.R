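# Mediation and moderated-mediation (conditional process) models linking a
# dichotomous exposure X, a continuous mediator M, and a continuous outcome
# Y, estimated by ordinary least squares with percentile-bootstrap intervals
# for the indirect (product-of-coefficients) effects.

#' Yeo-Johnson normalization
#'
#' Power-transforms a continuous variable with the Yeo-Johnson family
#' (defined on all reals), the parameter chosen by maximum likelihood, and
#' standardizes the result to mean 0 and sd 1. The transform is monotone,
#' so ranks are preserved.
#'
#' @param values finite numeric vector, length >= 3, non-constant.
#' @return list with `values` (the standardized transform) and `lambda`.
#' @export
yeo_johnson <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0)
    stop("constant vector: Yeo-Johnson transform undefined")
  pt <- car::powerTransform(values, family = "yjPower")
  lam <- unname(pt$lambda)
  y <- car::yjPower(values, lam)
  list(values = as.numeric(scale(y)), lambda = lam)
}

.check_dichotomous <- function(x, name) {
  if (!all(x %in% c(0, 1)))
    stop(name, " must be coded 0/1")
  if (length(unique(x)) < 2)
    stop(name, " must have both levels present")
}

# OLS slope p-values for a response on a design matrix with intercept;
# aliased (collinear) columns get NA, zero-residual fits get p = 0.
.ols_p <- function(y, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("v", seq_along(df))
  fit <- stats::lm(y ~ ., data = df)
  co <- stats::coef(summary(fit))
  out <- rep(NA_real_, ncol(X) + 1)
  names(out) <- c("(Intercept)", names(df))
  pv <- co[, 4]
  pv[!is.finite(pv) & abs(co[, 3]) > 1e8] <- 0
  out[rownames(co)] <- pv
  out
}

# two-predictor OLS slopes on centered data with a collinearity fallback:
# when M and X are (numerically) collinear the effect is attributed to the
# mediator (b = cov(M,Y)/var(M), c = 0), which is the limit of the noiseless
# construction M = a*X.
.two_pred_slopes <- function(smm, sxm, sxx, smy, sxy) {
  det <- smm * sxx - sxm^2
  deg <- !is.finite(det) | det <= 1e-12 * pmax(smm * sxx, 1e-300)
  b <- (smy * sxx - sxy * sxm) / det
  cc <- (smm * sxy - sxm * smy) / det
  b[deg] <- (smy / smm)[deg]
  cc[deg] <- 0
  list(b = b, c = cc)
}

# vectorized bootstrap of (a, b, c) over B joint row-resamples
.boot_paths <- function(X, M, Y, B) {
  n <- length(X)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  Xb <- matrix(X[idx], n, B); Mb <- matrix(M[idx], n, B)
  Yb <- matrix(Y[idx], n, B)
  Xc <- sweep(Xb, 2, colMeans(Xb)); Mc <- sweep(Mb, 2, colMeans(Mb))
  Yc <- sweep(Yb, 2, colMeans(Yb))
  sxx <- colSums(Xc^2); sxm <- colSums(Xc * Mc)
  a <- sxm / sxx
  smm <- colSums(Mc^2); smy <- colSums(Mc * Yc); sxy <- colSums(Xc * Yc)
  sl <- .two_pred_slopes(smm, sxm, sxx, smy, sxy)
  ok <- is.finite(a) & is.finite(sl$b) & is.finite(sl$c)
  list(a = a[ok], b = sl$b[ok], c = sl$c[ok])
}

#' Fit a three-variable mediation model
#'
#' Path `a` from the mediator model `M ~ X`; paths `b` (mediator) and `c`
#' (direct) from the outcome model `Y ~ M + X`. The mediation (indirect)
#' effect is `a*b`, the total effect `a*b + c`. Uncertainty for the product
#' terms comes from a joint-row percentile bootstrap; per-path p-values from
#' the OLS fits. Variables are fitted as given; apply [yeo_johnson()]
#' beforehand (or use [screen_models()]) for normalized analyses.
#'
#' @param X dichotomous exposure, coded 0/1, both levels present.
#' @param M continuous mediator.
#' @param Y continuous outcome.
#' @param n_boot bootstrap resamples (default 5000; < 200 warns).
#' @param seed optional integer seed for the bootstrap.
#' @param conf_level confidence level for percentile intervals.
#' @return object of class `mediation_fit` with elements `a`, `b`, `c`,
#'   `mediation_effect`, `total_effect`, `ci` (matrix with rows a, b, c,
#'   mediation, total), `p` (named vector a, b, c), `n`, `n_boot`.
#' @export
fit_mediation <- function(X, M, Y, n_boot = 5000, seed = NULL,
                          conf_level = 0.95) {
  n <- length(X)
  if (length(M) != n || length(Y) != n) stop("X, M, Y must be aligned")
  if (n < 10) stop("need at least 10 samples")
  .check_dichotomous(X, "X")
  if (n_boot < 200) warning("n_boot < 200: bootstrap intervals are unstable")
  if (!is.null(seed)) set.seed(seed)

  Xc <- X - mean(X); Mc <- M - mean(M); Yc <- Y - mean(Y)
  a <- sum(Xc * Mc) / sum(Xc^2)
  sl <- .two_pred_slopes(sum(Mc^2), sum(Mc * Xc), sum(Xc^2),
                         sum(Mc * Yc), sum(Xc * Yc))
  b <- sl$b; cc <- sl$c

  p_a <- .ols_p(M, cbind(X))[2]
  p_out <- .ols_p(Y, cbind(M, X))
  bt <- .boot_paths(X, M, Y, n_boot)
  alpha <- (1 - conf_level) / 2
  qs <- function(v) stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
  ci <- rbind(a = qs(bt$a), b = qs(bt$b), c = qs(bt$c),
              mediation = qs(bt$a * bt$b),
              total = qs(bt$a * bt$b + bt$c))
  colnames(ci) <- c("lower", "upper")
  structure(list(a = a, b = b, c = cc,
                 mediation_effect = a * b, total_effect = a * b + cc,
                 ci = ci,
                 p = c(a = unname(p_a), b = unname(p_out[2]),
                       c = unname(p_out[3])),
                 n = n, n_boot = n_boot, conf_level = conf_level),
            class = "mediation_fit")
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c,
    mediation = object$mediation_effect, total = object$total_effect)
}

#' @export
confint.mediation_fit <- function(object, parm, level, ...) object$ci

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation fit (n = %d, %d bootstrap resamples)\n", x$n, x$n_boot))
  cat(sprintf("  a = %.4g (p = %.3g), b = %.4g (p = %.3g), c = %.4g (p = %.3g)\n",
              x$a, x$p["a"], x$b, x$p["b"], x$c, x$p["c"]))
  cat(sprintf("  mediation a*b = %.4g [%.4g, %.4g], total = %.4g [%.4g, %.4g]\n",
              x$mediation_effect, x$ci["mediation", 1], x$ci["mediation", 2],
              x$total_effect, x$ci["total", 1], x$ci["total", 2]))
  invisible(x)
}

#' @export
summary.mediation_fit <- function(object, ...) {
  out <- data.frame(estimate = coef(object),
                    lower = object$ci[, 1], upper = object$ci[, 2])
  out$p_value <- c(object$p, NA, NA)
  out
}

#' Fit a moderated-mediation (conditional process) model
#'
#' Mediator model `M ~ a1*X + a2*W + a3*(X*W)`; outcome model `Y ~ b*M +
#' c*X`. The index of moderated mediation is `a3*b`: the change in the
#' indirect effect per unit of the moderator. Conditional indirect effects
#' are `(a1 + a3*w)*b` at moderator level w.
#'
#' @inheritParams fit_mediation
#' @param W dichotomous moderator, coded 0/1; all four X x W cells must be
#'   nonempty.
#' @return object of class `conditional_process_fit` (extends
#'   `mediation_fit`) with additional elements `a1`, `a2`, `a3`,
#'   `index_mod_med`, `r_squared`, and rows `a1`, `a3`, `index` in `ci`.
#' @export
fit_conditional_process <- function(X, W, M, Y, n_boot = 5000, seed = NULL,
                                    conf_level = 0.95) {
  n <- length(X)
  if (length(W) != n || length(M) != n || length(Y) != n)
    stop("X, W, M, Y must be aligned")
  if (n < 10) stop("need at least 10 samples")
  .check_dichotomous(X, "X"); .check_dichotomous(W, "W")
  cells <- table(factor(X, c(0, 1)), factor(W, c(0, 1)))
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty X x W cell: X = %s, W = %s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  if (n_boot < 200) warning("n_boot < 200: bootstrap intervals are unstable")
  if (!is.null(seed)) set.seed(seed)

  med_fit <- function(X, W, M) {
    Dm <- cbind(1, X, W, X * W)
    qr.coef(qr(Dm), M)
  }
  out_fit <- function(M, X, Y) {
    Do <- cbind(1, M, X)
    qr.coef(qr(Do), Y)
  }
  am <- med_fit(X, W, M)
  a1 <- am[2]; a2 <- am[3]; a3 <- am[4]
  oc <- out_fit(M, X, Y)
  b <- oc[2]; cc <- oc[3]

  p_med <- .ols_p(M, cbind(X, W, X * W))
  p_out <- .ols_p(Y, cbind(M, X))
  fitted_y <- cbind(1, M, X) %*% out_fit(M, X, Y)
  r2 <- 1 - sum((Y - fitted_y)^2) / sum((Y - mean(Y))^2)

  B <- n_boot
  a1b <- a3b <- bb <- numeric(B)
  keep <- logical(B)
  for (r in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    Xi <- X[i]; Wi <- W[i]
    if (length(unique(Xi)) < 2 || length(unique(Wi)) < 2) next
    ami <- tryCatch(med_fit(Xi, Wi, M[i]), error = function(e) NULL)
    if (is.null(ami) || anyNA(ami)) next
    oci <- out_fit(M[i], Xi, Y[i])
    a1b[r] <- ami[2]; a3b[r] <- ami[4]; bb[r] <- oci[2]
    keep[r] <- TRUE
  }
  a1b <- a1b[keep]; a3b <- a3b[keep]; bb <- bb[keep]
  alpha <- (1 - conf_level) / 2
  qs <- function(v) stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
  ci <- rbind(a1 = qs(a1b), a3 = qs(a3b), b = qs(bb),
              mediation = qs((a1b + a3b * mean(W)) * bb),
              index = qs(a3b * bb))
  colnames(ci) <- c("lower", "upper")
  a_mean <- a1 + a3 * mean(W)
  structure(list(a = unname(a_mean), b = unname(b), c = unname(cc),
                 a1 = unname(a1), a2 = unname(a2), a3 = unname(a3),
                 mediation_effect = unname(a_mean * b),
                 total_effect = unname(a_mean * b + cc),
                 index_mod_med = unname(a3 * b),
                 r_squared = r2,
                 ci = ci,
                 p = c(a1 = unname(p_med[2]), a2 = unname(p_med[3]),
                       a3 = unname(p_med[4]), b = unname(p_out[2]),
                       c = unname(p_out[3])),
                 n = n, n_boot = n_boot, conf_level = conf_level),
            class = c("conditional_process_fit", "mediation_fit"))
}

#' @export
print.conditional_process_fit <- function(x, ...) {
  cat(sprintf("Conditional process fit (n = %d, R^2 = %.4f)\n", x$n, x$r_squared))
  cat(sprintf("  mediator model: a1 = %.4g (p = %.3g), a2 = %.4g (p = %.3g), a3 = %.4g (p = %.3g)\n",
              x$a1, x$p["a1"], x$a2, x$p["a2"], x$a3, x$p["a3"]))
  cat(sprintf("  outcome model:  b = %.4g (p = %.3g), c = %.4g (p = %.3g)\n",
              x$b, x$p["b"], x$c, x$p["c"]))
  cat(sprintf("  index of moderated mediation a3*b = %.4g [%.4g, %.4g]\n",
              x$index_mod_med, x$ci["index", 1], x$ci["index", 2]))
  invisible(x)
}

#' Screen mediation models over outcome and mediator rosters
#'
#' Fits every (outcome, mediator) pair in both directions — the candidate
#' mediator as M with the outcome as Y, and swapped — yielding
#' `length(outcomes) * length(mediators) * 2` rows. A row is flagged
#' significant when the bootstrap CI of the mediation effect excludes 0; a
#' pair is "one-directional" when exactly one of its two directions is
#' significant. Continuous variables are Yeo-Johnson-normalized by default
#' before fitting. No multiplicity correction is applied to the
#' significance flags; an FDR column (Benjamini-Hochberg on a rough normal
#' approximation of the indirect effect) is provided for reference.
#'
#' @param outcomes named list (or data.frame) of continuous outcome vectors.
#' @param mediators named list (or data.frame) of continuous mediator vectors.
#' @param X dichotomous exposure, coded 0/1.
#' @param n_boot bootstrap resamples per model.
#' @param seed optional integer seed.
#' @param normalize apply [yeo_johnson()] to each continuous variable first.
#' @param conf_level confidence level for the bootstrap intervals.
#' @return data.frame of class `model_screen`: outcome, mediator, direction,
#'   a, b, c, mediation, total, ci_lower, ci_upper, p_a, p_b, p_c,
#'   significant, one_directional, fdr.
#' @export
screen_models <- function(outcomes, mediators, X, n_boot = 5000, seed = NULL,
                          normalize = TRUE, conf_level = 0.95) {
  outcomes <- as.list(as.data.frame(outcomes))
  mediators <- as.list(as.data.frame(mediators))
  if (length(outcomes) < 1 || length(mediators) < 1)
    stop("need at least one outcome and one mediator")
  if (length(intersect(names(outcomes), names(mediators))))
    stop("name collision between outcomes and mediators: ",
         paste(intersect(names(outcomes), names(mediators)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  if (normalize) {
    outcomes <- lapply(outcomes, function(v) yeo_johnson(v)$values)
    mediators <- lapply(mediators, function(v) yeo_johnson(v)$values)
  }
  rows <- list()
  for (o in names(outcomes)) {
    for (m in names(mediators)) {
      for (dir in c("mediator_as_M", "outcome_as_M")) {
        if (dir == "mediator_as_M") { Mv <- mediators[[m]]; Yv <- outcomes[[o]] }
        else { Mv <- outcomes[[o]]; Yv <- mediators[[m]] }
        f <- fit_mediation(X, Mv, Yv, n_boot = n_boot)
        sig <- f$ci["mediation", 1] > 0 || f$ci["mediation", 2] < 0
        se_ab <- diff(f$ci["mediation", ]) /
          (2 * stats::qnorm(1 - (1 - conf_level) / 2))
        rows[[length(rows) + 1]] <- data.frame(
          outcome = o, mediator = m, direction = dir,
          a = f$a, b = f$b, c = f$c,
          mediation = f$mediation_effect, total = f$total_effect,
          ci_lower = f$ci["mediation", 1], ci_upper = f$ci["mediation", 2],
          p_a = f$p["a"], p_b = f$p["b"], p_c = f$p["c"],
          significant = sig,
          z_approx = if (se_ab > 0) f$mediation_effect / se_ab else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  key <- paste(out$outcome, out$mediator)
  nsig <- tapply(out$significant, key, sum)[key]
  out$one_directional <- out$significant & nsig == 1
  out$fdr <- stats::p.adjust(2 * stats::pnorm(-abs(out$z_approx)), "BH")
  out$z_approx <- NULL
  class(out) <- c("model_screen", "data.frame")
  out
}

#' @export
print.model_screen <- function(x, ...) {
  cat(sprintf("Mediation model screen: %d models (%d significant, %d one-directional)\n",
              nrow(x), sum(x$significant), sum(x$one_directional)))
  sig <- x[x$significant, c("outcome", "mediator", "direction", "mediation",
                            "ci_lower", "ci_upper")]
  if (nrow(sig)) print(utils::head(as.data.frame(sig), 15), digits = 3)
  invisible(x)
}
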
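#' Filter taxa by prevalence
#'
#' Prevalence of a taxon is the fraction of samples in which it is observed
#' (abundance > 0). Taxa below the threshold are removed; samples are left
#' untouched. When `group` is supplied, prevalence is computed within each
#' group and a taxon is retained according to `group_mode`:
#' `"intersection"` (default) keeps taxa that meet the threshold in every
#' group, so all downstream networks share one node universe; `"union"`
#' keeps taxa that meet it in at least one group.
#'
#' @param x abundance matrix, samples x taxa.
#' @param min_prevalence fraction in \[0, 1\].
#' @param group optional factor/character of group labels, one per sample.
#' @param group_mode `"intersection"` or `"union"`.
#' @return filtered abundance matrix.
#' @export
filter_by_prevalence <- function(x, min_prevalence, group = NULL,
                                 group_mode = c("intersection", "union")) {
  validate_abundance(x)
  group_mode <- match.arg(group_mode)
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1 ||
      min_prevalence < 0 || min_prevalence > 1)
    stop("min_prevalence must be a single number in [0, 1]")
  if (is.null(group)) {
    prev <- colMeans(x > 0)
    keep <- prev >= min_prevalence
  } else {
    if (length(group) != nrow(x))
      stop("group must have one label per sample")
    per <- vapply(split(seq_len(nrow(x)), group),
                  function(i) colMeans(x[i, , drop = FALSE] > 0),
                  numeric(ncol(x)))
    keep <- if (group_mode == "intersection")
      apply(per >= min_prevalence, 1, all)
    else
      apply(per >= min_prevalence, 1, any)
  }
  if (!any(keep))
    stop("prevalence filter removed all taxa (threshold ", min_prevalence, ")")
  x[, keep, drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' @param x abundance matrix, samples x taxa; every sample must have a
#'   positive total.
#' @return matrix whose rows sum to 1.
#' @export
to_relative <- function(x) {
  validate_abundance(x)
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    bad <- rownames(x)[which(tot <= 0)[1]]
    stop("sample '", bad, "' has zero total abundance")
  }
  sweep(x, 1, tot, "/")
}

#' Centered log-ratio transform
#'
#' Per sample, takes log(value + pseudocount) and subtracts the sample's
#' mean log, so every row sums to zero. Differences of CLR values within a
#' sample equal log-ratios of the (pseudocounted) abundances, which is why
#' the CLR covariance approximates that of the latent absolute abundances
#' for compositional data. The transform is invariant to per-sample
#' rescaling, so counts and relative abundances give the same result when
#' the pseudocount is scaled accordingly (or is zero).
#'
#' @param x abundance matrix, samples x taxa.
#' @param pseudocount nonnegative value added before the log. Default: 0 if
#'   the table has no zeros; 1 for count-like tables (integers); half the
#'   smallest nonzero value otherwise.
#' @return real matrix, samples x taxa, rows centered to zero.
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  validate_abundance(x)
  if (is.null(pseudocount)) {
    if (!any(x == 0)) pseudocount <- 0
    else if (all(x == round(x)) && max(x) > 1) pseudocount <- 1
    else pseudocount <- min(x[x > 0]) / 2
  }
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(x == 0))
    stop("zeros present: a positive pseudocount is required")
  lx <- log(x + pseudocount)
  lx - rowMeans(lx)
}
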
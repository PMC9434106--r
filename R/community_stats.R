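#' PCA of standardized environmental variables
#'
#' Columns are z-scored, so the decomposition acts on the correlation
#' structure.  For reproducible output each principal axis is oriented so
#' that its largest-magnitude loading is positive.
#'
#' @param env numeric matrix or data.frame, samples x variables, complete
#'   (no missing cells), with at least 2 samples and 2 variables.
#' @return list of class \code{pca_result}: \code{scores} (samples x PCs),
#'   \code{loadings} (variables x PCs, orthonormal), \code{explained}
#'   (variance fractions per axis, non-increasing), \code{sdev}.
#' @export
pca_env <- function(env) {
  env <- as.matrix(env)
  if (!is.numeric(env)) stop("environmental matrix must be numeric")
  if (nrow(env) < 2 || ncol(env) < 2) stop("PCA needs at least 2 samples and 2 variables")
  if (anyNA(env)) stop("environmental matrix has missing cells")
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant environmental variable '%s' (sd = 0)",
                 colnames(env)[sds == 0][1]))
  fit <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| element of each axis positive
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  structure(list(scores = fit$x, loadings = fit$rotation,
                 explained = fit$sdev^2 / sum(fit$sdev^2), sdev = fit$sdev),
            class = "pca_result")
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson's partition of
#' squared distances), with free permutation of sample labels.  The p-value
#' is \code{(1 + #[permuted F >= observed F]) / (1 + n_perm)} and is
#' reproducible given the seed.  Computation is delegated to
#' \code{vegan::adonis2}.
#'
#' @param dist square symmetric dissimilarity matrix (e.g. a betaMNTD matrix)
#'   or a \code{dist} object.
#' @param grouping factor-like vector of group labels, one per sample; at
#'   least 2 groups.
#' @param n_perm number of permutations (default 999).
#' @param seed seed for the permutation stream.
#' @return list of class \code{permanova_result}: \code{pseudo_f},
#'   \code{r_squared}, \code{p_value}, \code{n_perm}, \code{grouping}.
#' @export
permanova <- function(dist, grouping, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(dist)
  grouping <- as.factor(grouping)
  n <- attr(d, "Size")
  if (length(grouping) != n) stop("grouping length does not match distance matrix")
  if (nlevels(droplevels(grouping)) < 2) stop("PERMANOVA needs at least 2 groups")
  set.seed(derive_seed(seed, "permanova"))
  df <- data.frame(g = grouping)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  structure(list(pseudo_f = fit$F[1], r_squared = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1], n_perm = n_perm,
                 grouping = deparse(substitute(grouping))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.4f (%.2f%%), p = %.4g (%d permutations)\n",
              x$pseudo_f, x$r_squared, 100 * x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 by iterative monotone regression over several
#' random starts (via \code{vegan::metaMDS}/\code{monoMDS}) and returns the
#' best configuration.  Convergence per start: stress improvement below 1e-6
#' or 500 iterations.
#'
#' @param dist square symmetric dissimilarity matrix or \code{dist}.
#' @param k embedding dimension (must be below the number of samples).
#' @param n_restarts random restarts (default 20).
#' @param seed seed for the restarts.
#' @return list of class \code{nmds_result}: \code{points} (samples x k),
#'   \code{stress} (Kruskal stress-1, in [0, 1]), \code{converged}.
#' @export
nmds <- function(dist, k = 2, n_restarts = 20, seed = 1L) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (k < 1) stop("k must be at least 1")
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of samples (%d)", k, n))
  set.seed(derive_seed(seed, "nmds"))
  fit <- vegan::metaMDS(d, k = k, trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE, expand = FALSE,
                        maxit = 500, sratmax = 0.999999)
  structure(list(points = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress = %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}
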
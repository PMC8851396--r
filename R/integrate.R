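#' Random-forest trait importance for treatment classification
#'
#' Bagged CART classifier with out-of-bag permutation importance: the
#' importance of a trait is the mean decrease in OOB classification accuracy
#' when that trait's values are shuffled. Deterministic for a given seed.
#'
#' @param traits numeric matrix or data.frame (samples x traits), no missing
#'   values
#' @param labels class labels, one per sample; >= 2 classes, >= 2 samples each
#' @param n_trees number of trees (default 500)
#' @param mtry features tried per split; default \code{floor(sqrt(p))}
#' @param min_node minimum node size to attempt a split (default 2)
#' @param seed integer RNG seed
#' @return list: \code{importance} (named, mean decrease accuracy),
#'   \code{rank} (1 = most important), \code{oob_accuracy}, \code{n_trees},
#'   \code{seed}
#' @export
rf_trait_importance <- function(traits, labels, n_trees = 500, mtry = NULL,
                                min_node = 2, seed = 1L) {
  X <- as.matrix(traits)
  if (!is.numeric(X)) stop("traits must be numeric")
  if (anyNA(X)) stop("missing trait values are not allowed")
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least two classes")
  if (any(table(f) < 2)) stop("every class needs at least two samples")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- .rf_importance_cpp(X, as.integer(f) - 1L, nlevels(f),
                            as.integer(n_trees), as.integer(mtry),
                            as.integer(min_node))
  imp <- as.numeric(res$importance)
  names(imp) <- colnames(X)
  list(importance = imp,
       rank = rank(-imp, ties.method = "first"),
       oob_accuracy = res$oob_accuracy,
       n_trees = as.integer(n_trees), seed = as.integer(seed))
}

#' Trait-metabolite Pearson correlation matrix
#'
#' Pearson correlation and two-sided p-value for every trait x compound pair
#' over samples aligned between the two blocks. No multiplicity correction by
#' default (set \code{adjust = "BH"} for Benjamini-Hochberg within each
#' trait). Constant compounds or traits yield \code{NA} correlations, flagged
#' invalid and never significant.
#'
#' @param trait_values numeric matrix/data.frame, samples x traits, with
#'   sample ids as row names
#' @param ft a [feature_table()] over the same samples
#' @param alpha significance level (default 0.05)
#' @param adjust "none" (default) or "BH"
#' @param log_abundance correlate traits with log2 abundances (default TRUE;
#'   Pearson r on raw lognormal intensities is badly attenuated)
#' @return data.frame: trait, compound_id, r, p, significant
#' @export
trait_metabolite_correlation <- function(trait_values, ft, alpha = 0.05,
                                         adjust = c("none", "BH"),
                                         log_abundance = TRUE) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(ft, "feature_table"))
  TV <- as.matrix(trait_values)
  mis <- setdiff(rownames(TV), rownames(ft$abundance))
  mis2 <- setdiff(rownames(ft$abundance), rownames(TV))
  if (length(mis) || length(mis2))
    stop("sample ids not aligned between blocks: ",
         paste(utils::head(c(mis, mis2), 5), collapse = ", "))
  A <- ft$abundance[rownames(TV), , drop = FALSE]
  if (log_abundance) A <- log2(A)
  n <- nrow(TV)
  if (n < 4) stop("need at least four aligned samples")

  out <- list()
  for (tr in colnames(TV)) {
    x <- TV[, tr]
    r <- suppressWarnings(stats::cor(x, A, use = "pairwise.complete.obs"))[1, ]
    # two-sided t-test p from r; pair-specific n accounts for missing cells
    npair <- colSums(!is.na(A) & is.finite(x))
    tstat <- r * sqrt(pmax(npair - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), pmax(npair - 2, 1), lower.tail = FALSE)
    p[!is.finite(r) | npair < 4] <- NA_real_
    if (adjust == "BH") p <- stats::p.adjust(p, "BH")
    out[[tr]] <- data.frame(trait = tr, compound_id = colnames(A),
                            r = as.numeric(r), p = as.numeric(p),
                            significant = !is.na(p) & p < alpha,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Escoufier's RV coefficient between two data blocks
#'
#' Multivariate generalisation of the squared Pearson correlation:
#' \code{RV = trace(XX'YY') / sqrt(trace((XX')^2) trace((YY')^2))} on
#' column-centered blocks. Lies in [0, 1]; invariant to orthogonal rotation
#' and global rescaling of either block.
#'
#' @param X,Y numeric matrices with the same number of rows (samples)
#' @return RV coefficient in [0, 1]
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  Sxy <- crossprod(Xc, Yc)
  Sxx <- crossprod(Xc)
  Syy <- crossprod(Yc)
  num <- sum(Sxy^2)
  den <- sqrt(sum(Sxx^2) * sum(Syy^2))
  if (den == 0) stop("zero total variance in one of the blocks")
  num / den
}

#' Co-inertia analysis of two matched data blocks
#'
#' SVD of the cross-covariance of the column-centered (optionally scaled)
#' blocks: paired axes maximise the covariance between block projections.
#' The RV coefficient is attached as the global concordance summary.
#'
#' @param X,Y numeric matrices over the same samples (rows)
#' @param n_axes number of co-inertia axes to keep; clipped to the smaller
#'   block dimension with a warning when too large
#' @param scale_x,scale_y per-block scaling, as in [opls_da_fit()]:
#'   "uv" is the trait-block convention, "pareto" the metabolite-block one
#' @return object of class \code{coinertia}: \code{axes_x}, \code{axes_y}
#'   (block loadings), \code{scores_x}, \code{scores_y}, \code{singular_values},
#'   \code{rv}
#' @export
coinertia <- function(X, Y, n_axes = 2,
                      scale_x = c("uv", "pareto", "none"),
                      scale_y = c("pareto", "uv", "none")) {
  scale_x <- match.arg(scale_x); scale_y <- match.arg(scale_y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  Xs <- .scale_block(X, scale_x)$X
  Ys <- .scale_block(Y, scale_y)$X
  kmax <- min(ncol(Xs), ncol(Ys))
  if (n_axes > kmax) {
    warning("n_axes clipped to ", kmax)
    n_axes <- kmax
  }
  s <- svd(crossprod(Ys, Xs) / nrow(Xs), nu = n_axes, nv = n_axes)
  structure(list(
    axes_x = s$v, axes_y = s$u,
    scores_x = Xs %*% s$v, scores_y = Ys %*% s$u,
    singular_values = s$d[seq_len(n_axes)],
    rv = rv_coefficient(Xs, Ys)
  ), class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat("Co-inertia analysis:", length(x$singular_values), "axes\n")
  cat("  singular values:",
      paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  cat(sprintf("  RV coefficient = %.4f\n", x$rv))
  invisible(x)
}

#' Permutation test for the RV coefficient
#'
#' Rows of Y are permuted \code{n_perm} times; the add-one estimator gives
#' the p-value of the observed RV against the permutation null.
#'
#' @inheritParams rv_coefficient
#' @param n_perm number of row permutations (default 199)
#' @param seed integer RNG seed
#' @return list: \code{p}, \code{rv_obs}, \code{rv_perm}
#' @export
rv_permutation_test <- function(X, Y, n_perm = 199, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  rv_obs <- rv_coefficient(X, Y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rv_perm <- vapply(seq_len(n_perm), function(i) {
    rv_coefficient(X, Y[sample(nrow(Y)), , drop = FALSE])
  }, numeric(1))
  list(p = (1 + sum(rv_perm >= rv_obs)) / (1 + n_perm),
       rv_obs = rv_obs, rv_perm = rv_perm)
}
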
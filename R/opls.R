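# Column scaling used across the multivariate tools. Unit-variance (uv)
# scaling is conventional for trait tables, Pareto for LC-MS intensities.
.scale_block <- function(X, scaling = c("pareto", "uv", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  scl <- switch(scaling, uv = sds, pareto = sqrt(sds),
                none = rep(1, ncol(X)))
  if (scaling != "none" && any(scl == 0)) {
    bad <- colnames(X)[scl == 0]
    if (is.null(bad)) bad <- which(scl == 0)
    stop("constant column(s) under ", scaling, " scaling: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl,
       scaling = scaling)
}

.one_hot <- function(classes) {
  f <- factor(classes)
  if (nlevels(f) < 2) stop("need at least two classes")
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  list(Y = Y, levels = levels(f), f = f)
}

# dominant left singular vector of X'Y (the converged NIPALS PLS2 weight),
# sign-fixed for determinism
.pls_weight <- function(X, Y) {
  s <- svd(crossprod(X, Y), nu = 1, nv = 0)
  w <- s$u[, 1]
  j <- which.max(abs(w))
  if (w[j] < 0) w <- -w
  list(w = w, sv = s$d[1])
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis: the
#' class matrix is one-hot encoded and centered, X is centered and scaled,
#' and \code{n_ortho} components orthogonal to the class-predictive variation
#' are extracted and removed before ordinary NIPALS PLS2 components are
#' fitted on the filtered matrix. With \code{n_ortho = 0} the model is plain
#' PLS-DA.
#'
#' @param X numeric matrix, samples x variables
#' @param classes class labels, one per row of X; >= 2 classes with >= 2
#'   samples each
#' @param n_ortho number of orthogonal components (>= 0)
#' @param scaling "pareto" (default, metabolomics convention), "uv" or "none"
#' @param n_pred number of predictive components; default
#'   \code{nlevels(classes) - 1}
#' @return object of class \code{opls_model}: predictive weights \code{W},
#'   scores \code{Tp}, loadings \code{P}, Y-loadings \code{C}, orthogonal
#'   \code{Wo}/\code{To}/\code{Po}, \code{R2Y}, \code{vip}, centering/scaling
#'   vectors and class encoding
#' @export
opls_da_fit <- function(X, classes, n_ortho = 1,
                        scaling = c("pareto", "uv", "none"),
                        n_pred = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  enc <- .one_hot(classes)
  if (any(table(enc$f) < 2)) stop("every class needs at least two samples")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  n <- nrow(X); p <- ncol(X); k <- ncol(enc$Y)
  if (is.null(n_pred)) n_pred <- k - 1L
  n_pred <- max(1L, min(n_pred, p, n - 1L))

  sc <- .scale_block(X, scaling)
  Xd <- sc$X
  ym <- colMeans(enc$Y)
  Y0 <- sweep(enc$Y, 2, ym)
  ssy_tot <- sum(Y0^2)

  Wo <- To <- Po <- NULL
  if (n_ortho > 0) {
    Wo <- matrix(0, p, n_ortho); To <- matrix(0, n, n_ortho)
    Po <- matrix(0, p, n_ortho)
    kept <- 0L
    for (a in seq_len(n_ortho)) {
      pw <- .pls_weight(Xd, Y0)
      t_p <- Xd %*% pw$w
      pl <- crossprod(Xd, t_p) / sum(t_p^2)
      # orthonormal basis of X'Y: variation predictive of any class contrast
      U <- qr.Q(qr(crossprod(Xd, Y0)))
      wo <- pl - U %*% crossprod(U, pl)
      nw <- sqrt(sum(wo^2))
      if (nw < 1e-12 * max(1, sqrt(sum(pl^2)))) break   # nothing orthogonal left
      wo <- wo / nw
      t_o <- Xd %*% wo
      p_o <- crossprod(Xd, t_o) / sum(t_o^2)
      Xd <- Xd - tcrossprod(t_o, p_o)
      kept <- kept + 1L
      Wo[, kept] <- wo; To[, kept] <- t_o; Po[, kept] <- p_o
    }
    if (kept < n_ortho) {
      Wo <- Wo[, seq_len(kept), drop = FALSE]
      To <- To[, seq_len(kept), drop = FALSE]
      Po <- Po[, seq_len(kept), drop = FALSE]
      n_ortho <- kept
    }
  }

  W <- matrix(0, p, n_pred); Tp <- matrix(0, n, n_pred)
  P <- matrix(0, p, n_pred); C <- matrix(0, k, n_pred)
  Yr <- Y0
  for (a in seq_len(n_pred)) {
    pw <- .pls_weight(Xd, Yr)
    if (pw$sv < 1e-12) { n_pred <- a - 1L; break }
    w <- pw$w
    t_p <- Xd %*% w
    cc <- crossprod(Yr, t_p) / sum(t_p^2)
    pl <- crossprod(Xd, t_p) / sum(t_p^2)
    Xd <- Xd - tcrossprod(t_p, pl)
    Yr <- Yr - tcrossprod(t_p, cc)
    W[, a] <- w; Tp[, a] <- t_p; P[, a] <- pl; C[, a] <- cc
  }
  if (n_pred < 1) stop("no predictive variation in X for these classes")
  W <- W[, seq_len(n_pred), drop = FALSE]
  Tp <- Tp[, seq_len(n_pred), drop = FALSE]
  P <- P[, seq_len(n_pred), drop = FALSE]
  C <- C[, seq_len(n_pred), drop = FALSE]
  vn <- colnames(X)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  rownames(W) <- rownames(P) <- vn
  if (!is.null(Wo)) rownames(Wo) <- rownames(Po) <- vn

  model <- structure(list(
    W = W, Tp = Tp, P = P, C = C,
    Wo = Wo, To = To, Po = Po, n_ortho = n_ortho, n_pred = n_pred,
    center = sc$center, scale = sc$scale, scaling = scaling,
    y_means = ym, levels = enc$levels, classes = enc$f,
    R2Y = 1 - sum(Yr^2) / ssy_tot,
    ssy_tot = ssy_tot
  ), class = "opls_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA: %d predictive + %d orthogonal component(s), %s scaling\n",
              x$n_pred, x$n_ortho, x$scaling))
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  R2Y = %.4f\n", x$R2Y))
  invisible(x)
}

#' Predict from an OPLS-DA model
#'
#' Applies the training centering/scaling, strips the stored orthogonal
#' components, projects on the predictive subspace and returns fitted class
#' scores and the arg-max class.
#'
#' @param object an [opls_da_fit()] model
#' @param newdata matrix with the training variables
#' @param ... unused
#' @return list with \code{scores} (predictive scores), \code{y} (fitted
#'   class-indicator values) and \code{class} (predicted labels)
#' @export
predict.opls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  if (object$n_ortho > 0) {
    for (a in seq_len(object$n_ortho)) {
      t_o <- X %*% object$Wo[, a]
      X <- X - tcrossprod(t_o, object$Po[, a])
    }
  }
  R <- object$W %*% solve(crossprod(object$P, object$W))
  Tn <- X %*% R
  Yh <- sweep(tcrossprod(Tn, object$C), 2, object$y_means, "+")
  colnames(Yh) <- object$levels
  list(scores = Tn, y = Yh,
       class = object$levels[max.col(Yh, ties.method = "first")])
}

#' VIP scores of an OPLS-DA model
#'
#' Variable importance in projection over the predictive components:
#' \code{VIP_j = sqrt(p * sum_a(SSY_a * (w_aj/||w_a||)^2) / sum_a SSY_a)}
#' where \code{SSY_a} is the Y-variance explained by component a. The mean of
#' squared VIPs is 1 by construction.
#'
#' @param model an [opls_da_fit()] model
#' @return numeric vector of VIP scores, one per variable
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "opls_model")) stop("model must be a fitted opls_model")
  W <- model$W
  p <- nrow(W)
  ssy <- vapply(seq_len(ncol(W)), function(a) {
    sum(model$Tp[, a]^2) * sum(model$C[, a]^2)
  }, numeric(1))
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.vector(wn^2 %*% ssy) / sum(ssy))
  names(v) <- rownames(W)
  v
}

#' Select discriminant variables by VIP threshold
#'
#' Strictly-greater-than filter on the VIP scores, returned in descending
#' VIP order. Published thresholds in this domain are typically 1.1-1.2.
#'
#' @param vip named numeric vector of VIP scores
#' @param threshold VIP cut-off, > 0
#' @return character vector of variable ids (or integer indices when the
#'   vector is unnamed), sorted by descending VIP
#' @export
select_discriminant <- function(vip, threshold = 1.2) {
  if (threshold <= 0) stop("threshold must be positive")
  ids <- if (is.null(names(vip))) seq_along(vip) else names(vip)
  sel <- vip > threshold
  ids[sel][order(vip[sel], decreasing = TRUE)]
}

# deterministic stratified fold assignment
.stratified_folds <- function(f, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(f))
  for (lev in levels(f)) {
    idx <- which(f == lev)
    fold[idx] <- ((sample(seq_along(idx)) - 1L) %% folds) + 1L
  }
  fold
}

# cross-validated PRESS / TSS of the class matrix
.opls_cv <- function(X, classes, n_ortho, folds, scaling, seed, n_pred = NULL) {
  X <- as.matrix(X)
  enc <- .one_hot(classes)
  minc <- min(table(enc$f))
  if (minc < folds) {
    warning("smallest class has ", minc, " samples; folds reduced to ", minc)
    folds <- minc
  }
  if (folds < 2) stop("need at least 2 samples per class for cross-validation")
  fold <- .stratified_folds(enc$f, folds, seed)
  press <- 0; tss <- 0; n_comp <- 0
  for (v in seq_len(folds)) {
    tr <- fold != v; te <- fold == v
    fit <- opls_da_fit(X[tr, , drop = FALSE], enc$f[tr], n_ortho = n_ortho,
                       scaling = scaling, n_pred = n_pred)
    n_comp <- max(n_comp, fit$n_pred + fit$n_ortho)
    pr <- predict(fit, X[te, , drop = FALSE])
    Yte <- enc$Y[te, fit$levels, drop = FALSE]
    press <- press + sum((Yte - pr$y)^2)
    tss <- tss + sum(sweep(Yte, 2, fit$y_means)^2)
  }
  list(press = press, tss = tss, n = nrow(X), k = ncol(enc$Y),
       n_comp = n_comp, folds = folds)
}

#' Cross-validated predictive ability Q2Y
#'
#' Stratified K-fold cross-validation of an OPLS-DA model:
#' \code{Q2Y = 1 - PRESS/TSS} over held-out class-matrix predictions, with a
#' deterministic fold assignment derived from \code{seed}. When a class has
#' fewer samples than folds, the fold count is reduced with a warning.
#'
#' @inheritParams opls_da_fit
#' @param folds number of cross-validation folds (default 7)
#' @param seed integer controlling the fold assignment
#' @return Q2Y (<= 1; negative when the model predicts worse than the mean)
#' @export
q2y <- function(X, classes, n_ortho = 1, folds = 7,
                scaling = c("pareto", "uv", "none"), seed = 1L,
                n_pred = NULL) {
  scaling <- match.arg(scaling)
  cv <- .opls_cv(X, classes, n_ortho, folds, scaling, seed, n_pred)
  1 - cv$press / cv$tss
}

#' Permutation test for OPLS-DA overfitting
#'
#' Class labels are permuted \code{n_perm} times and Q2Y recomputed with the
#' same fold scheme; the add-one estimator
#' \code{p = (1 + #[Q2_perm >= Q2_obs]) / (1 + n_perm)} avoids p = 0. The
#' permuted R2Y distribution is returned alongside.
#'
#' @inheritParams q2y
#' @param n_perm number of label permutations (default 200)
#' @return list: \code{p}, \code{q2_obs}, \code{q2_perm}, \code{r2_perm},
#'   \code{n_perm}
#' @export
permutation_test <- function(X, classes, n_perm = 200, seed = 1L,
                             n_ortho = 1, folds = 7,
                             scaling = c("pareto", "uv", "none"),
                             n_pred = NULL) {
  scaling <- match.arg(scaling)
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- as.matrix(X)
  f <- factor(classes)
  q2_obs <- q2y(X, f, n_ortho = n_ortho, folds = folds, scaling = scaling,
                seed = seed, n_pred = n_pred)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  q2_perm <- numeric(n_perm)
  r2_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    fp <- sample(f)
    q2_perm[i] <- suppressWarnings(
      q2y(X, fp, n_ortho = n_ortho, folds = folds, scaling = scaling,
          seed = seed, n_pred = n_pred))
    r2_perm[i] <- opls_da_fit(X, fp, n_ortho = n_ortho, scaling = scaling,
                              n_pred = n_pred)$R2Y
  }
  list(p = (1 + sum(q2_perm >= q2_obs)) / (1 + n_perm),
       q2_obs = q2_obs, q2_perm = q2_perm, r2_perm = r2_perm,
       n_perm = n_perm)
}

#' CV-ANOVA significance test of an OPLS-DA model
#'
#' F-test comparing the cross-validated predictive residuals (PRESS) against
#' the total variation of the class matrix, in the published SIMCA-style
#' formulation: \code{F = ((SStot - PRESS)/df1) / (PRESS/df2)} with
#' \code{df1 = A} (fitted components, predictive + orthogonal) and
#' \code{df2 = N - A - 1}. A non-positive F (PRESS >= SStot, typical for a
#' null model) yields p = 1; the statistic is conservative under the null.
#'
#' @inheritParams q2y
#' @return p-value in [0, 1]; a zero cross-validated residual is reported as
#'   the smallest representable double with a warning
#' @export
cv_anova <- function(X, classes, n_ortho = 1, folds = 7,
                     scaling = c("pareto", "uv", "none"), seed = 1L,
                     n_pred = NULL) {
  scaling <- match.arg(scaling)
  cv <- .opls_cv(X, classes, n_ortho, folds, scaling, seed, n_pred)
  if (cv$press <= 0) {
    warning("zero cross-validated residual; p reported at the machine bound")
    return(.Machine$double.xmin)
  }
  df1 <- cv$n_comp
  df2 <- cv$n - cv$n_comp - 1
  if (df2 <= 0) stop("too few samples for CV-ANOVA degrees of freedom")
  F <- ((cv$tss - cv$press) / df1) / (cv$press / df2)
  if (!is.finite(F) || F <= 0) return(1)
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' Full OPLS-DA validation battery
#'
#' Q2Y, CV-ANOVA and permutation testing for one model, mirroring the
#' standard metabolomics validation workflow.
#'
#' @inheritParams permutation_test
#' @return list: \code{r2y}, \code{q2y}, \code{cv_anova_p},
#'   \code{permutation_p}, \code{n_permutations}, \code{q2_perm},
#'   \code{r2_perm}
#' @export
opls_validate <- function(X, classes, n_ortho = 1, folds = 7, n_perm = 200,
                          scaling = c("pareto", "uv", "none"), seed = 1L,
                          n_pred = NULL) {
  scaling <- match.arg(scaling)
  fit <- opls_da_fit(X, classes, n_ortho = n_ortho, scaling = scaling,
                     n_pred = n_pred)
  q2 <- q2y(X, classes, n_ortho = n_ortho, folds = folds, scaling = scaling,
            seed = seed, n_pred = n_pred)
  cvp <- cv_anova(X, classes, n_ortho = n_ortho, folds = folds,
                  scaling = scaling, seed = seed, n_pred = n_pred)
  pt <- if (n_perm >= 1)
    permutation_test(X, classes, n_perm = n_perm, seed = seed,
                     n_ortho = n_ortho, folds = folds, scaling = scaling,
                     n_pred = n_pred)
  else list(p = NA_real_, q2_perm = numeric(0), r2_perm = numeric(0),
            n_perm = 0L)
  list(r2y = fit$R2Y, q2y = q2, cv_anova_p = cvp, permutation_p = pt$p,
       n_permutations = pt$n_perm, q2_perm = pt$q2_perm,
       r2_perm = pt$r2_perm, model = fit)
}
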
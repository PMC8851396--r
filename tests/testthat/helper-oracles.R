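# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive and structurally different from the package code paths.

# SIMPLS (de Jong) PLS2 fit: an algorithmically independent reference for
# PLS-DA predictions (the package uses NIPALS with deflation).
oracle_simpls <- function(X, Y, ncomp) {
  Xm <- colMeans(X); Ym <- colMeans(Y)
  Xc <- sweep(X, 2, Xm); Yc <- sweep(Y, 2, Ym)
  S <- crossprod(Xc, Yc)
  p <- ncol(X); k <- ncol(Y)
  R <- matrix(0, p, ncomp); Q <- matrix(0, k, ncomp); V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    q <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% q
    tt <- Xc %*% r
    tt <- tt - mean(tt)
    nt <- sqrt(sum(tt^2)); tt <- tt / nt; r <- r / nt
    pl <- crossprod(Xc, tt)
    q <- crossprod(Yc, tt)
    v <- pl
    if (a > 1)
      v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1), drop = FALSE], pl)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- q; V[, a] <- v
  }
  list(B = R %*% t(Q), Xm = Xm, Ym = Ym)
}

oracle_simpls_predict <- function(fit, X) {
  sweep(sweep(X, 2, fit$Xm) %*% fit$B, 2, fit$Ym, "+")
}

# Brute-force generalized Ward agglomerator, O(n^3) per step: inter-cluster
# distances are recomputed from the ORIGINAL dissimilarity matrix with the
# set formula at every step (no Lance-Williams incremental update).
oracle_ward <- function(D) {
  n <- nrow(D)
  cl <- lapply(seq_len(n), function(i) i)
  heights <- numeric(0)
  merged <- list()
  setd <- function(A, B) {
    na <- length(A); nb <- length(B)
    mab <- mean(D[A, B, drop = FALSE])
    sa <- if (na > 1) sum(D[A, A][upper.tri(diag(na))]) else 0
    sb <- if (nb > 1) sum(D[B, B][upper.tri(diag(nb))]) else 0
    2 * na * nb / (na + nb) * (mab - sa / na^2 - sb / nb^2)
  }
  while (length(cl) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(cl) - 1)) {
      for (j in seq(i + 1, length(cl))) {
        d <- setd(cl[[i]], cl[[j]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    merged[[length(merged) + 1]] <- sort(c(cl[[bi]], cl[[bj]]))
    cl[[bi]] <- sort(c(cl[[bi]], cl[[bj]]))
    cl[[bj]] <- NULL
  }
  list(heights = heights, merged = merged)
}

# leaf sets below each internal node of a ward_hca tree, in merge order
hca_merge_sets <- function(w) {
  n <- nrow(w$merge) + 1
  sets <- vector("list", nrow(w$merge))
  leaf <- function(k) if (k < 0) -k else sets[[k]]
  for (s in seq_len(nrow(w$merge)))
    sets[[s]] <- sort(c(leaf(w$merge[s, 1]), leaf(w$merge[s, 2])))
  sets
}

# brute-force volcano double filter
oracle_volcano_sig <- function(ab, g, contrast, alpha, fc) {
  sig <- logical(ncol(ab))
  ps <- rep(NA_real_, ncol(ab))
  fcs <- rep(NA_real_, ncol(ab))
  for (j in seq_len(ncol(ab))) {
    y <- ab[, j]; ok <- is.finite(y)
    gv <- g[ok]
    if (sum(ok) < 4 || length(unique(gv)) < 2 || any(table(gv) < 2)) next
    ps[j] <- if (stats::var(y[ok]) == 0) 1 else
      summary(stats::aov(y[ok] ~ factor(gv)))[[1]][["Pr(>F)"]][1]
    m1 <- mean(y[ok][gv == contrast[1]]); m2 <- mean(y[ok][gv == contrast[2]])
    if (is.finite(m1) && is.finite(m2) && m1 > 0 && m2 > 0) fcs[j] <- m1 / m2
  }
  m <- sum(!is.na(ps))
  padj <- pmin(1, ps * m)
  !is.na(padj) & !is.na(fcs) & padj < alpha & (fcs >= fc | fcs <= 1 / fc)
}

# RV via explicit n x n configuration matrices (different route from the
# package's p-space crossproducts)
oracle_rv <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  S1 <- Xc %*% t(Xc); S2 <- Yc %*% t(Yc)
  sum(S1 * S2) / sqrt(sum(S1 * S1) * sum(S2 * S2))
}

# small synthetic configs shared across tests
tiny_config <- function(seed = 1L, ...) {
  synth_config(n_compounds = 60, seed = seed, ...)
}

planted_config <- function(seed = 1L, ...) {
  subs <- c("CTRL", "B", "C", "D", "F", "H", "O", "P")
  synth_config(
    seed = seed,
    substance_growth_effect = stats::setNames(
      c(1, 0.90, 1, 1, 1, 1.12, 1, 1), subs),
    substance_chlf_effect = stats::setNames(
      c(0, -0.03, 0, 0, 0, 0.04, 0, 0), subs),
    ...)
}
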
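# shared small fixture: two classes separated along a planted direction
sep_data <- function(n = 24, p = 12, snr = 5, seed = 1) {
  set.seed(seed)
  cl <- factor(rep(c("a", "b"), length.out = n))
  d <- rnorm(p); d <- d / sqrt(sum(d^2))
  X <- matrix(rnorm(n * p), n, p) +
    outer(ifelse(cl == "b", snr / 2, -snr / 2), d)
  list(X = X, classes = cl, d = d)
}

test_that("perfect separation with no other variation gives R2Y = 1", {
  cl <- factor(rep(c("a", "b"), each = 6))
  X <- cbind(as.numeric(cl == "b"), rep(c(-1, 1), 6))
  fit <- opls_da_fit(X, cl, n_ortho = 0, scaling = "uv")
  expect_equal(fit$R2Y, 1)
  expect_gt(q2y(X, cl, n_ortho = 0, scaling = "uv", folds = 3), 0.9)
})

test_that("n_ortho = 0 equals the independent SIMPLS oracle", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:3, 1)
    nc <- if (k == 2) sample(1:3, 1) else 1
    n <- 21; p <- sample(c(8, 15), 1)
    cl <- factor(rep(letters[1:k], length.out = n))
    X <- matrix(rnorm(n * p), n, p) + outer(as.integer(cl), seq_len(p) / 4)
    fit <- opls_da_fit(X, cl, n_ortho = 0, scaling = "uv", n_pred = nc)
    pr <- predict(fit, X)$y
    Y <- stats::model.matrix(~ cl - 1); colnames(Y) <- levels(cl)
    o <- oracle_simpls(scale(X), Y, nc)
    expect_lt(max(abs(pr - oracle_simpls_predict(o, scale(X)))), 1e-8)
  }
})

test_that("predictive and orthogonal scores are orthogonal", {
  set.seed(22)
  for (i in 1:10) {
    n <- 20; p <- 15
    cl <- factor(rep(c("a", "b"), 10))
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + 2 * (as.integer(cl) - 1)
    fit <- opls_da_fit(X, cl, n_ortho = sample(1:3, 1), scaling = "uv")
    if (fit$n_ortho > 0)
      expect_lt(max(abs(crossprod(fit$Tp, fit$To))), 1e-8)
  }
})

test_that("planted discriminant direction is recovered at SNR 5", {
  # direction planted in raw space, so the fit is run unscaled
  hits <- vapply(1:10, function(s) {
    sd <- sep_data(n = 40, snr = 5, seed = s)
    fit <- opls_da_fit(sd$X, sd$classes, n_ortho = 1, scaling = "none")
    abs(stats::cor(fit$W[, 1], sd$d))
  }, numeric(1))
  expect_true(all(hits >= 0.95))
})

test_that("VIP: normalization identity and signal concentration", {
  # single variable: normalization forces VIP = 1
  cl <- factor(rep(c("a", "b"), each = 5))
  X1 <- matrix(c(rnorm(5), rnorm(5, 2)), ncol = 1)
  expect_equal(unname(opls_da_fit(X1, cl, n_ortho = 0,
                                  scaling = "uv")$vip), 1)
  set.seed(23)
  arg1 <- 0L
  for (s in 1:20) {
    n <- 20; p <- 10
    cls <- factor(rep(c("a", "b"), 10))
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + 3 * (as.integer(cls) - 1)
    fit <- opls_da_fit(X, cls, n_ortho = 1, scaling = "uv")
    expect_equal(sum(fit$vip^2), p, tolerance = 1e-8)
    arg1 <- arg1 + (which.max(fit$vip) == 1)
  }
  expect_gte(arg1, 19)
})

test_that("select_discriminant applies a strict threshold, sorted", {
  vip <- c(a = 1.3, b = 1.1, c = 0.9)
  expect_identical(select_discriminant(vip, 1.2), "a")
  expect_identical(select_discriminant(vip, 1.1), "a")   # strict inequality
  expect_identical(select_discriminant(vip, 0.5), c("a", "b", "c"))
  expect_identical(select_discriminant(c(a = 1, b = 2), 0.5), c("b", "a"))
  expect_error(select_discriminant(vip, 0), "positive")
})

test_that("Q2Y: signal, null behaviour and relation to R2Y", {
  sd <- sep_data(snr = 6, seed = 3)
  expect_gt(q2y(sd$X, sd$classes, n_ortho = 0, scaling = "uv"), 0.5)
  # permuted labels: Q2Y <= 0 in most runs. n = 60 keeps the chance
  # alignment of a shuffled labeling with the true class direction small
  # (at n ~ 24 it alone pushes Q2 > 0 in ~15% of shuffles)
  sd60 <- sep_data(n = 60, snr = 6, seed = 3)
  set.seed(24)
  q2null <- vapply(1:20, function(i) {
    q2y(sd60$X, sample(sd60$classes), n_ortho = 0, scaling = "uv", seed = i)
  }, numeric(1))
  expect_gte(mean(q2null <= 0), 0.9)
  # Q2Y <= R2Y empirically (not asserted as a theorem; wide margin)
  cmp <- vapply(1:25, function(s) {
    d <- sep_data(n = 20, p = 8, snr = sample(0:4, 1), seed = 100 + s)
    fit <- opls_da_fit(d$X, d$classes, n_ortho = 0, scaling = "uv")
    q2 <- q2y(d$X, d$classes, n_ortho = 0, scaling = "uv", seed = s)
    q2 <= fit$R2Y + 1e-10
  }, logical(1))
  expect_gte(mean(cmp), 0.9)
})

test_that("fold handling and scaling validation", {
  cl <- factor(rep(c("a", "b"), each = 4))
  X <- matrix(rnorm(8 * 5), 8, 5)
  expect_warning(q2y(X, cl, folds = 7, scaling = "uv"), "folds reduced")
  Xc <- X; Xc[, 2] <- 1
  colnames(Xc) <- paste0("v", 1:5)
  expect_error(opls_da_fit(Xc, cl, scaling = "uv"), "v2")
  expect_error(opls_da_fit(X, factor(rep("a", 8))), "two classes")
})

test_that("permutation test: determinism and minimal p with strong signal", {
  sd <- sep_data(snr = 8, seed = 5)
  pt1 <- permutation_test(sd$X, sd$classes, n_perm = 39, seed = 9,
                          n_ortho = 0, scaling = "uv")
  pt2 <- permutation_test(sd$X, sd$classes, n_perm = 39, seed = 9,
                          n_ortho = 0, scaling = "uv")
  expect_identical(pt1$p, pt2$p)
  expect_equal(pt1$p, 1 / 40)   # add-one estimator floor
  expect_length(pt1$q2_perm, 39)
})

test_that("CV-ANOVA: degenerate fit, null conservativeness, probability", {
  # perfect cross-validated prediction: PRESS = 0, machine-bound p
  cl <- factor(rep(c("a", "b"), each = 8))
  X0 <- cbind(as.numeric(cl == "b"), rep(c(-1, 1), 8))
  expect_lt(suppressWarnings(cv_anova(X0, cl, n_ortho = 0, scaling = "uv")),
            1e-6)
  # pure-noise labels: p > 0.05 nearly always
  set.seed(25)
  pnull <- vapply(1:20, function(i) {
    Xn <- matrix(rnorm(16 * 10), 16, 10)
    cv_anova(Xn, cl, n_ortho = 0, scaling = "uv", seed = i)
  }, numeric(1))
  expect_gte(mean(pnull > 0.05), 0.9)
  expect_true(all(pnull >= 0 & pnull <= 1))
})

test_that("R2Y is non-decreasing in n_ortho on training data", {
  set.seed(26)
  cl <- factor(rep(c("a", "b"), 10))
  X <- matrix(rnorm(20 * 12), 20, 12)
  X[, 1] <- X[, 1] + 2 * (as.integer(cl) - 1)
  r2 <- vapply(0:3, function(no) {
    opls_da_fit(X, cl, n_ortho = no, scaling = "uv")$R2Y
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})
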
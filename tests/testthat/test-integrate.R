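test_that("random forest recovers a planted informative trait", {
  hits <- 0L
  for (s in 1:20) {
    y <- factor(rep(c("a", "b"), each = 20))
    set.seed(1000 + s)
    X <- cbind(sig = as.numeric(y == "b"),
               matrix(rnorm(40 * 4), 40, 4,
                      dimnames = list(NULL, paste0("noise", 1:4))))
    rf <- rf_trait_importance(X, y, n_trees = 100, seed = s)
    hits <- hits + (rf$rank[["sig"]] == 1 && rf$oob_accuracy > 0.95)
  }
  expect_gte(hits, 19L)
})

test_that("random forest under the null: importance near 0, chance accuracy", {
  accs <- imps <- numeric(10)
  for (s in 1:10) {
    set.seed(2000 + s)
    y <- factor(rep(c("a", "b", "c", "d"), each = 10))
    X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("t", 1:5)))
    rf <- rf_trait_importance(X, y, n_trees = 100, seed = s)
    accs[s] <- rf$oob_accuracy
    imps[s] <- mean(rf$importance)
  }
  expect_lt(abs(mean(accs) - 0.25), 0.12)   # 4 balanced classes
  expect_lt(abs(mean(imps)), 0.02)
})

test_that("duplicating a noise trait leaves the informative rank unchanged", {
  set.seed(3000)
  y <- factor(rep(c("a", "b"), each = 20))
  X <- cbind(sig = as.numeric(y == "b"),
             matrix(rnorm(40 * 3), 40, 3,
                    dimnames = list(NULL, paste0("noise", 1:3))))
  X2 <- cbind(X, noise1b = X[, "noise1"])
  rf1 <- rf_trait_importance(X, y, n_trees = 200, seed = 4)
  rf2 <- rf_trait_importance(X2, y, n_trees = 200, seed = 4)
  expect_equal(rf1$rank[["sig"]], 1L)
  expect_equal(rf2$rank[["sig"]], 1L)
  # determinism
  rf3 <- rf_trait_importance(X, y, n_trees = 200, seed = 4)
  expect_identical(rf1, rf3)
  expect_error(rf_trait_importance(X, factor(c("a", rep("b", 39)))),
               "at least two samples")
})

test_that("trait-metabolite correlation: exact, null and degenerate cases", {
  set.seed(41)
  n <- 24
  tv <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "tr"))
  ab <- cbind(lin = 2 * tv[, 1] + 5,
              const = rep(3, n),
              matrix(exp(rnorm(n * 48)), n, 48,
                     dimnames = list(NULL, sprintf("r%02d", 1:48))))
  ab[, "lin"] <- ab[, "lin"] - min(ab[, "lin"]) + 1   # keep positive
  ft <- feature_table(
    `rownames<-`(ab, rownames(tv)),
    data.frame(sample_id = rownames(tv), substance = "CTRL",
               condition = "control", replicate = 1:n),
    data.frame(compound_id = colnames(ab),
               category = "x", stringsAsFactors = FALSE))
  cm <- trait_metabolite_correlation(tv, ft, log_abundance = FALSE)
  expect_equal(cm$r[cm$compound_id == "lin"], 1)
  expect_lt(cm$p[cm$compound_id == "lin"], 1e-12)
  cst <- cm[cm$compound_id == "const", ]
  expect_true(is.na(cst$r) || is.na(cst$p))
  expect_false(cst$significant)
  tv_bad <- tv
  rownames(tv_bad)[1] <- "GHOST"
  expect_error(trait_metabolite_correlation(tv_bad, ft), "GHOST")
})

test_that("null correlation calibration: about 5% flagged", {
  set.seed(42)
  n <- 40; m <- 1000
  tv <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "tr"))
  ab <- matrix(exp(rnorm(n * m)), n, m,
               dimnames = list(rownames(tv), sprintf("c%04d", 1:m)))
  ft <- feature_table(ab,
    data.frame(sample_id = rownames(tv), substance = "CTRL",
               condition = "control", replicate = 1:n),
    data.frame(compound_id = colnames(ab), category = "x"))
  cm <- trait_metabolite_correlation(tv, ft, alpha = 0.05)
  expect_gt(mean(cm$significant), 0.02)
  expect_lt(mean(cm$significant), 0.08)
})

test_that("RV coefficient: identity, invariances, oracle agreement", {
  set.seed(43)
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(rv_coefficient(X, X), 1)
  R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_lt(abs(rv_coefficient(X, X %*% R) - 1), 1e-10)
  expect_lt(abs(rv_coefficient(X, 3.7 * X) - 1), 1e-10)
  # stated 3x2 example: Y is a scaled copy of X
  X3 <- matrix(c(1, 0, 0, 1, -1, -1), 3, 2, byrow = TRUE)
  expect_equal(rv_coefficient(X3, 2 * X3), 1)
  for (i in 1:20) {
    A <- matrix(rnorm(4 * 3), 4, 3); B <- matrix(rnorm(4 * 2), 4, 2)
    expect_lt(abs(rv_coefficient(A, B) - oracle_rv(A, B)), 1e-10)
  }
  expect_error(rv_coefficient(matrix(1, 4, 2), X[1:4, ]), "variance")
  # joint row reordering leaves RV unchanged
  A <- matrix(rnorm(8 * 3), 8); B <- matrix(rnorm(8 * 5), 8)
  pr <- sample(8)
  expect_equal(rv_coefficient(A[pr, ], B[pr, ]), rv_coefficient(A, B))
})

test_that("co-inertia: self-comparison, orthonormal axes, clipping", {
  set.seed(44)
  X <- matrix(rnorm(12 * 5), 12, 5)
  ci <- coinertia(X, X, n_axes = 3, scale_x = "uv", scale_y = "uv")
  expect_equal(ci$rv, 1)
  expect_true(all(diff(ci$singular_values) <= 1e-12))
  expect_equal(crossprod(ci$axes_x), diag(3), tolerance = 1e-8)
  expect_equal(crossprod(ci$axes_y), diag(3), tolerance = 1e-8)
  expect_warning(coinertia(X, X[, 1:2], n_axes = 5, scale_x = "uv",
                           scale_y = "uv"), "clipped")
})

test_that("RV permutation test: maximal statistic, null, determinism", {
  set.seed(45)
  X <- matrix(rnorm(12 * 4), 12, 4)
  t1 <- rv_permutation_test(X, X, n_perm = 49, seed = 7)
  expect_equal(t1$p, 1 / 50)
  expect_identical(t1$p, rv_permutation_test(X, X, n_perm = 49, seed = 7)$p)
  pn <- vapply(1:10, function(s) {
    rv_permutation_test(matrix(rnorm(48), 12), matrix(rnorm(36), 12),
                        n_perm = 39, seed = s)$p
  }, numeric(1))
  expect_gte(mean(pn > 0.05), 0.8)
})

test_that("independent blocks: RV permutation p is non-significant", {
  ps <- vapply(1:30, function(s) {
    cfg <- tiny_config(seed = s, metab_effect_sd = 0, coupling = 0,
                       missing_fraction = 0)
    sim <- simulate_experiment(cfg)
    tt <- build_trait_table(sim$observations, "lettuce")
    tm <- trait_matrix(tt, "late")
    al <- intersect(rownames(tm), rownames(sim$features$abundance))
    rv_permutation_test(scale(tm[al, ]), log(sim$features$abundance[al, ]),
                        n_perm = 99, seed = s)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("integration chain recovers metabolites coupled to the top trait", {
  # world where biomass is the discriminating trait (moderate growth
  # effects, photosynthesis neutral), plant-level vigour dominates the
  # within-group variance (plant_sd raised via its config knob) and
  # compounds are maximally coupled to the plant growth latent
  subs <- c("CTRL", "B", "H")
  cfg <- synth_config(
    seed = 3, coupling = 1, n_compounds = 200, missing_fraction = 0,
    substances = subs, conditions = "control", metab_reps = 8,
    metab_effect_sd = 0.2, plant_sd = 0.25,
    substance_growth_effect = setNames(c(1, 0.9, 1.15), subs),
    substance_chlf_effect = setNames(c(0, 0, 0), subs))
  truth <- ground_truth(cfg)
  sim <- simulate_experiment(cfg)
  tt <- build_trait_table(sim$observations, "lettuce")
  tm <- trait_matrix(tt, "late")
  rf <- rf_trait_importance(tm, attr(tm, "groups"), n_trees = 200, seed = 1)
  top <- names(rf$importance)[rf$rank == 1]
  expect_true(top %in% c("db_end", "wue", "rgr"))
  al <- intersect(rownames(tm), rownames(sim$features$abundance))
  ftal <- ft_subset_samples(sim$features,
                            match(al, rownames(sim$features$abundance)))
  cm <- trait_metabolite_correlation(tm[al, "db_end", drop = FALSE], ftal)
  coupled <- sprintf("cmp%04d", which(abs(truth$coupling_vector) > 1.5))
  recovered <- mean(coupled %in% cm$compound_id[cm$significant])
  expect_gte(recovered, 0.8)
})
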
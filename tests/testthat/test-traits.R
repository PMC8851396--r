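test_that("digital biomass: arithmetic, homogeneity, domain errors", {
  expect_equal(digital_biomass(1, 1), 1)
  expect_equal(digital_biomass(100, 200), 2000)
  expect_equal(digital_biomass(100, 200, sqrt = FALSE), 200^2 * 100)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 1, 1e4); b <- runif(1, 1, 1e4); cc <- runif(1, 0.5, 3)
    # scaling both areas by c^2 scales the volume by c^3
    expect_equal(digital_biomass(cc^2 * a, cc^2 * b),
                 cc^3 * digital_biomass(a, b))
    expect_gt(digital_biomass(a * 1.01, b), digital_biomass(a, b))
    expect_gt(digital_biomass(a, b * 1.01), digital_biomass(a, b))
  }
  expect_error(digital_biomass(-1, 5), "positive")
  expect_error(digital_biomass(5, 0), "positive")
})

test_that("relative growth rate: formula, invariance, errors", {
  expect_equal(relative_growth_rate(100, 100, 0, 5), 0)
  expect_equal(relative_growth_rate(100, 200, 0, 12), log(2) / 12)
  set.seed(2)
  for (i in 1:20) {
    d1 <- runif(1, 1, 100); d2 <- runif(1, 1, 100); s <- runif(1, 0.1, 10)
    expect_equal(relative_growth_rate(s * d1, s * d2, 0, 3),
                 relative_growth_rate(d1, d2, 0, 3))
  }
  expect_error(relative_growth_rate(100, 200, 5, 5), "t2")
  expect_error(relative_growth_rate(0, 200, 0, 5), "positive")
})

test_that("chlorophyll fluorescence derivations", {
  d <- chlf_derive(200, 1000, 500, 700, 180)
  expect_equal(d$fv_fm, 0.8)
  expect_equal(d$fvp_fmp, (700 - 180) / 700)
  expect_equal(d$phi_psii, (700 - 500) / 700)
  expect_equal(d$npq, (1000 - 700) / 700)
  # closed reaction centres: Fm' = Ft
  expect_equal(chlf_derive(200, 1000, 700, 700, 180)$phi_psii, 0)
  # no quenching: Fm = Fm'
  expect_equal(chlf_derive(200, 1000, 500, 1000, 180)$npq, 0)
  expect_error(chlf_derive(200, 100, 50, 80, 30), "Fm >= F0")
  expect_error(chlf_derive(200, 1000, 800, 700, 180), "Fm_prime >= Ft")
})

test_that("delta T: subtraction and translation invariance", {
  expect_equal(delta_t(21, 21), 0)
  expect_equal(delta_t(22.5, 21), 1.5)
  expect_equal(delta_t(22.5 + 3, 21 + 3), 1.5)
  expect_error(delta_t(NA_real_, 21), "finite")
})

test_that("trait table assembly: phases, RGR composition, exclusions", {
  cfg <- tiny_config(seed = 5)
  obs <- generate_phenotyping(cfg)
  tt <- build_trait_table(obs, "lettuce")
  expect_setequal(unique(tt$phase), c("early", "late"))
  # row count = plants with coverage x 2 phases
  expect_equal(nrow(tt), length(unique(obs$plant_id)) * 2)

  # single plant, DB doubling over the early phase -> rgr = ln2/12
  one <- obs[obs$plant_id == obs$plant_id[1] & obs$dop <= 12, ]
  one$psa_side <- 10
  one$psa_top <- 1  # DB = psa_side
  one$psa_side[one$dop == 12] <- 20
  t1 <- suppressWarnings(build_trait_table(one, "lettuce"))  # late phase absent
  expect_equal(t1$rgr[t1$phase == "early"], log(2) / 12)

  # plant observed only at dop 0 is excluded with a warning
  short <- obs[obs$dop == 0 & obs$plant_id == obs$plant_id[1], ]
  both <- rbind(obs[obs$plant_id != obs$plant_id[1], ], short)
  expect_warning(t2 <- build_trait_table(both, "lettuce"), "excluded")
  expect_false(obs$plant_id[1] %in% t2$plant_id)

  # same observations, different crop: identical early rows, late differs
  # only via the window end (tomato observations extend to day 24)
  cfg_t <- synth_config("tomato", n_compounds = 60, seed = 5)
  obs_t <- generate_phenotyping(cfg_t)
  tt_t <- build_trait_table(obs_t, "tomato")
  expect_true(all(obs_t$dop[obs_t$dop > 12] <= 24))
  expect_setequal(unique(tt_t$phase), c("early", "late"))
})

test_that("ChlF yields from the generator are always valid", {
  for (s in 1:5) {
    tt <- build_trait_table(generate_phenotyping(tiny_config(seed = s)),
                            "lettuce")
    expect_true(all(tt$fvp_fmp >= 0 & tt$fvp_fmp <= 1))
    expect_true(all(tt$phi_psii >= 0 & tt$phi_psii <= 1))
    expect_true(all(tt$qy_max >= 0 & tt$qy_max <= 1))
    expect_true(all(tt$npq >= 0))
  }
})

test_that("group comparison: Tukey contracts and calibration", {
  cfg <- tiny_config(seed = 2)
  tt <- build_trait_table(generate_phenotyping(cfg), "lettuce")
  res <- compare_groups(tt, "db_end", "late")
  expect_true(all(res$pairs$p_adj >= 0 & res$pairs$p_adj <= 1))

  # identical group data duplicated -> p = 1 for that pair
  a <- tt[tt$substance %in% c("CTRL", "B") & tt$phase == "late" &
            tt$condition == "control", ]
  b <- a[a$substance == "CTRL", ]
  b$substance <- "X"
  dup <- rbind(a, b)
  res2 <- compare_groups(dup, "db_end", "late")
  pr <- res2$pairs
  self <- pr[(pr$group1 == "X_control" & pr$group2 == "CTRL_control") |
               (pr$group1 == "CTRL_control" & pr$group2 == "X_control"), ]
  expect_equal(self$p_adj, 1)

  # type-I error of the ANOVA+Tukey pair under the null, and power at a
  # 3-sigma shift (sub-sampled relative to a full calibration study)
  set.seed(7)
  rej <- replicate(400, {
    y <- rnorm(16)
    d <- data.frame(plant_id = 1:16, substance = rep(c("A", "B"), each = 8),
                    condition = "control", phase = "late", db_end = y)
    compare_groups(d, "db_end", "late")$pairs$p_adj[1] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
  pow <- replicate(200, {
    y <- c(rnorm(8), rnorm(8, 3))
    d <- data.frame(plant_id = 1:16, substance = rep(c("A", "B"), each = 8),
                    condition = "control", phase = "late", db_end = y)
    compare_groups(d, "db_end", "late")$pairs$p_adj[1] < 0.05
  })
  expect_gt(mean(pow), 0.99)
})
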
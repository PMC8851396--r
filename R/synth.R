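#' Configuration for the synthetic experiment generator
#'
#' Describes one crop trial: design constants (replicates, substances,
#' conditions, phenotyping days), the planted treatment effects, and the
#' stochastic structure of the coupled metabolite block. Defaults emulate the
#' stated experimental design: 8 (lettuce) or 6 (tomato) biological
#' replicates, an untreated control plus seven protein-hydrolysate
#' substances, 10 phenotyping rounds over 21 (lettuce) or 24 (tomato) days,
#' and a late-phase salt growth reduction of 32% of control digital biomass.
#'
#' @param crop "lettuce" or "tomato"
#' @param n_reps biological replicates per substance x condition (default 8
#'   for lettuce, 6 for tomato)
#' @param substances treatment codes; first element is the untreated control
#' @param conditions growth conditions, subset of c("control", "salt")
#' @param dops phenotyping days; strictly increasing, starting at 0
#' @param salt_growth_reduction late-phase fractional reduction of digital
#'   biomass under salt, in [0, 1)
#' @param substance_growth_effect named numeric: multiplicative effect of each
#'   substance on the intrinsic logistic growth rate (control = 1)
#' @param substance_chlf_effect named numeric: additive shift of each
#'   substance on light-adapted quantum yields (control = 0)
#' @param n_compounds number of annotated compounds in the metabolite block
#' @param n_latent rank of the treatment-structured metabolite signal
#' @param coupling trait-metabolite coupling strength in [0, 1]
#' @param noise_cv multiplicative lognormal coefficient of variation of the
#'   imaging measurements
#' @param plant_sd sd of the per-plant lognormal vigour intercept (biological
#'   replicate variation; the within-treatment variance is not pinned down by
#'   the emulated design, so it is exposed here)
#' @param metab_effect_sd scale of the per-compound treatment loadings; 0
#'   removes all treatment structure from the metabolome
#' @param metab_noise_sd lognormal sd of metabolite abundances
#' @param metab_reps metabolomics replicates per treatment (>= 4)
#' @param missing_fraction fraction of compounds subjected to random dropout
#'   (exercises the presence filter)
#' @param seed integer RNG seed
#' @return object of class \code{synth_config}
#' @export
synth_config <- function(crop = c("lettuce", "tomato"),
                         n_reps = NULL,
                         substances = c("CTRL", "B", "C", "D", "F", "H", "O", "P"),
                         conditions = c("control", "salt"),
                         dops = NULL,
                         salt_growth_reduction = 0.32,
                         substance_growth_effect = NULL,
                         substance_chlf_effect = NULL,
                         n_compounds = 800,
                         n_latent = 4,
                         coupling = 0.5,
                         noise_cv = 0.08,
                         plant_sd = 0.1,
                         metab_effect_sd = 0.6,
                         metab_noise_sd = 0.3,
                         metab_reps = 4,
                         missing_fraction = 0.1,
                         seed = 1L) {
  crop <- match.arg(crop)
  if (is.null(n_reps)) n_reps <- if (crop == "lettuce") 8L else 6L
  if (is.null(dops)) {
    end <- if (crop == "lettuce") 21 else 24
    dops <- unique(round(seq(0, end, length.out = 10)))
  }
  if (!all(conditions %in% c("control", "salt")) || !length(conditions))
    stop("conditions must be a non-empty subset of c('control', 'salt')")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (any(diff(dops) <= 0) || dops[1] != 0)
    stop("dops must be strictly increasing and start at 0")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (salt_growth_reduction < 0 || salt_growth_reduction >= 1)
    stop("salt_growth_reduction must lie in [0, 1)")
  if (anyDuplicated(substances)) stop("duplicate substance codes")

  # planted effects default to the qualitative pattern reported for lettuce:
  # P strongest growth promoter, H strong promoter with the clearest
  # photosynthetic benefit, B mild inhibitor, the rest near-neutral
  ge <- stats::setNames(rep(1, length(substances)), substances)
  ge[intersect(names(ge), c("B", "C", "D", "F", "H", "O", "P"))] <-
    c(B = 0.92, C = 1.00, D = 1.03, F = 1.02, H = 1.06, O = 1.01, P = 1.10)[
      intersect(substances, c("B", "C", "D", "F", "H", "O", "P"))]
  if (!is.null(substance_growth_effect))
    ge[names(substance_growth_effect)] <- substance_growth_effect
  ce <- stats::setNames(rep(0, length(substances)), substances)
  ce[intersect(names(ce), c("B", "C", "D", "F", "H", "O", "P"))] <-
    c(B = -0.02, C = 0, D = 0.005, F = 0, H = 0.03, O = 0.005, P = 0.02)[
      intersect(substances, c("B", "C", "D", "F", "H", "O", "P"))]
  if (!is.null(substance_chlf_effect))
    ce[names(substance_chlf_effect)] <- substance_chlf_effect

  structure(list(
    crop = crop, n_reps = as.integer(n_reps), substances = substances,
    conditions = conditions, dops = dops,
    salt_growth_reduction = salt_growth_reduction,
    substance_growth_effect = ge, substance_chlf_effect = ce,
    n_compounds = as.integer(n_compounds), n_latent = as.integer(n_latent),
    coupling = coupling, noise_cv = noise_cv, plant_sd = plant_sd,
    metab_effect_sd = metab_effect_sd, metab_noise_sd = metab_noise_sd,
    metab_reps = as.integer(metab_reps),
    missing_fraction = missing_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# growth-law and measurement constants of the stated world; see the methods
# vignette for the rationale behind each value
.synth_pars <- function(crop) {
  if (crop == "lettuce")
    list(psa0 = 2000, K = 8e4, r = 0.22, side_shape = 1.6, side_exp = 0.9)
  else
    list(psa0 = 1500, K = 6e4, r = 0.18, side_shape = 1.4, side_exp = 0.9)
}

#' Ground truth of a synthetic experiment
#'
#' Deterministically derives (from the config seed) every latent quantity the
#' generator uses: per-plant growth intercepts, per-group metabolite latent
#' scores, per-compound treatment loadings and the trait-metabolite coupling
#' vector. Recovery tests compare pipeline output against this object.
#'
#' @param config a [synth_config()]
#' @return object of class \code{synth_truth}
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  groups <- expand.grid(substance = config$substances,
                        condition = config$conditions,
                        stringsAsFactors = FALSE)
  groups$group_id <- paste(groups$substance, groups$condition, sep = "_")
  plant <- groups[rep(seq_len(nrow(groups)), each = config$n_reps), ]
  plant$replicate <- rep(seq_len(config$n_reps), nrow(groups))
  plant$plant_id <- sprintf("%s_%s_r%02d", plant$substance,
                            substr(plant$condition, 1, 4), plant$replicate)
  rownames(plant) <- NULL

  pars <- .synth_pars(config$crop)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  # biological replicate variation scales with the measurement-noise knob so
  # that noise_cv = 0 yields a fully deterministic world
  plant$intercept <- stats::rnorm(nrow(plant), 0,
                                  config$plant_sd * config$noise_cv / 0.08)

  # treatment structure of the metabolome: group scores on n_latent factors,
  # compound loadings, and a coupling vector tying compounds to the plant
  # growth latent
  gs <- matrix(stats::rnorm(nrow(groups) * config$n_latent),
               nrow(groups), config$n_latent,
               dimnames = list(groups$group_id, NULL))
  ld <- matrix(stats::rnorm(config$n_compounds * config$n_latent,
                            0, config$metab_effect_sd),
               config$n_compounds, config$n_latent)
  kv <- stats::rnorm(config$n_compounds, 0, 1)
  baseline <- stats::rnorm(config$n_compounds, log(1e5), 1.2)
  structure(list(
    plants = plant, groups = groups,
    growth_multiplier = config$substance_growth_effect,
    chlf_shift = config$substance_chlf_effect,
    group_scores = gs, compound_loadings = ld,
    coupling_vector = kv, baseline = baseline
  ), class = "synth_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# logistic growth solution: K N0 e^{rt} / (K + N0 (e^{rt} - 1)); strictly
# increasing in r for every t > 0, which gives effect monotonicity for free
.logistic_psa <- function(t, psa0, K, r) {
  e <- exp(r * t)
  K * psa0 * e / (K + psa0 * (e - 1))
}

# ramp from 0 (t <= t0) to 1 (t >= t0), hard switch
.after <- function(t, t0) as.numeric(t > t0)

#' Generate synthetic phenotyping observations
#'
#' One record per plant x phenotyping day. Top-view projected shoot area
#' follows logistic growth with per-plant lognormal intercepts and
#' multiplicative lognormal measurement noise; the side view is a power
#' function of the top view. Salt reduces digital biomass by
#' \code{salt_growth_reduction} after the day-12 phase boundary. Fluorescence
#' primitives are generated by inverting target quantum yields so that
#' Fv'/Fm' and PhiPSII decline and NPQ rises under salt; canopy temperature
#' is the chamber temperature plus an offset shifted by condition and
#' substance.
#'
#' @param config a [synth_config()]
#' @param truth optional [ground_truth()] for \code{config}; recomputed when
#'   missing
#' @return data.frame of plant observations (the phenotyping CSV dialect)
#' @export
generate_phenotyping <- function(config, truth = ground_truth(config)) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "synth_truth"))
  pars <- .synth_pars(config$crop)
  plants <- truth$plants
  dops <- config$dops
  n <- nrow(plants) * length(dops)

  df <- plants[rep(seq_len(nrow(plants)), each = length(dops)),
               c("plant_id", "substance", "condition", "replicate", "intercept")]
  df$crop <- config$crop
  df$dop <- rep(dops, nrow(plants))
  rownames(df) <- NULL

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  nsf <- config$noise_cv / 0.08   # auxiliary noise relative to the default
  # a growth promoter raises both the intrinsic rate and the attainable
  # size, so its relative-growth-rate advantage persists into the late
  # (near-saturation) phase instead of flipping sign
  # the per-plant intercept scales initial size AND attainable size: vigour
  # differences persist to the end of the trial instead of being forgotten
  # by logistic saturation
  g <- config$substance_growth_effect[df$substance]
  base <- .logistic_psa(df$dop, pars$psa0 * exp(df$intercept),
                        pars$K * g * exp(df$intercept), pars$r * g)
  # DB = psa_side * sqrt(psa_top) scales as psa_top^(side_exp + 1/2); pick
  # the psa_top factor that yields the requested DB reduction after day 12
  db_exp <- pars$side_exp + 0.5
  salt_f <- ifelse(df$condition == "salt",
                   (1 - config$salt_growth_reduction)^
                     (.after(df$dop, 12) / db_exp), 1)
  df$psa_top <- base * salt_f * exp(stats::rnorm(n, 0, sdlog))
  df$psa_side <- pars$side_shape * df$psa_top^pars$side_exp *
    exp(stats::rnorm(n, 0, sdlog / 2))

  # chlorophyll fluorescence: draw target yields, then invert to primitives
  ce <- config$substance_chlf_effect[df$substance]
  salt_late <- (df$condition == "salt") * .after(df$dop, 12)
  csd <- config$noise_cv / 4
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  fv_fm <- clamp(0.80 - 0.03 * salt_late + ce / 2 +
                   stats::rnorm(n, 0, csd / 2), 0.3, 0.86)
  gamma2 <- clamp(0.65 - 0.08 * salt_late + ce +
                    stats::rnorm(n, 0, csd), 0.05, fv_fm - 0.02)
  qp2 <- clamp(0.85 + stats::rnorm(n, 0, csd), 0.4, 0.99)
  npq2 <- pmax(0.50 + 0.30 * salt_late - 2 * ce +
                 stats::rnorm(n, 0, csd * 2), 0.01)
  gamma4 <- clamp(gamma2 - 0.15, 0.03, 1)
  qp4 <- clamp(qp2 - 0.15, 0.2, 0.99)
  npq4 <- npq2 + 0.40

  Fm <- 1000 * exp(stats::rnorm(n, 0, sdlog / 2))
  df$Fm <- Fm
  df$F0 <- (1 - fv_fm) * Fm
  fmp2 <- Fm / (1 + npq2)
  df$Fm_prime_lss2 <- fmp2
  df$F0_prime_lss2 <- (1 - gamma2) * fmp2
  df$Ft_lss2 <- (1 - gamma2 * qp2) * fmp2
  fmp4 <- Fm / (1 + npq4)
  df$Fm_prime_lss4 <- fmp4
  df$F0_prime_lss4 <- (1 - gamma4) * fmp4
  df$Ft_lss4 <- (1 - gamma4 * qp4) * fmp4

  # thermal: canopy offset rises under late salt (stomatal closure), falls
  # with photosynthetic benefit of the substance
  df$t_chamber <- 22 + stats::rnorm(n, 0, 0.3 * nsf)
  offset <- -1.0 + 0.8 * salt_late - 8 * ce + stats::rnorm(n, 0, 0.25 * nsf)
  df$t_canopy <- df$t_chamber + offset

  df$water_added <- pmax(5 + 25 * df$psa_top / pars$K +
                           stats::rnorm(n, 0, 0.5 * nsf), 1)
  df$intercept <- NULL
  df[, c("plant_id", "crop", "substance", "condition", "replicate", "dop",
         "psa_top", "psa_side", "F0", "Fm",
         "Ft_lss2", "Fm_prime_lss2", "F0_prime_lss2",
         "Ft_lss4", "Fm_prime_lss4", "F0_prime_lss4",
         "t_canopy", "t_chamber", "water_added")]
}

#' Generate a synthetic metabolite feature table coupled to the phenome
#'
#' Log abundance of each compound is baseline + treatment loading x group
#' latent scores + coupling x compound coupling x plant growth latent +
#' lognormal noise. A configurable fraction of compounds receives
#' missing-at-random dropout so the presence filter has work to do. Compound
#' categories are assigned cyclically from a fixed pathway-category list.
#'
#' @param config a [synth_config()]
#' @param truth matching [ground_truth()]
#' @return a [feature_table()] with \code{config$metab_reps} samples per
#'   substance x condition group
#' @export
generate_metabolome <- function(config, truth = ground_truth(config)) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "synth_truth"))
  if (config$coupling < 0 || config$coupling > 1)
    stop("coupling must lie in [0, 1]")
  if (config$metab_reps < 4) stop("need >= 4 metabolomics replicates")
  pars <- .synth_pars(config$crop)

  sel <- truth$plants[truth$plants$replicate <= config$metab_reps, ]
  m <- config$n_compounds
  cats <- c("phenylpropanoids", "alkaloids", "terpenes", "lipids",
            "hormones", "carbohydrates", "cofactors")
  compound_id <- sprintf("cmp%04d", seq_len(m))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)

  psd <- config$plant_sd * config$noise_cv / 0.08
  z <- if (psd > 0) sel$intercept / psd else rep(0, nrow(sel))
  # variance-preserving mixing: the per-plant metabolite latent is
  # corr = coupling with the plant growth latent, so the RV between blocks
  # rises monotonically with coupling without inflating total variance
  w <- stats::rnorm(nrow(sel))
  plant_latent <- config$coupling * z +
    sqrt(1 - config$coupling^2) * w
  gsc <- truth$group_scores[sel$group_id, , drop = FALSE]
  mu <- matrix(truth$baseline, nrow(sel), m, byrow = TRUE) +
    gsc %*% t(truth$compound_loadings) +
    outer(plant_latent, truth$coupling_vector)
  ab <- exp(mu + matrix(stats::rnorm(nrow(sel) * m, 0, config$metab_noise_sd),
                        nrow(sel), m))
  dimnames(ab) <- list(sel$plant_id, compound_id)

  if (config$missing_fraction > 0) {
    n_miss <- round(config$missing_fraction * m)
    if (n_miss > 0) {
      idx <- sample.int(m, n_miss)
      for (j in idx) {
        d <- stats::runif(1, 0, 0.6)   # per-compound dropout rate
        ab[stats::runif(nrow(sel)) < d, j] <- NA_real_
      }
    }
  }

  feature_table(
    abundance = ab,
    samples = data.frame(sample_id = sel$plant_id,
                         substance = sel$substance,
                         condition = sel$condition,
                         replicate = sel$replicate,
                         stringsAsFactors = FALSE),
    compounds = data.frame(compound_id = compound_id,
                           category = rep_len(cats, m),
                           stringsAsFactors = FALSE)
  )
}

#' Generate a full synthetic experiment
#'
#' Convenience wrapper: ground truth, phenotyping observations and the
#' coupled metabolite table in one call.
#' @param config a [synth_config()]
#' @return list with \code{truth}, \code{observations}, \code{features}
#' @export
simulate_experiment <- function(config) {
  truth <- ground_truth(config)
  list(truth = truth,
       observations = generate_phenotyping(config, truth),
       features = generate_metabolome(config, truth))
}
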
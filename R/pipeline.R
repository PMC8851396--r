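#' Pipeline run configuration
#'
#' Bundles every stage's settings with the defaults used throughout the
#' domain: Tukey comparisons at P < 0.05, OPLS-DA validated with 200
#' permutations and 7-fold cross-validation, volcano filtering at Bonferroni
#' P < 0.01 with FC >= 1.3, correlation screening at P < 0.05.
#'
#' @param synth a [synth_config()] describing the input experiment (the
#'   pipeline can also be fed files; see [run_pipeline()])
#' @param pbc_tolerance neutral band of [classify_substance()]
#' @param hca_distance distance for the phenotype dendrogram
#' @param mva_scaling scaling for OPLS-DA on log abundances
#' @param n_ortho orthogonal components of the OPLS-DA models
#' @param n_pred predictive components; NULL = classes - 1
#' @param folds cross-validation folds (reduced automatically when a class is
#'   smaller)
#' @param n_perm label permutations for model validation; 0 skips validation
#' @param volcano_alpha,volcano_fc volcano thresholds
#' @param vip_threshold VIP cut-off for discriminant compounds
#' @param n_trees random-forest size
#' @param cor_alpha trait-metabolite correlation significance level
#' @param rv_n_perm permutations for the RV test
#' @param presence_fraction presence-filter threshold
#' @param seed master seed for every stochastic stage
#' @return object of class \code{run_config}
#' @export
run_config <- function(synth = synth_config(),
                       pbc_tolerance = 0.05,
                       hca_distance = "euclidean",
                       mva_scaling = "pareto",
                       n_ortho = 1, n_pred = NULL, folds = 7, n_perm = 200,
                       volcano_alpha = 0.01, volcano_fc = 1.3,
                       vip_threshold = 1.2,
                       n_trees = 500, cor_alpha = 0.05, rv_n_perm = 199,
                       presence_fraction = 0.75,
                       seed = 1L) {
  stopifnot(inherits(synth, "synth_config"))
  structure(list(synth = synth, pbc_tolerance = pbc_tolerance,
                 hca_distance = hca_distance, mva_scaling = mva_scaling,
                 n_ortho = n_ortho, n_pred = n_pred, folds = folds,
                 n_perm = n_perm, volcano_alpha = volcano_alpha,
                 volcano_fc = volcano_fc, vip_threshold = vip_threshold,
                 n_trees = n_trees, cor_alpha = cor_alpha,
                 rv_n_perm = rv_n_perm,
                 presence_fraction = presence_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Per-plant trait matrix for one phase
#'
#' @param trait_table output of [build_trait_table()]
#' @param phase "early" or "late"
#' @param traits trait columns to keep
#' @return numeric matrix with plant ids as row names; a \code{groups}
#'   attribute holds the substance x condition label per row
#' @export
trait_matrix <- function(trait_table, phase = "late",
                         traits = c("db_end", "rgr", "fvp_fmp", "phi_psii",
                                    "npq", "qy_max", "qy_lss4", "delta_t",
                                    "wue")) {
  tt <- trait_table[trait_table$phase == phase, , drop = FALSE]
  m <- as.matrix(tt[, traits, drop = FALSE])
  rownames(m) <- tt$plant_id
  attr(m, "groups") <- paste(tt$substance, tt$condition, sep = "_")
  m
}

#' Replace residual missing abundances by half the compound minimum
#'
#' Standard metabolomics imputation applied after the presence filter so the
#' multivariate stages see a complete matrix. Compounds entirely missing are
#' dropped.
#' @param ft a [feature_table()]
#' @return complete \code{feature_table}
#' @export
ft_impute_halfmin <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  ab <- ft$abundance
  all_na <- colSums(!is.na(ab)) == 0
  if (any(all_na)) {
    ab <- ab[, !all_na, drop = FALSE]
    ft$compounds <- ft$compounds[!all_na, , drop = FALSE]
  }
  for (j in which(colSums(is.na(ab)) > 0))
    ab[is.na(ab[, j]), j] <- min(ab[, j], na.rm = TRUE) / 2
  feature_table(ab, ft$samples, ft$compounds)
}

#' Run the full phenomics-metabolomics pipeline
#'
#' Executes, in order: synthetic-data generation (or file input), trait
#' derivation, PBC scoring and classification, Ward HCA of the phenotype and
#' metabolite blocks, presence filtering, OPLS-DA with VIP ranking and the
#' validation battery, per-substance volcano analysis with pathway-category
#' aggregation, random-forest trait importance, trait-metabolite correlation
#' for the top-ranked trait, and co-inertia/RV concordance. Identical
#' config + seed gives an identical report. When \code{out_dir} is given,
#' every stage's tables are written (CSV/JSON/Newick) as they are produced.
#'
#' @param config a [run_config()]
#' @param observations optional phenotyping data.frame (overrides synthesis)
#' @param features optional [feature_table()] (overrides synthesis)
#' @param out_dir optional output directory
#' @return list of stage outputs (see Details) with a provenance block
#' @export
run_pipeline <- function(config, observations = NULL, features = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) if (!is.null(out_dir)) writer(
    file.path(out_dir, name))
  log <- list()

  # stage 1: inputs
  if (is.null(observations) || is.null(features)) {
    sim <- simulate_experiment(config$synth)
    if (is.null(observations)) observations <- sim$observations
    if (is.null(features)) features <- sim$features
  }
  emit("observations.csv", function(p) write_phenotyping(observations, p))
  log$n_observations <- nrow(observations)

  # stage 2: traits
  traits <- build_trait_table(observations, crop = observations$crop[1])
  emit("traits.csv",
       function(p) utils::write.csv(traits, p, row.names = FALSE))
  log$n_trait_rows <- nrow(traits)

  # stage 3: PBC index
  pbc <- pbc_pipeline(traits, tolerance = config$pbc_tolerance)
  emit("pbc_records.csv",
       function(p) utils::write.csv(pbc$records, p, row.names = FALSE))
  emit("pbc_classification.csv",
       function(p) utils::write.csv(pbc$classification, p, row.names = FALSE))

  # stage 4: phenotype HCA on group means of uv-scaled late-phase traits
  tm <- trait_matrix(traits, "late")
  gm <- apply(tm, 2, function(col) tapply(col, attr(tm, "groups"), mean))
  hca_pheno <- ward_hca(.scale_block(gm, "uv")$X, config$hca_distance)
  emit("hca_phenotype.nwk", function(p) hca_newick(hca_pheno, p))

  # stage 5: presence filter + metabolite HCA + OPLS-DA battery
  ft <- presence_filter(features, config$presence_fraction)
  log$n_compounds_in <- ncol(features$abundance)
  log$n_compounds_retained <- ncol(ft$abundance)
  ft <- ft_impute_halfmin(ft)
  lab <- log2(ft$abundance)
  gmm <- apply(lab, 2, function(col) tapply(col, ft_groups(ft), mean))
  hca_metab <- ward_hca(gmm, "squared_euclidean")
  emit("hca_metabolome.nwk", function(p) hca_newick(hca_metab, p))

  cls <- ft_groups(ft)
  folds <- min(config$folds, min(table(cls)))
  mva <- opls_validate(lab, cls, n_ortho = config$n_ortho, folds = folds,
                       n_perm = config$n_perm, scaling = config$mva_scaling,
                       seed = config$seed, n_pred = config$n_pred)
  vip <- mva$model$vip
  disc <- select_discriminant(vip, config$vip_threshold)
  log$n_vip_selected <- length(disc)
  emit("vip.csv", function(p) utils::write.csv(
    data.frame(compound_id = names(vip), vip = as.numeric(vip),
               discriminant = names(vip) %in% disc), p, row.names = FALSE))
  emit("opls_scores.csv", function(p) utils::write.csv(
    data.frame(sample_id = rownames(ft$abundance), group = as.character(cls),
               mva$model$Tp), p, row.names = FALSE))
  emit("opls_summary.json", function(p) jsonlite::write_json(
    list(r2y = mva$r2y, q2y = mva$q2y, cv_anova_p = mva$cv_anova_p,
         permutation_p = if (is.na(mva$permutation_p)) "skipped"
                         else mva$permutation_p,
         n_permutations = mva$n_permutations,
         n_pred = mva$model$n_pred, n_ortho = mva$model$n_ortho),
    p, auto_unbox = TRUE, digits = NA))

  # stage 6: volcano per substance vs matched control, within condition
  control <- config$synth$substances[1]
  volcanoes <- list()
  categories <- list()
  for (cond in unique(ft$samples$condition)) {
    for (s in setdiff(unique(ft$samples$substance), control)) {
      key <- paste(s, cond, sep = "_")
      ref <- paste(control, cond, sep = "_")
      if (!all(c(key, ref) %in% levels(cls))) next
      v <- volcano(ft, c(key, ref), alpha = config$volcano_alpha,
                   fc_threshold = config$volcano_fc)
      volcanoes[[key]] <- v
      categories[[key]] <- category_cumulative_fc(v, ft$compounds)
    }
  }
  log$n_volcano_significant <- vapply(volcanoes,
                                      function(v) sum(v$significant),
                                      integer(1))
  emit("volcano.csv", function(p) utils::write.csv(
    do.call(rbind, lapply(names(volcanoes), function(k)
      cbind(contrast = k, volcanoes[[k]]))), p, row.names = FALSE))

  # stage 7: random-forest trait importance on late-phase traits
  rf <- rf_trait_importance(tm, attr(tm, "groups"),
                            n_trees = config$n_trees, seed = config$seed)
  emit("rf_importance.csv", function(p) utils::write.csv(
    data.frame(trait = names(rf$importance),
               importance = as.numeric(rf$importance),
               rank = as.integer(rf$rank)), p, row.names = FALSE))

  # stage 8: trait-metabolite correlation for the top-ranked trait
  top_trait <- names(rf$importance)[rf$rank == 1]
  aligned <- intersect(rownames(tm), rownames(ft$abundance))
  cor_tab <- trait_metabolite_correlation(
    tm[aligned, top_trait, drop = FALSE], ft_subset_samples(
      ft, match(aligned, rownames(ft$abundance))), alpha = config$cor_alpha)
  emit("correlation.csv",
       function(p) utils::write.csv(cor_tab, p, row.names = FALSE))

  # stage 9: co-inertia / RV between aligned blocks
  cia <- coinertia(tm[aligned, , drop = FALSE],
                   lab[aligned, , drop = FALSE])
  rv_test <- if (config$rv_n_perm >= 1)
    rv_permutation_test(tm[aligned, , drop = FALSE],
                        lab[aligned, , drop = FALSE],
                        n_perm = config$rv_n_perm, seed = config$seed)
  else list(p = NA_real_, rv_obs = cia$rv, rv_perm = numeric(0))
  emit("cia_summary.json", function(p) jsonlite::write_json(
    list(rv = cia$rv, rv_p = if (is.na(rv_test$p)) "skipped" else rv_test$p,
         singular_values = cia$singular_values),
    p, auto_unbox = TRUE, digits = NA))

  report <- list(
    traits = traits, pbc = pbc,
    hca_phenotype = hca_pheno, hca_metabolome = hca_metab,
    mva = mva[c("r2y", "q2y", "cv_anova_p", "permutation_p",
                "n_permutations")],
    vip = vip, discriminant_compounds = disc,
    volcano = volcanoes, categories = categories,
    rf = rf, top_trait = top_trait, correlation = cor_tab,
    cia = cia, rv_test = rv_test[c("p", "rv_obs")],
    log = log,
    provenance = list(seed = config$seed,
                      crop = config$synth$crop,
                      package_version = as.character(
                        utils::packageVersion("phenometab")))
  )
  emit("report.json", function(p) jsonlite::write_json(
    list(provenance = report$provenance, log = log,
         mva = report$mva, rv = rv_test$rv_obs),
    p, auto_unbox = TRUE, digits = NA))
  report
}
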
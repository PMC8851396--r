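# CSV dialect: UTF-8, comma-separated, mandatory header, missing = empty cell.

.pheno_required <- c("plant_id", "crop", "substance", "condition", "dop",
                     "psa_top", "psa_side", "F0", "Fm",
                     "Ft_lss2", "Fm_prime_lss2", "F0_prime_lss2",
                     "Ft_lss4", "Fm_prime_lss4", "F0_prime_lss4",
                     "t_canopy", "t_chamber", "water_added")

#' Write phenotyping observations to CSV
#' @param observations data.frame as produced by [generate_phenotyping()]
#' @param path output file
#' @export
write_phenotyping <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a phenotyping CSV
#'
#' Enforces the column registry and per-row sanity checks (positive areas,
#' temperatures within 0-50 degrees C, non-negative day of phenotyping).
#' Invalid rows are rejected and reported via the \code{rejected} attribute
#' and a warning, never silently dropped.
#'
#' @param path CSV path
#' @return data.frame of validated observations; \code{attr(, "rejected")}
#'   holds the rejected rows with a \code{reason} column
#' @export
read_phenotyping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.pheno_required, names(df))
  if (length(miss))
    stop("phenotyping file missing column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(df))
  bad_area <- !is.finite(df$psa_top) | !is.finite(df$psa_side) |
    df$psa_top <= 0 | df$psa_side <= 0
  bad_temp <- !is.finite(df$t_canopy) | !is.finite(df$t_chamber) |
    df$t_canopy < 0 | df$t_canopy > 50 | df$t_chamber < 0 | df$t_chamber > 50
  bad_dop <- !is.finite(df$dop) | df$dop < 0
  reason[bad_dop] <- "invalid dop"
  reason[bad_temp] <- "temperature outside 0-50 C"
  reason[bad_area] <- "non-positive projected area"
  ok <- is.na(reason)
  out <- df[ok, , drop = FALSE]
  rej <- df[!ok, , drop = FALSE]
  if (nrow(rej)) {
    rej$reason <- reason[!ok]
    warning(nrow(rej), " row(s) rejected during phenotyping import")
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Write a feature table as CSV (abundances + metadata + categories)
#'
#' Three files: \code{<stem>.csv} (wide matrix, first column sample_id,
#' missing as empty cells), \code{<stem>_samples.csv} and
#' \code{<stem>_compounds.csv}.
#'
#' @param ft a [feature_table()]
#' @param stem path stem without extension
#' @return the three paths, invisibly
#' @export
write_feature_table <- function(ft, stem) {
  stopifnot(inherits(ft, "feature_table"))
  ab <- data.frame(sample_id = rownames(ft$abundance), ft$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  paths <- paste0(stem, c(".csv", "_samples.csv", "_compounds.csv"))
  utils::write.csv(ab, paths[1], row.names = FALSE, na = "")
  utils::write.csv(ft$samples, paths[2], row.names = FALSE, na = "")
  utils::write.csv(ft$compounds, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a feature table from CSV
#'
#' Blank cells are read as missing (\code{NA}), never as zero. Sample ids
#' must match between the abundance matrix and the metadata; duplicate
#' compound ids are an error.
#'
#' @param path abundance CSV (first column sample_id)
#' @param metadata_path sample metadata CSV
#' @param compounds_path optional compound annotation CSV; when missing every
#'   compound is categorised "unmapped"
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path, metadata_path, compounds_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(metadata_path)) stop("file not found: ", metadata_path)
  ab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(ab)[1] != "sample_id") stop("first column must be sample_id")
  if (anyDuplicated(names(ab)[-1]))
    stop("duplicate compound ids: ",
         paste(utils::head(unique(names(ab)[-1][duplicated(names(ab)[-1])]), 5),
               collapse = ", "))
  m <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ab$sample_id
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!setequal(meta$sample_id, rownames(m)))
    stop("sample ids differ between abundance and metadata: ",
         paste(utils::head(c(setdiff(meta$sample_id, rownames(m)),
                             setdiff(rownames(m), meta$sample_id)), 5),
               collapse = ", "))
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  cmp <- if (!is.null(compounds_path)) {
    utils::read.csv(compounds_path, stringsAsFactors = FALSE)
  } else {
    data.frame(compound_id = colnames(m), category = "unmapped",
               stringsAsFactors = FALSE)
  }
  cmp <- cmp[match(colnames(m), cmp$compound_id), , drop = FALSE]
  if (anyNA(cmp$compound_id)) stop("compound annotation incomplete")
  rownames(cmp) <- NULL
  feature_table(m, meta, cmp)
}

#' Serialize / restore a synthetic-experiment configuration
#'
#' JSON round trip of a [synth_config()]; every field survives unchanged.
#' @param config a [synth_config()]
#' @param path JSON path
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth_config(
    crop = x$crop, n_reps = x$n_reps, substances = x$substances,
    conditions = x$conditions, dops = x$dops,
    salt_growth_reduction = x$salt_growth_reduction,
    substance_growth_effect = unlist(x$substance_growth_effect),
    substance_chlf_effect = unlist(x$substance_chlf_effect),
    n_compounds = x$n_compounds, n_latent = x$n_latent,
    coupling = x$coupling, noise_cv = x$noise_cv, plant_sd = x$plant_sd,
    metab_effect_sd = x$metab_effect_sd, metab_noise_sd = x$metab_noise_sd,
    metab_reps = x$metab_reps, missing_fraction = x$missing_fraction,
    seed = x$seed)
}
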
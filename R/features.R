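#' Metabolomics feature table
#'
#' Container for an annotated untargeted-metabolomics dataset: an abundance
#' matrix (samples x compounds, missing values as \code{NA}), per-sample
#' metadata (substance, condition, replicate) and a compound-to-category
#' annotation table.
#'
#' @param abundance numeric matrix, samples in rows, compounds in columns;
#'   row names are sample ids, column names compound ids
#' @param samples data.frame with at least \code{sample_id},
#'   \code{substance}, \code{condition}; one row per abundance row
#' @param compounds data.frame with \code{compound_id} and \code{category};
#'   one row per abundance column
#' @return object of class \code{feature_table}
#' @export
feature_table <- function(abundance, samples, compounds) {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) stop("abundance must be numeric")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate compound ids in abundance matrix")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate sample ids in abundance matrix")
  req <- c("sample_id", "substance", "condition")
  if (!all(req %in% names(samples)))
    stop("samples metadata must contain: ", paste(req, collapse = ", "))
  if (nrow(samples) != nrow(abundance))
    stop("samples metadata rows do not match abundance rows")
  if (!identical(as.character(samples$sample_id), rownames(abundance)))
    stop("sample ids in metadata do not match abundance row names")
  if (!all(c("compound_id", "category") %in% names(compounds)))
    stop("compounds annotation must contain compound_id and category")
  cn <- colnames(abundance)
  if (is.null(cn)) cn <- character(0)
  if (!identical(as.character(compounds$compound_id), cn))
    stop("compound ids in annotation do not match abundance column names")
  if (any(abundance <= 0, na.rm = TRUE))
    stop("abundances must be positive (use NA for missing)")
  structure(list(abundance = abundance, samples = samples,
                 compounds = compounds), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$abundance), "samples x",
      ncol(x$abundance), "compounds\n")
  cat("  groups:", length(unique(paste(x$samples$substance,
                                       x$samples$condition))), "\n")
  cat("  missing:", sum(is.na(x$abundance)), "cells\n")
  invisible(x)
}

#' Treatment-group labels of a feature table
#' @param ft a [feature_table()]
#' @return factor of substance x condition group per sample
#' @export
ft_groups <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  factor(paste(ft$samples$substance, ft$samples$condition, sep = "_"))
}

#' Presence filter (the "75% rule")
#'
#' Retains a compound only if it was detected (non-missing) in at least
#' \code{fraction} of the replicates of at least one treatment group.
#' Abundances are never altered.
#'
#' @param ft a [feature_table()]
#' @param fraction required presence fraction within at least one group,
#'   in (0, 1]; default 0.75
#' @return filtered \code{feature_table}; the number of removed compounds is
#'   available as \code{attr(, "n_removed")}
#' @export
presence_filter <- function(ft, fraction = 0.75) {
  stopifnot(inherits(ft, "feature_table"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  g <- ft_groups(ft)
  if (!nlevels(g)) stop("no treatment-group metadata")
  pres <- !is.na(ft$abundance)
  keep <- rep(FALSE, ncol(pres))
  for (lev in levels(g)) {
    frac <- colMeans(pres[g == lev, , drop = FALSE])
    keep <- keep | (frac >= fraction)
  }
  out <- feature_table(ft$abundance[, keep, drop = FALSE],
                       ft$samples,
                       ft$compounds[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Subset a feature table by sample
#' @param ft a [feature_table()]
#' @param idx logical or integer sample index
#' @return subsetted \code{feature_table}
#' @export
ft_subset_samples <- function(ft, idx) {
  feature_table(ft$abundance[idx, , drop = FALSE],
                ft$samples[idx, , drop = FALSE],
                ft$compounds)
}
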
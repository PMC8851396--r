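#' Volcano analysis: ANOVA + fold-change filtering of compounds
#'
#' For each compound, a one-way fixed-effects ANOVA across the contrast
#' groups gives a raw p-value; Bonferroni correction is applied over all
#' tested compounds. The fold change is the ratio of raw (unlogged) group
#' mean abundances, treated over reference. A compound is significant when
#' the adjusted p is below \code{alpha} AND the fold change passes the
#' two-sided threshold (\code{>= fc_threshold} or \code{<= 1/fc_threshold}).
#'
#' @param ft a [feature_table()]
#' @param contrast character vector of length 2: the treated and the
#'   reference group label (as in [ft_groups()]), e.g.
#'   \code{c("H_salt", "CTRL_salt")}; or \code{NULL} to use an omnibus ANOVA
#'   across all groups with FC between the first two
#' @param alpha adjusted-p cut-off (default 0.01)
#' @param fc_threshold fold-change cut-off on the ratio scale (default 1.3)
#' @param anova_groups "contrast" (default): ANOVA across the two contrast
#'   groups only (t-test-equivalent F); "all": omnibus ANOVA across every
#'   group in the table, with FC still taken between the contrast pair
#' @return data.frame per compound: mean_treated, mean_reference, fc,
#'   log2_fc, p, p_adj, significant; compounds whose reference mean is
#'   non-positive or undefined keep their p-values but are excluded from FC
#'   (fc = NA, never significant)
#' @export
volcano <- function(ft, contrast, alpha = 0.01, fc_threshold = 1.3,
                    anova_groups = c("contrast", "all")) {
  stopifnot(inherits(ft, "feature_table"))
  anova_groups <- match.arg(anova_groups)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  g <- ft_groups(ft)
  if (length(contrast) != 2 || !all(contrast %in% levels(g)))
    stop("contrast must name two existing groups")
  use <- if (anova_groups == "all") rep(TRUE, length(g)) else g %in% contrast
  sub <- ft$abundance[use, , drop = FALSE]
  gs <- droplevels(g[use])
  if (any(table(gs) < 2)) stop("both contrast groups need >= 2 replicates")

  m <- ncol(sub)
  p_raw <- rep(NA_real_, m)
  mt <- mr <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    y <- sub[, j]
    ok <- is.finite(y)
    if (sum(ok) < 4 || length(unique(gs[ok])) < 2) next
    yv <- y[ok]; gv <- droplevels(gs[ok])
    if (any(table(gv) < 2)) next
    mt[j] <- mean(yv[gv == contrast[1]])
    mr[j] <- mean(yv[gv == contrast[2]])
    if (stats::var(yv) == 0) { p_raw[j] <- 1; next }
    fit <- stats::oneway.test(yv ~ gv, var.equal = TRUE)
    p_raw[j] <- fit$p.value
  }
  tested <- sum(!is.na(p_raw))
  p_adj <- pmin(1, p_raw * tested)
  fc <- ifelse(is.na(mr) | mr <= 0 | is.na(mt) | mt <= 0, NA_real_, mt / mr)
  sig <- !is.na(p_adj) & !is.na(fc) & p_adj < alpha &
    (fc >= fc_threshold | fc <= 1 / fc_threshold)
  data.frame(
    compound_id = colnames(sub),
    mean_treated = mt, mean_reference = mr,
    fc = fc, log2_fc = log2(fc),
    p = p_raw, p_adj = p_adj, significant = sig,
    stringsAsFactors = FALSE
  )
}

#' Cumulative fold change per pathway category
#'
#' Aggregates the significant compounds of a volcano result by pathway
#' category: the individual log2 fold changes (small dots) and their
#' arithmetic mean per category (large dots). Significant compounds absent
#' from the category map are grouped under "unmapped".
#'
#' @param volcano_result output of [volcano()]
#' @param category_map data.frame with columns \code{compound_id},
#'   \code{category}
#' @return list with \code{summary} (data.frame: category, mean_log2_fc,
#'   count) and \code{members} (data.frame: category, compound_id, log2_fc)
#' @export
category_cumulative_fc <- function(volcano_result, category_map) {
  if (!all(c("compound_id", "category") %in% names(category_map)))
    stop("category_map needs compound_id and category columns")
  sig <- volcano_result[volcano_result$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig))
    return(list(summary = data.frame(category = character(0),
                                     mean_log2_fc = numeric(0),
                                     count = integer(0)),
                members = data.frame(category = character(0),
                                     compound_id = character(0),
                                     log2_fc = numeric(0))))
  cat_of <- category_map$category[match(sig$compound_id,
                                        category_map$compound_id)]
  cat_of[is.na(cat_of)] <- "unmapped"
  members <- data.frame(category = cat_of, compound_id = sig$compound_id,
                        log2_fc = sig$log2_fc, stringsAsFactors = FALSE)
  agg <- stats::aggregate(log2_fc ~ category, members, mean)
  cnt <- stats::aggregate(log2_fc ~ category, members, length)
  summary <- data.frame(category = agg$category,
                        mean_log2_fc = agg$log2_fc,
                        count = as.integer(cnt$log2_fc),
                        stringsAsFactors = FALSE)
  list(summary = summary, members = members)
}
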
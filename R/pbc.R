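#' Log2 trait ratio of treated vs control plants
#'
#' One component of the PBC index: \code{log2(treated/control)} for
#' positive-valued traits (DB, RGR, Fv'/Fm', PhiPSII). The canopy temperature
#' depression can be negative, so for \code{trait_kind = "delta_t"} the ratio
#' is computed on absolute canopy temperatures (chamber + depression,
#' strictly positive in degrees C) and inverted so a cooler treated canopy
#' contributes positively. A non-positive mean of a ratio trait (possible for
#' RGR under stress) falls back to the difference scaled by the control's
#' absolute value, with a warning.
#'
#' @param treated_mean,control_mean group means of the trait
#' @param trait_kind "ratio" (default) or "delta_t"
#' @param t_ref reference chamber temperature (degrees C) used to place
#'   temperature depressions on a positive absolute scale
#' @return dimensionless log2 ratio
#' @export
trait_log_ratio <- function(treated_mean, control_mean,
                            trait_kind = c("ratio", "delta_t"),
                            t_ref = 22) {
  trait_kind <- match.arg(trait_kind)
  if (!is.finite(treated_mean) || !is.finite(control_mean))
    stop("group means must be finite")
  if (trait_kind == "delta_t") {
    tt <- t_ref + treated_mean
    tc <- t_ref + control_mean
    if (tt <= 0 || tc <= 0)
      stop("absolute canopy temperatures must be positive (delta_t)")
    return(log2(tc / tt))   # cooler treated canopy scores positive
  }
  if (treated_mean <= 0 || control_mean <= 0) {
    warning("non-positive mean for a ratio trait; ",
            "using scaled difference (treated - control)/|control|")
    return((treated_mean - control_mean) / abs(control_mean))
  }
  log2(treated_mean / control_mean)
}

#' PBC index from the five trait ratios
#'
#' The Plant Biostimulant Characterisation index is the plain sum of the five
#' log2 trait ratios (DB, RGR, Fv'/Fm', PhiPSII, deltaT) of one substance in
#' one condition and phase.
#'
#' @param ratios numeric vector of exactly five finite log2 ratios
#' @return the index (dimensionless)
#' @export
pbc_index <- function(ratios) {
  if (length(ratios) != 5) stop("the PBC index sums exactly five trait ratios")
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  sum(ratios)
}

#' Classify substances from their PBC indexes
#'
#' The sign of the index under control conditions labels a substance a growth
#' promoter (positive) or growth inhibitor (negative); under salt it labels a
#' stress alleviator or stress aggravator. Indexes within \code{tolerance} of
#' zero are labelled neutral.
#'
#' @param pbc data.frame with columns substance, condition, phase, index
#'   (as produced by [pbc_pipeline()])
#' @param tolerance half-width of the neutral band around 0 (default 0.05)
#' @return data.frame substance, condition, phase, index, label
#' @export
classify_substance <- function(pbc, tolerance = 0.05) {
  req <- c("substance", "condition", "phase", "index")
  if (!all(req %in% names(pbc)))
    stop("pbc table must contain: ", paste(req, collapse = ", "))
  for (s in unique(pbc$substance)) {
    have <- unique(pbc$condition[pbc$substance == s])
    if (!all(c("control", "salt") %in% have))
      stop("substance ", s, " lacks an index for condition: ",
           paste(setdiff(c("control", "salt"), have), collapse = ", "))
  }
  lab <- function(index, condition) {
    if (abs(index) < tolerance) return("neutral")
    if (condition == "control") {
      if (index > 0) "growth promoter" else "growth inhibitor"
    } else {
      if (index > 0) "stress alleviator" else "stress aggravator"
    }
  }
  pbc$label <- mapply(lab, pbc$index, pbc$condition)
  pbc[, c("substance", "condition", "phase", "index", "label")]
}

#' PBC scoring of every substance from a trait table
#'
#' For each substance, condition and phase, the mean of each of the five PBC
#' traits (DB at phase end, RGR, Fv'/Fm', PhiPSII, deltaT) over replicates is
#' compared against the same-condition untreated control via
#' [trait_log_ratio()], the five ratios are summed into the PBC index, and
#' substances are classified by index sign.
#'
#' @param trait_table output of [build_trait_table()]
#' @param control code of the untreated control substance (default "CTRL")
#' @param tolerance neutral band for [classify_substance()]
#' @param t_ref reference temperature for the deltaT ratio
#' @return list with \code{records} (one row per substance x condition x
#'   phase: the five ratios and the index) and \code{classification}
#' @export
pbc_pipeline <- function(trait_table, control = "CTRL", tolerance = 0.05,
                         t_ref = 22) {
  tt <- as.data.frame(trait_table)
  if (!control %in% tt$substance)
    stop("trait table lacks the untreated control group '", control, "'")
  traits <- c(db = "db_end", rgr = "rgr", fvp_fmp = "fvp_fmp",
              phi_psii = "phi_psii", delta_t = "delta_t")
  subs <- setdiff(unique(tt$substance), control)
  rows <- list()
  for (cond in unique(tt$condition)) {
    for (ph in unique(tt$phase)) {
      ctl <- tt[tt$substance == control & tt$condition == cond &
                  tt$phase == ph, , drop = FALSE]
      if (!nrow(ctl))
        stop("no control rows for condition ", cond, ", phase ", ph)
      cm <- vapply(traits, function(col) mean(ctl[[col]]), numeric(1))
      for (s in subs) {
        tr <- tt[tt$substance == s & tt$condition == cond &
                   tt$phase == ph, , drop = FALSE]
        if (!nrow(tr)) next
        tm <- vapply(traits, function(col) mean(tr[[col]]), numeric(1))
        ratios <- vapply(names(traits), function(k) {
          trait_log_ratio(tm[[k]], cm[[k]],
                          trait_kind = if (k == "delta_t") "delta_t" else "ratio",
                          t_ref = t_ref)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          substance = s, condition = cond, phase = ph,
          ratio_db = ratios[["db"]], ratio_rgr = ratios[["rgr"]],
          ratio_fvp_fmp = ratios[["fvp_fmp"]],
          ratio_phi_psii = ratios[["phi_psii"]],
          ratio_delta_t = ratios[["delta_t"]],
          index = pbc_index(unname(ratios)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  cls <- if (all(c("control", "salt") %in% records$condition))
    classify_substance(records, tolerance = tolerance)
  else {
    records$label <- NA_character_
    records[, c("substance", "condition", "phase", "index", "label")]
  }
  list(records = records, classification = cls)
}

#' PBC index matrix in publication layout
#'
#' Reshapes PBC records into a substances x (condition, phase) matrix.
#' @param records the \code{records} element of [pbc_pipeline()]
#' @return numeric matrix, rows = substances
#' @export
pbc_matrix <- function(records) {
  key <- paste(records$condition, records$phase, sep = ".")
  subs <- unique(records$substance)
  cols <- unique(key)
  m <- matrix(NA_real_, length(subs), length(cols),
              dimnames = list(subs, cols))
  m[cbind(match(records$substance, subs), match(key, cols))] <- records$index
  m
}

#' Parallel-coordinates plot of the five PBC trait ratios
#'
#' One polyline per substance across the five trait axes, faceting left to
#' the caller (one call per condition x phase).
#' @param records the \code{records} element of [pbc_pipeline()], pre-filtered
#'   to one condition and phase
#' @param ... passed to [graphics::matplot()]
#' @return invisibly, the plotted ratio matrix
#' @export
plot_pbc_parallel <- function(records, ...) {
  rc <- c("ratio_db", "ratio_rgr", "ratio_fvp_fmp", "ratio_phi_psii",
          "ratio_delta_t")
  m <- t(as.matrix(records[, rc]))
  rownames(m) <- c("DB", "RGR", "Fv'/Fm'", "PhiPSII", "dT")
  graphics::matplot(m, type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "", ylab = "log2(treated/control)", ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m))
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = records$substance, bty = "n",
                   col = seq_len(ncol(m)), lty = 1, cex = 0.7)
  invisible(m)
}
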
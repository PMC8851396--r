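#' Digital biomass from projected shoot areas
#'
#' Computes the volume proxy ("digital biomass", DB) of a plant from its
#' top-view and side-view projected shoot areas (PSA). The canonical
#' expression \code{PSA_side^2 * PSA_top} has units of pixels^6; by default a
#' square root is applied so the result is volume-dimensioned (pixels^3),
#' i.e. \code{DB = psa_side * sqrt(psa_top)}. Set \code{sqrt = FALSE} to get
#' the unrooted product.
#'
#' @param psa_top top-view projected shoot area (pixels^2), > 0
#' @param psa_side side-view projected shoot area (pixels^2), > 0
#' @param sqrt logical; apply the square root (default \code{TRUE})
#' @return digital biomass (pixels^3, or pixels^6 when \code{sqrt = FALSE})
#' @examples
#' digital_biomass(100, 200)  # 2000
#' @export
digital_biomass <- function(psa_top, psa_side, sqrt = TRUE) {
  if (any(!is.finite(psa_top)) || any(!is.finite(psa_side)))
    stop("projected shoot areas must be finite")
  if (any(psa_top <= 0) || any(psa_side <= 0))
    stop("projected shoot areas must be strictly positive")
  v <- psa_side^2 * psa_top
  if (sqrt) base::sqrt(v) else v
}

#' Relative growth rate
#'
#' RGR between two time points on the digital-biomass (volume) scale:
#' \code{(ln DM2 - ln DM1) / (T2 - T1)}, in day^-1.
#'
#' @param dm1,dm2 digital biomass at the earlier/later time point, > 0
#' @param t1,t2 days; \code{t2 > t1}
#' @return relative growth rate (day^-1)
#' @examples
#' relative_growth_rate(100, 200, 0, 12)  # log(2)/12
#' @export
relative_growth_rate <- function(dm1, dm2, t1, t2) {
  if (any(dm1 <= 0) || any(dm2 <= 0))
    stop("digital biomass must be strictly positive")
  if (any(t2 <= t1)) stop("t2 must be greater than t1")
  (log(dm2) - log(dm1)) / (t2 - t1)
}

#' Canopy temperature depression
#'
#' Average canopy temperature normalised against the air temperature inside
#' the thermal-imaging chamber: \code{t_canopy - t_chamber} (degrees C).
#' Negative values mean the canopy is cooler than the surrounding air
#' (transpirational cooling); the sign convention is configurable downstream.
#'
#' @param t_canopy,t_chamber temperatures in degrees Celsius
#' @return temperature difference in degrees Celsius
#' @export
delta_t <- function(t_canopy, t_chamber) {
  if (any(!is.finite(t_canopy)) || any(!is.finite(t_chamber)))
    stop("temperatures must be finite")
  t_canopy - t_chamber
}

#' Derived chlorophyll fluorescence parameters
#'
#' Standard PAM quantities from the measured fluorescence levels: dark-adapted
#' maximum quantum yield Fv/Fm = (Fm - F0)/Fm; light-adapted maximum quantum
#' yield Fv'/Fm' = (Fm' - F0')/Fm'; PSII operating efficiency
#' PhiPSII = (Fm' - Ft)/Fm'; non-photochemical quenching
#' NPQ = (Fm - Fm')/Fm'.
#'
#' @param F0,Fm dark-adapted minimum and maximum fluorescence, \code{Fm >= F0 > 0}
#' @param Ft steady-state fluorescence in the light
#' @param Fm_prime,F0_prime light-adapted maximum and minimum fluorescence
#' @return list with components \code{fv_fm}, \code{fvp_fmp}, \code{phi_psii},
#'   \code{npq}
#' @examples
#' chlf_derive(200, 1000, 500, 700, 180)
#' @export
chlf_derive <- function(F0, Fm, Ft, Fm_prime, F0_prime) {
  if (any(F0 <= 0) || any(Fm < F0)) stop("require Fm >= F0 > 0")
  if (any(Fm_prime <= 0)) stop("Fm_prime must be positive")
  if (any(Fm_prime < Ft)) stop("require Fm_prime >= Ft")
  out <- list(
    fv_fm    = (Fm - F0) / Fm,
    fvp_fmp  = (Fm_prime - F0_prime) / Fm_prime,
    phi_psii = (Fm_prime - Ft) / Fm_prime,
    npq      = (Fm - Fm_prime) / Fm_prime
  )
  ys <- c(out$fv_fm, out$fvp_fmp, out$phi_psii)
  if (any(ys < 0 | ys > 1))
    stop("derived quantum yields fall outside [0, 1]: check input fluorescence levels")
  if (any(out$npq < 0))
    stop("NPQ is negative: Fm_prime exceeds dark-adapted Fm")
  out
}

#' Phase window boundaries per crop
#'
#' Early phase runs from day 0 to day 12 for both crops; the late phase ends
#' at day 21 (lettuce) or day 24 (tomato).
#' @param crop "lettuce" or "tomato"
#' @return named vector \code{c(early_end, late_end)}
#' @export
phase_windows <- function(crop = c("lettuce", "tomato")) {
  crop <- match.arg(crop)
  c(early_end = 12, late_end = if (crop == "lettuce") 21L else 24L)
}

#' Build a per-plant, per-phase trait table
#'
#' Aggregates raw per-round plant observations into one row per plant and
#' phase (early: day 0-12, late: day 12 to end of trial). DB is computed at
#' the phase boundaries, RGR from the first/last in-phase DB, the
#' chlorophyll-fluorescence traits and the canopy temperature depression as
#' within-phase means at actinic step Lss2, and WUE as phase biomass gain per
#' unit water added. Plants lacking observations on both sides of a phase
#' window are excluded with a warning.
#'
#' @param observations data.frame of plant observations (one row per plant x
#'   phenotyping day) as produced by [generate_phenotyping()] or
#'   [read_phenotyping()]
#' @param crop "lettuce" or "tomato"; sets the late-phase end day
#' @param db_sqrt passed to [digital_biomass()]
#' @return data.frame with columns plant_id, crop, substance, condition,
#'   phase, db_start, db_end, rgr, fvp_fmp, phi_psii, npq, qy_max, qy_lss4,
#'   delta_t, wue
#' @export
build_trait_table <- function(observations, crop = c("lettuce", "tomato"),
                              db_sqrt = TRUE) {
  crop <- match.arg(crop)
  obs <- as.data.frame(observations)
  req <- c("plant_id", "substance", "condition", "dop", "psa_top", "psa_side",
           "F0", "Fm", "Ft_lss2", "Fm_prime_lss2", "F0_prime_lss2",
           "Ft_lss4", "Fm_prime_lss4",
           "t_canopy", "t_chamber", "water_added")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("observations missing columns: ",
                         paste(miss, collapse = ", "))
  win <- phase_windows(crop)
  phases <- list(early = c(0, win[["early_end"]]),
                 late  = c(win[["early_end"]], win[["late_end"]]))

  obs$db <- digital_biomass(obs$psa_top, obs$psa_side, sqrt = db_sqrt)
  chlf <- chlf_derive(obs$F0, obs$Fm, obs$Ft_lss2, obs$Fm_prime_lss2,
                      obs$F0_prime_lss2)
  obs$fvp_fmp <- chlf$fvp_fmp
  obs$phi_psii <- chlf$phi_psii
  obs$npq <- chlf$npq
  obs$qy_max <- chlf$fv_fm
  obs$qy_lss4 <- (obs$Fm_prime_lss4 - obs$Ft_lss4) / obs$Fm_prime_lss4
  obs$dt <- delta_t(obs$t_canopy, obs$t_chamber)

  rows <- list()
  dropped <- character(0)
  for (pid in unique(obs$plant_id)) {
    po <- obs[obs$plant_id == pid, , drop = FALSE]
    po <- po[order(po$dop), , drop = FALSE]
    for (ph in names(phases)) {
      lo <- phases[[ph]][1]; hi <- phases[[ph]][2]
      inph <- po[po$dop >= lo & po$dop <= hi, , drop = FALSE]
      # need at least two rounds inside the window to measure growth
      if (nrow(inph) < 2 || diff(range(inph$dop)) <= 0) {
        dropped <- c(dropped, paste0(pid, "/", ph))
        next
      }
      d0 <- inph[1, ]; d1 <- inph[nrow(inph), ]
      water <- sum(inph$water_added, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = pid, crop = crop,
        substance = po$substance[1], condition = po$condition[1],
        phase = ph,
        db_start = d0$db, db_end = d1$db,
        rgr = relative_growth_rate(d0$db, d1$db, d0$dop, d1$dop),
        fvp_fmp = mean(inph$fvp_fmp), phi_psii = mean(inph$phi_psii),
        npq = mean(inph$npq), qy_max = mean(inph$qy_max),
        qy_lss4 = mean(inph$qy_lss4),
        delta_t = mean(inph$dt),
        wue = if (water > 0) (d1$db - d0$db) / water else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(dropped))
    warning(length(dropped), " plant/phase combinations excluded for ",
            "insufficient in-phase coverage: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (!length(rows)) stop("no plant has sufficient phase coverage")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise group comparison of a trait (ANOVA + Tukey HSD)
#'
#' One-way fixed-effects ANOVA on substance x condition groups for a single
#' trait within one phase, followed by Tukey's honest significant difference
#' for all pairwise contrasts. This is a deliberate simplification of a
#' repeated-measures mixed model: phase aggregation removes the longitudinal
#' structure first.
#'
#' @param trait_table output of [build_trait_table()]
#' @param trait trait column name (e.g. "rgr")
#' @param phase "early" or "late"
#' @return list with \code{anova_p}, \code{group_means} and \code{pairs}
#'   (data.frame: group1, group2, diff, p_adj)
#' @export
compare_groups <- function(trait_table, trait, phase = c("early", "late")) {
  phase <- match.arg(phase)
  tt <- trait_table[trait_table$phase == phase, , drop = FALSE]
  if (!trait %in% names(tt)) stop("unknown trait: ", trait)
  g <- factor(paste(tt$substance, tt$condition, sep = "_"))
  y <- tt[[trait]]
  ok <- is.finite(y)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two replicates")
  if (all(tapply(y, g, stats::var) == 0))
    stop("zero within-group variance in every group")
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit)$g
  pr <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  list(
    anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
    group_means = tapply(y, g, mean),
    pairs = data.frame(group1 = pr[, 1], group2 = pr[, 2],
                       diff = tk[, "diff"], p_adj = tk[, "p adj"],
                       row.names = NULL, stringsAsFactors = FALSE)
  )
}
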
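# Batch-culture characterization: spherical cell volume, viable cell
# volume, cumulative cell days (log-mean integral of VCD), growth rate and
# specific productivity via maximum-correlation window selection, 2^-ddCt
# knockdown quantification, and per-timepoint comparison against a mock
# control.

#' Volume of a spherical cell
#'
#' `4/3 * pi * (d/2)^3`, assuming the cell is a perfect sphere.
#'
#' @param diameter_um viable cell diameter in um (vectorized, > 0).
#' @return volume per cell in um^3.
#' @examples
#' volumePerCell(15)  # 1767.1459 um^3
#' @export
volumePerCell <- function(diameter_um) {
  if (any(!is.finite(diameter_um) | diameter_um <= 0)) {
    .csError("DomainError", "cell diameter must be positive")
  }
  4 / 3 * pi * (diameter_um / 2)^3
}

#' Viable cell volume
#'
#' Total volume of viable cells per ml: `volume_per_cell * 1e-9 * VCD`
#' (um^3 to mm^3 conversion).
#'
#' @param vcd_cells_per_ml viable cell density (cells/ml, >= 0).
#' @param volume_per_cell_um3 per-cell volume (um^3, >= 0).
#' @return VCV in mm^3/ml.
#' @export
viableCellVolume <- function(vcd_cells_per_ml, volume_per_cell_um3) {
  if (any(vcd_cells_per_ml < 0) || any(volume_per_cell_um3 < 0)) {
    .csError("DomainError", "VCD and cell volume must be non-negative")
  }
  volume_per_cell_um3 * 1e-9 * vcd_cells_per_ml
}

#' Cumulative cell days
#'
#' Running integral of viable cell density over time using the log-mean
#' interval term
#' `(VCD_{i+1} - VCD_i) * (t_{i+1} - t_i) / ((ln VCD_{i+1} - ln VCD_i) * 24)`
#' with time in hours post transfection (the division by 24 yields days).
#' A degenerate interval (`VCD_{i+1} == VCD_i`) uses the continuous limit
#' `VCD_i * dt / 24`. On an exactly exponential trajectory the result
#' equals the analytic integral `(VCD(t) - VCD(0)) / (mu * 24)` at every
#' point. The identical formula applied to VCV scaled by 1e-3 gives the
#' volume-based cumulative quantity in cm^3 * days.
#'
#' @param t_hours strictly increasing sampling times (hours).
#' @param vcd viable cell densities (> 0) at `t_hours`.
#' @return cumulative cell days at each time point (first element 0), in
#'   `cells * days` per ml for VCD input.
#' @examples
#' cumulativeCellDays(c(0, 24), c(1e5, 2e5))  # 0, 1e5/log(2)
#' @export
cumulativeCellDays <- function(t_hours, vcd) {
  if (length(t_hours) != length(vcd) || length(vcd) < 2L) {
    .csError("DomainError", "need >= 2 matched (time, VCD) points")
  }
  if (any(diff(t_hours) <= 0)) {
    .csError("DomainError", "time points must be strictly increasing")
  }
  if (any(!is.finite(vcd) | vcd <= 0)) {
    .csError("DomainError", "VCD must be positive at every analyzed point")
  }
  n <- length(vcd)
  v1 <- vcd[-n]
  v2 <- vcd[-1L]
  dt <- diff(t_hours)
  term <- ifelse(v2 == v1,
                 v1 * dt / 24,
                 (v2 - v1) * dt / ((log(v2) - log(v1)) * 24))
  c(0, cumsum(term))
}

#' Combine replicate culture series onto a common trajectory
#'
#' Replicates are rescaled so that their anchor measurements coincide
#' (seeding-density correction), then averaged pointwise. The anchor is the
#' first measurement for growth quantities (VCD/VCV) and the second time
#' point for cumulative quantities (whose first value is identically 0).
#' Time grids are matched to the first replicate's grid by nearest time
#' point within a tolerance.
#'
#' @param series data.frame with columns `replicate`, `t` (hours) and
#'   `value`.
#' @param reference anchor value the replicates are rescaled to; default is
#'   the mean of the replicate anchors.
#' @param anchor_index index of the anchor time point (1 for growth, 2 for
#'   cumulative cell days).
#' @param tolerance_h maximum time distance for grid matching.
#' @return data.frame with `t`, combined `value`, and `n_replicates` used
#'   per point.
#' @export
combineCultureReplicates <- function(series, reference = NULL,
                                     anchor_index = 1L, tolerance_h = 2) {
  reps <- split(series, series$replicate)
  if (length(reps) < 2L) {
    warning("single replicate returned unchanged")
    r <- reps[[1L]]
    return(data.frame(t = r$t, value = r$value, n_replicates = 1L))
  }
  grid <- reps[[1L]]$t
  mat <- vapply(reps, function(r) {
    vapply(grid, function(tt) {
      i <- which.min(abs(r$t - tt))
      if (abs(r$t[i] - tt) <= tolerance_h) r$value[i] else NA_real_
    }, numeric(1L))
  }, numeric(length(grid)))
  anchors <- mat[anchor_index, ]
  if (any(!is.finite(anchors) | anchors <= 0)) {
    .csError("DomainError", "replicate anchor measurements must be positive")
  }
  if (is.null(reference)) reference <- mean(anchors)
  scaled <- sweep(mat, 2L, reference / anchors, `*`)
  data.frame(t = grid,
             value = rowMeans(scaled, na.rm = TRUE),
             n_replicates = rowSums(is.finite(scaled)))
}

# Maximum-correlation window search shared by growth rate and specific
# productivity: Pearson r of y vs x over windows [start .. k] for k with at
# least `min_points` points; returns the window end with the highest r.
# r values are compared at 1e-10 tolerance; exact ties go to the LATEST
# eligible end so that noiseless data uses all collinear points.
.maxCorWindow <- function(x, y, start, min_points) {
  n <- length(x)
  ends <- seq.int(start + min_points - 1L, n)
  if (!length(ends) || ends[1L] > n) {
    .csError("DomainError", sprintf(
      "need at least %d time points from position %d", min_points, start))
  }
  r <- vapply(ends, function(k) {
    xs <- x[start:k]
    if (stats::var(xs) == 0) {
      .csError("DomainError", "zero time/abscissa variance in window")
    }
    if (stats::var(y[start:k]) == 0) return(0)
    stats::cor(xs, y[start:k])
  }, numeric(1L))
  best <- max(r)
  tpxy <- ends[max(which(r >= best - 1e-10))]
  list(tpxy = tpxy, r_max = r[ends == tpxy])
}

.olsSlope <- function(x, y) {
  stats::cov(x, y) / stats::var(x)
}

#' Exponential growth rate via the maximum-correlation window
#'
#' Pearson correlations between ln-transformed VCD (or VCV) and culture
#' time are computed for windows starting at the first analyzed time point
#' (TP01) and including at least `min_points` points; the window end with
#' the highest correlation (r_MAX) defines TPXY. The growth rate is the
#' ordinary least-squares slope of ln(VCD) versus time (1/h) over
#' TP01..TPXY, or over TP01..`window_end` when a common window end across
#' treatments is imposed (the minimum TPXY over the treatments being
#' compared).
#'
#' @param t_hours sampling times (hours post transfection).
#' @param vcd viable cell density (or VCV) at each time.
#' @param min_points minimum window length (4).
#' @param window_end optional imposed window end index.
#' @return list with `rate` (1/h), `r_max`, `tpxy` (index of the selected
#'   window end), and `window_end` actually used for the slope.
#' @export
growthRate <- function(t_hours, vcd, min_points = 4L, window_end = NULL) {
  if (any(!is.finite(vcd) | vcd <= 0)) {
    .csError("DomainError", "VCD must be positive for ln transformation")
  }
  lnv <- log(vcd)
  w <- .maxCorWindow(t_hours, lnv, start = 1L, min_points = min_points)
  end <- window_end %||% w$tpxy
  list(rate = .olsSlope(t_hours[1:end], lnv[1:end]),
       r_max = w$r_max, tpxy = w$tpxy, window_end = end)
}

#' Growth rates of several arms with a common window end
#'
#' Applies [growthRate()] to each arm of a comparison set (a mock control
#' and its knockdown arms) and refits every slope on the common interval
#' TP01..min(TPXY over arms).
#'
#' @param series_list named list; each element a list/data.frame with `t`
#'   and `value`.
#' @param min_points minimum window length.
#' @return data.frame per arm: `rate`, `r_max`, `tpxy`, `window_end`.
#' @export
growthRates <- function(series_list, min_points = 4L) {
  fits <- lapply(series_list, function(s)
    growthRate(s$t, s$value, min_points = min_points))
  common <- min(vapply(fits, `[[`, integer(1L), "tpxy"))
  out <- do.call(rbind, lapply(names(series_list), function(a) {
    s <- series_list[[a]]
    f <- growthRate(s$t, s$value, min_points = min_points,
                    window_end = common)
    data.frame(arm = a, rate = f$rate, r_max = f$r_max, tpxy = f$tpxy,
               window_end = common, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Specific productivity via the maximum-correlation window
#'
#' Pearson correlations between cumulative cell days (CCD, cell- or
#' volume-based) and titer are computed for windows starting at the second
#' measurement (TP02, the first with a non-zero integral) including at
#' least `min_points` points; the end with the highest correlation defines
#' TPXY. The specific productivity is the least-squares slope of titer
#' versus CCD over TP01..TPXY (or an imposed common end), scaled by
#' `unit_factor`: with titer in ug/ml and CCD in cells*days/ml the default
#' 1e6 yields pg/(cell*day); for CCD_CV in cm^3*days/ml use 1e-3 for
#' mg/(cm^3*day).
#'
#' @param t_hours sampling times (used only for ordering/diagnostics).
#' @param ccd cumulative cell days at each time point.
#' @param titer product concentration at each time point.
#' @param min_points minimum window length (5).
#' @param window_end optional imposed window end index.
#' @param unit_factor slope scale factor.
#' @return list with `qp`, `r_max`, `tpxy`, `window_end`.
#' @export
specificProductivity <- function(t_hours, ccd, titer, min_points = 5L,
                                 window_end = NULL, unit_factor = 1e6) {
  if (length(ccd) != length(titer)) {
    .csError("DomainError", "CCD and titer series must be matched")
  }
  w <- .maxCorWindow(ccd, titer, start = 2L, min_points = min_points)
  end <- window_end %||% w$tpxy
  list(qp = .olsSlope(ccd[1:end], titer[1:end]) * unit_factor,
       r_max = w$r_max, tpxy = w$tpxy, window_end = end)
}

#' Specific productivities of several arms with a common window end
#'
#' @param series_list named list; each element with `ccd` and `titer`
#'   (and optionally `t`).
#' @param min_points minimum window length.
#' @param unit_factor slope scale factor (see [specificProductivity()]).
#' @return data.frame per arm: `qp`, `r_max`, `tpxy`, `window_end`.
#' @export
specificProductivities <- function(series_list, min_points = 5L,
                                   unit_factor = 1e6) {
  fits <- lapply(series_list, function(s)
    specificProductivity(s$t %||% seq_along(s$ccd), s$ccd, s$titer,
                         min_points = min_points, unit_factor = unit_factor))
  common <- min(vapply(fits, `[[`, integer(1L), "tpxy"))
  out <- do.call(rbind, lapply(names(series_list), function(a) {
    s <- series_list[[a]]
    f <- specificProductivity(s$t %||% seq_along(s$ccd), s$ccd, s$titer,
                              min_points = min_points, window_end = common,
                              unit_factor = unit_factor)
    data.frame(arm = a, qp = f$qp, r_max = f$r_max, tpxy = f$tpxy,
               window_end = common, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are summarized by their mean;
#' `dCt = mean(Ct_target) - mean(Ct_reference)` (reference gene, e.g.
#' Gapdh), `ddCt = dCt_sample - dCt_calibrator` (calibrator, e.g. the mock
#' transfection), fold change `2^-ddCt`, knockdown `%(1 - fold) * 100`.
#'
#' @param target_ct,reference_ct Ct replicates of the target and reference
#'   gene in the sample.
#' @param calibrator_dct dCt of the calibrator; alternatively supply
#'   `calibrator_target_ct` and `calibrator_reference_ct`.
#' @param calibrator_target_ct,calibrator_reference_ct calibrator Ct
#'   replicates.
#' @return list with `dct`, `ddct`, `fold_change`, `knockdown_pct`.
#' @examples
#' ddctFoldChange(22, 15, calibrator_target_ct = 20,
#'                calibrator_reference_ct = 15)  # fold 0.25, 75% knockdown
#' @export
ddctFoldChange <- function(target_ct, reference_ct, calibrator_dct = NULL,
                           calibrator_target_ct = NULL,
                           calibrator_reference_ct = NULL) {
  if (any(!is.finite(c(target_ct, reference_ct)))) {
    .csError("DomainError", "Ct values must be finite")
  }
  dct <- mean(target_ct) - mean(reference_ct)
  if (is.null(calibrator_dct)) {
    if (is.null(calibrator_target_ct) || is.null(calibrator_reference_ct)) {
      .csError("ConfigError", "supply calibrator_dct or the calibrator Cts")
    }
    calibrator_dct <- mean(calibrator_target_ct) - mean(calibrator_reference_ct)
  }
  ddct <- dct - calibrator_dct
  fold <- 2^(-ddct)
  list(dct = dct, ddct = ddct, fold_change = fold,
       knockdown_pct = (1 - fold) * 100)
}

#' Compare knockdown arms against the mock control at one time point
#'
#' One-way ANOVA over arms followed by Dunnett's post hoc test against the
#' mock control; arms with fewer than two replicates are skipped with a
#' status. This provides the +/- significance flag layer over culture
#' trajectories.
#'
#' @param data data.frame with columns `arm` and `value` (one time point,
#'   one row per replicate).
#' @param mock name of the control arm.
#' @param alpha significance level.
#' @return data.frame per non-mock arm: `estimate` (arm minus mock),
#'   `p_value`, `flag` ("+", "-", or ""), `status`.
#' @export
compareToControl <- function(data, mock = "mock", alpha = 0.05) {
  counts <- table(data$arm)
  if (!mock %in% names(counts)) {
    .csError("ConfigError", sprintf("mock arm '%s' not present", mock))
  }
  arms <- setdiff(names(counts), mock)
  skipped <- names(counts)[counts < 2L]
  out <- data.frame(arm = arms, estimate = NA_real_, p_value = NA_real_,
                    flag = "", status = "skipped",
                    stringsAsFactors = FALSE)
  if (mock %in% skipped) return(out)
  keep <- setdiff(arms, skipped)
  if (!length(keep)) return(out)
  d <- data[data$arm %in% c(mock, keep), , drop = FALSE]
  d$arm <- stats::relevel(factor(d$arm), ref = mock)
  means <- tapply(d$value, d$arm, mean)
  if (stats::var(d$value) == 0) {
    # identical arms: nothing to flag
    i <- match(keep, out$arm)
    out$estimate[i] <- 0
    out$p_value[i] <- 1
    out$status[i] <- "ok"
    return(out)
  }
  fit <- stats::aov(value ~ arm, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(arm = "Dunnett"))
  sm <- summary(gl)
  est <- unname(sm$test$coefficients)
  p <- unname(sm$test$pvalues)
  cmp_arms <- sub(" - .*$", "", names(sm$test$coefficients))
  i <- match(cmp_arms, out$arm)
  out$estimate[i] <- est
  out$p_value[i] <- p
  out$flag[i] <- ifelse(p < alpha, ifelse(est > 0, "+", "-"), "")
  out$status[i] <- "ok"
  out
}

#' Read a batch-culture CSV
#'
#' Expects tidy columns `arm`, `replicate`, `hours_post_transfection`,
#' `vcd_cells_per_ml`, `viability_pct`, `diameter_um`, `titer_ug_per_ml`;
#' a named `column_map` (new = old) adapts instrument export layouts.
#'
#' @param path CSV file.
#' @param column_map optional named character vector renaming columns.
#' @return data.frame.
#' @export
readCultureCsv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (new in names(column_map)) {
      names(df)[names(df) == column_map[[new]]] <- new
    }
  }
  need <- c("arm", "replicate", "hours_post_transfection", "vcd_cells_per_ml",
            "viability_pct", "diameter_um", "titer_ug_per_ml")
  if (!all(need %in% names(df))) {
    .csError("ConfigError", sprintf(
      "culture CSV %s needs columns: %s", path, paste(need, collapse = ", ")))
  }
  df
}
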
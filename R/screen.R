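#' Percent titer improvement over a control
#'
#' `100 * (variant / control - 1)`, reported unrounded and rounded to the
#' nearest integer (half away from zero). Decisions elsewhere in the package
#' always use the unrounded value; the rounded one is for display.
#'
#' @param variant_titer,control_titer titers in mM (vectorised).
#' @return data frame with columns `percent` and `rounded`.
#' @export
#' @examples
#' percent_improvement(20.9, 11.5)  # +81.7%, rounds to +82
percent_improvement <- function(variant_titer, control_titer) {
  if (any(control_titer <= 0)) stop("control titer must be positive")
  pct <- 100 * (variant_titer / control_titer - 1)
  data.frame(percent = pct, rounded = round_half_away(pct))
}

#' Confidence interval of the plate-control mean
#'
#' Two-sided t-based confidence interval (default 90%) for the mean titer of
#' the control measurements on one plate; the decision rules compare variant
#' titers against its upper bound.
#'
#' @param titers numeric vector of control titers (length >= 2).
#' @param level two-sided confidence level (default 0.90).
#' @param plate_id optional label.
#' @return list with `plate_id`, `mean`, `sd`, `n`, `low`, `high`, `level`.
#' @export
control_ci <- function(titers, level = 0.90, plate_id = NA_character_) {
  titers <- as.numeric(titers)
  n <- length(titers)
  if (n < 2L) stop("need at least 2 control measurements for a CI")
  m <- mean(titers)
  s <- stats::sd(titers)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) * s / sqrt(n)
  list(plate_id = plate_id, mean = m, sd = s, n = n,
       low = m - half, high = m + half, level = level)
}

#' First-pass screen selection on one or more plates
#'
#' Stage 1 of the two-step characterisation: variants are measured once (no
#' technical replicates) and compared with the control measurements on the
#' same plate only. A variant passes when its titer (a) exceeds the upper
#' bound of the two-sided 90% confidence interval of the control mean and (b)
#' is at least `min_gain_mM` (default 1 mM) above the control mean. Cross-plate
#' comparisons are refused by construction: every decision is relative to its
#' own plate's controls.
#'
#' @param records data frame with columns `strain_id`, `plate_id`, `titer`,
#'   `is_control` (and optionally `biomass`, `replicate`).
#' @param level control-CI confidence level (default 0.90).
#' @param min_gain_mM absolute titer gain threshold in mM (default 1.0).
#' @return data frame of decisions: `strain_id`, `plate_id`, `stage`,
#'   `titer`, `titer_improvement` (percent), `passed`, `reasons`.
#' @export
stage1_select <- function(records, level = 0.90, min_gain_mM = 1.0) {
  r <- as.data.frame(records)
  stopifnot(all(c("strain_id", "plate_id", "titer", "is_control") %in% names(r)))
  out <- lapply(split(r, r$plate_id), function(plate) {
    ctrl <- plate$titer[plate$is_control]
    if (length(ctrl) < 2L) {
      stop("plate '", plate$plate_id[1], "' has fewer than 2 control measurements")
    }
    ci <- control_ci(ctrl, level = level, plate_id = plate$plate_id[1])
    var <- plate[!plate$is_control, , drop = FALSE]
    if (nrow(var) == 0L) return(NULL)
    above_ci <- var$titer > ci$high
    above_gain <- var$titer >= ci$mean + min_gain_mM
    reasons <- mapply(function(a, g) {
      paste(c(if (!a) "within control CI",
              if (!g) sprintf("gain below %.1f mM", min_gain_mM),
              if (a && g) "ok"), collapse = "; ")
    }, above_ci, above_gain)
    data.frame(
      strain_id = var$strain_id,
      plate_id = var$plate_id,
      stage = 1L,
      titer = var$titer,
      titer_improvement = percent_improvement(var$titer, ci$mean)$percent,
      passed = above_ci & above_gain,
      reasons = reasons,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Confirmatory screen decision for one variant
#'
#' Stage 2 of the two-step characterisation: the variant and the same-plate
#' control are measured in technical triplicates. The variant is called
#' *improved* when all three hold: its mean titer exceeds the upper bound of
#' the two-sided 90% confidence interval of the control mean, the titer
#' improvement is at least `min_titer_gain` (default +10%; exactly 10.0%
#' passes), and biomass formation is reduced by at most `max_biomass_loss`
#' (default 35%).
#'
#' @param variant_titers,control_titers numeric triplicates of titers (mM).
#' @param variant_biomass,control_biomass numeric triplicates of final
#'   biomass (OD600); omit both to skip the biomass criterion.
#' @param min_titer_gain minimum relative titer gain (default 0.10).
#' @param max_biomass_loss maximum tolerated relative biomass reduction
#'   (default 0.35).
#' @param level control-CI confidence level (default 0.90).
#' @param strain_id optional label.
#' @return one-row data frame: `strain_id`, `stage`, `titer_improvement`,
#'   `biomass_change` (both percent), `passed`, `reasons`.
#' @export
stage2_confirm <- function(variant_titers, control_titers,
                           variant_biomass = NULL, control_biomass = NULL,
                           min_titer_gain = 0.10, max_biomass_loss = 0.35,
                           level = 0.90, strain_id = NA_character_) {
  if (length(variant_titers) < 3L || length(control_titers) < 3L) {
    stop("stage 2 requires technical triplicates of variant and control")
  }
  ci <- control_ci(control_titers, level = level)
  vm <- mean(variant_titers)
  improvement <- percent_improvement(vm, ci$mean)$percent
  above_ci <- vm > ci$high
  enough_gain <- improvement >= 100 * min_titer_gain
  biomass_change <- NA_real_
  biomass_ok <- TRUE
  if (!is.null(variant_biomass) && !is.null(control_biomass)) {
    if (length(variant_biomass) < 3L || length(control_biomass) < 3L) {
      stop("stage 2 requires technical triplicates of variant and control")
    }
    biomass_change <- 100 * (mean(variant_biomass) / mean(control_biomass) - 1)
    biomass_ok <- biomass_change >= -100 * max_biomass_loss
  }
  reasons <- paste(c(
    if (!above_ci) "within control CI",
    if (!enough_gain) sprintf("titer gain below %.0f%%", 100 * min_titer_gain),
    if (!biomass_ok) sprintf("biomass reduced by more than %.0f%%",
                             100 * max_biomass_loss),
    if (above_ci && enough_gain && biomass_ok) "improved"
  ), collapse = "; ")
  data.frame(strain_id = strain_id, stage = 2L,
             titer_improvement = improvement,
             biomass_change = biomass_change,
             passed = above_ci && enough_gain && biomass_ok,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Apply the confirmatory decision to a plate table
#'
#' Convenience wrapper running [stage2_confirm()] for every non-control strain
#' on each plate against that plate's control triplicate.
#'
#' @param records data frame with `strain_id`, `plate_id`, `replicate`,
#'   `titer`, `biomass`, `is_control`.
#' @param ... passed to [stage2_confirm()].
#' @return data frame of per-strain decisions.
#' @export
screen_stage2 <- function(records, ...) {
  r <- as.data.frame(records)
  out <- lapply(split(r, r$plate_id), function(plate) {
    ctrl <- plate[plate$is_control, , drop = FALSE]
    var <- plate[!plate$is_control, , drop = FALSE]
    if (nrow(var) == 0L) return(NULL)
    per_strain <- lapply(split(var, var$strain_id), function(s) {
      cbind(stage2_confirm(
        s$titer, ctrl$titer,
        if ("biomass" %in% names(s)) s$biomass else NULL,
        if ("biomass" %in% names(ctrl)) ctrl$biomass else NULL,
        strain_id = s$strain_id[1], ...
      ), plate_id = plate$plate_id[1])
    })
    do.call(rbind, per_strain)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sample t test on titers
#'
#' Student's (pooled-variance) two-sided t test by default, with a Welch
#' option. Degenerate input with zero variance in both samples is handled
#' explicitly: equal means give `t = 0, p = 1`; different means are flagged
#' with `p = 0` and a warning, since the test statistic degenerates.
#'
#' @param sample_a,sample_b numeric vectors (length >= 2 each).
#' @param var_equal pooled variance (Student, default `TRUE`) or Welch.
#' @return list with `statistic`, `p_value`, `df`, `method`.
#' @export
compare_titers <- function(sample_a, sample_b, var_equal = TRUE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("need at least 2 values per sample")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      return(list(statistic = 0, p_value = 1,
                  df = length(sample_a) + length(sample_b) - 2L,
                  method = "Student (degenerate: zero variance)"))
    }
    warning("zero variance in both samples with different means: p -> 0")
    return(list(statistic = sign(mean(sample_a) - mean(sample_b)) * Inf,
                p_value = 0,
                df = length(sample_a) + length(sample_b) - 2L,
                method = "Student (degenerate: zero variance)"))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
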
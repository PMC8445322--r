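#' Reporter half-life from a pulse-chase densitometry table
#'
#' The mature (pre-existing) band fraction `mature / (mature + HM)`,
#' normalized to its value at t = 0, decays exponentially with the reporter's
#' half-life. The half-life is estimated by unweighted least squares on the
#' log fraction; a non-decaying series returns `Inf` (consistent with a
#' half-life too long to resolve over the chase), and a one-sided flag is
#' raised whenever the slope's confidence interval includes zero.
#'
#' @param table Data frame with columns `time_h`, `mature_band`, `HM_band`,
#'   including t = 0.
#' @param conf_level Confidence level for the slope interval flag.
#' @return A one-row tibble: `half_life_h`, `se_h` (delta-method standard
#'   error, `NA` when not estimable), `slope_log_per_h`, and
#'   `ci_includes_zero`.
#' @examples
#' tab <- generate_pulse_chase_table(24, c(0, 6, 24, 48), noise_cv = 0)
#' half_life_from_pulse_chase(tab)$half_life_h # 24
#' @export
half_life_from_pulse_chase <- function(table, conf_level = 0.95) {
  need <- c("time_h", "mature_band", "HM_band")
  if (!all(need %in% names(table))) {
    abort(paste("`table` must have columns:", paste(need, collapse = ", ")),
          class = "retroflux_domain_error")
  }
  if (nrow(table) < 2L || !any(table$time_h == 0)) {
    abort("Need at least 2 time points including t = 0.",
          class = "retroflux_insufficient_data_error")
  }
  m <- table$mature_band / (table$mature_band + table$HM_band)
  m0 <- m[table$time_h == 0][1]
  if (!is.finite(m0) || m0 <= 0) {
    abort("Mature fraction at t = 0 must be positive.",
          class = "retroflux_domain_error")
  }
  mn <- m / m0
  keep <- is.finite(mn) & mn > 0
  fit <- lm(log(mn[keep]) ~ table$time_h[keep])
  b <- unname(coef(fit)[2])
  se_b <- suppressWarnings(summary(fit)$coefficients[2, 2])
  df <- fit$df.residual
  ci_zero <- if (df >= 1 && is.finite(se_b) && se_b > 0) {
    tcrit <- qt(1 - (1 - conf_level) / 2, df)
    (b + tcrit * se_b) >= 0
  } else {
    NA
  }
  if (b >= 0) {
    return(tibble(half_life_h = Inf, se_h = NA_real_, slope_log_per_h = b,
                  ci_includes_zero = ci_zero))
  }
  hl <- -log(2) / b
  se_h <- if (is.finite(se_b) && df >= 1) log(2) / b^2 * se_b else NA_real_
  tibble(half_life_h = hl, se_h = se_h, slope_log_per_h = b,
         ci_includes_zero = ci_zero)
}

#' Fraction of the MVB reporter pool secreted in exosomes
#'
#' The exosome-secreted share measured against whole-cell reporter is
#' converted to a share of the MVB-resident pool by dividing by the fraction
#' of cellular reporter residing in MVBs. With the measured 6% whole-cell
#' share and 62% MVB residence, about 10% of the MVB pool is secreted.
#'
#' @param exo_frac_wcl Exosome-secreted fraction of whole-cell reporter over
#'   the observation window, in `[0, mvb_frac]`.
#' @param mvb_frac Fraction of cellular reporter in MVBs, in `(0, 1]`.
#' @return `exo_frac_wcl / mvb_frac`.
#' @examples
#' exosome_mvb_fraction(0.06, 0.62) # ~0.097
#' @export
exosome_mvb_fraction <- function(exo_frac_wcl, mvb_frac) {
  if (!is.numeric(mvb_frac) || mvb_frac <= 0 || mvb_frac > 1) {
    abort("`mvb_frac` must lie in (0, 1].", class = "retroflux_domain_error")
  }
  if (!is.numeric(exo_frac_wcl) || exo_frac_wcl < 0) {
    abort("`exo_frac_wcl` must be >= 0.", class = "retroflux_domain_error")
  }
  if (exo_frac_wcl > mvb_frac) {
    abort("`exo_frac_wcl` cannot exceed `mvb_frac`: more reporter secreted than resides in MVBs.",
          class = "retroflux_inconsistency_error")
  }
  exo_frac_wcl / mvb_frac
}

#' Percent change in the exosomal GFP/normalizer ratio
#'
#' Computes, per replicate, the GFP band intensity over the geometric mean of
#' the normalizer band(s) (total CD63, optionally also IFITM3), then reports
#' the percent reduction of the treated-condition mean relative to control
#' (positive = decrease, the reporting convention for dimerizer-induced loss
#' of GFP-positive exosomes).
#'
#' @param blot Data frame from [generate_exosome_blot_table()] or with the
#'   same columns.
#' @param treated_label,control_label Condition labels to compare.
#' @param normalizers Character vector among `"cd63"`, `"ifitm3"`.
#' @return A one-row tibble: `percent_change` (positive = reduction),
#'   `mean_ratio_treated`, `mean_ratio_control`, `n_treated`, `n_control`,
#'   `n_dropped`.
#' @export
exosome_ratio_change <- function(blot, treated_label, control_label = "control",
                                 normalizers = "cd63") {
  cols <- paste0(normalizers, "_signal")
  need <- c("condition", "gfp_signal", cols)
  if (!all(need %in% names(blot))) {
    abort(paste("`blot` must have columns:", paste(need, collapse = ", ")),
          class = "retroflux_domain_error")
  }
  sub <- blot[blot$condition %in% c(treated_label, control_label), , drop = FALSE]
  if (!all(c(treated_label, control_label) %in% sub$condition)) {
    abort("Both conditions must be present with >= 1 replicate.",
          class = "retroflux_domain_error")
  }
  norm_mat <- as.matrix(sub[, cols, drop = FALSE])
  bad <- apply(norm_mat <= 0, 1, any)
  if (any(bad)) {
    warn(sprintf("Dropped %d replicate(s) with zero normalizer signal.", sum(bad)))
    sub <- sub[!bad, , drop = FALSE]
    norm_mat <- norm_mat[!bad, , drop = FALSE]
  }
  ratio <- sub$gfp_signal / exp(rowMeans(log(norm_mat)))
  mt <- mean(ratio[sub$condition == treated_label])
  mc <- mean(ratio[sub$condition == control_label])
  tibble(
    percent_change = 100 * (1 - mt / mc),
    mean_ratio_treated = mt,
    mean_ratio_control = mc,
    n_treated = sum(sub$condition == treated_label),
    n_control = sum(sub$condition == control_label),
    n_dropped = sum(bad)
  )
}

#' Per-MVB immunogold ILV:LM ratios
#'
#' @param counts Data frame with columns `gold_ilv`, `gold_lm` (and
#'   optionally `mvb_id`).
#' @return A tibble with `mvb_id` and `ratio` (`NA` where `gold_lm == 0`).
#' @export
immunogold_ratios <- function(counts) {
  if (!all(c("gold_ilv", "gold_lm") %in% names(counts)) || nrow(counts) == 0) {
    abort("`counts` must be non-empty with columns gold_ilv, gold_lm.",
          class = "retroflux_domain_error")
  }
  if (any(counts$gold_ilv < 0 | counts$gold_lm < 0)) {
    abort("Gold counts must be non-negative.", class = "retroflux_domain_error")
  }
  tibble(
    mvb_id = if ("mvb_id" %in% names(counts)) counts$mvb_id else seq_len(nrow(counts)),
    ratio = ifelse(counts$gold_lm > 0, counts$gold_ilv / counts$gold_lm, NA_real_)
  )
}

#' Median and IQR of per-MVB immunogold ratios
#'
#' MVBs with no limiting-membrane gold particle have an undefined ratio and
#' are excluded from the summary (their count is reported).
#'
#' @param counts Data frame with columns `gold_ilv`, `gold_lm`.
#' @return A one-row tibble: `median_ratio`, `iqr_low`, `iqr_high`, `iqr`,
#'   `n_mvb`, `n_zero_lm`.
#' @examples
#' immunogold_ratio_summary(
#'   tibble::tibble(gold_ilv = c(20, 6, 4), gold_lm = c(10, 3, 2))
#' )
#' @export
immunogold_ratio_summary <- function(counts) {
  ratios <- immunogold_ratios(counts)
  ok <- !is.na(ratios$ratio)
  if (!any(ok)) {
    abort("No MVB with gold_lm > 0; median ratio undefined.",
          class = "retroflux_domain_error")
  }
  q <- stats::quantile(ratios$ratio[ok], c(0.25, 0.5, 0.75), names = FALSE)
  tibble(median_ratio = q[2], iqr_low = q[1], iqr_high = q[3],
         iqr = q[3] - q[1], n_mvb = sum(ok), n_zero_lm = sum(!ok))
}

#' Lower bound on the retrofusing fraction of the intraluminal pool
#'
#' Partitions the intraluminal signal lost over the observation window among
#' the three ILV fates. The intraluminal loss is the intraluminal fraction
#' `f_ilv = rho / (1 + rho)` minus the remaining normalized signal; the parts
#' explained by lysosomal degradation (from the pulse-chase half-life) and by
#' exosome secretion (from the exosome/MVB fraction) are charged, under the
#' default convention, to the intraluminal pool — ILVs being the degradable
#' and secretable entities — and the unexplained remainder is a lower bound
#' on the retrofusing share of the ILV pool. It is a lower bound because not
#' every re-exposed reporter is necessarily cleaved within the window.
#'
#' @param remaining_6h Normalized endolysosomal signal remaining at the end
#'   of the window (fraction of t = 0).
#' @param rho ILV:LM abundance ratio at t = 0.
#' @param half_life_h Reporter degradation half-life in hours (may be `Inf`).
#' @param exo_frac_wcl Exosome-secreted fraction of whole-cell reporter over
#'   the window.
#' @param mvb_frac Fraction of cellular reporter in MVBs.
#' @param window_h Observation window in hours.
#' @param convention `"ilv_pool"` (default: degradation and secretion charged
#'   to the intraluminal pool) or `"total_pool"` (charged against the whole
#'   endolysosomal signal); the two give materially different bounds and the
#'   choice is reported with the result.
#' @return A one-row tibble of class `fate_breakdown`:
#'   `frac_secreted_of_mvb`, `frac_degraded_of_ilv`,
#'   `frac_retrofused_of_ilv_lower_bound`, `frac_inert_remaining`, plus the
#'   convention used.
#' @export
retrofusion_lower_bound <- function(remaining_6h, rho = 2, half_life_h = 24,
                                    exo_frac_wcl = 0.06, mvb_frac = 0.62,
                                    window_h = 6,
                                    convention = c("ilv_pool", "total_pool")) {
  convention <- match.arg(convention)
  if (remaining_6h < 0 || remaining_6h > 1) {
    abort("`remaining_6h` must lie in [0, 1].", class = "retroflux_domain_error")
  }
  if (half_life_h <= 0 || window_h <= 0) {
    abort("`half_life_h` and `window_h` must be > 0.",
          class = "retroflux_domain_error")
  }
  f_ilv <- intraluminal_fraction(rho)
  sec_mvb <- exosome_mvb_fraction(exo_frac_wcl, mvb_frac)
  degraded <- 1 - 2^(-window_h / half_life_h)
  if (remaining_6h > f_ilv) {
    warn("Remaining signal exceeds the intraluminal fraction: no detectable intraluminal loss; lower bound is 0.")
  }
  loss <- max(0, f_ilv - remaining_6h)
  explained <- switch(convention,
    ilv_pool = f_ilv * degraded + sec_mvb,
    total_pool = degraded + sec_mvb
  )
  bound <- max(0, loss - explained) / f_ilv
  out <- tibble(
    frac_secreted_of_mvb = sec_mvb,
    frac_degraded_of_ilv = degraded,
    frac_retrofused_of_ilv_lower_bound = min(1, bound),
    frac_inert_remaining = min(1, remaining_6h / f_ilv),
    convention = convention
  )
  class(out) <- c("fate_breakdown", class(out))
  out
}
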
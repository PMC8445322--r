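#' Construct a normalized decay curve
#'
#' A `decay_curve` is a tibble with columns `time_min` and `value` holding the
#' background-subtracted, first-frame-normalized endolysosomal GFP trace of
#' one movie; the condition label travels as an attribute. Most users create
#' one via [background_subtract_normalize()].
#'
#' @param time_min Strictly increasing time grid in minutes.
#' @param value Normalized intensities; `value[1]` must equal 1.
#' @param condition_label Text label for the experimental condition.
#' @return A tibble of class `decay_curve`.
#' @export
decay_curve <- function(time_min, value, condition_label = "control") {
  if (length(time_min) != length(value) || length(time_min) < 1L) {
    abort("`time_min` and `value` must be equal-length, non-empty vectors.",
          class = "retroflux_domain_error")
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    abort("`time_min` must be strictly increasing.",
          class = "retroflux_domain_error")
  }
  if (abs(value[1] - 1) > 1e-12) {
    abort("A decay curve must be normalized: `value[1]` must be 1.",
          class = "retroflux_domain_error")
  }
  out <- tibble(time_min = as.numeric(time_min), value = as.numeric(value))
  class(out) <- c("decay_curve", class(out))
  attr(out, "condition_label") <- condition_label
  out
}

#' Background-subtract and normalize an endolysosomal trace
#'
#' Implements the core normalization of the quantification pipeline: the
#' median GFP background in the cytosol is subtracted frame-by-frame from the
#' median GFP signal in endolysosomes, and the corrected trace is divided by
#' its first-frame value, so every curve starts at exactly 1. Negative
#' corrected values at later frames (noise) are retained, not clipped.
#'
#' @param el_median Per-frame median endolysosomal GFP intensities.
#' @param cyto_median Per-frame median cytosolic GFP intensities (background).
#' @param time_min Per-frame times in minutes (default: index-based, assuming
#'   3-min frames).
#' @param condition_label Condition label attached to the curve.
#' @return A [decay_curve()].
#' @examples
#' background_subtract_normalize(c(100, 80), c(20, 20), time_min = c(0, 3))
#' @export
background_subtract_normalize <- function(el_median, cyto_median,
                                          time_min = (seq_along(el_median) - 1) * 3,
                                          condition_label = "control") {
  if (length(el_median) != length(cyto_median)) {
    abort("`el_median` and `cyto_median` must have the same length.",
          class = "retroflux_domain_error")
  }
  corrected <- el_median - cyto_median
  if (!is.finite(corrected[1]) || corrected[1] <= 0) {
    abort("First-frame corrected intensity must be positive to normalize.",
          class = "retroflux_normalization_error")
  }
  if (any(corrected < 0, na.rm = TRUE)) {
    warn("Negative background-corrected intensities retained (noise).")
  }
  decay_curve(time_min, corrected / corrected[1], condition_label)
}

#' Fit slope A of the near-linear decay phase
#'
#' After an initial equilibration phase the normalized endolysosomal GFP
#' signal decays near-linearly; its slope ("slope A") over a fixed window
#' (default 90-360 min) is the primary rate readout. The slope is the
#' ordinary least-squares slope of normalized value against time in hours,
#' so a decaying curve has a negative slope.
#'
#' @param curve A [decay_curve()].
#' @param window Two-element numeric, fit window in minutes (inclusive).
#' @return A one-row tibble with `slope_A_per_h` (signed), `slope_magnitude`,
#'   `intercept`, `n_points` and the window bounds.
#' @examples
#' cv <- decay_curve(seq(0, 360, 3), 1 - 0.05 * seq(0, 360, 3) / 60)
#' fit_slope_A(cv)$slope_A_per_h # -0.05
#' @export
fit_slope_A <- function(curve, window = c(90, 360)) {
  stopifnot(inherits(curve, "decay_curve"), length(window) == 2L)
  keep <- curve$time_min >= window[1] & curve$time_min <= window[2]
  if (sum(keep) < 3L) {
    abort("Slope fitting requires at least 3 points inside the window.",
          class = "retroflux_insufficient_data_error")
  }
  t_h <- curve$time_min[keep] / 60
  fit <- lm(curve$value[keep] ~ t_h)
  slope <- unname(coef(fit)[2])
  tibble(
    condition = attr(curve, "condition_label") %||% NA_character_,
    slope_A_per_h = slope,
    slope_magnitude = abs(slope),
    intercept = unname(coef(fit)[1]),
    n_points = sum(keep),
    window_start_min = window[1],
    window_end_min = window[2]
  )
}

#' Remaining fraction of the initial signal at a query time
#'
#' Linearly interpolates the normalized curve at `t_query` minutes; at 360
#' min this is the "% of GFP fluorescence at t = 0 remaining at 6 h" readout.
#'
#' @param curve A [decay_curve()].
#' @param t_query Query time in minutes; must lie inside the sampled range.
#' @return The interpolated normalized value.
#' @export
remaining_fraction <- function(curve, t_query) {
  stopifnot(inherits(curve, "decay_curve"))
  rng <- range(curve$time_min)
  if (t_query < rng[1] || t_query > rng[2]) {
    abort(sprintf("`t_query` = %g min is outside the sampled range [%g, %g].",
                  t_query, rng[1], rng[2]),
          class = "retroflux_range_error")
  }
  approx(curve$time_min, curve$value, xout = t_query)$y
}

#' Summarise replicate decay curves per condition
#'
#' Aggregates per-movie slope-A and remaining-fraction readouts into one row
#' per condition, reporting mean and SD across replicates (the convention for
#' time-lapse replicates).
#'
#' @param curves A list of [decay_curve()] objects; condition labels are taken
#'   from each curve.
#' @param window Slope-fit window in minutes.
#' @param t_remaining Times (minutes) at which remaining fractions are
#'   reported; defaults to 6 h and, when sampled, 9 h.
#' @return A `condition_summary` tibble with columns `condition`,
#'   `slope_A_per_h`, `slope_sd`, `remaining_6h`, `remaining_9h`, `n`.
#' @export
summarize_conditions <- function(curves, window = c(90, 360),
                                 t_remaining = c(360, 540)) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  rows <- map(curves, function(cv) {
    sl <- fit_slope_A(cv, window = window)
    rem <- map_dbl(t_remaining, function(tq) {
      if (tq >= min(cv$time_min) && tq <= max(cv$time_min)) {
        remaining_fraction(cv, tq)
      } else {
        NA_real_
      }
    })
    tibble(condition = sl$condition, slope_A_per_h = sl$slope_A_per_h,
           remaining_6h = rem[1],
           remaining_9h = if (length(rem) > 1) rem[2] else NA_real_)
  })
  out <- bind_rows(rows) |>
    group_by(.data$condition) |>
    summarise(
      slope_sd = stats::sd(.data$slope_A_per_h),
      slope_A_per_h = mean(.data$slope_A_per_h),
      remaining_sd_6h = stats::sd(.data$remaining_6h),
      remaining_6h = mean(.data$remaining_6h),
      remaining_9h = mean(.data$remaining_9h),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    select("condition", "slope_A_per_h", "slope_sd", "remaining_6h",
           "remaining_sd_6h", "remaining_9h", "n")
  class(out) <- c("condition_summary", class(out))
  out
}

#' Express condition slopes relative to a control
#'
#' Divides each condition's slope A by the control condition's slope, the
#' convention used to report perturbations (e.g. a retrofusion blocker that
#' halves the decay rate gives `slope_rel_control` = 0.5). The control maps
#' to exactly 1.
#'
#' @param summaries A `condition_summary` tibble (see
#'   [summarize_conditions()]), or any tibble with columns `condition` and
#'   `slope_A_per_h`.
#' @param control_label Label of the control condition.
#' @return The input with a `slope_rel_control` column added.
#' @export
relative_to_control <- function(summaries, control_label = "control") {
  stopifnot(is.data.frame(summaries),
            all(c("condition", "slope_A_per_h") %in% names(summaries)))
  ctrl <- summaries$slope_A_per_h[summaries$condition == control_label]
  if (length(ctrl) != 1L || is.na(ctrl) || ctrl == 0) {
    abort("Control condition missing or has zero slope; cannot normalize.",
          class = "retroflux_normalization_error")
  }
  mutate(summaries, slope_rel_control = .data$slope_A_per_h / ctrl)
}
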
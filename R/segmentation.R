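#' Linearly interpolate a per-frame threshold
#'
#' The quantification macro asks for a threshold on the first and last frame
#' and interpolates linearly in between, absorbing slow drifts in staining
#' intensity. Frames are indexed 1-based: frame 1 gets `t_first`, frame
#' `n_frames` gets `t_last`, exactly.
#'
#' @param t_first Threshold at the first frame (>= 0).
#' @param t_last Threshold at the last frame (>= 0).
#' @param frame_idx Frame index in `1:n_frames`.
#' @param n_frames Total number of frames (>= 2).
#' @return The interpolated threshold.
#' @examples
#' interpolate_threshold(100, 200, frame_idx = 6, n_frames = 11) # 150
#' @export
interpolate_threshold <- function(t_first, t_last, frame_idx, n_frames) {
  if (n_frames < 2) {
    abort("`n_frames` must be >= 2.", class = "retroflux_domain_error")
  }
  if (frame_idx < 1 || frame_idx > n_frames) {
    abort("`frame_idx` must be in 1:n_frames.", class = "retroflux_domain_error")
  }
  if (t_first < 0 || t_last < 0) {
    abort("Thresholds must be >= 0.", class = "retroflux_domain_error")
  }
  t_first + (t_last - t_first) * (frame_idx - 1) / (n_frames - 1)
}

#' Threshold specification for compartment segmentation
#'
#' Holds the first/last-frame thresholds for the endolysosome mask (lysosome
#' channel) and the plasma-membrane mask (GFP channel), a single threshold
#' for nuclei (red channel), and the low "cell" threshold (as a fraction of
#' the frame's GFP maximum) used to confine the cytosol mask to cells.
#'
#' @param el Two-element numeric `c(first, last)` for the EL threshold.
#' @param nuc Single nucleus threshold.
#' @param pm Two-element numeric `c(first, last)` for the PM threshold.
#' @param cell_frac Fraction of the per-frame GFP maximum below which pixels
#'   are treated as outside cells (default 0.05).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(el, nuc, pm, cell_frac = 0.05) {
  if (length(el) != 2L || length(pm) != 2L || length(nuc) != 1L) {
    abort("`el` and `pm` need first/last values; `nuc` a single value.",
          class = "retroflux_domain_error")
  }
  if (any(c(el, nuc, pm) < 0) || cell_frac < 0 || cell_frac > 1) {
    abort("Thresholds must be >= 0 and `cell_frac` in [0, 1].",
          class = "retroflux_domain_error")
  }
  structure(list(el = as.numeric(el), nuc = as.numeric(nuc),
                 pm = as.numeric(pm), cell_frac = cell_frac),
            class = "threshold_spec")
}

#' Automatic Otsu thresholds from the first and last frame
#'
#' Reproducible stand-in for the macro's interactive threshold picking:
#' Otsu's method (via \pkg{EBImage}) on the lysosome channel (first and last
#' frame) for EL, on the red channel (first frame) for nuclei, and on the
#' GFP channel outside the EL and nucleus masks (first and last frame)
#' for the plasma membrane.
#'
#' @param stack Numeric array `rows x cols x channel x frame` with channels
#'   named `gfp`, `red`, `lyso`.
#' @param cell_frac Passed to [threshold_spec()].
#' @return A [threshold_spec()].
#' @export
auto_threshold_spec <- function(stack, cell_frac = 0.05) {
  stopifnot(length(dim(stack)) == 4L)
  n <- dim(stack)[4]
  otsu1 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(rng[2] + 1) # flat frame: nothing above threshold
    as.numeric(EBImage::otsu(EBImage::Image(m), range = rng, levels = 256L))
  }
  el <- c(otsu1(stack[, , "lyso", 1]), otsu1(stack[, , "lyso", n]))
  nuc <- otsu1(stack[, , "red", 1])
  pm_frame <- function(i, el_thr) {
    g <- stack[, , "gfp", i]
    # PM is sought among above-background cell pixels outside EL and nuclei;
    # when the reporter rim has fully decayed this region is flat and no PM
    # threshold (hence no PM mask) results
    region <- stack[, , "lyso", i] < el_thr & stack[, , "red", i] < nuc &
      g > cell_frac * max(g)
    if (!any(region)) return(max(g) + 1)
    otsu1(matrix(g[region], nrow = 1))
  }
  pm <- c(pm_frame(1, el[1]), pm_frame(n, el[2]))
  threshold_spec(el = el, nuc = nuc, pm = pm, cell_frac = cell_frac)
}

#' Segment one frame into mutually exclusive compartments
#'
#' Re-implements the per-frame segmentation of the quantification macro:
#' endolysosomes (EL) from the lysosome channel with the interpolated
#' threshold; nuclei (N) from the red channel; the plasma membrane (PM) from
#' the GFP channel, restricted to the area outside nuclei and EL; and the
#' cytosol (CYTO) as the remaining above-background cell area after masking
#' out all previous segmentations. Thresholds are closed (`>=`) comparisons
#' and the precedence order EL > N > PM > CYTO enforces disjointness.
#'
#' @param gfp,red,lyso Numeric matrices of the three channels (same shape).
#' @param spec A [threshold_spec()].
#' @param frame_idx,n_frames Frame position used for threshold interpolation.
#' @return An object of class `compartment_masks`: logical matrices `EL`,
#'   `N`, `PM`, `CYTO` plus the thresholds actually applied.
#' @export
segment_compartments <- function(gfp, red, lyso, spec, frame_idx, n_frames) {
  stopifnot(inherits(spec, "threshold_spec"),
            identical(dim(gfp), dim(red)), identical(dim(gfp), dim(lyso)))
  thr_el <- interpolate_threshold(spec$el[1], spec$el[2], frame_idx, n_frames)
  thr_pm <- interpolate_threshold(spec$pm[1], spec$pm[2], frame_idx, n_frames)
  el <- lyso >= thr_el
  if (!any(el)) {
    warn(sprintf("Empty endolysosome mask on frame %d.", frame_idx))
  }
  n <- (red >= spec$nuc) & !el
  pm <- (gfp >= thr_pm) & !el & !n
  gmax <- max(gfp)
  # flat zero frames contain no cell; otherwise gate on the low cell threshold
  cell <- if (gmax > 0) gfp > spec$cell_frac * gmax else array(FALSE, dim(gfp))
  cyto <- cell & !el & !n & !pm
  structure(
    list(EL = el, N = n, PM = pm, CYTO = cyto,
         thresholds = c(EL = thr_el, N = spec$nuc, PM = thr_pm),
         frame_idx = frame_idx),
    class = "compartment_masks"
  )
}

#' Segment every frame of a stack
#'
#' @param stack Numeric array `rows x cols x channel x frame` with channels
#'   named `gfp`, `red`, `lyso`.
#' @param spec A [threshold_spec()], or `NULL` for [auto_threshold_spec()].
#' @return A list of [segment_compartments()] results, one per frame.
#' @export
segment_stack <- function(stack, spec = NULL) {
  stopifnot(length(dim(stack)) == 4L)
  spec <- spec %||% auto_threshold_spec(stack)
  n <- dim(stack)[4]
  lapply(seq_len(n), function(i) {
    segment_compartments(stack[, , "gfp", i], stack[, , "red", i],
                         stack[, , "lyso", i], spec, i, n)
  })
}

#' Per-frame compartment intensity table
#'
#' Computes the mean and median intensity of every channel over every
#' compartment mask on every frame — the numeric table the downstream decay
#' analysis consumes. Empty masks yield rows with `area_px = 0` and missing
#' statistics rather than an error.
#'
#' @param stack Numeric array `rows x cols x channel x frame`.
#' @param masks A list of per-frame masks from [segment_stack()].
#' @param frame_interval_s Seconds between frames (for the `time_min`
#'   column).
#' @return A tibble with columns `frame`, `time_min`, `compartment`,
#'   `channel`, `mean`, `median`, `area_px`.
#' @export
measure_intensities <- function(stack, masks, frame_interval_s = 180) {
  stopifnot(length(dim(stack)) == 4L, length(masks) == dim(stack)[4])
  channels <- dimnames(stack)[[3]]
  comps <- c("EL", "N", "PM", "CYTO")
  rows <- list()
  for (i in seq_along(masks)) {
    for (comp in comps) {
      m <- masks[[i]][[comp]]
      area <- sum(m)
      for (ch in channels) {
        px <- stack[, , ch, i][m]
        rows[[length(rows) + 1L]] <- tibble(
          frame = i,
          time_min = (i - 1) * frame_interval_s / 60,
          compartment = comp,
          channel = ch,
          mean = if (area > 0) mean(px) else NA_real_,
          median = if (area > 0) median(px) else NA_real_,
          area_px = area
        )
      }
    }
  }
  bind_rows(rows)
}

#' Jaccard overlap of two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return Intersection over union; 1 when both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
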
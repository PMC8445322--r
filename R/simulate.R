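#' Acquisition parameters of a simulated time-lapse
#'
#' Mirrors the live-imaging protocol the pipeline was built around: one frame
#' every 180 s for at least 6 h (120 frames), three channels (GFP reporter,
#' nuclear red marker, lysosomal far-red marker). Noise is off by default so
#' ground truth is exact; enable Poisson shot noise and Gaussian read noise
#' to exercise robustness.
#'
#' @param frame_interval_s Seconds between frames (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param amplitudes Named numeric vector of structure intensities in camera
#'   counts: `gfp_el`, `gfp_cyto`, `gfp_pm`, `gfp_nuc`, `red_nuc`, `sir_el`.
#' @param shot_noise Apply Poisson shot noise to every pixel?
#' @param read_noise_sd Gaussian read-noise SD in counts (>= 0).
#' @param bleach_per_frame Per-channel photobleaching rate per frame (named
#'   `gfp`, `red`, `lyso`; default all 0).
#' @param sir_drift Fractional linear drift of the lysosomal-channel
#'   intensity from first to last frame (default +0.1, i.e. a mild 10%
#'   ramp that exercises threshold interpolation).
#' @param rng_seed Integer seed for the noise draws.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_interval_s = 180,
                               n_frames = 120,
                               amplitudes = c(gfp_el = 200, gfp_cyto = 20,
                                              gfp_pm = 150, gfp_nuc = 150,
                                              red_nuc = 180, sir_el = 150),
                               shot_noise = FALSE,
                               read_noise_sd = 0,
                               bleach_per_frame = c(gfp = 0, red = 0, lyso = 0),
                               sir_drift = 0.1,
                               rng_seed = 1L) {
  if (frame_interval_s <= 0) {
    abort("`frame_interval_s` must be > 0.", class = "retroflux_domain_error")
  }
  if (n_frames < 2) {
    abort("`n_frames` must be >= 2.", class = "retroflux_domain_error")
  }
  if (read_noise_sd < 0) {
    abort("`read_noise_sd` must be >= 0.", class = "retroflux_domain_error")
  }
  need <- c("gfp_el", "gfp_cyto", "gfp_pm", "gfp_nuc", "red_nuc", "sir_el")
  if (!all(need %in% names(amplitudes))) {
    abort(paste("`amplitudes` must name:", paste(need, collapse = ", ")),
          class = "retroflux_domain_error")
  }
  structure(
    list(frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
         amplitudes = amplitudes, shot_noise = shot_noise,
         read_noise_sd = read_noise_sd, bleach_per_frame = bleach_per_frame,
         sir_drift = sir_drift, rng_seed = as.integer(rng_seed)),
    class = "acquisition_params"
  )
}

#' Simulate a three-channel reporter time-lapse with ground truth
#'
#' Renders the kinetic model onto a synthetic cell field: endolysosomal GFP
#' scales with the observable pool `L + I_dyn + I_inert`, nuclear GFP rises
#' with the cleaved pool, a plasma-membrane reporter rim is cleaved with the
#' same rate as the endosomal limiting membrane (it contributes to nuclear
#' GFP in the real system but never to the endolysosomal trace), cytosolic
#' GFP background is constant; the red channel marks nuclei and the far-red
#' channel marks endolysosomes (with an optional slow drift). Noise, when
#' enabled, is applied only after the noiseless ground truth is recorded.
#'
#' @param geometry A [generate_geometry()] layout.
#' @param kinetics A [kinetic_params()] object.
#' @param acq An [acquisition_params()] object.
#' @return An object of class `retro_sim`: list with `stack` (numeric array
#'   `rows x cols x channel x frame`, channels named `gfp`, `red`, `lyso`),
#'   and `truth` (geometry, static masks, the [simulate_pools()] trajectory,
#'   the per-frame true EL median trace, and the generating parameters).
#' @examples
#' geo <- generate_geometry(1, seed = 3, image_shape = c(96, 96))
#' sim <- generate_timelapse(geo, kinetic_params(), acquisition_params(n_frames = 5))
#' dim(sim$stack)
#' @export
generate_timelapse <- function(geometry, kinetics, acq = acquisition_params()) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(kinetics, "kinetic_params"),
            inherits(acq, "acquisition_params"))
  sh <- geometry$image_shape
  masks <- geometry_masks(geometry)
  times_min <- (seq_len(acq$n_frames) - 1) * acq$frame_interval_s / 60
  pools <- simulate_pools(kinetics, times_min)
  A <- acq$amplitudes

  stack <- array(0, dim = c(sh[1], sh[2], 3, acq$n_frames),
                 dimnames = list(NULL, NULL, c("gfp", "red", "lyso"), NULL))
  drift <- 1 + acq$sir_drift * (seq_len(acq$n_frames) - 1) / (acq$n_frames - 1)
  pm_trace <- exp(-kinetics$k_cleave * times_min)
  bl <- function(ch, i) (1 - acq$bleach_per_frame[[ch]])^(i - 1)

  for (i in seq_len(acq$n_frames)) {
    gfp <- matrix(0, sh[1], sh[2])
    gfp[masks$CELL] <- A[["gfp_cyto"]]
    gfp[masks$EL] <- gfp[masks$EL] + A[["gfp_el"]] * pools$EL_observable[i]
    gfp[masks$N] <- gfp[masks$N] + A[["gfp_nuc"]] * pools$N_nuc[i]
    gfp[masks$PM] <- gfp[masks$PM] + A[["gfp_pm"]] * pm_trace[i]
    red <- matrix(0, sh[1], sh[2])
    red[masks$N] <- A[["red_nuc"]]
    lyso <- matrix(0, sh[1], sh[2])
    lyso[masks$EL] <- A[["sir_el"]] * drift[i]
    stack[, , "gfp", i] <- gfp * bl("gfp", i)
    stack[, , "red", i] <- red * bl("red", i)
    stack[, , "lyso", i] <- lyso * bl("lyso", i)
  }

  truth <- list(
    geometry = geometry,
    masks = masks,
    pools = pools,
    trace = tibble(
      frame = seq_len(acq$n_frames),
      time_min = times_min,
      el_true = A[["gfp_cyto"]] + A[["gfp_el"]] * pools$EL_observable,
      cyto_true = A[["gfp_cyto"]],
      el_observable = pools$EL_observable
    ),
    kinetics = kinetics,
    acq = acq
  )

  if (acq$shot_noise || acq$read_noise_sd > 0) {
    stack <- withr::with_seed(acq$rng_seed, {
      noisy <- stack
      if (acq$shot_noise) {
        noisy[] <- rpois(length(noisy), lambda = pmax(noisy, 0))
      }
      if (acq$read_noise_sd > 0) {
        noisy[] <- noisy + rnorm(length(noisy), sd = acq$read_noise_sd)
      }
      pmax(noisy, 0)
    })
  }

  structure(list(stack = stack, truth = truth), class = "retro_sim")
}

#' @export
print.retro_sim <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<retro_sim> %d x %d px, %d channels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  print(x$truth$kinetics)
  invisible(x)
}
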
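# shared fixtures, built in code and cached per test file

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# small field, two cells
tiny_geometry <- function(seed = 7) {
  cached(paste0("geo", seed),
         generate_geometry(2, seed = seed, image_shape = c(128, 128)))
}

# pure-cleavage, no-retrofusion parameters: the 2/3-plateau regime
plateau_params <- function() {
  kinetic_params(rho = 2, phi_dynamic = 0, k_cleave = 0.1,
                 half_life_h = Inf, k_sec = 0)
}

# noiseless 6-h movie in the plateau regime (121 frames, 180 s apart)
plateau_sim <- function() {
  cached("plateau_sim",
         generate_timelapse(tiny_geometry(), plateau_params(),
                            acquisition_params(n_frames = 121)))
}

# quantify a stack exactly as the pipeline does, returning the decay curve
quantify_curve <- function(stack, frame_interval_s = 180, spec = NULL) {
  masks <- segment_stack(stack, spec)
  tab <- measure_intensities(stack, masks, frame_interval_s)
  el <- dplyr::filter(tab, compartment == "EL", channel == "gfp")
  cyto <- dplyr::filter(tab, compartment == "CYTO", channel == "gfp")
  background_subtract_normalize(el$median, cyto$median, time_min = el$time_min)
}

# random valid kinetic parameter draw for property tests
random_params <- function() {
  kinetic_params(
    rho = stats::runif(1, 0, 5),
    phi_dynamic = stats::runif(1),
    k_cleave = stats::runif(1, 0, 0.5),
    k_retro = stats::runif(1, 0, 0.05),
    half_life_h = stats::runif(1, 5, 100),
    k_sec = stats::runif(1, 0, 0.002)
  )
}
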
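#' Simulate a DMM pulse-chase densitometry table
#'
#' Emulates the mannosidase-I-inhibition pulse-chase used to estimate the
#' reporter half-life: the pre-existing, maturely glycosylated pool decays as
#' `2^(-t / half_life_h)` while newly synthesised, high-mannose reporter
#' accumulates so that total reporter stays at steady state. Band intensities
#' receive multiplicative lognormal noise with the stated coefficient of
#' variation (the standard assumption for blot densitometry).
#'
#' @param half_life_h Reporter half-life in hours (> 0).
#' @param times_h Sorted chase times in hours starting at 0.
#' @param noise_cv Coefficient of variation of the lognormal band noise
#'   (>= 0; 0 for a noiseless table).
#' @param seed Integer seed.
#' @param total Steady-state total band intensity (arbitrary units).
#' @return A tibble with columns `time_h`, `mature_band`, `HM_band`.
#' @examples
#' generate_pulse_chase_table(24, c(0, 6, 24, 48), noise_cv = 0)
#' @export
generate_pulse_chase_table <- function(half_life_h, times_h = c(0, 6, 24, 48),
                                       noise_cv = 0, seed = 1L, total = 100) {
  if (noise_cv < 0) {
    abort("`noise_cv` must be >= 0.", class = "retroflux_domain_error")
  }
  if (half_life_h <= 0) {
    abort("`half_life_h` must be > 0.", class = "retroflux_domain_error")
  }
  if (is.unsorted(times_h) || times_h[1] != 0) {
    abort("`times_h` must be sorted and start at 0.",
          class = "retroflux_domain_error")
  }
  mature <- total * 2^(-times_h / half_life_h)
  hm <- total - mature
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    withr::with_seed(seed, {
      mature <- mature * rlnorm(length(mature), -sdlog^2 / 2, sdlog)
      hm <- hm * rlnorm(length(hm), -sdlog^2 / 2, sdlog)
    })
  }
  tibble(time_h = times_h, mature_band = mature, HM_band = hm)
}

#' Simulate per-MVB immunogold particle counts
#'
#' Each MVB receives a Poisson-distributed number of gold particles; each
#' particle lands on an intraluminal vesicle with probability
#' `rho / (1 + rho)` and on the limiting membrane otherwise, so the pooled
#' ILV:LM count ratio estimates `rho`.
#'
#' @param rho True ILV:LM abundance ratio (>= 0).
#' @param n_mvb Number of MVBs (>= 1).
#' @param mean_total Mean gold particles per MVB (> 0).
#' @param seed Integer seed.
#' @return A tibble with columns `mvb_id`, `gold_ilv`, `gold_lm`
#'   (non-negative integers).
#' @export
generate_immunogold_counts <- function(rho, n_mvb, mean_total = 30, seed = 1L) {
  if (!is.numeric(rho) || rho < 0 || !is.finite(rho)) {
    abort("`rho` must be finite and >= 0.", class = "retroflux_domain_error")
  }
  if (n_mvb < 1) {
    abort("`n_mvb` must be >= 1.", class = "retroflux_domain_error")
  }
  if (mean_total <= 0) {
    abort("`mean_total` must be > 0.", class = "retroflux_domain_error")
  }
  p_ilv <- intraluminal_fraction(rho)
  withr::with_seed(seed, {
    total <- rpois(n_mvb, mean_total)
    ilv <- rbinom(n_mvb, total, p_ilv)
    tibble(mvb_id = seq_len(n_mvb), gold_ilv = as.integer(ilv),
           gold_lm = as.integer(total - ilv))
  })
}

#' Simulate an exosome immunoblot densitometry table
#'
#' Generates replicate exosome-fraction band intensities (GFP, total CD63
#' and optionally an IFITM3 loading signal) whose expected GFP/CD63 ratio per
#' condition equals the specified truth. Noise is multiplicative lognormal
#' with mean 1, so the per-replicate ratio is unbiased.
#'
#' @param true_ratio Named numeric vector of true GFP-over-normalizer ratios,
#'   one per condition (all > 0), e.g. `c(control = 1, treated = 0.7)`.
#' @param n_replicates Replicates per condition.
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param seed Integer seed.
#' @param include_ifitm3 Add an `ifitm3_signal` column for dual
#'   normalization?
#' @param base_signal Mean CD63 band intensity (arbitrary units).
#' @return A tibble with columns `condition`, `replicate`, `gfp_signal`,
#'   `cd63_signal` and optionally `ifitm3_signal`.
#' @export
generate_exosome_blot_table <- function(true_ratio, n_replicates = 5,
                                        noise_cv = 0, seed = 1L,
                                        include_ifitm3 = FALSE,
                                        base_signal = 100) {
  if (is.null(names(true_ratio)) || any(!nzchar(names(true_ratio)))) {
    abort("`true_ratio` must be a named vector of conditions.",
          class = "retroflux_domain_error")
  }
  if (any(true_ratio <= 0)) {
    abort("All true ratios must be > 0.", class = "retroflux_domain_error")
  }
  if (noise_cv < 0) {
    abort("`noise_cv` must be >= 0.", class = "retroflux_domain_error")
  }
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  lnoise <- function(n) {
    if (sdlog == 0) rep(1, n) else rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  withr::with_seed(seed, {
    rows <- imap(as.list(true_ratio), function(ratio, cond) {
      cd63 <- base_signal * lnoise(n_replicates)
      gfp <- ratio * cd63 * lnoise(n_replicates)
      out <- tibble(condition = cond, replicate = seq_len(n_replicates),
                    gfp_signal = gfp, cd63_signal = cd63)
      if (include_ifitm3) {
        # loading-matched IFITM3 signal: same scale as CD63, own noise
        out$ifitm3_signal <- cd63 * lnoise(n_replicates)
      }
      out
    })
    bind_rows(rows)
  })
}
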
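#' Intraluminal fraction of endolysosomal reporter
#'
#' Converts the ILV:LM abundance ratio `rho` (reporter on intraluminal
#' vesicles relative to the limiting membrane, as measured per MVB by
#' immunogold labelling) into the fraction of endolysosomal reporter that is
#' intraluminal, `rho / (1 + rho)`. At the measured 2:1 ratio this is 2/3,
#' the predicted no-retrofusion plateau of the normalized decay curve.
#'
#' @param rho Non-negative, finite ILV:LM abundance ratio.
#' @return The intraluminal fraction, a number in `[0, 1)`.
#' @examples
#' intraluminal_fraction(2) # 2/3
#' @export
intraluminal_fraction <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0) {
    abort("`rho` must be a single finite number >= 0.", class = "retroflux_domain_error")
  }
  rho / (1 + rho)
}

#' Kinetic parameters of the cleavable reporter model
#'
#' Bundles and validates the parameters of the six-pool compartmental model:
#' limiting-membrane reporter (L), retrofusion-competent ("dynamic") and
#' retrofusion-inert intraluminal reporter (I_dyn, I_inert), nuclear cleaved
#' reporter (N_nuc), degraded (D) and secreted (S) pools, all as fractions of
#' the initial endolysosomal reporter.
#'
#' Defaults describe an unperturbed cell: a 2:1 intraluminal:limiting-membrane
#' ratio, half of the intraluminal pool competent for retrofusion, cleavage
#' fast relative to retrofusion, and a reporter half-life of 24 h.
#'
#' @param rho ILV:LM abundance ratio at t = 0 (dimensionless, >= 0).
#' @param phi_dynamic Fraction of the intraluminal pool competent for
#'   retrofusion, in `[0, 1]`.
#' @param k_cleave Per-minute protease cleavage rate of cytosol-exposed
#'   (limiting-membrane) reporter.
#' @param k_retro Per-minute retrofusion transfer rate (dynamic intraluminal
#'   pool to limiting membrane).
#' @param half_life_h Reporter degradation half-life in hours; the per-minute
#'   degradation rate is `log(2) / (60 * half_life_h)`. Use `Inf` for no
#'   degradation.
#' @param k_sec Per-minute secretion rate of intraluminal reporter into
#'   exosomes.
#' @param t_eq_min End of the equilibration window (minutes); decay slopes are
#'   fitted after this point.
#' @param t_fit_end_min End of the decay-fit window (minutes).
#' @return An object of class `kinetic_params` (a validated named list, with
#'   derived fields `f_ilv` and `k_deg`).
#' @examples
#' p <- kinetic_params(rho = 2, phi_dynamic = 0)
#' p$f_ilv # 2/3
#' @export
kinetic_params <- function(rho = 2,
                           phi_dynamic = 0.5,
                           k_cleave = 0.03,
                           k_retro = 0.002,
                           half_life_h = 24,
                           k_sec = 3e-4,
                           t_eq_min = 90,
                           t_fit_end_min = 360) {
  chk_scalar <- function(x, name, lo = 0, allow_inf = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (is.finite(x) || allow_inf) && x >= lo
    if (!ok) {
      abort(sprintf("`%s` must be a single number >= %g.", name, lo),
            class = "retroflux_domain_error")
    }
  }
  chk_scalar(rho, "rho")
  chk_scalar(phi_dynamic, "phi_dynamic")
  chk_scalar(k_cleave, "k_cleave")
  chk_scalar(k_retro, "k_retro")
  chk_scalar(half_life_h, "half_life_h", lo = .Machine$double.eps, allow_inf = TRUE)
  chk_scalar(k_sec, "k_sec")
  if (phi_dynamic > 1) {
    abort("`phi_dynamic` must lie in [0, 1].", class = "retroflux_domain_error")
  }
  if (!(t_eq_min < t_fit_end_min)) {
    abort("`t_eq_min` must be smaller than `t_fit_end_min`.",
          class = "retroflux_domain_error")
  }
  structure(
    list(
      rho = rho,
      f_ilv = intraluminal_fraction(rho),
      phi_dynamic = phi_dynamic,
      k_cleave = k_cleave,
      k_retro = k_retro,
      half_life_h = half_life_h,
      k_deg = if (is.finite(half_life_h)) log(2) / (60 * half_life_h) else 0,
      k_sec = k_sec,
      t_eq_min = t_eq_min,
      t_fit_end_min = t_fit_end_min
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  rho = %g (f_ilv = %.4f), phi_dynamic = %g\n",
              x$rho, x$f_ilv, x$phi_dynamic))
  cat(sprintf("  k_cleave = %g /min, k_retro = %g /min, k_sec = %g /min\n",
              x$k_cleave, x$k_retro, x$k_sec))
  cat(sprintf("  half_life_h = %g h (k_deg = %g /min)\n", x$half_life_h, x$k_deg))
  cat(sprintf("  fit window: [%g, %g] min\n", x$t_eq_min, x$t_fit_end_min))
  invisible(x)
}

# Initial pool state: all reporter starts on the endolysosome, split between
# the limiting membrane and the two intraluminal pools.
initial_pool_state <- function(params) {
  f <- params$f_ilv
  c(
    L = 1 - f,
    I_dyn = f * params$phi_dynamic,
    I_inert = f * (1 - params$phi_dynamic),
    N_nuc = 0,
    D = 0,
    S = 0
  )
}

# Generator matrix of the linear pool ODE system dx/dt = Q x, state ordered
# (L, I_dyn, I_inert, N_nuc, D, S). Columns sum to zero, so propagation by the
# matrix exponential conserves total reporter exactly.
pool_generator <- function(params) {
  kc <- params$k_cleave
  kr <- params$k_retro
  kd <- params$k_deg
  ks <- params$k_sec
  Q <- matrix(0, 6, 6,
              dimnames = list(c("L", "I_dyn", "I_inert", "N_nuc", "D", "S"),
                              c("L", "I_dyn", "I_inert", "N_nuc", "D", "S")))
  Q["L", "L"] <- -kc
  Q["L", "I_dyn"] <- kr
  Q["I_dyn", "I_dyn"] <- -(kr + kd + ks)
  Q["I_inert", "I_inert"] <- -(kd + ks)
  Q["N_nuc", "L"] <- kc
  Q["D", "I_dyn"] <- kd
  Q["D", "I_inert"] <- kd
  Q["S", "I_dyn"] <- ks
  Q["S", "I_inert"] <- ks
  Q
}

#' Forward-simulate the reporter pool trajectories
#'
#' Propagates the six-pool linear system through time. Cleavage removes
#' reporter from the limiting membrane into the nucleus; retrofusion transfers
#' dynamic intraluminal reporter back to the limiting membrane (where it
#' becomes cleavable); degradation and secretion drain both intraluminal
#' pools. The observable endolysosomal signal is `L + I_dyn + I_inert`.
#'
#' Propagation uses the matrix exponential of the generator over each time
#' step, so the solution is the exact solution of the linear system (up to
#' floating point) and total reporter is conserved at every time point.
#'
#' @param params A [kinetic_params()] object.
#' @param times Numeric vector of times in minutes, sorted increasing,
#'   starting at 0.
#' @return A tibble of class `pool_sim` with columns `t_min`, `L`, `I_dyn`,
#'   `I_inert`, `N_nuc`, `D`, `S`, `EL_observable`.
#' @examples
#' sim <- simulate_pools(kinetic_params(phi_dynamic = 0), seq(0, 360, by = 3))
#' tail(sim$EL_observable, 1)
#' @export
simulate_pools <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    abort("`times` must be a numeric vector without NAs.",
          class = "retroflux_domain_error")
  }
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must start at 0 and be strictly increasing.",
          class = "retroflux_domain_error")
  }
  Q <- pool_generator(params)
  x <- initial_pool_state(params)
  out <- matrix(NA_real_, nrow = length(times), ncol = 6,
                dimnames = list(NULL, names(x)))
  out[1, ] <- x
  if (length(times) > 1L) {
    dts <- diff(times)
    # one expm per distinct step length; uniform grids cost a single expm
    step_mats <- lapply(
      setNames(nm = unique(dts)),
      function(dt) as.matrix(Matrix::expm(Q * dt))
    )
    for (i in seq_along(dts)) {
      x <- drop(step_mats[[as.character(dts[i])]] %*% x)
      out[i + 1, ] <- x
    }
  }
  res <- as_tibble(out)
  res <- mutate(res,
                t_min = times,
                EL_observable = .data$L + .data$I_dyn + .data$I_inert,
                .before = 1)
  class(res) <- c("pool_sim", class(res))
  attr(res, "params") <- params
  res
}

#' Predicted long-time plateau of the endolysosomal signal
#'
#' In the pure-cleavage limit (no degradation, no secretion) the normalized
#' endolysosomal signal decays to a plateau: the limiting-membrane pool is
#' consumed by cleavage, the dynamic intraluminal pool is eventually
#' re-exposed by retrofusion and cleaved too, and only the retrofusion-inert
#' intraluminal pool persists. The plateau is therefore
#' `f_ilv * (1 - phi_dynamic)` when `k_retro > 0`, and `f_ilv` when
#' `k_retro == 0`. With a 2:1 intraluminal:limiting-membrane ratio and no
#' retrofusion this is 2/3, i.e. the 66%-70% band expected in the absence of
#' retrofusion.
#'
#' @param params A [kinetic_params()] object with `k_cleave > 0` and
#'   `k_deg == k_sec == 0` (set `half_life_h = Inf`, `k_sec = 0`).
#' @return The limiting fraction of the initial endolysosomal signal.
#' @examples
#' predict_plateau(kinetic_params(rho = 2, phi_dynamic = 0,
#'                                half_life_h = Inf, k_sec = 0))
#' @export
predict_plateau <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k_cleave <= 0) {
    abort("Plateau undefined: `k_cleave` must be > 0 (no cleavage, no decay).",
          class = "retroflux_plateau_error")
  }
  if (params$k_deg > 0 || params$k_sec > 0) {
    abort(paste0("`predict_plateau()` applies to the pure-cleavage limit: ",
                 "set `half_life_h = Inf` and `k_sec = 0`."),
          class = "retroflux_domain_error")
  }
  if (params$k_retro > 0) {
    params$f_ilv * (1 - params$phi_dynamic)
  } else {
    params$f_ilv
  }
}
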
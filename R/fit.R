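#' Fit the kinetic model to a normalized decay curve
#'
#' Estimates the cleavage rate, retrofusion rate and dynamic intraluminal
#' fraction (`k_cleave`, `k_retro`, `phi_dynamic`) by bounded least squares
#' against the observable endolysosomal signal of [simulate_pools()]. The
#' abundance ratio, degradation half-life and secretion rate are taken as
#' fixed (they are measured independently, by immunogold labelling,
#' pulse-chase and exosome blots respectively).
#'
#' Optimisation uses Levenberg-Marquardt with box constraints
#' (`minpack.lm::nls.lm`) from several seeded starting points to avoid local
#' minima; ties are broken by lowest residual sum of squares, then by lowest
#' `k_retro`.
#'
#' @param curve A [decay_curve()] (background-subtracted, first-frame
#'   normalized endolysosomal trace).
#' @param fixed Named list with elements `rho`, `half_life_h` and `k_sec`.
#' @param n_starts Number of multi-start attempts (default 5).
#' @param seed Integer seed for start-point jitter.
#' @param upper Named upper bounds for `k_cleave`, `k_retro` (per minute);
#'   `phi_dynamic` is always bounded by 1.
#' @return An object of class `kinetics_fit`; see [tidy.kinetics_fit()] and
#'   [glance.kinetics_fit()].
#' @seealso [simulate_pools()], [decay_curve()]
#' @export
fit_kinetics <- function(curve,
                         fixed = list(rho = 2, half_life_h = 24, k_sec = 0),
                         n_starts = 5,
                         seed = 1L,
                         upper = c(k_cleave = 1, k_retro = 0.1)) {
  stopifnot(inherits(curve, "decay_curve"))
  for (nm in c("rho", "half_life_h", "k_sec")) {
    if (is.null(fixed[[nm]]) || !is.numeric(fixed[[nm]])) {
      abort(sprintf("`fixed` must supply a numeric `%s`.", nm),
            class = "retroflux_domain_error")
    }
  }
  times <- curve$time_min
  values <- curve$value
  if (length(times) < 5L) {
    abort("At least 5 time points are required to fit the kinetic model.",
          class = "retroflux_insufficient_data_error")
  }

  make_params <- function(theta) {
    kinetic_params(
      rho = fixed$rho,
      phi_dynamic = theta[["phi_dynamic"]],
      k_cleave = theta[["k_cleave"]],
      k_retro = theta[["k_retro"]],
      half_life_h = fixed$half_life_h,
      k_sec = fixed$k_sec
    )
  }
  observable <- function(theta) {
    simulate_pools(make_params(theta), times)$EL_observable
  }
  resid_fun <- function(theta) observable(theta) - values

  lower <- c(k_cleave = 0, k_retro = 0, phi_dynamic = 0)
  upper <- c(k_cleave = unname(upper[["k_cleave"]]),
             k_retro = unname(upper[["k_retro"]]),
             phi_dynamic = 1)

  # deterministic coarse starts spanning the box, plus seeded jitter
  base_starts <- list(
    c(k_cleave = 0.02, k_retro = 0.002, phi_dynamic = 0.5),
    c(k_cleave = 0.10, k_retro = 0.010, phi_dynamic = 0.8),
    c(k_cleave = 0.01, k_retro = 0.0005, phi_dynamic = 0.2)
  )
  starts <- withr::with_seed(seed, {
    extra <- max(0, n_starts - length(base_starts))
    jitters <- replicate(extra, {
      c(k_cleave = stats::runif(1, 0.005, 0.5),
        k_retro = stats::runif(1, 1e-4, 0.05),
        phi_dynamic = stats::runif(1, 0.05, 0.95))
    }, simplify = FALSE)
    c(head(base_starts, n_starts), jitters)
  })

  fits <- map(starts, function(st) {
    tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) {
    abort("All optimisation starts failed.", class = "retroflux_fit_error")
  }
  ssr <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  kr <- vapply(fits, function(f) f$par[["k_retro"]], numeric(1))
  best <- order(ssr, kr)[1]
  fit <- fits[[best]]
  # nls.lm info codes 1:4 signal convergence; 0 and 5+ do not
  converged <- fit$info %in% 1:4

  estimates <- c(k_cleave = fit$par[["k_cleave"]],
                 k_retro = fit$par[["k_retro"]],
                 phi_dynamic = fit$par[["phi_dynamic"]])
  structure(
    list(
      estimates = estimates,
      fixed = fixed,
      ssr = ssr[best],
      converged = converged,
      info = fit$info,
      message = fit$message,
      n_starts = length(fits),
      n_obs = length(times),
      curve = curve,
      fitted = observable(estimates)
    ),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>\n")
  cat(sprintf("  k_cleave = %.5g /min, k_retro = %.5g /min, phi_dynamic = %.4f\n",
              x$estimates[["k_cleave"]], x$estimates[["k_retro"]],
              x$estimates[["phi_dynamic"]]))
  cat(sprintf("  SSR = %.4g over %d points (%d starts)%s\n",
              x$ssr, x$n_obs, x$n_starts,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Tidy the estimated kinetic parameters
#'
#' @param x A `kinetics_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' One-row fit summary
#'
#' @param x A `kinetics_fit` object.
#' @param ... Unused.
#' @return A tibble with the residual sum of squares, convergence flag,
#'   number of observations and number of optimisation starts.
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(ssr = x$ssr, converged = x$converged, n_obs = x$n_obs,
         n_starts = x$n_starts)
}

#' Augment a decay curve with fitted values
#'
#' @param x A `kinetics_fit` object.
#' @param ... Unused.
#' @return The fitted curve as a tibble with columns `time_min`, `value`,
#'   `.fitted` and `.resid`.
#' @importFrom generics augment
#' @export
augment.kinetics_fit <- function(x, ...) {
  tibble(
    time_min = x$curve$time_min,
    value = x$curve$value,
    .fitted = x$fitted,
    .resid = x$curve$value - x$fitted
  )
}
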
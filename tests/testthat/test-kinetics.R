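test_that("intraluminal_fraction converts abundance ratios to fractions", {
  expect_equal(intraluminal_fraction(2), 2 / 3, tolerance = 1e-12)
  expect_equal(intraluminal_fraction(0), 0)
  expect_equal(intraluminal_fraction(1), 0.5)
  expect_error(intraluminal_fraction(-0.1), class = "retroflux_domain_error")
  expect_error(intraluminal_fraction(Inf), class = "retroflux_domain_error")
  expect_error(intraluminal_fraction(NA_real_), class = "retroflux_domain_error")
})

test_that("kinetic_params validates and derives fields", {
  p <- kinetic_params(rho = 3, half_life_h = 24)
  expect_equal(p$f_ilv, 3 / 4, tolerance = 1e-12)
  expect_equal(p$k_deg, log(2) / (60 * 24))
  expect_equal(kinetic_params(half_life_h = Inf)$k_deg, 0)
  expect_error(kinetic_params(phi_dynamic = 1.2), class = "retroflux_domain_error")
  expect_error(kinetic_params(k_retro = -1), class = "retroflux_domain_error")
  expect_error(kinetic_params(t_eq_min = 400, t_fit_end_min = 360),
               class = "retroflux_domain_error")
})

test_that("pool state starts from the intraluminal split and stays conserved", {
  withr::with_seed(42, {
    for (i in 1:100) {
      p <- random_params()
      sim <- simulate_pools(p, c(0, sort(stats::runif(20, 1, 600))))
      expect_equal(sim$L[1], 1 - p$f_ilv)
      expect_equal(sim$I_dyn[1], p$f_ilv * p$phi_dynamic)
      expect_equal(sim$I_inert[1], p$f_ilv * (1 - p$phi_dynamic))
      pools <- as.matrix(sim[, c("L", "I_dyn", "I_inert", "N_nuc", "D", "S")])
      expect_true(all(pools >= -1e-12))
      expect_true(max(abs(rowSums(pools) - 1)) < 1e-9)
      # endolysosomal observable never increases
      expect_true(all(diff(sim$EL_observable) <= 1e-12))
    }
  })
})

test_that("simulate_pools rejects bad time grids", {
  p <- kinetic_params()
  expect_error(simulate_pools(p, c(10, 20)), class = "retroflux_domain_error")
  expect_error(simulate_pools(p, c(0, 5, 5)), class = "retroflux_domain_error")
  expect_error(simulate_pools(p, c(0, 10, 5)), class = "retroflux_domain_error")
})

test_that("with all rates zero the pools are constant", {
  p <- kinetic_params(k_cleave = 0, k_retro = 0, half_life_h = Inf, k_sec = 0)
  sim <- simulate_pools(p, seq(0, 600, by = 60))
  for (col in c("L", "I_dyn", "I_inert", "N_nuc", "D", "S")) {
    expect_equal(sim[[col]], rep(sim[[col]][1], nrow(sim)))
  }
})

test_that("solver matches the hand-derived two-exponential closed form", {
  # rho = 2, phi = 1, cleavage + retrofusion only: I(t) = I0 exp(-kr t),
  # L(t) = L0 exp(-kc t) + kr I0 (exp(-kr t) - exp(-kc t)) / (kc - kr)
  kc <- 0.2
  kr <- 0.01
  p <- kinetic_params(rho = 2, phi_dynamic = 1, k_cleave = kc, k_retro = kr,
                      half_life_h = Inf, k_sec = 0)
  times <- seq(0, 360, by = 4)
  sim <- simulate_pools(p, times)
  I0 <- 2 / 3
  L0 <- 1 / 3
  I_cf <- I0 * exp(-kr * times)
  L_cf <- L0 * exp(-kc * times) +
    kr * I0 * (exp(-kr * times) - exp(-kc * times)) / (kc - kr)
  expect_true(max(abs(sim$EL_observable - (I_cf + L_cf))) < 1e-8)
})

test_that("solver agrees with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, x, p) {
    list(c(
      p$k_retro * x[2] - p$k_cleave * x[1],
      -(p$k_retro + p$k_deg + p$k_sec) * x[2],
      -(p$k_deg + p$k_sec) * x[3],
      p$k_cleave * x[1],
      p$k_deg * (x[2] + x[3]),
      p$k_sec * (x[2] + x[3])
    ))
  }
  times <- seq(0, 540, by = 20)
  withr::with_seed(11, {
    for (i in 1:100) {
      p <- random_params()
      sim <- simulate_pools(p, times)
      x0 <- c(1 - p$f_ilv, p$f_ilv * p$phi_dynamic,
              p$f_ilv * (1 - p$phi_dynamic), 0, 0, 0)
      ref <- deSolve::ode(x0, times, rhs, p, rtol = 1e-11, atol = 1e-12)
      dev <- max(abs(as.matrix(ref[, 2:7]) -
                       as.matrix(sim[, c("L", "I_dyn", "I_inert", "N_nuc", "D", "S")])))
      expect_true(dev < 1e-8)
    }
  })
})

test_that("predict_plateau gives the retrofusion-inert intraluminal fraction", {
  expect_equal(predict_plateau(plateau_params()), 2 / 3, tolerance = 1e-12)
  p_full <- kinetic_params(rho = 2, phi_dynamic = 1, k_cleave = 0.1,
                           k_retro = 0.01, half_life_h = Inf, k_sec = 0)
  expect_equal(predict_plateau(p_full), 0)
  p_half <- kinetic_params(rho = 2, phi_dynamic = 0.5, k_cleave = 0.1,
                           k_retro = 0.01, half_life_h = Inf, k_sec = 0)
  expect_equal(predict_plateau(p_half), 1 / 3, tolerance = 1e-12)
  # long-time forward simulation converges to the same value
  sim <- simulate_pools(p_half, c(0, 10^(1:4) * 10))
  expect_equal(tail(sim$EL_observable, 1), 1 / 3, tolerance = 1e-6)
  expect_error(predict_plateau(kinetic_params(k_cleave = 0, half_life_h = Inf,
                                              k_sec = 0)),
               class = "retroflux_plateau_error")
  expect_error(predict_plateau(kinetic_params(k_cleave = 0.1, half_life_h = 24)),
               class = "retroflux_domain_error")
})

test_that("plateau equals the intraluminal fraction exactly when nothing retrofuses", {
  for (rho in c(0.5, 1, 2, 4)) {
    p <- kinetic_params(rho = rho, phi_dynamic = 0, k_cleave = 0.2,
                        half_life_h = Inf, k_sec = 0)
    expect_identical(predict_plateau(p), intraluminal_fraction(rho))
  }
})
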
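test_that("pulse-chase half-life is recovered from noiseless tables", {
  for (hl in c(12, 24, 48)) {
    tab <- generate_pulse_chase_table(hl, c(0, 4, 8, 16, 24, 48), noise_cv = 0)
    est <- half_life_from_pulse_chase(tab)
    expect_lt(abs(est$half_life_h - hl) / hl, 0.05)
  }
})

test_that("a two-point halving table gives the definitional half-life", {
  tab <- tibble::tibble(time_h = c(0, 24), mature_band = c(1, 0.5),
                        HM_band = c(0, 0.5))
  expect_equal(half_life_from_pulse_chase(tab)$half_life_h, 24)
})

test_that("non-decaying pulse-chase series flag an unresolvable half-life", {
  tab <- tibble::tibble(time_h = c(0, 12, 24), mature_band = c(50, 50, 50),
                        HM_band = c(0, 0, 0))
  est <- half_life_from_pulse_chase(tab)
  expect_identical(est$half_life_h, Inf)
  expect_error(half_life_from_pulse_chase(tab[2, ]),
               class = "retroflux_insufficient_data_error")
})

test_that("exosome secretion is rescaled from whole-cell to the MVB pool", {
  expect_equal(exosome_mvb_fraction(0.06, 0.62), 0.06 / 0.62)
  expect_equal(round(100 * exosome_mvb_fraction(0.06, 0.62), 1), 9.7)
  expect_equal(exosome_mvb_fraction(0, 0.5), 0)
  expect_equal(exosome_mvb_fraction(0.31, 0.62), 0.5)
  expect_error(exosome_mvb_fraction(0.7, 0.62),
               class = "retroflux_inconsistency_error")
  # scale invariance of the underlying ratio
  expect_equal(exosome_mvb_fraction(0.06, 0.62),
               exosome_mvb_fraction(0.06 * 0.5, 0.62 * 0.5))
})

test_that("exosome ratio changes reproduce the generating percent change", {
  tab <- generate_exosome_blot_table(c(control = 1, treated = 0.7), noise_cv = 0)
  out <- exosome_ratio_change(tab, "treated")
  expect_equal(out$percent_change, 30, tolerance = 1e-9)
  same <- generate_exosome_blot_table(c(control = 1, treated = 1), noise_cv = 0)
  expect_equal(exosome_ratio_change(same, "treated")$percent_change, 0)
  dual <- generate_exosome_blot_table(c(control = 1, treated = 0.9),
                                      noise_cv = 0, include_ifitm3 = TRUE)
  out2 <- exosome_ratio_change(dual, "treated",
                               normalizers = c("cd63", "ifitm3"))
  expect_equal(out2$percent_change, 10, tolerance = 1e-9)
})

test_that("replicates with zero normalizer signal are dropped with a warning", {
  tab <- generate_exosome_blot_table(c(control = 1, treated = 0.7), noise_cv = 0)
  tab$cd63_signal[1] <- 0
  expect_warning(out <- exosome_ratio_change(tab, "treated"), "Dropped 1")
  expect_equal(out$n_dropped, 1)
  expect_equal(out$percent_change, 30, tolerance = 1e-9)
})

test_that("immunogold summaries report per-MVB median and IQR", {
  tab <- tibble::tibble(gold_ilv = c(20, 6, 4), gold_lm = c(10, 3, 2))
  expect_equal(immunogold_ratios(tab)$ratio, c(2, 2, 2))
  s <- immunogold_ratio_summary(tab)
  expect_equal(s$median_ratio, 2)
  expect_equal(s$iqr, 0)
  # zero-LM MVBs are excluded but counted
  one <- tibble::tibble(gold_ilv = c(0, 3), gold_lm = c(5, 0))
  expect_equal(immunogold_ratios(one)$ratio, c(0, NA))
  s1 <- immunogold_ratio_summary(one)
  expect_equal(s1$median_ratio, 0)
  expect_equal(s1$n_zero_lm, 1)
  expect_error(immunogold_ratio_summary(tibble::tibble()),
               class = "retroflux_domain_error")
})

test_that("sampled immunogold medians concentrate around the generating ratio", {
  tab <- generate_immunogold_counts(rho = 2, n_mvb = 10000, seed = 4)
  s <- immunogold_ratio_summary(tab)
  expect_true(s$median_ratio > 1.8 && s$median_ratio < 2.2)
})

test_that("the retrofusion lower bound matches independent arithmetic", {
  # spreadsheet-style evaluation of the stated convention, kept separate
  # from the implementation: f_ilv = 2/3; loss = f_ilv - 0.41;
  # degraded = 1 - 2^(-6/24); secreted of MVB pool = 0.06/0.62
  f_ilv <- 2 / 3
  loss <- f_ilv - 0.41
  degraded <- 1 - 2^(-6 / 24)
  sec_mvb <- 0.06 / 0.62
  expected <- max(0, loss - f_ilv * degraded - sec_mvb) / f_ilv
  out <- retrofusion_lower_bound(0.41, rho = 2, half_life_h = 24,
                                 exo_frac_wcl = 0.06, mvb_frac = 0.62,
                                 window_h = 6)
  expect_equal(out$frac_retrofused_of_ilv_lower_bound, expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.0807351, tolerance = 1e-6) # frozen regression value
  expect_equal(out$frac_secreted_of_mvb, sec_mvb)
  expect_equal(out$frac_degraded_of_ilv, degraded)
})

test_that("with no degradation or secretion all loss is attributed to retrofusion", {
  out <- retrofusion_lower_bound(0.41, rho = 2, half_life_h = Inf,
                                 exo_frac_wcl = 0, mvb_frac = 0.62)
  expect_equal(out$frac_retrofused_of_ilv_lower_bound,
               (2 / 3 - 0.41) / (2 / 3), tolerance = 1e-12)
  # no intraluminal loss at all
  zero <- retrofusion_lower_bound(2 / 3, rho = 2, half_life_h = Inf,
                                  exo_frac_wcl = 0, mvb_frac = 0.62)
  expect_equal(zero$frac_retrofused_of_ilv_lower_bound, 0)
  expect_warning(
    over <- retrofusion_lower_bound(0.8, rho = 2, half_life_h = Inf,
                                    exo_frac_wcl = 0, mvb_frac = 0.62),
    "no detectable intraluminal loss"
  )
  expect_equal(over$frac_retrofused_of_ilv_lower_bound, 0)
})

test_that("the lower bound shrinks as degradation or secretion explain more", {
  base <- retrofusion_lower_bound(0.41)$frac_retrofused_of_ilv_lower_bound
  more_sec <- retrofusion_lower_bound(0.41, exo_frac_wcl = 0.12)
  shorter_hl <- retrofusion_lower_bound(0.41, half_life_h = 12)
  expect_lte(more_sec$frac_retrofused_of_ilv_lower_bound, base)
  expect_lte(shorter_hl$frac_retrofused_of_ilv_lower_bound, base)
  # alternative accounting convention is available and differs
  alt <- retrofusion_lower_bound(0.41, convention = "total_pool")
  expect_false(isTRUE(all.equal(alt$frac_retrofused_of_ilv_lower_bound, base)))
})
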
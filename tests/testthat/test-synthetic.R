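test_that("geometry generation is deterministic and respects its invariants", {
  g1 <- generate_geometry(3, seed = 7, image_shape = c(160, 160))
  g2 <- generate_geometry(3, seed = 7, image_shape = c(160, 160))
  expect_identical(g1$cells, g2$cells)
  expect_identical(g1$endolysosomes, g2$endolysosomes)

  expect_true(all(g1$endolysosomes$r >= 2))
  masks <- geometry_masks(g1)
  # pairwise disjointness: no pixel belongs to two compartments
  overlap <- masks$EL + masks$N + masks$PM + masks$CYTO
  expect_true(all(overlap <= 1))
  # every compartment sits inside the imaged cells
  expect_true(all(masks$CELL[masks$EL | masks$N | masks$PM | masks$CYTO]))
})

test_that("every endolysosome lies inside its cell's cytoplasm", {
  g <- generate_geometry(5, seed = 1, image_shape = c(256, 256))
  # brute-force check of each disc against its own cell and nucleus
  for (i in seq_len(nrow(g$endolysosomes))) {
    e <- g$endolysosomes[i, ]
    cl <- g$cells[g$cells$cell_id == e$cell_id, ]
    d_cell <- sqrt((e$cy - cl$cy)^2 + (e$cx - cl$cx)^2)
    d_nuc <- sqrt((e$cy - cl$nuc_cy)^2 + (e$cx - cl$nuc_cx)^2)
    expect_lt(d_cell + e$r, cl$r - g$pm_thickness_px)
    expect_gt(d_nuc, cl$nuc_r + e$r)
  }
  # and no endolysosome pixel escapes the cytoplasm mask
  masks <- geometry_masks(g)
  cytoplasm_or_el <- masks$CYTO | masks$EL
  expect_true(all(cytoplasm_or_el[masks$EL]))
})

test_that("placement fails cleanly when the field cannot hold the cells", {
  expect_error(generate_geometry(40, seed = 1, image_shape = c(96, 96)),
               class = "retroflux_placement_error")
})

test_that("without protease activation the endolysosomal GFP trace stays at 1", {
  geo <- tiny_geometry()
  kin <- kinetic_params(k_cleave = 0, k_retro = 0, half_life_h = Inf, k_sec = 0)
  sim <- generate_timelapse(geo, kin, acquisition_params(n_frames = 6))
  curve <- quantify_curve(sim$stack)
  expect_equal(curve$value, rep(1, 6), tolerance = 1e-12)
})

test_that("a static simulation produces bitwise-identical frames", {
  geo <- tiny_geometry()
  kin <- kinetic_params(k_cleave = 0, k_retro = 0, half_life_h = Inf, k_sec = 0)
  sim <- generate_timelapse(geo, kin,
                            acquisition_params(n_frames = 4, sir_drift = 0))
  expect_identical(sim$stack[, , , 1], sim$stack[, , , 4])
})

test_that("noiseless no-retrofusion movies decay to the predicted plateau", {
  sim <- plateau_sim()
  curve <- quantify_curve(sim$stack)
  expect_equal(tail(curve$value, 1), 2 / 3, tolerance = 0.02)
  # the recorded ground-truth trace matches the kinetic observable exactly
  expect_equal(sim$truth$trace$el_observable, sim$truth$pools$EL_observable,
               tolerance = 1e-9)
})

test_that("noise is applied only after ground truth is recorded", {
  geo <- tiny_geometry()
  kin <- plateau_params()
  noisy <- generate_timelapse(geo, kin,
                              acquisition_params(n_frames = 3, shot_noise = TRUE,
                                                 read_noise_sd = 2, rng_seed = 5))
  clean <- generate_timelapse(geo, kin, acquisition_params(n_frames = 3))
  expect_identical(noisy$truth$trace, clean$truth$trace)
  expect_false(identical(noisy$stack, clean$stack))
})

test_that("shot noise leaves the expected EL median at the noiseless value", {
  geo <- tiny_geometry()
  kin <- plateau_params()
  clean <- generate_timelapse(geo, kin, acquisition_params(n_frames = 2))
  el_mask <- clean$truth$masks$EL
  true_med <- median(clean$stack[, , "gfp", 1][el_mask])
  meds <- vapply(1:20, function(s) {
    noisy <- generate_timelapse(geo, kin,
                                acquisition_params(n_frames = 2, shot_noise = TRUE,
                                                   rng_seed = s))
    median(noisy$stack[, , "gfp", 1][el_mask])
  }, numeric(1))
  # Poisson median is within ~1 count of the mean at these intensities
  expect_lt(abs(mean(meds) - true_med) / true_med, 0.01)
})

test_that("pulse-chase tables follow the stated decay law", {
  tab <- generate_pulse_chase_table(24, c(0, 6, 24, 48), noise_cv = 0)
  expect_equal(tab$HM_band[1], 0)
  expect_equal(tab$mature_band[tab$time_h == 24],
               0.5 * tab$mature_band[tab$time_h == 0])
  loss6 <- 1 - tab$mature_band[tab$time_h == 6] / tab$mature_band[1]
  expect_equal(loss6, 1 - 2^(-0.25), tolerance = 1e-12)
  expect_error(generate_pulse_chase_table(24, c(0, 6), noise_cv = -1),
               class = "retroflux_domain_error")
  expect_identical(generate_pulse_chase_table(24, noise_cv = 0.2, seed = 3),
                   generate_pulse_chase_table(24, noise_cv = 0.2, seed = 3))
})

test_that("immunogold counts estimate the generating ILV:LM ratio", {
  tab <- generate_immunogold_counts(rho = 2, n_mvb = 10000, mean_total = 30,
                                    seed = 2)
  expect_true(all(tab$gold_ilv >= 0 & tab$gold_lm >= 0))
  pooled <- sum(tab$gold_ilv) / sum(tab$gold_lm)
  # binomial sampling: SE of the pooled ratio at n = 10^4, mean 30 is ~0.01
  expect_true(pooled > 1.9 && pooled < 2.1)
  expect_true(all(generate_immunogold_counts(0, 100, seed = 1)$gold_ilv == 0))
  expect_identical(generate_immunogold_counts(2, 50, seed = 9),
                   generate_immunogold_counts(2, 50, seed = 9))
  expect_error(generate_immunogold_counts(2, 10, mean_total = 0),
               class = "retroflux_domain_error")
})

test_that("exosome blot tables reproduce the specified ratios", {
  tab <- generate_exosome_blot_table(c(control = 1, treated = 0.7), noise_cv = 0)
  ratios <- tapply(tab$gfp_signal / tab$cd63_signal, tab$condition, mean)
  expect_equal(unname(ratios["control"]), 1)
  expect_equal(unname(ratios["treated"]), 0.7)
  expect_error(generate_exosome_blot_table(c(a = -1)),
               class = "retroflux_domain_error")
  expect_error(generate_exosome_blot_table(c(1, 2)),
               class = "retroflux_domain_error")
})

test_that("noisy blot ratios are unbiased over many seeds", {
  est <- vapply(1:500, function(s) {
    tab <- generate_exosome_blot_table(c(a = 0.8), n_replicates = 6,
                                       noise_cv = 0.1, seed = s)
    mean(tab$gfp_signal / tab$cd63_signal)
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), 4 * se + 1e-4)
})
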
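test_that("noiseless phantom signal follows the mono-exponential forward model", {
  sp <- small_phantom_spec(noise_sigma = 0, seed = 7)
  ph <- make_phantom(sp)
  core <- which(ph$truth$labels == 3L)
  te <- sp$echo_times
  # every core voxel decays as s0 * exp(-TE / its own T2)
  nvox <- prod(sp$grid_shape)
  sig <- matrix(ph$volume$signal, nrow = nvox)
  expected <- sp$s0 * outer(ph$truth$t2[core], te,
                            function(t2, te) exp(-te / t2))
  expect_equal(sig[core, ], expected, tolerance = 1e-12)
  # outside the brain the signal is exactly zero
  expect_true(all(sig[ph$truth$labels == 0L, ] == 0))
})

test_that("fixed class T2 inverts exactly through the downstream fit", {
  sp <- small_phantom_spec(noise_sigma = 0,
                           class_t2 = c(uninjured = 30, penumbra = 45,
                                        core = 70),
                           class_t2_sd = c(uninjured = 0, penumbra = 0,
                                           core = 0),
                           seed = 1)
  ph <- make_phantom(sp)
  core <- which(ph$truth$labels == 3L)
  v <- core[1L]
  nvox <- prod(sp$grid_shape)
  s <- matrix(ph$volume$signal, nrow = nvox)[v, ]
  expect_equal(s, sp$s0 * exp(-sp$echo_times / 70), tolerance = 1e-12)
  f <- fit_t2_voxel(s, sp$echo_times)
  expect_equal(f$t2, 70, tolerance = 1e-6)
})

test_that("symmetric phantom has equal hemisphere voxel counts when nothing is lost", {
  sp <- small_phantom_spec(noise_sigma = 0, lost_fraction = 0)
  ph <- make_phantom(sp)
  cols <- slice.index(ph$truth$brain_mask, 2L)
  n_ipsi <- sum(ph$truth$brain_mask & cols > sp$midline_col)
  n_contra <- sum(ph$truth$brain_mask & cols <= sp$midline_col)
  expect_identical(n_ipsi, n_contra)
  expect_identical(ph$truth$true_lost, 0)
})

test_that("true core volume matches a brute-force point-in-ellipsoid count", {
  sp <- small_phantom_spec(noise_sigma = 0, seed = 2)
  ph <- make_phantom(sp)
  gs <- sp$grid_shape
  n <- 0L
  for (k in seq_len(gs[3L])) {
    for (j in seq_len(gs[2L])) {
      for (i in seq_len(gs[1L])) {
        d <- ((i - sp$core_center[1L]) / sp$core_semiaxes[1L])^2 +
          ((j - sp$core_center[2L]) / sp$core_semiaxes[2L])^2 +
          ((k - sp$core_center[3L]) / sp$core_semiaxes[3L])^2
        if (d <= 1) n <- n + 1L
      }
    }
  }
  expect_equal(unname(ph$truth$true_volumes["core"]),
               n * prod(sp$voxel_size))
})

test_that("phantom label bookkeeping conserves the grid", {
  for (lf in c(0, 0.12)) {
    sp <- small_phantom_spec(noise_sigma = 10, lost_fraction = lf, seed = 5)
    ph <- make_phantom(sp)
    counts <- table(factor(ph$truth$labels, levels = 0:3))
    lost_vox <- ph$truth$true_lost / prod(sp$voxel_size)
    # outside includes lost voxels; classes + outside fill the grid
    expect_identical(as.integer(sum(counts)), as.integer(prod(sp$grid_shape)))
    expect_equal(sum(ph$truth$true_volumes) + ph$truth$true_lost +
                   (counts[["0"]] - lost_vox) * prod(sp$voxel_size),
                 prod(sp$grid_shape) * prod(sp$voxel_size))
  }
})

test_that("phantom generation is bit-identical for identical spec and seed", {
  sp <- small_phantom_spec(noise_sigma = 15, lost_fraction = 0.05, seed = 9)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$volume$signal, b$volume$signal)
  expect_identical(a$truth$labels, b$truth$labels)
  c_ <- make_phantom(small_phantom_spec(noise_sigma = 15,
                                        lost_fraction = 0.05, seed = 10))
  expect_false(identical(a$volume$signal, c_$volume$signal))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(echo_times = c(10, 10, 20)), "increasing")
  expect_error(phantom_spec(class_t2 = c(uninjured = 50, penumbra = 45,
                                         core = 70)),
               "ordered")
  expect_error(phantom_spec(lost_fraction = 1.5))
  # lesion pushed across the midline into the contralateral side
  sp <- small_phantom_spec()
  sp$core_center[2L] <- sp$midline_col - 2
  expect_error(make_phantom(sp), "ipsilateral")
})

test_that("noiseless sweep components sit at nominal amplitude and latency", {
  sp <- ephys_spec(noise_sd = 0)
  tr <- make_fepsp_sweep(sp, 650)
  m <- measure_components(tr)
  s <- io_sigmoid(650, 1, sp$io_half_current, sp$io_slope)
  expect_equal(m$fp1_amp_mv, sp$fp1_amp * s, tolerance = 1e-12)
  expect_equal(m$fp2_amp_mv, sp$fp2_amp * s, tolerance = 1e-12)
  expect_equal(m$vb_amp_mv, sp$vb_amp * s, tolerance = 1e-12)
  expect_equal(m$fp1_latency_ms, sp$fp1_latency)
  expect_equal(m$fp2_latency_ms, sp$fp2_latency)
})

test_that("zero-current sweep amplitudes equal the sigmoid at the origin", {
  sp <- ephys_spec(noise_sd = 0)
  m <- measure_components(make_fepsp_sweep(sp, 0))
  base <- 1 / (1 + exp(sp$io_slope * sp$io_half_current))
  expect_equal(m$fp1_amp_mv, sp$fp1_amp * base, tolerance = 1e-12)
  expect_lt(m$fp1_amp_mv, 0.1 * sp$fp1_amp)
})

test_that("pharmacological blockade flags silence the right components", {
  m_cnqx <- measure_components(
    make_fepsp_sweep(ephys_spec(noise_sd = 0, cnqx = TRUE), 650))
  expect_identical(m_cnqx$fp1_amp_mv, 0)
  expect_identical(m_cnqx$fp2_amp_mv, 0)
  expect_gt(m_cnqx$vb_amp_mv, 0)
  m_ttx <- measure_components(
    make_fepsp_sweep(ephys_spec(noise_sd = 0, ttx = TRUE), 650))
  expect_identical(m_ttx$vb_amp_mv, 0)
  expect_identical(m_ttx$fp1_amp_mv, 0)
  expect_identical(m_ttx$fp2_amp_mv, 0)
})

test_that("input-output series covers the standard grid and scales with potentiation", {
  sp1 <- ephys_spec(noise_sd = 0, potentiation_factor = 1)
  sp2 <- ephys_spec(noise_sd = 0, potentiation_factor = 2)
  tr1 <- make_io_series(sp1)
  tr2 <- make_io_series(sp2)
  expect_length(tr1, 14L)
  a1 <- vapply(tr1, function(t) measure_components(t)$fp1_amp_mv,
               numeric(1))
  a2 <- vapply(tr2, function(t) measure_components(t)$fp1_amp_mv,
               numeric(1))
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  # noiseless amplitudes equal the generating sigmoid on the grid
  grid <- seq(0, 650, by = 50)
  expect_equal(a1, io_sigmoid(grid, sp1$fp1_amp, sp1$io_half_current,
                              sp1$io_slope),
               tolerance = 1e-12)
  expect_error(make_io_series(sp1, c(0, 50, 50)), "duplicate")
})

test_that("paired-pulse generator enforces non-overlap and encodes facilitation", {
  sp <- ephys_spec(noise_sd = 0, facilitation_factor = 1.5)
  expect_error(make_paired_pulse(sp, 50, interval_ms = 8), "overlap")
  pp <- make_paired_pulse(sp, 50, 75)
  expect_length(pp$stim_times_ms, 2L)
  expect_equal(diff(pp$stim_times_ms), 75)
  r <- paired_pulse_facilitation(pp)
  expect_equal(r$ppf_percent, 50, tolerance = 1e-9)
})

test_that("sweep generation is deterministic per seed", {
  sp <- ephys_spec(seed = 21)
  expect_identical(make_fepsp_sweep(sp, 300)$voltage_mv,
                   make_fepsp_sweep(sp, 300)$voltage_mv)
  a <- make_io_series(sp)
  b <- make_io_series(sp)
  expect_identical(lapply(a, `[[`, "voltage_mv"),
                   lapply(b, `[[`, "voltage_mv"))
})

test_that("Ct table encodes imposed group shifts", {
  ct0 <- make_ct_table(4, c(sham = 0, hi = 0), noise_sd = 0)
  f0 <- delta_delta_ct(ct0, "Gria2", "Gapdh", "sham")
  expect_equal(f0$fold, rep(1, 8))
  ct1 <- make_ct_table(4, c(sham = 0, hi = -1), noise_sd = 0)
  f1 <- delta_delta_ct(ct1, "Gria2", "Gapdh", "sham")
  expect_equal(f1$fold[f1$group == "hi"], rep(2, 4))
})

test_that("noisy Ct folds converge to the imposed effect at large n", {
  ct <- make_ct_table(10000, c(sham = 0, hi = 1), seed = 3, noise_sd = 0.3)
  s <- fold_change_summary(delta_delta_ct(ct, "Gria2", "Gapdh", "sham"))
  expect_equal(s$geo_mean_fold[s$group == "hi"], 0.5, tolerance = 0.02)
  expect_equal(s$geo_mean_fold[s$group == "sham"], 1, tolerance = 1e-12)
})
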
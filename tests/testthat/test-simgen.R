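noiseless <- function(...) {
  sim_config(..., psf_sigma_um = c(0, 0, 0), photon_scale = 0,
             read_noise_sd = 0)
}

test_that("a single-nucleus field realizes the configured territory fraction", {
  cfg <- noiseless(n_nuclei = 1, field_shape = c(40L, 120L, 120L),
                   territory_volume_fraction = 0.3,
                   territory_irregularity = 0,
                   pairing_fraction = 1, paired_mode_merged_prob = 1,
                   seed = 2)
  sf <- simulate_field(cfg)
  expect_equal(nrow(sf$truth$nuclei), 1L)
  expect_equal(nrow(sf$truth$signals), 1L)
  frac <- sf$truth$signals$volume_um3 / sf$truth$nuclei$voxel_volume_um3
  expect_gte(frac, 0.28)
  expect_lte(frac, 0.32)
  # the signal label volume agrees with the recorded truth volume
  vv <- prod(cfg$voxel_size)
  expect_equal(sum(sf$signal_labels$chr2$labels > 0) * vv,
               sf$truth$signals$volume_um3)
})

test_that("identical config and seed give bit-identical stacks and truth", {
  cfg <- sim_config(n_nuclei = 4, field_shape = c(30L, 200L, 200L), seed = 9)
  s1 <- simulate_field(cfg)
  s2 <- simulate_field(cfg)
  expect_identical(s1$image$data, s2$image$data)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$nucleus_labels$labels, s2$nucleus_labels$labels)
  # a different seed changes the field
  s3 <- simulate_field(cfg, seed = 10)
  expect_false(identical(s1$image$data$dna, s3$image$data$dna))
})

test_that("degenerate pairing fractions yield all-paired or all-unpaired truth", {
  cfg1 <- noiseless(n_nuclei = 12, field_shape = c(30L, 260L, 260L),
                    pairing_fraction = 1, seed = 3)
  expect_true(all(simulate_field(cfg1)$truth$pairing$state == "paired"))
  cfg0 <- noiseless(n_nuclei = 12, field_shape = c(30L, 260L, 260L),
                    pairing_fraction = 0, seed = 3)
  expect_true(all(simulate_field(cfg0)$truth$pairing$state == "unpaired"))
})

test_that("pairing-state frequencies follow the configured fraction", {
  # Bernoulli draws sit inside the 99% binomial band of the target fraction
  set.seed(17)
  for (p in c(0.25, 0.7)) {
    x <- ctquant:::draw_pairing_states(5000, p)
    band <- qbinom(c(0.005, 0.995), 5000, p) / 5000
    expect_gte(mean(x), band[1])
    expect_lte(mean(x), band[2])
  }
})

test_that("truth pairing geometry respects the placement threshold", {
  cfg <- noiseless(n_nuclei = 30, field_shape = c(30L, 420L, 420L),
                   pairing_fraction = 0.5, paired_mode_merged_prob = 0.4,
                   seed = 12)
  tr <- simulate_field(cfg)$truth$pairing
  paired2 <- tr$state == "paired" & tr$n_true_signals == 2
  expect_true(all(tr$placed_distance_um[paired2] <= cfg$pairing_distance_um))
  expect_true(all(is.na(tr$placed_distance_um[tr$n_true_signals == 1])))
  unp <- tr$state == "unpaired"
  expect_true(all(tr$placed_distance_um[unp] > 1.5 * cfg$pairing_distance_um))
  expect_true(all(tr$placed_distance_um[unp] <= 3 * cfg$pairing_distance_um))
  # every signal references an existing nucleus
  sg <- simulate_field(cfg)$truth$signals
  expect_true(all(sg$nucleus_id %in% seq_len(cfg$n_nuclei)))
})

test_that("rendered blobs match closed-form and ellipsoid definitions", {
  d <- c(45L, 45L, 45L)
  vs <- c(0.1, 0.1, 0.1)
  m <- render_blob(c(2.2, 2.2, 2.2), c(2, 2, 2), 0, d, vs)
  expect_equal(sum(m) * prod(vs), 4 / 3 * pi * 2^3, tolerance = 0.02)

  # irregularity 0 is exactly the voxel-centre ellipsoid inequality
  ax <- c(1.2, 0.8, 1.5)
  mb <- render_blob(c(2.2, 2.2, 2.2), ax, 0, d, vs)
  co <- (seq_len(45) - 1) * 0.1 - 2.2
  u2 <- outer(outer((co / ax[1])^2, (co / ax[2])^2, `+`), (co / ax[3])^2, `+`)
  expect_identical(mb, u2 <= 1)
})

test_that("irregular blobs stay connected with near-preserved volume", {
  d <- c(60L, 60L, 60L)
  vs <- c(0.1, 0.1, 0.1)
  base <- render_blob(c(3, 3, 3), c(1.5, 1.5, 1.5), 0, d, vs)
  for (seed in 1:5) {
    m <- render_blob(c(3, 3, 3), c(1.5, 1.5, 1.5), 1.0, d, vs, seed = seed)
    lab <- ctquant:::cpp_label3d(m, d)
    expect_equal(max(lab), 1L, label = sprintf("connectivity, seed %d", seed))
    expect_equal(sum(m), sum(base), tolerance = 0.10,
                 label = sprintf("volume, seed %d", seed))
  }
  expect_error(render_blob(c(0.2, 3, 3), c(1.5, 1.5, 1.5), 0, d, vs),
               "exceeds grid")
})

test_that("optics are the identity when disabled and deterministic when seeded", {
  f <- image_field(list(a = array(runif(20^3, 0, 50), rep(20L, 3))),
                   c(0.3, 0.1, 0.1))
  out <- apply_optics(f, psf_sigma_um = c(0, 0, 0), photon_scale = 0,
                      read_noise_sd = 0)
  expect_identical(out$data$a, f$data$a)
  n1 <- apply_optics(f, photon_scale = 1, read_noise_sd = 2, seed = 5)
  n2 <- apply_optics(f, photon_scale = 1, read_noise_sd = 2, seed = 5)
  expect_identical(n1$data$a, n2$data$a)
  expect_error(apply_optics(f, photon_scale = -1), "nonnegative")
})

test_that("shot noise preserves the mean intensity", {
  f <- image_field(list(a = array(100, c(50L, 50L, 50L))), c(0.1, 0.1, 0.1))
  n <- apply_optics(f, psf_sigma_um = c(0, 0, 0), photon_scale = 2,
                    read_noise_sd = 0, seed = 8)
  expect_equal(mean(n$data$a), 100, tolerance = 0.01)
})

test_that("infeasible placement fails with a crowding error", {
  cfg <- sim_config(n_nuclei = 60, field_shape = c(20L, 80L, 80L),
                    max_place_attempts = 30, seed = 1)
  expect_error(simulate_field(cfg), "too crowded")
  expect_error(sim_config(pairing_fraction = 1.4), "out of range")
  expect_error(sim_config(territory_volume_fraction = 0), "out of range")
  expect_error(sim_config(voxel_size = c(0.3, 0, 0.1)), "positive")
})

test_that("voxelized truth volumes track the analytic ellipsoid volumes", {
  cfg <- noiseless(n_nuclei = 8, field_shape = c(30L, 220L, 220L), seed = 4)
  tr <- simulate_field(cfg)$truth$nuclei
  # >= 20 voxels per radius in y/x at these settings
  expect_true(all(abs(tr$voxel_volume_um3 / tr$analytic_volume_um3 - 1) < 0.05))
})
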
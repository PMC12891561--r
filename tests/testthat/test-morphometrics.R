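vs_iso <- c(0.1, 0.1, 0.1)

digital_ball <- function(r_vox, voxel = 0.1) {
  r <- r_vox * voxel
  d <- as.integer(rep(2 * r_vox + 7, 3))
  render_blob(rep(r + 3 * voxel, 3), rep(r, 3), 0, d, rep(voxel, 3))
}

test_that("digital ball and cube reproduce closed-form geometry", {
  m <- digital_ball(20)
  r <- measure_region(m, vs_iso)
  expect_equal(r$volume_um3, 4 / 3 * pi * 8, tolerance = 0.02)
  expect_gte(r$sphericity, 0.95)
  expect_lte(r$sphericity, 1.02)
  expect_equal(r$surface_area_um2, 4 * pi * 4, tolerance = 0.05)

  cm <- array(FALSE, rep(64L, 3))
  cm[3:62, 3:62, 3:62] <- TRUE
  rc <- measure_region(cm, vs_iso)
  expect_equal(rc$volume_um3, 6^3, tolerance = 1e-12)
  expect_equal(rc$sphericity, (pi / 6)^(1 / 3), tolerance = 0.025)

  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  expect_equal(measure_region(sv, vs_iso)$volume_um3, 1e-3)
})

test_that("measure_region validates its mask", {
  expect_error(measure_region(array(FALSE, c(4, 4, 4)), vs_iso), "empty")
  two <- array(FALSE, c(9, 9, 9)); two[2, 2, 2] <- TRUE; two[8, 8, 8] <- TRUE
  expect_error(measure_region(two, vs_iso), "connected")
  expect_error(measure_region(matrix(TRUE, 2, 2), vs_iso), "3D")
})

test_that("component volumes add exactly over disjoint unions", {
  set.seed(3)
  d <- c(40L, 40L, 40L)
  lab <- array(0L, d)
  centers <- list(c(1, 1, 1), c(1, 3, 1), c(3, 2, 3))
  for (k in 1:3) {
    m <- render_blob(centers[[k]], rep(0.4, 3), 0.8, d, vs_iso)
    lab[m & lab == 0L] <- k
  }
  met <- measure_labels(lab, vs_iso)
  expect_equal(sum(met$volume_um3), sum(lab > 0) * prod(vs_iso),
               tolerance = 1e-12)
})

test_that("sphericity is invariant to translation and stable under rotation", {
  m <- digital_ball(8)
  s0 <- measure_region(m, vs_iso)$sphericity
  # translate by padding on one side
  shifted <- array(FALSE, dim(m) + c(5L, 0L, 0L))
  shifted[-(1:5), , ] <- m
  expect_equal(measure_region(shifted, vs_iso)$sphericity, s0)

  # irregular blob: 90-degree rotations on an isotropic grid
  b <- render_blob(c(1.5, 1.5, 1.5), c(1.0, 0.7, 0.5), 0.8,
                   c(31L, 31L, 31L), vs_iso, seed = 2)
  s1 <- measure_region(b, vs_iso)$sphericity
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    expect_equal(measure_region(aperm(b, perm), vs_iso)$sphericity, s1,
                 tolerance = 0.02)
  }
})

test_that("digital-ball sphericity approaches 1 as the radius grows", {
  s <- vapply(c(5, 10, 20, 40), function(r)
    measure_region(digital_ball(r), vs_iso)$sphericity, 1.0)
  expect_true(all(diff(s) >= -0.02))
  expect_true(all(s >= 0.95 & s <= 1.02))
})

test_that("normalized volume is a plain ratio with the combined-homolog rule", {
  expect_equal(normalized_volume(30, 100), 0.30)
  # combined volume of two unpaired homologs, normalized once
  expect_equal(normalized_volume(12 + 18, 100), 0.30)
  expect_equal(normalized_volume(0, 50), 0)
  expect_error(normalized_volume(1, 0), "positive")
  expect_warning(v <- normalized_volume(120, 100), "exceeds 1")
  expect_equal(v, 1.2)
})

test_that("territory overlap percentages come from exact voxel counts", {
  d <- c(12L, 24L, 24L)
  nuc <- array(1L, d)
  a <- array(0L, d); b <- array(0L, d)
  a[1:4, 1:5, 1:5] <- 1L                 # |A| = 100
  b[1:8, 1:5, 6:10] <- 1L                # |B| = 200, disjoint from A
  b[1:2, 1:5, 1:5] <- 1L                 # move 50 voxels onto A
  b[1:2, 1:5, 6:10] <- 0L
  expect_equal(sum(a > 0), 100); expect_equal(sum(b > 0), 200)
  ov <- overlap_percent(a, b, nuc, 1L, vs_iso)
  expect_equal(sum(a > 0 & b > 0), 50)
  expect_equal(ov$overlap_of_a_pct, 50)
  expect_equal(ov$overlap_of_b_pct, 25)
  expect_equal(ov$intersection_volume_um3, 50 * prod(vs_iso))

  ident <- overlap_percent(a, a, nuc, 1L, vs_iso)
  expect_equal(ident$overlap_of_a_pct, 100)
  expect_equal(ident$overlap_of_b_pct, 100)

  disj <- array(0L, d); disj[9:12, 20:24, 20:24] <- 1L
  dv <- overlap_percent(a, disj, nuc, 1L, vs_iso)
  expect_equal(dv$overlap_of_a_pct, 0)
  expect_equal(dv$overlap_of_b_pct, 0)

  none <- overlap_percent(a, array(0L, d), nuc, 1L, vs_iso)
  expect_false(none$defined)
  expect_true(is.na(none$overlap_of_a_pct))
})

test_that("overlap intersection is symmetric and bounded for random masks", {
  set.seed(14)
  d <- c(16L, 16L, 16L)
  nuc <- array(1L, d)
  for (i in 1:8) {
    a <- array(as.integer(runif(prod(d)) < 0.3), d)
    b <- array(as.integer(runif(prod(d)) < 0.4), d)
    if (sum(a) == 0 || sum(b) == 0) next
    oab <- overlap_percent(a, b, nuc, 1L, vs_iso)
    oba <- overlap_percent(b, a, nuc, 1L, vs_iso)
    expect_identical(oab$intersection_volume_um3, oba$intersection_volume_um3)
    expect_lte(oab$intersection_volume_um3,
               min(sum(a), sum(b)) * prod(vs_iso))
  }
})

test_that("focus exclusion recovers the nucleoplasmic mean and focus volume", {
  d <- c(20L, 40L, 40L)
  nuc <- render_blob(c(1, 2, 2), c(0.9, 1.6, 1.6), 0, d, vs_iso)
  ch <- array(0, d)
  ch[nuc] <- 50

  r0 <- intensity_excluding_foci(ch, nuc, vs_iso, k_foci = 0)
  expect_identical(r0$mean_outside_foci, 50)
  expect_false(r0$flagged)

  blob <- render_blob(c(1, 1.4, 1.4), rep(0.3, 3), 0, d, vs_iso) & nuc
  ch[blob] <- 200
  r1 <- intensity_excluding_foci(ch, nuc, vs_iso, k_foci = 1)
  expect_equal(r1$n_found, 1L)
  expect_equal(r1$foci[[1]]$volume_um3, sum(blob) * prod(vs_iso))
  expect_identical(r1$mean_outside_foci, 50)

  # asking for more foci than exist flags the record instead of failing
  r2 <- intensity_excluding_foci(ch, nuc, vs_iso, k_foci = 2)
  expect_equal(r2$n_found, 1L)
  expect_true(r2$flagged)
})

test_that("two simulated nuclear-body foci are recovered near their true centres", {
  cfg <- sim_config(n_nuclei = 2, field_shape = c(40L, 160L, 160L),
                    include_foci = TRUE, n_foci = 2, seed = 6)
  sf <- simulate_field(cfg)
  nl <- sf$nucleus_labels$labels
  for (nid in 1:2) {
    fx <- intensity_excluding_foci(sf$image$data$polII, nl == nid,
                                   cfg$voxel_size, k_foci = 2)
    expect_equal(fx$n_found, 2L)
    tr <- sf$truth$foci[sf$truth$foci$nucleus_id == nid, ]
    for (f in fx$foci) {
      dd <- sqrt((tr$center_z_um - f$centroid_um[1])^2 +
                   (tr$center_y_um - f$centroid_um[2])^2 +
                   (tr$center_x_um - f$centroid_um[3])^2)
      expect_lt(min(dd), 2 * max(cfg$voxel_size))
    }
    # nucleoplasmic mean, foci removed, sits near the configured level
    expect_equal(fx$mean_outside_foci, cfg$focus_background_intensity,
                 tolerance = 0.1)
  }
})
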
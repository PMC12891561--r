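sig_row <- function(nid, ch, z, y, x) {
  data.frame(nucleus_id = nid, channel = ch,
             centroid_z_um = z, centroid_y_um = y, centroid_x_um = x)
}

test_that("pairing call follows the 0.8 um rule with an inclusive boundary", {
  two <- function(d) rbind(sig_row(1, "chr3", 0, 0, 0), sig_row(1, "chr3", 0, 0, d))
  r <- call_pairing(two(0.5))
  expect_identical(r$status, "paired")
  expect_identical(r$basis, "distance")
  expect_equal(r$min_distance_um, 0.5)

  expect_identical(call_pairing(two(0.80))$status, "paired")
  expect_identical(call_pairing(two(0.81))$status, "unpaired")

  # the rule is on true 3D distance, not any single axis
  diag3 <- rbind(sig_row(1, "chr3", 0, 0, 0),
                 sig_row(1, "chr3", 0.5, 0.5, 0.5))
  expect_identical(call_pairing(diag3)$status, "unpaired")
  expect_equal(call_pairing(diag3)$min_distance_um, sqrt(0.75))
})

test_that("signal multiplicity drives the call basis", {
  one <- sig_row(7, "chrX", 1, 2, 3)
  r1 <- call_pairing(one)
  expect_identical(r1$status, "paired")
  expect_identical(r1$basis, "single_signal")

  r0 <- call_pairing(one[0, ], nucleus_id = 7, target = "chrX")
  expect_identical(r0$status, "ambiguous")

  three <- rbind(sig_row(1, "c", 0, 0, 0), sig_row(1, "c", 0, 0, 0.3),
                 sig_row(1, "c", 0, 0, 2))
  r3 <- call_pairing(three)
  expect_identical(r3$status, "ambiguous")
  expect_equal(r3$min_distance_um, 0.3)

  mixed <- rbind(sig_row(1, "c", 0, 0, 0), sig_row(2, "c", 0, 0, 1))
  expect_error(call_pairing(mixed), "single nucleus")
})

test_that("paired sets are nested as the distance threshold grows", {
  set.seed(5)
  sigs <- do.call(rbind, lapply(1:40, function(i) {
    rbind(sig_row(i, "chr2", 0, 0, 0),
          sig_row(i, "chr2", 0, 0, runif(1, 0, 2.5)))
  }))
  prev <- character(0)
  for (thr in c(0.2, 0.5, 0.8, 1.2, 2.0)) {
    calls <- call_pairing_all(sigs, threshold_um = thr)
    paired <- calls$nucleus_id[calls$status == "paired"]
    expect_true(all(prev %in% paired),
                label = sprintf("nesting at threshold %.1f", thr))
    prev <- paired
  }
})

test_that("conformation classes cross arm and centromere states", {
  mk <- function(status) list(status = status)
  r <- classify_conformation(mk("paired"), mk("paired"), mk("paired"))
  expect_identical(r$class_label, "both_arms_paired/cen_paired")
  r <- classify_conformation(mk("paired"), mk("unpaired"), mk("unpaired"))
  expect_identical(r$class_label, "one_arm_paired/cen_unpaired")
  r <- classify_conformation(mk("unpaired"), mk("unpaired"), mk("unpaired"))
  expect_identical(r$class_label, "no_arms_paired/cen_unpaired")

  # all six labels occur, arms are exchangeable, ambiguity propagates
  states <- c("paired", "unpaired")
  labs <- character(0)
  for (l in states) for (rr in states) for (cen in states) {
    cl <- classify_conformation(mk(l), mk(rr), mk(cen))
    labs <- c(labs, cl$class_label)
    expect_identical(cl$class_label,
                     classify_conformation(mk(rr), mk(l), mk(cen))$class_label)
  }
  expect_length(unique(labs), 6L)
  amb <- classify_conformation(mk("ambiguous"), mk("paired"), mk("paired"))
  expect_true(amb$ambiguous)
  expect_identical(amb$class_label, "ambiguous")
})

test_that("arm-level summaries respect set containment of pairing states", {
  # fraction with at least one arm paired >= fraction with both arms paired
  set.seed(8)
  mk <- function(status) list(status = status)
  st <- matrix(sample(c("paired", "unpaired"), 200, replace = TRUE), ncol = 2)
  cls <- apply(st, 1, function(s)
    classify_conformation(mk(s[1]), mk(s[2]), mk("paired"))$arm_state)
  expect_gte(mean(cls != "no_arms_paired"), mean(cls == "both_arms_paired"))
})

test_that("replicate aggregation reports mean and SD across replicates", {
  calls <- data.frame(
    target = "chr2",
    replicate = rep(1:3, each = 20),
    status = c(rep(c("paired", "unpaired"), c(16, 4)),   # 80 %
               rep(c("paired", "unpaired"), c(14, 6)),   # 70 %
               rep(c("paired", "unpaired"), c(15, 5))))  # 75 %
  s <- aggregate_pairing(calls, min_nuclei = 30, min_replicates = 3)
  expect_equal(s$mean_pct, 75)
  expect_equal(s$sd_pct, 5)
  expect_equal(s$total_nuclei, 60L)
  expect_true(s$reportable)
  reps <- attr(s, "replicates")
  expect_equal(reps$pct_paired, c(80, 70, 75))

  # below the reporting minimums the summary is returned but flagged
  s2 <- aggregate_pairing(calls, min_nuclei = 300, min_replicates = 3)
  expect_false(s2$reportable)
  expect_equal(s2$mean_pct, 75)
})

test_that("degenerate replicates are excluded or leave the SD undefined", {
  one <- data.frame(target = "chr2", replicate = 1,
                    status = rep(c("paired", "unpaired"), c(3, 1)))
  s <- aggregate_pairing(one, min_nuclei = 2, min_replicates = 3)
  expect_equal(s$mean_pct, 75)
  expect_true(is.na(s$sd_pct))
  expect_false(s$reportable)

  allamb <- data.frame(target = "chr2", replicate = c(1, 1, 2, 2),
                       status = c("paired", "paired", "ambiguous", "ambiguous"))
  expect_message(s3 <- aggregate_pairing(allamb, min_nuclei = 1,
                                         min_replicates = 1),
                 "no non-ambiguous")
  expect_equal(s3$n_replicates, 1L)
  expect_equal(s3$mean_pct, 100)
  expect_error(aggregate_pairing(data.frame(target = "x", status = "paired")),
               "replicate")
})

test_that("pairing calls recover the simulated ground truth states", {
  cfg <- sim_config(n_nuclei = 40, field_shape = c(28L, 300L, 300L),
                    voxel_size = c(0.35, 0.22, 0.22),
                    pairing_fraction = 0.5, seed = 42)
  sf <- simulate_field(cfg)
  seg <- segment_nuclei(sf$image$data$dna, cfg$voxel_size)
  expect_equal(nrow(seg$nuclei), 40L)
  ss <- segment_signals(sf$image$data$chr2, seg$labels, cfg$voxel_size,
                        channel_name = "chr2")
  calls <- call_pairing_all(ss$signals, 0.8,
                            nucleus_ids = seg$nuclei$nucleus_id)
  m <- match_truth_nuclei(seg$nuclei, sf$truth$nuclei)
  truth_state <- sf$truth$pairing$state[match(m[calls$nucleus_id],
                                              sf$truth$pairing$nucleus_id)]
  ok <- calls$status == truth_state
  nonamb <- calls$status != "ambiguous"
  expect_gte(mean(ok[nonamb]), 0.95)
})
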
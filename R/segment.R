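# Split a foreground mask into objects: seeded watershed on the Euclidean
# distance transform, seeds at regional maxima of the smoothed transform,
# maxima closer than seed_min_sep_um (within one component) merged into one
# seed.  Components that receive no seed keep their own label.
split_objects <- function(mask, voxel_size, seed_smooth_um, seed_min_sep_um) {
  d <- dim(mask)
  ed <- cpp_edt3d(mask, d, voxel_size)
  eds <- gauss_blur_um(array(ed, d), voxel_size, rep_len(seed_smooth_um, 3L))
  mx <- cpp_maxfilter26(eds, d)
  peaks <- mask & (eds >= mx - 1e-9)
  seeds <- cpp_label3d(peaks, d)

  ns <- max(seeds)
  if (ns > 1L) {
    comp <- cpp_label3d(mask, d)
    sidx <- which(seeds > 0L)
    slab <- seeds[sidx]
    ctr <- t(vapply(split(sidx, slab),
                    function(ix) centroid_um(ix, d, voxel_size),
                    numeric(3)))
    scomp <- vapply(split(comp[sidx], slab), function(v) v[1], 1L)
    parent <- seq_len(ns)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        if (scomp[i] == scomp[j] &&
            sqrt(sum((ctr[i, ] - ctr[j, ])^2)) < seed_min_sep_um) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    remap <- vapply(seq_len(ns), find, 1L)
    seeds[sidx] <- remap[slab]
  }

  lab <- cpp_watershed(ed, seeds, mask, d)
  orphan <- mask & (lab == 0L)
  if (any(orphan)) {
    extra <- cpp_label3d(orphan, d)
    lab[orphan] <- extra[orphan] + max(lab)
  }
  lab
}

#' Segment nuclei from a DNA counterstain channel
#'
#' Foreground is taken by a global automatic threshold (Otsu) after optional
#' Gaussian smoothing in physical units; touching nuclei are split by a
#' seeded watershed on the Euclidean distance transform of the foreground
#' (anisotropy-aware, distances in micrometres), seeded at the regional
#' maxima of the smoothed distance transform. Components smaller than
#' `min_volume_um3` are removed and border-touching nuclei are flagged.
#'
#' @param dna numeric 3D array (z, y, x), nonnegative intensities.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param min_volume_um3 minimum object volume kept (um^3).
#' @param exclude_border if `TRUE` (default), border-touching nuclei are
#'   flagged `included = FALSE` (their volume is truncated by the stack).
#' @param smooth_sigma_um Gaussian smoothing sigma (um) before thresholding.
#' @param threshold optional fixed intensity threshold; default Otsu.
#' @param seed_smooth_um smoothing sigma (um) applied to the distance
#'   transform before taking its regional maxima as watershed seeds.
#' @param seed_min_sep_um regional maxima closer than this (within one
#'   foreground component) are merged into one seed, preventing
#'   oversegmentation from distance-transform plateaus.
#'
#' @return list with `labels` (a [label_volume()], dense labels) and
#'   `nuclei`, a data frame with one row per nucleus: `nucleus_id`, centroid
#'   (um), `volume_um3`, `touches_border`, `included`, `reason`.
#' @export
segment_nuclei <- function(dna, voxel_size, min_volume_um3 = 20,
                           exclude_border = TRUE, smooth_sigma_um = 0.15,
                           threshold = NULL, seed_smooth_um = 0.3,
                           seed_min_sep_um = 2.0) {
  if (length(dim(dna)) != 3L) stop("`dna` must be a 3D array")
  if (min_volume_um3 < 0) stop("`min_volume_um3` must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  d <- dim(dna)
  vv <- voxel_volume_um3(voxel_size)

  sm <- gauss_blur_um(dna, voxel_size, rep_len(smooth_sigma_um, 3L))
  thr <- threshold %||% otsu_threshold(sm)
  mask <- sm > thr
  empty <- list(labels = label_volume(array(0L, d), voxel_size),
                nuclei = data.frame(
                  nucleus_id = integer(0), centroid_z_um = numeric(0),
                  centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                  volume_um3 = numeric(0), touches_border = logical(0),
                  included = logical(0), reason = character(0)))
  if (!any(mask)) return(empty)

  lab <- split_objects(mask, voxel_size, seed_smooth_um, seed_min_sep_um)

  idx_by <- split(which(lab > 0L), lab[lab > 0L])
  vols <- vapply(idx_by, length, 1L) * vv
  keep <- vols >= min_volume_um3
  idx_by <- idx_by[keep]
  if (length(idx_by) == 0L) return(empty)

  out <- array(0L, d)
  rows <- vector("list", length(idx_by))
  for (k in seq_along(idx_by)) {
    ix <- idx_by[[k]]
    out[ix] <- k
    zyx <- arrayInd(ix, d)
    border <- any(zyx == 1L) || any(zyx[, 1] == d[1]) ||
      any(zyx[, 2] == d[2]) || any(zyx[, 3] == d[3])
    ctr <- (colMeans(zyx) - 1) * voxel_size
    included <- !(exclude_border && border)
    rows[[k]] <- data.frame(
      nucleus_id = k, centroid_z_um = ctr[1], centroid_y_um = ctr[2],
      centroid_x_um = ctr[3], volume_um3 = length(ix) * vv,
      touches_border = border, included = included,
      reason = if (included) "" else "touches_border")
  }
  list(labels = label_volume(out, voxel_size), nuclei = do.call(rbind, rows))
}

#' Segment FISH signals within segmented nuclei
#'
#' Thresholds the channel per nucleus (Otsu on within-nucleus intensities, so
#' each nucleus gets its own cutoff), splits touching signals by the same
#' distance-transform watershed used for nuclei, keeps components above
#' `min_volume_um3`, and assigns each component to the nucleus containing its
#' centroid. Channel foreground voxels lying outside every nucleus (by a
#' global Otsu threshold) are discarded and counted in the
#' `discarded_voxels` diagnostic.
#'
#' @param channel numeric 3D array on the same grid as `nuclei`.
#' @param nuclei a [label_volume()] of segmented nuclei (or integer array).
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param min_volume_um3 minimum signal volume kept (um^3).
#' @param channel_name name recorded in the output records.
#' @param nucleus_ids nuclei to process; defaults to all labels present.
#' @param seed_smooth_um,seed_min_sep_um watershed-splitting parameters (see
#'   [segment_nuclei()]); the default merge radius is sized to the signal
#'   scale so one signal is not split while blur-bridged homologs are.
#'
#' @return list with `labels` (signal [label_volume()], labels dense across
#'   the field), `signals` (data frame: `nucleus_id`, `channel`,
#'   `component_id`, centroid (um), `volume_um3`, `mean_intensity`) and
#'   `discarded_voxels` (count of out-of-nucleus foreground voxels).
#' @export
segment_signals <- function(channel, nuclei, voxel_size,
                            min_volume_um3 = 0.05, channel_name = "signal",
                            nucleus_ids = NULL, seed_smooth_um = 0.15,
                            seed_min_sep_um = 1.2) {
  nuc <- if (inherits(nuclei, "label_volume")) nuclei$labels else nuclei
  if (!identical(dim(channel), dim(nuc)))
    stop("`channel` and `nuclei` must share one voxel grid")
  voxel_size <- as.numeric(voxel_size)
  d <- dim(channel)
  vv <- voxel_volume_um3(voxel_size)

  gthr <- otsu_threshold(as.numeric(channel))
  discarded <- sum(channel > gthr & nuc == 0L)

  idx_by <- split(which(nuc > 0L), nuc[nuc > 0L])
  if (!is.null(nucleus_ids))
    idx_by <- idx_by[names(idx_by) %in% as.character(nucleus_ids)]

  out <- array(0L, d)
  rows <- list()
  next_lab <- 0L
  for (nm in names(idx_by)) {
    nid <- as.integer(nm)
    ix <- idx_by[[nm]]
    intens <- channel[ix]
    thr <- otsu_threshold(intens)
    fg <- ix[intens > thr]
    if (length(fg) == 0L) next
    zyx <- arrayInd(fg, d)
    lo <- apply(zyx, 2, min); hi <- apply(zyx, 2, max)
    sd3 <- hi - lo + 1L
    sub <- array(FALSE, sd3)
    sub[cbind(zyx[, 1] - lo[1] + 1L, zyx[, 2] - lo[2] + 1L,
              zyx[, 3] - lo[3] + 1L)] <- TRUE
    # watershed-split touching signals (e.g. homologs bridged by PSF blur)
    sl <- split_objects(sub, voxel_size, seed_smooth_um, seed_min_sep_um)
    sidx <- which(sl > 0L)
    comp_by <- split(sidx, sl[sidx])
    for (ci in comp_by) {
      if (length(ci) * vv < min_volume_um3) next
      czyx <- arrayInd(ci, sd3)
      gz <- czyx[, 1] + lo[1] - 1L
      gy <- czyx[, 2] + lo[2] - 1L
      gx <- czyx[, 3] + lo[3] - 1L
      gidx <- gz + d[1] * (gy - 1L) + d[1] * d[2] * (gx - 1L)
      ctr <- (c(mean(gz), mean(gy), mean(gx)) - 1) * voxel_size
      # assignment by centroid containment
      cv <- pmin(d, pmax(1L, as.integer(round(ctr / voxel_size)) + 1L))
      if (nuc[cv[1], cv[2], cv[3]] != nid) {
        discarded <- discarded + length(gidx)
        next
      }
      next_lab <- next_lab + 1L
      out[gidx] <- next_lab
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus_id = nid, channel = channel_name, component_id = next_lab,
        centroid_z_um = ctr[1], centroid_y_um = ctr[2], centroid_x_um = ctr[3],
        volume_um3 = length(gidx) * vv,
        mean_intensity = mean(channel[gidx]))
    }
  }
  signals <- if (length(rows)) do.call(rbind, rows) else data.frame(
    nucleus_id = integer(0), channel = character(0), component_id = integer(0),
    centroid_z_um = numeric(0), centroid_y_um = numeric(0),
    centroid_x_um = numeric(0), volume_um3 = numeric(0),
    mean_intensity = numeric(0))
  list(labels = label_volume(out, voxel_size), signals = signals,
       discarded_voxels = discarded)
}
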
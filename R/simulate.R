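#' Configuration for the synthetic embryo-field simulator
#'
#' Builds a validated configuration for [simulate_field()]. The simulator
#' emulates a confocal z-stack of a syncytial-blastoderm-like field: a lawn of
#' non-overlapping, roughly ellipsoidal nuclei (DNA counterstain channel),
#' per-nucleus FISH territory signals occupying a set fraction of nuclear
#' volume, homolog pairs placed either paired (merged, or two signals within
#' the pairing distance) or unpaired (well beyond it), optional bright
#' nuclear-body-like foci in an intensity channel, and finally Gaussian PSF
#' blur plus Poisson/Gaussian camera noise.
#'
#' @param field_shape integer length-3, voxels per axis (z, y, x).
#' @param voxel_size micrometres per voxel (z, y, x); anisotropic by default
#'   as in a confocal stack.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um mean nucleus radius; per-axis semi-axes are
#'   jittered by up to `radius_jitter` (fraction).
#' @param radius_jitter relative semi-axis jitter in `[0, 1)`.
#' @param channels character vector of territory (FISH) channel names.
#' @param territory_volume_fraction per-channel fraction of nuclear volume
#'   occupied by the territory signal (recycled); a merged paired signal gets
#'   the full fraction, each of two homolog signals half of it.
#' @param territory_irregularity dimensionless `>= 0`; 0 renders exact
#'   discretized ellipsoids, larger values add smooth radial boundary bumps.
#' @param pairing_fraction per-channel probability that a nucleus's homolog
#'   pair is placed paired (recycled).
#' @param paired_mode_merged_prob probability that a paired pair is rendered
#'   as one merged signal rather than two signals within the threshold.
#' @param pairing_distance_um pairing placement threshold (micrometres).
#' @param include_foci add an intensity channel with small bright foci
#'   (histone-locus-body-like) plus uniform nucleoplasmic signal.
#' @param n_foci foci per nucleus.
#' @param focus_radius_um focus radius.
#' @param focus_intensity,focus_background_intensity intensities of foci and
#'   of the nucleoplasm in the focus channel (arbitrary units).
#' @param focus_channel name of the focus/intensity channel.
#' @param dna_intensity,territory_intensity,territory_background_intensity,background_intensity
#'   ideal-image intensity levels (arbitrary units).
#' @param psf_sigma_um Gaussian PSF sigma per axis (z, y, x), micrometres.
#' @param photon_scale photons per intensity unit for the Poisson draw; 0
#'   disables shot noise. At the default intensities `photon_scale = 1`
#'   yields SNR about 10 on the DNA channel.
#' @param read_noise_sd additive Gaussian read-noise sd; 0 disables.
#' @param border_margin_um minimum distance from nucleus centre to the field
#'   border; the default (one maximal jittered radius plus 0.3 um of blur
#'   allowance) keeps nuclei clear of the border; set smaller to exercise
#'   border-exclusion logic downstream.
#' @param seed default RNG seed used by [simulate_field()].
#' @param max_place_attempts rejection-sampling attempts per nucleus before a
#'   "field too crowded" error.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(field_shape = c(48L, 320L, 320L),
                       voxel_size = c(0.3, 0.1, 0.1),
                       n_nuclei = 15L,
                       nucleus_radius_um = 2.5,
                       radius_jitter = 0.1,
                       channels = "chr2",
                       territory_volume_fraction = 0.06,
                       territory_irregularity = 0.5,
                       pairing_fraction = 0.5,
                       paired_mode_merged_prob = 0.5,
                       pairing_distance_um = 0.8,
                       include_foci = FALSE,
                       n_foci = 2L,
                       focus_radius_um = 0.5,
                       focus_intensity = 200,
                       focus_background_intensity = 50,
                       focus_channel = "polII",
                       dna_intensity = 100,
                       territory_intensity = 150,
                       territory_background_intensity = 10,
                       background_intensity = 2,
                       psf_sigma_um = c(0.3, 0.12, 0.12),
                       photon_scale = 1,
                       read_noise_sd = 2,
                       border_margin_um = NULL,
                       seed = 1L,
                       max_place_attempts = 200L) {
  field_shape <- as.integer(field_shape)
  if (length(field_shape) != 3L || any(field_shape < 4L))
    stop("`field_shape` must be 3 integers >= 4 (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be strictly positive (z, y, x)")
  if (n_nuclei < 1L) stop("`n_nuclei` must be >= 1")
  if (nucleus_radius_um <= 0) stop("`nucleus_radius_um` must be positive")
  if (radius_jitter < 0 || radius_jitter >= 1)
    stop("`radius_jitter` must be in [0, 1)")
  nch <- length(channels)
  if (nch < 1L || anyDuplicated(channels)) stop("territory channels must be unique")
  territory_volume_fraction <- rep_len(territory_volume_fraction, nch)
  pairing_fraction <- rep_len(pairing_fraction, nch)
  chk_frac <- function(x, nm, open0 = FALSE, open1 = FALSE) {
    lo_ok <- if (open0) x > 0 else x >= 0
    hi_ok <- if (open1) x < 1 else x <= 1
    if (any(!is.finite(x)) || any(!lo_ok) || any(!hi_ok))
      stop(sprintf("`%s` out of range", nm))
  }
  chk_frac(territory_volume_fraction, "territory_volume_fraction",
           open0 = TRUE, open1 = TRUE)
  chk_frac(pairing_fraction, "pairing_fraction")
  chk_frac(paired_mode_merged_prob, "paired_mode_merged_prob")
  if (territory_irregularity < 0) stop("`territory_irregularity` must be >= 0")
  if (pairing_distance_um <= 0) stop("`pairing_distance_um` must be positive")
  if (photon_scale < 0 || read_noise_sd < 0)
    stop("noise parameters must be nonnegative")
  if (any(psf_sigma_um < 0)) stop("`psf_sigma_um` must be nonnegative")
  structure(list(
    field_shape = field_shape, voxel_size = voxel_size,
    n_nuclei = as.integer(n_nuclei),
    nucleus_radius_um = nucleus_radius_um, radius_jitter = radius_jitter,
    channels = as.character(channels),
    territory_volume_fraction = territory_volume_fraction,
    territory_irregularity = territory_irregularity,
    pairing_fraction = pairing_fraction,
    paired_mode_merged_prob = paired_mode_merged_prob,
    pairing_distance_um = pairing_distance_um,
    include_foci = isTRUE(include_foci), n_foci = as.integer(n_foci),
    focus_radius_um = focus_radius_um, focus_intensity = focus_intensity,
    focus_background_intensity = focus_background_intensity,
    focus_channel = focus_channel,
    dna_intensity = dna_intensity, territory_intensity = territory_intensity,
    territory_background_intensity = territory_background_intensity,
    background_intensity = background_intensity,
    psf_sigma_um = rep_len(as.numeric(psf_sigma_um), 3L),
    photon_scale = photon_scale, read_noise_sd = read_noise_sd,
    border_margin_um = border_margin_um %||%
      (nucleus_radius_um * (1 + radius_jitter) + 0.3),
    seed = as.integer(seed),
    max_place_attempts = as.integer(max_place_attempts)
  ), class = "sim_config")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# flat voxel indices of a (possibly irregular) blob; exact discretized
# ellipsoid at irregularity 0, smooth radial bump modulation otherwise.
# Draws bump randomness from the current RNG stream.
blob_indices <- function(center_um, semi_axes_um, irregularity,
                         dim, voxel_size, strict = FALSE) {
  if (any(semi_axes_um <= 0)) stop("semi-axes must be positive")
  pad <- 1 + 0.5 * irregularity
  extent_um <- (dim - 1) * voxel_size
  if (strict &&
      (any(center_um - semi_axes_um * pad < 0) ||
       any(center_um + semi_axes_um * pad > extent_um)))
    stop("blob exceeds grid")
  lo <- pmax(1L, as.integer(floor((center_um - semi_axes_um * pad) / voxel_size)) + 1L)
  hi <- pmin(dim, as.integer(ceiling((center_um + semi_axes_um * pad) / voxel_size)) + 1L)
  if (any(lo > hi)) return(integer(0))
  uz <- ((lo[1]:hi[1]) - 1) * voxel_size[1] - center_um[1]
  uy <- ((lo[2]:hi[2]) - 1) * voxel_size[2] - center_um[2]
  ux <- ((lo[3]:hi[3]) - 1) * voxel_size[3] - center_um[3]
  uz <- uz / semi_axes_um[1]; uy <- uy / semi_axes_um[2]; ux <- ux / semi_axes_um[3]
  r2 <- outer(outer(uz^2, uy^2, `+`), ux^2, `+`)
  if (irregularity <= 0) {
    sel <- r2 <= 1
  } else {
    # smooth random radial modulation: star-shaped, hence connected
    nb <- 8L
    dirs <- matrix(stats::rnorm(3L * nb), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    cf <- stats::rnorm(nb)
    r <- sqrt(r2)
    nzr <- r > 0
    az <- array(rep(uz, times = length(uy) * length(ux)), dim(r2))
    ay <- aperm(array(rep(uy, times = length(uz) * length(ux)),
                      c(length(uy), length(uz), length(ux))), c(2, 1, 3))
    ax <- aperm(array(rep(ux, times = length(uz) * length(uy)),
                      c(length(ux), length(uz), length(uy))), c(2, 3, 1))
    g <- array(0, dim(r2))
    kappa <- 5
    for (j in seq_len(nb)) {
      dot <- array(0, dim(r2))
      dot[nzr] <- (az[nzr] * dirs[j, 1] + ay[nzr] * dirs[j, 2] +
                     ax[nzr] * dirs[j, 3]) / r[nzr]
      g <- g + cf[j] * exp(kappa * (dot - 1))
    }
    gs <- g
    m <- mean(g[nzr]); s <- stats::sd(g[nzr])
    if (is.finite(s) && s > 0) gs <- (g - m) / s else gs[] <- 0
    gs[!nzr] <- 0
    amp <- 0.12 * irregularity
    sel <- r <= 1 + amp * gs
  }
  loc <- which(sel, arr.ind = TRUE)
  if (nrow(loc) == 0L) return(integer(0))
  z <- loc[, 1] + lo[1] - 1L
  y <- loc[, 2] + lo[2] - 1L
  x <- loc[, 3] + lo[3] - 1L
  as.integer(z + dim[1] * (y - 1L) + dim[1] * dim[2] * (x - 1L))
}

#' Render a single (possibly irregular) blob as a voxel mask
#'
#' At `irregularity = 0` the mask is exactly the set of voxel centres inside
#' the ellipsoid. Larger irregularity perturbs the boundary with a smooth
#' random radial modulation (star-shaped, so the mask stays connected), with
#' approximate volume preservation.
#'
#' @param center_um,semi_axes_um blob centre and semi-axes (z, y, x) in um.
#' @param irregularity dimensionless `>= 0`.
#' @param dim field dimensions (z, y, x) in voxels.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @param seed optional RNG seed for the boundary modulation.
#' @return logical 3D array of dimension `dim`.
#' @export
render_blob <- function(center_um, semi_axes_um, irregularity = 0,
                        dim, voxel_size, seed = NULL) {
  run <- function() blob_indices(center_um, semi_axes_um, irregularity,
                                 dim, voxel_size, strict = TRUE)
  idx <- if (is.null(seed)) run() else with_seed(seed, run())
  mask <- array(FALSE, dim)
  mask[idx] <- TRUE
  mask
}

#' Apply idealized optics and camera noise to an image field
#'
#' Blurs each channel with an anisotropic Gaussian PSF specified in physical
#' units, then draws per-voxel Poisson shot noise at `photon_scale` photons
#' per intensity unit (the intensity scale is preserved: the expected output
#' equals the blurred input), then adds Gaussian read noise, clipping at 0.
#' All-zero noise parameters return the input unchanged.
#'
#' @param field an [image_field()].
#' @param psf_sigma_um Gaussian sigma per axis (z, y, x), micrometres.
#' @param photon_scale photons per intensity unit (0 = no shot noise).
#' @param read_noise_sd additive Gaussian sd (0 = none).
#' @param seed optional RNG seed; if `NULL` the current RNG stream is used.
#' @return an [image_field()] with the same channels.
#' @export
apply_optics <- function(field, psf_sigma_um = c(0.3, 0.12, 0.12),
                         photon_scale = 1, read_noise_sd = 2, seed = NULL) {
  stopifnot(inherits(field, "image_field"))
  psf_sigma_um <- rep_len(as.numeric(psf_sigma_um), 3L)
  if (any(psf_sigma_um < 0) || photon_scale < 0 || read_noise_sd < 0)
    stop("optics parameters must be nonnegative")
  run <- function() {
    out <- lapply(field$data, function(ch) {
      v <- gauss_blur_um(ch, field$voxel_size, psf_sigma_um)
      if (photon_scale > 0)
        v <- array(stats::rpois(length(v), as.numeric(v) * photon_scale) /
                     photon_scale, dim(v))
      if (read_noise_sd > 0)
        v <- v + array(stats::rnorm(length(v), 0, read_noise_sd), dim(v))
      v[v < 0] <- 0
      v
    })
    image_field(out, field$voxel_size, field$channels)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Bernoulli pairing-state draws for one channel (TRUE = paired)
draw_pairing_states <- function(n, fraction) stats::runif(n) < fraction

# rejection-sample non-overlapping nucleus centres and semi-axes
place_nuclei <- function(cfg) {
  extent_um <- (cfg$field_shape - 1) * cfg$voxel_size
  margin <- cfg$border_margin_um
  lo <- rep(margin, 3L)
  hi <- extent_um - margin
  if (any(hi < lo))
    stop("field too crowded: border margin exceeds the field extent")
  centers <- matrix(NA_real_, cfg$n_nuclei, 3L)
  axes <- matrix(NA_real_, cfg$n_nuclei, 3L)
  maxax <- numeric(cfg$n_nuclei)
  for (i in seq_len(cfg$n_nuclei)) {
    placed <- FALSE
    for (a in seq_len(cfg$max_place_attempts)) {
      ctr <- lo + stats::runif(3L) * (hi - lo)
      ax <- cfg$nucleus_radius_um *
        (1 + stats::runif(3L, -cfg$radius_jitter, cfg$radius_jitter))
      if (i > 1L) {
        dd <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - ctr)^2))
        if (any(dd <= 1.02 * (maxax[seq_len(i - 1L)] + max(ax)))) next
      }
      centers[i, ] <- ctr
      axes[i, ] <- ax
      maxax[i] <- max(ax)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("field too crowded: failed to place nucleus %d after %d attempts",
                   i, cfg$max_place_attempts))
  }
  list(centers = centers, axes = axes)
}

# place one homolog pair in a nucleus; returns list of per-signal
# (center, scale) plus the placed inter-centroid distance (NA if merged)
place_pair <- function(center, axes, frac, paired, merged_prob, thr) {
  if (paired && stats::runif(1) < merged_prob) {
    s <- frac^(1 / 3)
    room <- 0.93 - s
    if (room < 0) stop("territory_volume_fraction too large for merged signal")
    w <- stats::rnorm(3L); w <- w / sqrt(sum(w^2))
    ne <- sqrt(sum((w / axes)^2))
    t_off <- stats::runif(1, 0, room / ne)
    return(list(centers = list(center + t_off * w), scale = s,
                distance = NA_real_, n_signals = 1L))
  }
  s <- (frac / 2)^(1 / 3)
  for (try in 1:20) {
    w <- stats::rnorm(3L); w <- w / sqrt(sum(w^2))
    ne <- sqrt(sum((w / axes)^2))
    d_max <- 2 * (0.93 - s) / ne
    if (paired) {
      if (d_max <= 0) next
      d <- stats::runif(1, 0, min(thr, d_max))
    } else {
      # beyond 1.5x the threshold AND with clear surface separation, so the
      # two blobs stay resolvable as distinct signals after PSF blur
      d_lo <- max(1.5 * thr, 2 * s * max(axes) + 0.5)
      d_hi <- min(3 * thr, d_max)
      if (d_hi <= d_lo) next
      d <- stats::runif(1, d_lo, d_hi)
    }
    return(list(centers = list(center + (d / 2) * w, center - (d / 2) * w),
                scale = s, distance = d, n_signals = 2L))
  }
  stop("cannot place homolog signals: nucleus too small for the requested ",
       "territory fraction and separation; reduce territory_volume_fraction ",
       "or enlarge nuclei")
}

#' Simulate a synthetic multichannel embryo field with ground truth
#'
#' Renders the ideal (noiseless) field described by `config`, records exact
#' per-object ground truth, and applies optics/noise. Identical `config` and
#' `seed` give bit-identical results.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return object of class `sim_field`: list with elements
#'   \describe{
#'     \item{image}{noisy [image_field()] (DNA + territory channels, plus the
#'       focus channel when enabled).}
#'     \item{ideal}{the noiseless [image_field()].}
#'     \item{nucleus_labels}{[label_volume()] of true nucleus masks.}
#'     \item{signal_labels}{named list of [label_volume()]s, one per
#'       territory channel, labelling every placed signal.}
#'     \item{truth}{list of data frames: `nuclei` (id, centre, semi-axes,
#'       analytic and voxel volume), `signals` (nucleus, channel, homolog,
#'       voxel volume, centroid), `pairing` (nucleus, channel, state, placed
#'       distance, number of true signals), and `foci` when enabled.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_field <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_field_impl(config))
}

simulate_field_impl <- function(cfg) {
  d <- cfg$field_shape
  vv <- voxel_volume_um3(cfg$voxel_size)
  pl <- place_nuclei(cfg)
  n <- cfg$n_nuclei

  nuc_lab <- array(0L, d)
  nuc_idx <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- blob_indices(pl$centers[i, ], pl$axes[i, ], 0, d, cfg$voxel_size)
    nuc_lab[idx] <- i
    nuc_idx[[i]] <- idx
  }
  nuclei_df <- data.frame(
    nucleus_id = seq_len(n),
    center_z_um = pl$centers[, 1], center_y_um = pl$centers[, 2],
    center_x_um = pl$centers[, 3],
    semi_z_um = pl$axes[, 1], semi_y_um = pl$axes[, 2], semi_x_um = pl$axes[, 3],
    analytic_volume_um3 = 4 / 3 * pi * apply(pl$axes, 1, prod),
    voxel_volume_um3 = vapply(nuc_idx, length, 1L) * vv
  )

  sig_labs <- list()
  signals <- list()
  pairing <- list()
  for (ci in seq_along(cfg$channels)) {
    ch <- cfg$channels[ci]
    lab <- array(0L, d)
    states <- draw_pairing_states(n, cfg$pairing_fraction[ci])
    next_lab <- 0L
    for (i in seq_len(n)) {
      pp <- place_pair(pl$centers[i, ], pl$axes[i, ],
                       cfg$territory_volume_fraction[ci], states[i],
                       cfg$paired_mode_merged_prob, cfg$pairing_distance_um)
      for (h in seq_along(pp$centers)) {
        idx <- blob_indices(pp$centers[[h]], pp$scale * pl$axes[i, ],
                            cfg$territory_irregularity, d, cfg$voxel_size)
        idx <- idx[nuc_lab[idx] == i]  # clip to the host nucleus
        if (length(idx) == 0L)
          stop("internal: signal rendered empty after clipping")
        next_lab <- next_lab + 1L
        lab[idx] <- next_lab
        ctr <- centroid_um(idx, d, cfg$voxel_size)
        signals[[length(signals) + 1L]] <- data.frame(
          nucleus_id = i, channel = ch, homolog = h, label = next_lab,
          volume_um3 = length(idx) * vv,
          centroid_z_um = ctr[1], centroid_y_um = ctr[2], centroid_x_um = ctr[3])
      }
      pairing[[length(pairing) + 1L]] <- data.frame(
        nucleus_id = i, channel = ch,
        state = if (states[i]) "paired" else "unpaired",
        placed_distance_um = pp$distance, n_true_signals = pp$n_signals)
    }
    sig_labs[[ch]] <- label_volume(lab, cfg$voxel_size)
  }

  foci_df <- NULL
  foci_idx <- list()
  if (cfg$include_foci) {
    rows <- list()
    for (i in seq_len(n)) {
      for (k in seq_len(cfg$n_foci)) {
        for (try in 1:50) {
          w <- stats::rnorm(3L); w <- w / sqrt(sum(w^2))
          ne <- sqrt(sum((w / pl$axes[i, ])^2))
          t_off <- stats::runif(1, 0, 0.7 / ne)
          ctr <- pl$centers[i, ] + t_off * w
          ok <- TRUE
          for (r in rows) {
            if (r$nucleus_id == i &&
                sqrt(sum((c(r$center_z_um, r$center_y_um, r$center_x_um) - ctr)^2)) <
                  4.5 * cfg$focus_radius_um) { ok <- FALSE; break }
          }
          if (ok) break
        }
        idx <- blob_indices(ctr, rep(cfg$focus_radius_um, 3L), 0, d, cfg$voxel_size)
        idx <- idx[nuc_lab[idx] == i]
        foci_idx[[length(foci_idx) + 1L]] <- idx
        rows[[length(rows) + 1L]] <- data.frame(
          nucleus_id = i, focus = k,
          center_z_um = ctr[1], center_y_um = ctr[2], center_x_um = ctr[3],
          radius_um = cfg$focus_radius_um, volume_um3 = length(idx) * vv)
      }
    }
    foci_df <- do.call(rbind, rows)
  }

  # ideal intensities
  ideal <- list()
  dna <- array(cfg$background_intensity, d)
  dna[nuc_lab > 0L] <- cfg$dna_intensity
  ideal[["dna"]] <- dna
  for (ch in cfg$channels) {
    v <- array(cfg$background_intensity, d)
    v[nuc_lab > 0L] <- cfg$territory_background_intensity
    v[sig_labs[[ch]]$labels > 0L] <- cfg$territory_intensity
    ideal[[ch]] <- v
  }
  if (cfg$include_foci) {
    v <- array(cfg$background_intensity, d)
    v[nuc_lab > 0L] <- cfg$focus_background_intensity
    for (idx in foci_idx) v[idx] <- cfg$focus_intensity
    ideal[[cfg$focus_channel]] <- v
  }
  ideal_field <- image_field(ideal, cfg$voxel_size)
  noisy <- apply_optics(ideal_field, cfg$psf_sigma_um, cfg$photon_scale,
                        cfg$read_noise_sd)

  structure(list(
    image = noisy, ideal = ideal_field,
    nucleus_labels = label_volume(nuc_lab, cfg$voxel_size),
    signal_labels = sig_labs,
    truth = list(nuclei = nuclei_df,
                 signals = do.call(rbind, signals),
                 pairing = do.call(rbind, pairing),
                 foci = foci_df),
    config = cfg
  ), class = "sim_field")
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("<sim_field> %d nuclei, territory channel(s): %s\n",
              x$config$n_nuclei, paste(x$config$channels, collapse = ", ")))
  print(x$image)
  invisible(x)
}
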
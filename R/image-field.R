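#' Multichannel 3D image field
#'
#' Container for a multichannel 3D fluorescence stack with physical voxel
#' spacing. Arrays are indexed `[z, y, x]` and all physical quantities are in
#' micrometres; voxel centres sit at `(index - 1) * voxel_size` per axis.
#'
#' @param data named list of numeric 3D arrays (one per channel), all with
#'   identical dimensions, nonnegative intensities.
#' @param voxel_size numeric length-3, micrometres per voxel along (z, y, x).
#' @param channel_names optional character vector; defaults to `names(data)`.
#'
#' @return an object of class `image_field` with elements `data`,
#'   `voxel_size` and `channels`.
#' @export
image_field <- function(data, voxel_size, channel_names = names(data)) {
  if (!is.list(data) || length(data) < 1L)
    stop("`data` must be a non-empty list of 3D arrays")
  if (is.null(channel_names) || anyDuplicated(channel_names) ||
      any(!nzchar(channel_names)))
    stop("channels must carry unique non-empty names")
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array")
  if (length(unique(dims)) != 1L)
    stop("all channels must share one voxel grid")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (z, y, x)")
  names(data) <- channel_names
  structure(list(data = data, voxel_size = voxel_size,
                 channels = channel_names),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<image_field> %d channel(s) [%s], grid %d x %d x %d (z,y,x), voxel %s um\n",
              length(x$data), paste(x$channels, collapse = ", "),
              d[1], d[2], d[3],
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Labelled 3D segmentation volume
#'
#' Integer labels on the same grid as an [image_field()]; 0 is background and
#' labels are dense from 1. Each nonzero label is one 26-connected component.
#'
#' @param labels integer 3D array.
#' @param voxel_size micrometres per voxel along (z, y, x).
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (min(labels) < 0L) stop("labels must be nonnegative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive values (z, y, x)")
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d object(s), grid %s (z,y,x)\n",
              max(x$labels), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

# volume of one voxel in um^3
voxel_volume_um3 <- function(voxel_size) prod(voxel_size)

# physical centroid (um) of a set of flat voxel indices within dim d
centroid_um <- function(idx, d, voxel_size) {
  zyx <- arrayInd(idx, d)
  (colMeans(zyx) - 1) * voxel_size
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a fixed-bin histogram. Returns a
#' threshold value such that `x > threshold` is foreground; for a constant
#' input the threshold equals `max(x)` so the foreground is empty.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(Inf)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(hi)
  h <- tabulate(pmin(n_bins, 1L + as.integer((x - lo) / (hi - lo) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  lo + k * (hi - lo) / n_bins
}

# Gaussian blur of a 3D array, sigma given in physical um per axis (z, y, x)
gauss_blur_um <- function(vol, voxel_size, sigma_um) {
  sigma_um <- rep_len(as.numeric(sigma_um), 3L)
  if (all(sigma_um <= 0)) return(vol)
  out <- cpp_gauss3d(as.numeric(vol), dim(vol), sigma_um / voxel_size)
  array(out, dim(vol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
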
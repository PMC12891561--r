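#' Write a label volume as a multi-page 16-bit TIFF
#'
#' One page per z-slice; labels up to 65535 round-trip voxel-identically via
#' [read_labels_tiff()].
#'
#' @param labels a [label_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  l <- labels$labels
  if (max(l) > 65535L) stop("more than 65535 labels cannot be stored as 16-bit")
  pages <- lapply(seq_len(dim(l)[1]), function(z) l[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label volume written by [write_labels_tiff()]
#'
#' @param path TIFF file path.
#' @param voxel_size micrometres per voxel (z, y, x).
#' @return a [label_volume()].
#' @export
read_labels_tiff <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  l <- array(0L, d)
  for (z in seq_along(pages))
    l[z, , ] <- as.integer(round(pages[[z]] * 65535))
  label_volume(l, voxel_size)
}

#' Write an image field as per-channel multi-page TIFFs plus metadata
#'
#' Each channel goes to `<prefix>_<channel>.tif` (32-bit float pages scaled
#' to `[0, 1]`); voxel size, channel names and intensity scales go to
#' `<prefix>_meta.yaml` so [read_field_tiff()] can restore the field.
#'
#' @param field an [image_field()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the metadata file path, invisibly.
#' @export
write_field_tiff <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "image_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- list()
  for (ch in field$channels) {
    v <- field$data[[ch]]
    sc <- max(v, 1e-12)
    scales[[ch]] <- sc
    pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / sc)
    tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                    bits.per.sample = 32L, compression = "none")
  }
  meta <- list(voxel_size_um = as.numeric(field$voxel_size),
               channels = as.list(field$channels),
               intensity_scale = scales)
  mpath <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  yaml::write_yaml(meta, mpath)
  invisible(mpath)
}

#' Read an image field written by [write_field_tiff()]
#'
#' @param dir directory holding the TIFFs and metadata.
#' @param prefix file-name prefix used when writing.
#' @param voxel_size optional override of the metadata voxel size (z, y, x);
#'   an explicit value always wins over metadata, and an error is raised if
#'   neither is available.
#' @return an [image_field()].
#' @export
read_field_tiff <- function(dir, prefix = "field", voxel_size = NULL) {
  mpath <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  if (!file.exists(mpath)) stop("metadata file not found: ", mpath)
  meta <- yaml::read_yaml(mpath)
  vs <- voxel_size %||% meta$voxel_size_um
  if (is.null(vs)) stop("voxel size available neither as argument nor metadata")
  data <- list()
  for (ch in unlist(meta$channels)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                            all = TRUE)
    d <- c(length(pages), dim(pages[[1]]))
    v <- array(0, d)
    for (z in seq_along(pages)) v[z, , ] <- pages[[z]]
    sc <- meta$intensity_scale[[ch]] %||% 1
    data[[ch]] <- v * sc
  }
  image_field(data, vs)
}
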
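#' Run the full quantification pipeline
#'
#' Executes simulate-or-read, nucleus segmentation, per-channel signal
#' segmentation, morphometrics, pairing calls and replicate aggregation, and
#' the per-channel group statistics, writing per-stage CSVs, label TIFFs, a
#' JSON manifest and a log to `out_dir`. Identical configuration and seed
#' give identical output tables.
#'
#' @param config pipeline configuration: a named list, or the path of a YAML
#'   file holding one. Recognized sections (all optional except the channel
#'   roles):
#'   \describe{
#'     \item{simulation}{arguments for [sim_config()]; one simulated field
#'       per replicate. Mutually exclusive with `input`.}
#'     \item{input}{`dir`, `prefix`, optional `voxel_size` (z, y, x) for a
#'       field written by [write_field_tiff()]; the explicit voxel size
#'       overrides metadata.}
#'     \item{channels}{`dna` (exactly one), `territories` (>= 1),
#'       optional `intensity` focus channel.}
#'     \item{segmentation}{`min_nucleus_volume_um3`, `min_signal_volume_um3`,
#'       `exclude_border`, `smooth_sigma_um`.}
#'     \item{pairing}{`threshold_um`, `min_nuclei`, `min_replicates`.}
#'     \item{foci}{`k_foci`, `focus_min_volume_um3`.}
#'     \item{replicates}{number of simulated replicates (default 1).}
#'     \item{write_labels}{write label TIFFs (default TRUE).}
#'   }
#' @param out_dir output directory.
#' @param seed integer seed; replicate `r` uses `seed + r - 1`.
#' @return the run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  seed <- as.integer(seed %||% config$seed %||% 1L)

  # --- validation before any computation ---
  ch <- config$channels
  simulate_mode <- !is.null(config$simulation)
  if (simulate_mode && !is.null(config$input))
    stop("config must specify either `simulation` or `input`, not both")
  if (!simulate_mode && is.null(config$input))
    stop("config must specify `simulation` or `input`")
  if (simulate_mode && is.null(ch)) {
    simcfg0 <- do.call(sim_config, config$simulation %||% list())
    ch <- list(dna = "dna", territories = simcfg0$channels,
               intensity = if (simcfg0$include_foci) simcfg0$focus_channel)
  }
  if (is.null(ch$dna) || length(ch$dna) != 1L || !nzchar(ch$dna))
    stop("channel roles must name exactly one dna channel")
  if (is.null(ch$territories) || length(ch$territories) < 1L)
    stop("channel roles must name at least one territory channel")
  segp <- config$segmentation %||% list()
  pairp <- config$pairing %||% list()
  focp <- config$foci %||% list()
  n_rep <- as.integer(config$replicates %||% 1L)
  if (!simulate_mode && n_rep != 1L)
    stop("replicates > 1 requires simulation mode")
  write_labels <- config$write_labels %||% TRUE

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(sprintf("stage: %s", name), conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  simcfg <- NULL
  if (simulate_mode)
    simcfg <- stage("configure", do.call(sim_config, config$simulation %||% list()))

  nuclei_tab <- list(); signal_tab <- list(); call_tab <- list()
  overlap_tab <- list(); foci_tab <- list()
  counts <- list()

  for (r in seq_len(n_rep)) {
    rep_seed <- seed + r - 1L
    if (simulate_mode) {
      say("replicate %d: simulating field (seed %d)", r, rep_seed)
      sim <- stage("simulate", simulate_field(simcfg, seed = rep_seed))
      field <- sim$image
    } else {
      say("reading field from %s", config$input$dir)
      field <- stage("read", read_field_tiff(
        config$input$dir, config$input$prefix %||% "field",
        voxel_size = config$input$voxel_size))
    }
    if (!all(c(ch$dna, ch$territories) %in% field$channels))
      stage("validate", stop("channel roles do not resolve to existing channels: have ",
                             paste(field$channels, collapse = ", ")))
    vs <- field$voxel_size

    say("replicate %d: segmenting nuclei", r)
    seg <- stage("segment_nuclei", segment_nuclei(
      field$data[[ch$dna]], vs,
      min_volume_um3 = segp$min_nucleus_volume_um3 %||% 20,
      exclude_border = segp$exclude_border %||% TRUE,
      smooth_sigma_um = segp$smooth_sigma_um %||% 0.15))
    nuc <- seg$nuclei
    nuc$replicate <- r
    nuclei_tab[[r]] <- nuc
    included <- nuc$nucleus_id[nuc$included]
    if (write_labels)
      write_labels_tiff(seg$labels,
                        file.path(out_dir, sprintf("nuclei_labels_rep%d.tif", r)))

    rep_signals <- list()
    sig_labs <- list()
    for (tch in ch$territories) {
      say("replicate %d: segmenting signals in channel %s", r, tch)
      ss <- stage("segment_signals", segment_signals(
        field$data[[tch]], seg$labels, vs,
        min_volume_um3 = segp$min_signal_volume_um3 %||% 0.05,
        channel_name = tch, nucleus_ids = included))
      sig_labs[[tch]] <- ss$labels
      if (nrow(ss$signals)) {
        say("replicate %d: measuring %d signal(s) in %s", r,
            nrow(ss$signals), tch)
        met <- stage("measure", measure_labels(ss$labels, vs,
                                               intensity = field$data[[tch]]))
        sg <- merge(ss$signals, met[, c("label", "surface_area_um2",
                                        "sphericity")],
                    by.x = "component_id", by.y = "label")
        sg <- merge(sg, nuc[, c("nucleus_id", "volume_um3")],
                    by = "nucleus_id", suffixes = c("", "_nucleus"))
        sg$normalized_volume <- normalized_volume(sg$volume_um3,
                                                  sg$volume_um3_nucleus)
        sg$replicate <- r
        rep_signals[[tch]] <- sg
      }
      if (write_labels)
        write_labels_tiff(ss$labels,
                          file.path(out_dir,
                                    sprintf("%s_labels_rep%d.tif", tch, r)))
    }
    rep_signals <- do.call(rbind, unname(rep_signals))
    signal_tab[[r]] <- rep_signals

    say("replicate %d: calling pairing", r)
    calls <- stage("pairing", call_pairing_all(
      rep_signals %||% data.frame(nucleus_id = integer(0),
                                  channel = character(0),
                                  centroid_z_um = numeric(0),
                                  centroid_y_um = numeric(0),
                                  centroid_x_um = numeric(0)),
      threshold_um = pairp$threshold_um %||% 0.8,
      nucleus_ids = included, targets = ch$territories))
    calls$replicate <- r
    call_tab[[r]] <- calls

    if (length(ch$territories) >= 2L) {
      say("replicate %d: territory overlap", r)
      prs <- utils::combn(ch$territories, 2L)
      for (k in seq_len(ncol(prs))) {
        for (nid in included) {
          ov <- overlap_percent(sig_labs[[prs[1, k]]], sig_labs[[prs[2, k]]],
                                seg$labels, nid)
          ov$channel_a <- prs[1, k]; ov$channel_b <- prs[2, k]
          ov$replicate <- r
          overlap_tab[[length(overlap_tab) + 1L]] <- ov
        }
      }
    }

    if (!is.null(ch$intensity) && ch$intensity %in% field$channels) {
      say("replicate %d: focus intensity in channel %s", r, ch$intensity)
      for (nid in included) {
        nm <- seg$labels$labels == nid
        fx <- stage("foci", intensity_excluding_foci(
          field$data[[ch$intensity]], nm, vs,
          k_foci = focp$k_foci %||% 2L,
          focus_min_volume_um3 = focp$focus_min_volume_um3 %||% 0.02))
        fr <- data.frame(replicate = r, nucleus_id = nid,
                         mean_outside_foci = fx$mean_outside_foci,
                         n_foci_found = fx$n_found,
                         focus_volume_um3 = if (fx$n_found)
                           vapply(fx$foci, function(f) f$volume_um3, 1.0)[1]
                         else NA_real_)
        foci_tab[[length(foci_tab) + 1L]] <- fr
      }
    }

    counts[[r]] <- list(
      replicate = r, seed = rep_seed,
      nuclei_detected = nrow(nuc), nuclei_included = length(included),
      signals = if (is.null(rep_signals)) 0L else nrow(rep_signals),
      pairing_calls = nrow(calls),
      pairing_nonambiguous = sum(calls$status != "ambiguous"))
  }

  nuclei <- do.call(rbind, nuclei_tab)
  signals <- do.call(rbind, signal_tab)
  calls <- do.call(rbind, call_tab)
  say("aggregating pairing across %d replicate(s)", n_rep)
  summary_tab <- stage("aggregate", aggregate_pairing(
    calls, min_nuclei = pairp$min_nuclei %||% 300L,
    min_replicates = pairp$min_replicates %||% 3L))

  # per-channel paired vs combined-unpaired normalized volume comparisons
  stats_rows <- list(); bimod_rows <- list()
  if (!is.null(signals)) {
    for (tch in ch$territories) {
      grp <- pairing_volume_groups(signals[signals$channel == tch, ],
                                   calls[calls$target == tch, ])
      if (length(grp$paired) >= 2L && length(grp$unpaired) >= 2L) {
        mw <- mann_whitney_u(grp$paired, grp$unpaired)
        lv <- levene_test(grp$paired, grp$unpaired)
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          channel = tch, comparison = "paired_vs_combined_unpaired",
          test = c("Mann-Whitney U", "Levene"),
          statistic = c(mw$statistic, lv$statistic),
          p_value = c(mw$p_value, lv$p_value),
          n_paired = length(grp$paired), n_unpaired = length(grp$unpaired))
      }
      bm <- detect_bimodality(grp$paired)
      bimod_rows[[length(bimod_rows) + 1L]] <- data.frame(
        channel = tch, group = "paired", n = length(grp$paired),
        is_bimodal = bm$is_bimodal, antimode = bm$antimode,
        bandwidth = bm$bandwidth, flag = bm$flag)
    }
  }

  wcsv <- function(x, name) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) x <- x %||% data.frame()
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    p
  }
  files <- c(
    wcsv(nuclei, "nuclei.csv"), wcsv(signals, "signals.csv"),
    wcsv(calls, "pairing_calls.csv"),
    wcsv(summary_tab, "pairing_summary.csv"),
    wcsv(attr(summary_tab, "replicates"), "pairing_replicates.csv"),
    wcsv(if (length(overlap_tab)) do.call(rbind, overlap_tab) else NULL,
         "overlap.csv"),
    wcsv(if (length(foci_tab)) do.call(rbind, foci_tab) else NULL,
         "foci.csv"),
    wcsv(if (length(stats_rows)) do.call(rbind, stats_rows) else NULL,
         "stats.csv"),
    wcsv(if (length(bimod_rows)) do.call(rbind, bimod_rows) else NULL,
         "bimodality.csv"))

  cfg_file <- tempfile()
  writeLines(deparse(config), cfg_file)
  manifest <- list(
    package = "ctquant",
    version = as.character(utils::packageVersion("ctquant")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    config = config,
    stage_counts = counts,
    pairing_summary = summary_tab[, c("target", "mean_pct", "sd_pct",
                                      "total_nuclei", "n_replicates",
                                      "reportable")],
    files = basename(files))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}

#' Paired versus combined-unpaired normalized volume groups
#'
#' For one territory channel, builds the two comparison groups: nuclei
#' called paired contribute their (merged-signal) normalized volume; nuclei
#' called unpaired contribute the combined volume of the two homolog
#' signals, normalized to the nuclear volume, so both sides carry the same
#' total chromatin content. Ambiguous calls are excluded.
#'
#' @param signals signal table for one channel, with `nucleus_id`,
#'   `replicate`, `volume_um3` and `normalized_volume` columns (from
#'   [run_pipeline()]'s signal stage).
#' @param calls pairing-call table for the same channel with `nucleus_id`,
#'   `replicate` and `status`.
#' @return list with numeric vectors `paired` and `unpaired` of normalized
#'   volumes.
#' @export
pairing_volume_groups <- function(signals, calls) {
  paired <- numeric(0); unpaired <- numeric(0)
  if (is.null(signals) || nrow(signals) == 0L)
    return(list(paired = paired, unpaired = unpaired))
  key <- function(df) paste(df$replicate, df$nucleus_id)
  sk <- key(signals)
  for (i in seq_len(nrow(calls))) {
    st <- calls$status[i]
    if (st == "ambiguous") next
    rows <- signals[sk == paste(calls$replicate[i], calls$nucleus_id[i]), ,
                    drop = FALSE]
    if (nrow(rows) == 0L) next
    nucvol <- rows$volume_um3_nucleus[1] %||% (rows$volume_um3[1] /
                                                 rows$normalized_volume[1])
    nv <- sum(rows$volume_um3) / nucvol
    if (st == "paired") paired <- c(paired, nv) else unpaired <- c(unpaired, nv)
  }
  list(paired = paired, unpaired = unpaired)
}
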
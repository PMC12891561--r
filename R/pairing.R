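#' Call homolog pairing for one nucleus and target
#'
#' Homologs are called paired when the 3D distance between the two signal
#' centroids is at most `threshold_um` (inclusive) or when only one signal is
#' present (fully merged homologs). Zero signals (dropout) and more than two
#' signals (doublets, segmentation splits) are returned as `ambiguous` and
#' excluded from downstream percentages.
#'
#' @param signals data frame of signal records for a single nucleus and
#'   target: columns `nucleus_id`, `channel`, `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um` (as produced by [segment_signals()]).
#' @param threshold_um pairing distance threshold in micrometres.
#' @param nucleus_id,target identifiers, required when `signals` has no rows.
#' @return object of class `pairing_call`: list with `nucleus_id`, `target`,
#'   `n_signals`, `min_distance_um` (NA when fewer than two signals),
#'   `status` (`"paired"`, `"unpaired"` or `"ambiguous"`) and `basis`
#'   (`"single_signal"`, `"distance"` or NA).
#' @export
call_pairing <- function(signals, threshold_um = 0.8,
                         nucleus_id = NULL, target = NULL) {
  n <- nrow(signals)
  if (n > 0L) {
    if (length(unique(signals$nucleus_id)) != 1L ||
        length(unique(signals$channel)) != 1L)
      stop("`signals` must belong to a single nucleus and target")
    nucleus_id <- signals$nucleus_id[1]
    target <- as.character(signals$channel[1])
  } else if (is.null(nucleus_id) || is.null(target)) {
    stop("`nucleus_id` and `target` are required when no signals are present")
  }
  mind <- NA_real_
  if (n >= 2L) {
    pts <- as.matrix(signals[, c("centroid_z_um", "centroid_y_um",
                                 "centroid_x_um")])
    mind <- min(stats::dist(pts))
  }
  if (n == 0L) {
    status <- "ambiguous"; basis <- NA_character_
  } else if (n == 1L) {
    status <- "paired"; basis <- "single_signal"
  } else if (n == 2L) {
    status <- if (mind <= threshold_um) "paired" else "unpaired"
    basis <- "distance"
  } else {
    status <- "ambiguous"; basis <- NA_character_
  }
  structure(list(nucleus_id = nucleus_id, target = target, n_signals = n,
                 min_distance_um = mind, status = status, basis = basis),
            class = "pairing_call")
}

#' @export
print.pairing_call <- function(x, ...) {
  cat(sprintf("<pairing_call> nucleus %s, %s: %s (%d signal(s)%s)\n",
              format(x$nucleus_id), x$target, x$status, x$n_signals,
              if (is.na(x$min_distance_um)) ""
              else sprintf(", min distance %.3f um", x$min_distance_um)))
  invisible(x)
}

pairing_call_row <- function(call) {
  data.frame(nucleus_id = call$nucleus_id, target = call$target,
             n_signals = call$n_signals,
             min_distance_um = call$min_distance_um,
             status = call$status, basis = call$basis)
}

#' Pairing calls for every nucleus and target in a signal table
#'
#' Applies [call_pairing()] per nucleus and channel. Nuclei listed in
#' `nucleus_ids` but absent from `signals` yield `ambiguous` (dropout) calls.
#'
#' @param signals signal records (see [segment_signals()]).
#' @param threshold_um pairing distance threshold, micrometres.
#' @param nucleus_ids nuclei expected per target; default those present.
#' @param targets channels to call; default those present.
#' @return data frame with one row per nucleus and target.
#' @export
call_pairing_all <- function(signals, threshold_um = 0.8,
                             nucleus_ids = NULL, targets = NULL) {
  targets <- targets %||% unique(as.character(signals$channel))
  nucleus_ids <- nucleus_ids %||% sort(unique(signals$nucleus_id))
  rows <- list()
  for (tg in targets) {
    st <- signals[signals$channel == tg, , drop = FALSE]
    for (nid in nucleus_ids) {
      sn <- st[st$nucleus_id == nid, , drop = FALSE]
      rows[[length(rows) + 1L]] <- pairing_call_row(
        call_pairing(sn, threshold_um, nucleus_id = nid, target = tg))
    }
  }
  do.call(rbind, rows)
}

#' Classify the arm/centromere pairing conformation of one chromosome
#'
#' Crosses the pairing states of the two arms (both / one / no arms paired)
#' with the centromere state (paired / unpaired) into one of six
#' conformation classes. Any ambiguous input yields an ambiguous class,
#' which downstream percentages exclude.
#'
#' @param left_arm,right_arm,centromere [call_pairing()] results (or one-row
#'   data frames with a `status` column) for one nucleus and chromosome.
#' @return object of class `conformation_class`: list with `arm_state`,
#'   `centromere_state`, `class_label` and `ambiguous`.
#' @export
classify_conformation <- function(left_arm, right_arm, centromere) {
  st <- function(x) if (is.list(x) && !is.null(x$status)) x$status[1] else stop("invalid call")
  s <- c(st(left_arm), st(right_arm), st(centromere))
  if (any(s == "ambiguous"))
    return(structure(list(arm_state = NA_character_,
                          centromere_state = NA_character_,
                          class_label = "ambiguous", ambiguous = TRUE),
                     class = "conformation_class"))
  n_arms <- sum(s[1:2] == "paired")
  arm_state <- c("no_arms_paired", "one_arm_paired", "both_arms_paired")[n_arms + 1L]
  cen_state <- if (s[3] == "paired") "cen_paired" else "cen_unpaired"
  structure(list(arm_state = arm_state, centromere_state = cen_state,
                 class_label = paste(arm_state, cen_state, sep = "/"),
                 ambiguous = FALSE),
            class = "conformation_class")
}

#' @export
print.conformation_class <- function(x, ...) {
  cat(sprintf("<conformation_class> %s\n", x$class_label))
  invisible(x)
}

#' Aggregate pairing calls into replicate-level percentages
#'
#' Computes the percent of paired nuclei per replicate over non-ambiguous
#' calls, then the mean and standard deviation across replicates (the
#' replicate, not the nucleus, is the unit of the error bar). Summaries
#' failing the reporting minimums (defaults: at least 300 nuclei in total
#' and at least 3 replicates) are flagged `reportable = FALSE` but still
#' returned.
#'
#' @param calls data frame of pairing calls with columns `target`, `status`
#'   and `replicate`.
#' @param min_nuclei minimum total non-ambiguous nuclei per target.
#' @param min_replicates minimum number of contributing replicates.
#' @return data frame with one row per target: `target`, `mean_pct`,
#'   `sd_pct` (NA with a single replicate), `total_nuclei`, `n_replicates`,
#'   `reportable`; attribute `"replicates"` holds the per-replicate table.
#' @export
aggregate_pairing <- function(calls, min_nuclei = 300L, min_replicates = 3L) {
  if (is.null(calls$replicate)) stop("every call must carry a replicate id")
  rows <- list(); reps <- list()
  for (tg in unique(as.character(calls$target))) {
    ct <- calls[calls$target == tg, , drop = FALSE]
    per <- list()
    for (r in unique(ct$replicate)) {
      cr <- ct[ct$replicate == r & ct$status != "ambiguous", , drop = FALSE]
      if (nrow(cr) == 0L) {
        message(sprintf("target %s, replicate %s: no non-ambiguous calls; excluded",
                        tg, format(r)))
        next
      }
      per[[length(per) + 1L]] <- data.frame(
        target = tg, replicate = r, n_nuclei = nrow(cr),
        pct_paired = 100 * mean(cr$status == "paired"))
    }
    per <- if (length(per)) do.call(rbind, per) else
      data.frame(target = character(0), replicate = integer(0),
                 n_nuclei = integer(0), pct_paired = numeric(0))
    reps[[length(reps) + 1L]] <- per
    total <- sum(per$n_nuclei)
    nr <- nrow(per)
    rows[[length(rows) + 1L]] <- data.frame(
      target = tg,
      mean_pct = if (nr > 0L) mean(per$pct_paired) else NA_real_,
      sd_pct = if (nr > 1L) stats::sd(per$pct_paired) else NA_real_,
      total_nuclei = total, n_replicates = nr,
      reportable = total >= min_nuclei && nr >= min_replicates)
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, reps)
  out
}
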
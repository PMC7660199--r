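# Cross-cycle linking, threshold-free channel calling, codebook decoding,
# per-cell copy numbers and QC.
#
# Linking follows the colocalization rule: detections in different cycles
# closer than 2 px (320 nm at 160 nm pixels) in the cycle-1 frame are the
# same molecule. Only spots colocalized in the first two cycles are "real
# signals"; copy numbers count only spots present in every cycle.

#' Link detections across cycles into spot tracks
#'
#' Tracks are seeded from cycle-1 detections. For each later cycle,
#' track-detection pairs with aligned distance strictly below `radius_px`
#' are assigned greedily in ascending distance order (one-to-one;
#' deterministic, ties broken by track creation order). Detections in
#' cycles >= 2 not claimed by any track are reported as orphans — they can
#' never satisfy the first-two-cycles rule, so they start no track.
#'
#' @param detections data.frame from [detect_stack()] (needs `spot_id`,
#'   `cycle`, `aligned_row`, `aligned_col` plus `intensity_*` columns for
#'   downstream calling).
#' @param n_cycles total number of cycles.
#' @param radius_px colocalization radius, strict upper bound (default 2).
#' @return list of class `track_set`: `tracks` (data.frame: `track_id`,
#'   `anchor_row`, `anchor_col`, `det_<cycle>` detection spot_id or NA,
#'   `n_present`, `is_real_signal`, `is_complete`), `orphans` (spot_ids of
#'   unclaimed cycle>=2 detections), `detections`, `n_cycles`,
#'   `radius_px`.
#' @export
link_tracks <- function(detections, n_cycles, radius_px = 2.0) {
  stopifnot(all(c("spot_id", "cycle", "aligned_row", "aligned_col") %in%
                  names(detections)))
  d1 <- detections[detections$cycle == 1L, , drop = FALSE]
  nT <- nrow(d1)
  tracks <- data.frame(track_id = seq_len(nT),
                       anchor_row = d1$aligned_row,
                       anchor_col = d1$aligned_col)
  det_mat <- matrix(NA_integer_, nrow = nT, ncol = n_cycles)
  if (nT > 0) det_mat[, 1L] <- d1$spot_id
  orphans <- integer(0)

  for (cyc in seq_len(n_cycles)[-1L]) {
    dc <- detections[detections$cycle == cyc, , drop = FALSE]
    if (nrow(dc) == 0L || nT == 0L) {
      orphans <- c(orphans, dc$spot_id)
      next
    }
    # candidate pairs under the strict radius
    dr <- outer(tracks$anchor_row, dc$aligned_row, "-")
    dcn <- outer(tracks$anchor_col, dc$aligned_col, "-")
    dist <- sqrt(dr^2 + dcn^2)
    cand <- which(dist < radius_px, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cd <- dist[cand]
      ord <- order(cd, cand[, 1L])   # distance, then track creation order
      cand <- cand[ord, , drop = FALSE]
      track_used <- logical(nT); det_used <- logical(nrow(dc))
      for (i in seq_len(nrow(cand))) {
        tr <- cand[i, 1L]; de <- cand[i, 2L]
        if (track_used[tr] || det_used[de]) next
        track_used[tr] <- TRUE; det_used[de] <- TRUE
        det_mat[tr, cyc] <- dc$spot_id[de]
      }
      orphans <- c(orphans, dc$spot_id[!det_used])
    } else {
      orphans <- c(orphans, dc$spot_id)
    }
  }

  colnames(det_mat) <- paste0("det_", seq_len(n_cycles))
  tracks <- cbind(tracks, as.data.frame(det_mat))
  present <- !is.na(det_mat)
  tracks$n_present <- rowSums(present)
  tracks$is_real_signal <- if (n_cycles >= 2L)
    present[, 1L] & present[, 2L] else present[, 1L]
  tracks$is_complete <- tracks$n_present == n_cycles
  structure(list(tracks = tracks, orphans = orphans,
                 detections = detections, n_cycles = n_cycles,
                 radius_px = radius_px),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks over %d cycles (%d complete, %d real-signal), %d orphan detections\n",
              nrow(x$tracks), x$n_cycles, sum(x$tracks$is_complete),
              sum(x$tracks$is_real_signal), length(x$orphans)))
  invisible(x)
}

#' Threshold-free channel call from an intensity vector
#'
#' Every target is stained in every cycle, so no absolute intensity
#' threshold is needed: the called channel is simply the brightest one.
#' The call is flagged ambiguous when the brightest channel is not at
#' least `ambiguity_ratio` times the second brightest; weak spots remain
#' callable.
#'
#' @param intensity_vector one value per channel (background-subtracted;
#'   may be negative).
#' @param ambiguity_ratio dominance required over the runner-up
#'   (default 1.5).
#' @return list: `channel` (0-based argmax, or NA if all values missing),
#'   `ambiguous` (logical), `missing` (logical).
#' @export
call_color <- function(intensity_vector, ambiguity_ratio = 1.5) {
  v <- as.numeric(intensity_vector)
  if (all(is.na(v)))
    return(list(channel = NA_integer_, ambiguous = FALSE, missing = TRUE))
  best <- which.max(v)
  second <- if (length(v) > 1L) max(v[-best], na.rm = TRUE) else -Inf
  amb <- is.finite(second) && v[best] < ambiguity_ratio * second
  list(channel = as.integer(best - 1L), ambiguous = isTRUE(amb),
       missing = FALSE)
}

#' Call the color sequence of every track
#'
#' Applies [call_color()] to each track's per-cycle intensity vector.
#'
#' @param track_set from [link_tracks()].
#' @param channel_names channel names matching the `intensity_*` columns.
#' @param ambiguity_ratio passed to [call_color()].
#' @return the `track_set` with per-cycle `call_<cycle>` (0-based channel
#'   or NA) and `amb_<cycle>` columns added to `tracks`, plus a
#'   `sequence` string column ("." = missing, "?" suffix = ambiguous).
#' @export
call_tracks <- function(track_set, channel_names, ambiguity_ratio = 1.5) {
  tr <- track_set$tracks
  det <- track_set$detections
  icols <- paste0("intensity_", channel_names)
  stopifnot(all(icols %in% names(det)))
  n_cycles <- track_set$n_cycles
  for (cyc in seq_len(n_cycles)) {
    calls <- rep(NA_integer_, nrow(tr))
    ambs <- rep(FALSE, nrow(tr))
    ids <- tr[[paste0("det_", cyc)]]
    hit <- match(ids, det$spot_id)
    for (i in which(!is.na(hit))) {
      cc <- call_color(as.numeric(det[hit[i], icols]), ambiguity_ratio)
      calls[i] <- cc$channel
      ambs[i] <- cc$ambiguous || cc$missing
    }
    tr[[paste0("call_", cyc)]] <- calls
    tr[[paste0("amb_", cyc)]] <- ambs
  }
  call_cols <- paste0("call_", seq_len(n_cycles))
  amb_cols <- paste0("amb_", seq_len(n_cycles))
  tr$sequence <- apply(tr, 1L, function(r) {
    s <- ifelse(is.na(r[call_cols]), ".",
                paste0(r[call_cols], ifelse(as.logical(r[amb_cols]), "?", "")))
    paste(gsub(" ", "", s), collapse = "-")
  })
  track_set$tracks <- tr
  track_set
}

#' Decode a called color sequence against a codebook
#'
#' @param calls integer vector of 0-based per-cycle channel calls (NA =
#'   missing).
#' @param ambiguous logical vector flagging ambiguous cycles.
#' @param codebook a `codebook`.
#' @return list: `target_id` (or NA) and `status` ("decoded",
#'   "incomplete", "ambiguous" or "no-codebook-match").
#' @export
decode_track <- function(calls, ambiguous, codebook) {
  if (length(calls) != codebook$n_cycles)
    stop("call vector length does not match codebook n_cycles", call. = FALSE)
  if (anyNA(calls))
    return(list(target_id = NA_character_, status = "incomplete"))
  if (any(ambiguous))
    return(list(target_id = NA_character_, status = "ambiguous"))
  hit <- lookup_sequence(codebook, calls)
  if (is.na(hit))
    return(list(target_id = NA_character_, status = "no-codebook-match"))
  list(target_id = hit, status = "decoded")
}

#' Decode every called track
#'
#' @param track_set a called `track_set` (see [call_tracks()]).
#' @param codebook a `codebook`.
#' @return the `track_set` with `target_id` and `decode_status` columns
#'   added (`decode_status` of non-complete tracks is "incomplete").
#' @export
decode_tracks <- function(track_set, codebook) {
  tr <- track_set$tracks
  n_cycles <- track_set$n_cycles
  call_cols <- paste0("call_", seq_len(n_cycles))
  amb_cols <- paste0("amb_", seq_len(n_cycles))
  tgt <- character(nrow(tr)); status <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    res <- decode_track(as.integer(tr[i, call_cols]),
                        as.logical(tr[i, amb_cols]), codebook)
    tgt[i] <- if (is.na(res$target_id)) NA_character_ else res$target_id
    status[i] <- res$status
  }
  tr$target_id <- tgt
  tr$decode_status <- status
  track_set$tracks <- tr
  track_set
}

#' Per-cell, per-target copy numbers
#'
#' Counts only complete, successfully decoded tracks (present in every
#' cycle with a codebook-matching sequence). Cells are assigned by the
#' track anchor position against the label mask; anchors on label 0
#' (outside any cell) are excluded and reported.
#'
#' @param track_set a decoded `track_set`.
#' @param cellmask integer label matrix (0 = background).
#' @return list: `counts` (data.frame `cell_id`, `target_id`, `count`,
#'   long format, zero rows included for no decoded spots),
#'   `outside_cells` (number of decoded tracks outside any cell).
#' @export
copy_number <- function(track_set, cellmask) {
  tr <- track_set$tracks
  if (!is.matrix(cellmask))
    stop("cellmask must be an integer label matrix", call. = FALSE)
  dec <- tr[tr$is_complete & tr$decode_status == "decoded", , drop = FALSE]
  if (nrow(dec) == 0L)
    return(list(counts = data.frame(cell_id = integer(0),
                                    target_id = character(0),
                                    count = integer(0)),
                outside_cells = 0L))
  ri <- pmin(pmax(round(dec$anchor_row), 0), nrow(cellmask) - 1L)
  ci <- pmin(pmax(round(dec$anchor_col), 0), ncol(cellmask) - 1L)
  cell <- cellmask[cbind(ri + 1L, ci + 1L)]
  inside <- cell > 0L
  tab <- table(cell_id = cell[inside], target_id = dec$target_id[inside])
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  counts$cell_id <- as.integer(counts$cell_id)
  counts$count <- as.integer(counts$Freq); counts$Freq <- NULL
  counts <- counts[order(counts$cell_id, counts$target_id), ]
  rownames(counts) <- NULL
  list(counts = counts, outside_cells = sum(!inside))
}

#' Track-level QC metrics
#'
#' Reports the fractions behind the method's validation logic: how many
#' cycle-1 spots reappear in cycle 2 (non-specific binders fail this), how
#' many real-signal spots persist to cycle 3 and through every cycle, the
#' distribution of cycles-present per track, and (when intensities are
#' available) per-cycle called-channel intensity summaries.
#'
#' @param track_set a `track_set` (called or not).
#' @param channel_names optional; enables the per-cycle intensity summary.
#' @return list: `reappearance_c1_c2`, `real_signal_in_c3`,
#'   `real_signal_in_all`, `cycles_present_hist` (named integer vector),
#'   `n_tracks`, `n_orphans`, and optionally `intensity_by_cycle`
#'   (data.frame `cycle`, `mean_called`, `mean_other`,
#'   `signal_to_background`).
#' @export
qc_metrics <- function(track_set, channel_names = NULL) {
  tr <- track_set$tracks
  n_cycles <- track_set$n_cycles
  if (nrow(tr) == 0L)
    return(list(reappearance_c1_c2 = NA_real_, real_signal_in_c3 = NA_real_,
                real_signal_in_all = NA_real_,
                cycles_present_hist = integer(0), n_tracks = 0L,
                n_orphans = length(track_set$orphans)))
  present <- !is.na(as.matrix(tr[, paste0("det_", seq_len(n_cycles)),
                                 drop = FALSE]))
  out <- list()
  out$reappearance_c1_c2 <- if (n_cycles >= 2L) mean(present[, 2L]) else NA_real_
  rs <- tr$is_real_signal
  out$real_signal_in_c3 <- if (n_cycles >= 3L && any(rs))
    mean(present[rs, 3L]) else NA_real_
  out$real_signal_in_all <- if (any(rs))
    mean(tr$is_complete[rs]) else NA_real_
  out$cycles_present_hist <-
    table(factor(tr$n_present, levels = seq_len(n_cycles)))
  out$n_tracks <- nrow(tr)
  out$n_orphans <- length(track_set$orphans)

  if (!is.null(channel_names) &&
      all(paste0("call_", seq_len(n_cycles)) %in% names(tr))) {
    det <- track_set$detections
    icols <- paste0("intensity_", channel_names)
    summ <- lapply(seq_len(n_cycles), function(cyc) {
      ids <- tr[[paste0("det_", cyc)]]
      calls <- tr[[paste0("call_", cyc)]]
      hit <- match(ids, det$spot_id)
      ok <- !is.na(hit) & !is.na(calls)
      if (!any(ok)) return(data.frame(cycle = cyc, mean_called = NA_real_,
                                      mean_other = NA_real_,
                                      signal_to_background = NA_real_))
      iv <- as.matrix(det[hit[ok], icols])
      sel <- cbind(seq_len(nrow(iv)), calls[ok] + 1L)
      called <- iv[sel]
      mask <- matrix(TRUE, nrow(iv), ncol(iv)); mask[sel] <- FALSE
      other_vals <- iv[mask]
      spread <- if (length(other_vals) > 1L) stats::sd(other_vals) else NA_real_
      data.frame(cycle = cyc, mean_called = mean(called),
                 mean_other = if (length(other_vals)) mean(other_vals) else NA_real_,
                 signal_to_background = mean(called) / max(spread, 1e-9))
    })
    out$intensity_by_cycle <- do.call(rbind, summ)
  }
  out
}

#' Simulate per-cycle detection persistence of spot tracks
#'
#' Each of `n_tracks` tracks is independently detected in each of
#' `n_cycles` cycles with probability `p_detect`; returns the fraction
#' detected in every cycle. This is the survival arithmetic behind
#' all-cycle counting: with a 99.8% per-cycle detection rate, about 97% of
#' tracks survive 14 consecutive cycles. Uses the current RNG state (seed
#' with [set.seed()]).
#'
#' @param n_tracks number of tracks.
#' @param n_cycles number of cycles each must survive.
#' @param p_detect per-cycle detection probability.
#' @return fraction of tracks present in all `n_cycles` cycles.
#' @export
simulate_track_survival <- function(n_tracks, n_cycles, p_detect) {
  stopifnot(n_tracks >= 1, n_cycles >= 1, p_detect >= 0, p_detect <= 1)
  survived <- stats::rbinom(n_tracks, size = n_cycles, prob = p_detect)
  mean(survived == n_cycles)
}

#' Simulate the first-to-second-cycle reappearance fraction
#'
#' Draws `n_spots` cycle-1 detections at uniform positions in a square
#' field; a fraction `nonspecific_frac` are single-cycle non-specific
#' binders (absent in cycle 2), the remainder reappear in cycle 2 with
#' probability `p_redetect` at their true positions. The two cycles are
#' then linked with [link_tracks()] at the given radius and the fraction
#' of cycle-1 spots with a cycle-2 partner is returned. Uses the current
#' RNG state.
#'
#' @param n_spots cycle-1 spot count.
#' @param nonspecific_frac fraction of cycle-1 spots that are single-cycle
#'   non-specific binders.
#' @param p_redetect re-detection probability for real spots.
#' @param field_size square field side, px.
#' @param radius_px colocalization radius (default 2).
#' @param jitter_px localization jitter sd applied independently per cycle
#'   (default 0.15 px).
#' @return fraction of cycle-1 spots linked to a cycle-2 detection.
#' @export
simulate_reappearance <- function(n_spots, nonspecific_frac, p_redetect,
                                  field_size = 2048, radius_px = 2.0,
                                  jitter_px = 0.15) {
  stopifnot(n_spots >= 1, nonspecific_frac >= 0, nonspecific_frac <= 1)
  pos <- cbind(stats::runif(n_spots, 0, field_size),
               stats::runif(n_spots, 0, field_size))
  is_ns <- stats::runif(n_spots) < nonspecific_frac
  redetected <- !is_ns & stats::runif(n_spots) < p_redetect
  d1 <- data.frame(spot_id = seq_len(n_spots), cycle = 1L,
                   aligned_row = pos[, 1] + stats::rnorm(n_spots, sd = jitter_px),
                   aligned_col = pos[, 2] + stats::rnorm(n_spots, sd = jitter_px))
  n2 <- sum(redetected)
  d2 <- data.frame(spot_id = n_spots + seq_len(n2), cycle = 2L,
                   aligned_row = pos[redetected, 1] +
                     stats::rnorm(n2, sd = jitter_px),
                   aligned_col = pos[redetected, 2] +
                     stats::rnorm(n2, sd = jitter_px))
  ts <- link_tracks(rbind(d1, d2), n_cycles = 2L, radius_px = radius_px)
  mean(!is.na(ts$tracks$det_2))
}
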
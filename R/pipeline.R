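# Pipeline entry points: simulate -> detect -> decode -> qc, with plain
# file interfaces (TIFF/CSV/YAML/JSON) so stages can be rerun
# independently. A thin Rscript front-end lives at inst/cli/chainfish.

SIM_CONFIG_REQUIRED <- c("n_cycles", "n_channels")

#' Load and validate a simulation config file
#'
#' YAML (or JSON) keys mirror the [sim_config()] arguments. Unknown keys
#' and missing required keys (`n_cycles`, `n_channels`) are config errors
#' naming the offending keys.
#'
#' @param path YAML/JSON config file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(SIM_CONFIG_REQUIRED, names(raw))
  if (length(missing))
    stop("missing required config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

run_manifest <- function(stage, config, inputs, outputs, seed, t0, counts) {
  list(tool = paste0("chainfish ", as.character(utils::packageVersion("chainfish"))),
       stage = stage,
       config = config,
       inputs = inputs,
       outputs = outputs,
       seed = seed,
       wall_clock_s = round(as.numeric(Sys.time()) - t0, 3),
       record_counts = counts)
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Simulate an experiment and write it to disk
#'
#' Generates a default full codebook (lexicographic, targets `T001`...)
#' unless `codebook` is supplied, simulates, and writes the TIFF stack,
#' cell mask, ground truth, config echo and a run manifest.
#'
#' @param config a [sim_config()] or path to a YAML/JSON config.
#' @param out_dir output directory.
#' @param codebook optional `codebook` (or CSV path) overriding the
#'   default.
#' @param n_targets number of targets for the default codebook (ignored
#'   when `codebook` given).
#' @param seed optional seed overriding the config's.
#' @return invisibly, the `cycle_stack`.
#' @export
cmd_simulate <- function(config, out_dir, codebook = NULL, n_targets = 4L,
                         seed = NULL) {
  t0 <- as.numeric(Sys.time())
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  if (is.null(codebook))
    codebook <- generate_codebook(config$n_channels, config$n_cycles,
                                  sprintf("T%03d", seq_len(n_targets)))
  stack <- simulate_experiment(config, codebook)
  files <- write_stack(stack, out_dir)
  cb_path <- file.path(out_dir, "codebook.csv")
  write_codebook(codebook, cb_path)
  manifest <- run_manifest("simulate", unclass(config), character(0),
                           c(files, cb_path), config$seed, t0,
                           list(truth_records = nrow(stack$truth)))
  write_manifest(manifest, out_dir)
  invisible(stack)
}

#' Run the full decoding pipeline in memory
#'
#' register -> detect -> measure -> link -> call -> decode -> count -> qc.
#'
#' @param stack a `cycle_stack`.
#' @param codebook a `codebook`.
#' @param psf_sigma,min_snr detection parameters (see [detect_stack()]).
#' @param radius_px colocalization radius (default 2).
#' @param ambiguity_ratio channel-call dominance ratio (default 1.5).
#' @return list of class `decode_result`: `detections`, `offsets`,
#'   `tracks` (decoded track table), `orphans`, `counts`,
#'   `outside_cells`, `qc`.
#' @export
decode_stack <- function(stack, codebook, psf_sigma = NULL, min_snr = 5,
                         radius_px = 2.0, ambiguity_ratio = 1.5) {
  if (!identical(codebook$channel_names, stack$channel_names))
    stop("codebook channel names do not match the image stack", call. = FALSE)
  det <- detect_stack(stack, psf_sigma = psf_sigma, min_snr = min_snr)
  ts <- link_tracks(det$detections, n_cycles = codebook$n_cycles,
                    radius_px = radius_px)
  ts <- call_tracks(ts, codebook$channel_names, ambiguity_ratio)
  ts <- decode_tracks(ts, codebook)
  cn <- if (!is.null(stack$cellmask)) copy_number(ts, stack$cellmask)
        else list(counts = NULL, outside_cells = NA_integer_)
  qc <- qc_metrics(ts, stack$channel_names)
  structure(list(detections = det$detections, offsets = det$offsets,
                 tracks = ts$tracks, orphans = ts$orphans,
                 counts = cn$counts, outside_cells = cn$outside_cells,
                 qc = qc),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %d detections, %d tracks (%d decoded), %d orphans\n",
              nrow(x$detections), nrow(x$tracks),
              sum(x$tracks$decode_status == "decoded"), length(x$orphans)))
  invisible(x)
}

#' Decode a stack directory and write all outputs
#'
#' Reads the [write_stack()] layout (or any directory of
#' `cycle{c}_{channel}.tif` files plus optional `cellmask.tif`), validates
#' the codebook against the stack, runs [decode_stack()], and writes
#' `detections.csv`, `offsets.csv`, `tracks.csv`, `counts.csv`, `qc.json`
#' and a run manifest. When `truth.csv` is present, also writes
#' `eval.json` with detection recall/precision and the decode error rate
#' against ground truth (1 px match radius).
#'
#' @param images_dir directory with the cycle TIFFs.
#' @param codebook a `codebook` or codebook CSV path (defaults to
#'   `codebook.csv` inside `images_dir`).
#' @param out_dir output directory.
#' @param ... passed to [decode_stack()].
#' @return invisibly, the `decode_result`.
#' @export
cmd_decode <- function(images_dir, codebook = NULL, out_dir, ...) {
  t0 <- as.numeric(Sys.time())
  if (is.null(codebook)) codebook <- file.path(images_dir, "codebook.csv")
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  stack <- read_stack(images_dir, channel_names = codebook$channel_names)
  d <- dim(stack$images)
  if (d[3] != codebook$n_channels || d[4] != codebook$n_cycles)
    stop(sprintf("stack (%d channels x %d cycles) does not match codebook (%d x %d)",
                 d[3], d[4], codebook$n_channels, codebook$n_cycles),
         call. = FALSE)
  res <- decode_stack(stack, codebook, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  utils::write.csv(res$detections, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(res$offsets, file.path(out_dir, "offsets.csv"),
                   row.names = FALSE)
  utils::write.csv(res$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  if (!is.null(res$counts))
    utils::write.csv(res$counts, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
  qc <- res$qc
  qc$cycles_present_hist <- as.list(stats::setNames(
    as.integer(qc$cycles_present_hist), names(qc$cycles_present_hist)))
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows",
                       na = "null")

  outputs <- file.path(out_dir, c("detections.csv", "offsets.csv",
                                  "tracks.csv", "counts.csv", "qc.json"))
  if (!is.null(stack$truth)) {
    ev <- evaluate_against_truth(res, stack$truth, codebook$n_cycles)
    jsonlite::write_json(ev, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, file.path(out_dir, "eval.json"))
  }
  manifest <- run_manifest("decode", list(...), images_dir, outputs,
                           seed = NA, t0,
                           list(detections = nrow(res$detections),
                                tracks = nrow(res$tracks)))
  write_manifest(manifest, out_dir)
  invisible(res)
}

#' Evaluate a decode result against simulator ground truth
#'
#' Tracks are matched to specific ground-truth spots by anchor position
#' (nearest within `match_radius` px, one-to-one, cycle-1 frame).
#'
#' @param result a `decode_result`.
#' @param truth the simulator truth data.frame.
#' @param n_cycles number of cycles.
#' @param match_radius matching radius, px (default 1).
#' @return list with `track_recall` (fraction of specific true spots
#'   recovered as complete tracks), `decode_error_rate` (wrong-target
#'   fraction among decoded tracks), `decoded_correct`, `n_true_specific`,
#'   `n_decoded`.
#' @export
evaluate_against_truth <- function(result, truth, n_cycles,
                                   match_radius = 1.0) {
  spec <- truth[truth$target_id != "NONSPECIFIC", , drop = FALSE]
  # true specific spots stained in every cycle (dropout-free)
  pres_cols <- paste0("present_", seq_len(n_cycles))
  full <- rowSums(as.matrix(spec[, pres_cols, drop = FALSE])) == n_cycles
  tr <- result$tracks
  match <- match_points(cbind(tr$anchor_row, tr$anchor_col),
                        cbind(spec$row, spec$col), match_radius)
  matched_truth <- match$j   # per track: truth row index or NA

  complete <- tr$is_complete
  recovered <- !is.na(matched_truth) & complete
  track_recall <- if (sum(full) > 0)
    length(unique(matched_truth[recovered & matched_truth %in% which(full)])) /
      sum(full) else NA_real_

  decoded <- which(tr$decode_status == "decoded")
  correct <- vapply(decoded, function(i) {
    j <- matched_truth[i]
    !is.na(j) && identical(tr$target_id[i], spec$target_id[j])
  }, logical(1))
  list(track_recall = track_recall,
       decode_error_rate = if (length(decoded)) mean(!correct) else NA_real_,
       decoded_correct = sum(correct),
       n_true_specific = sum(full),
       n_decoded = length(decoded))
}

# greedy one-to-one nearest matching of point set a to point set b
match_points <- function(a, b, radius) {
  na <- nrow(a); nb <- nrow(b)
  j <- rep(NA_integer_, na)
  if (na == 0L || nb == 0L) return(list(j = j))
  dist <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  cand <- which(dist <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list(j = j))
  ord <- order(dist[cand])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  for (i in seq_len(nrow(cand))) {
    ai <- cand[i, 1]; bi <- cand[i, 2]
    if (used_a[ai] || used_b[bi]) next
    used_a[ai] <- TRUE; used_b[bi] <- TRUE
    j[ai] <- bi
  }
  list(j = j)
}
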
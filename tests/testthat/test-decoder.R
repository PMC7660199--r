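make_detections <- function(...) {
  # rows: list(cycle, row, col) triples
  rows <- list(...)
  df <- data.frame(spot_id = seq_along(rows),
                   cycle = vapply(rows, `[[`, 0, 1),
                   aligned_row = vapply(rows, `[[`, 0, 2),
                   aligned_col = vapply(rows, `[[`, 0, 3))
  df
}

test_that("colocalization linking applies the strict 2 px rule", {
  # same position in all cycles: one complete track
  ts <- link_tracks(make_detections(c(1, 10, 10), c(2, 10, 10), c(3, 10, 10)),
                    n_cycles = 3)
  expect_equal(nrow(ts$tracks), 1L)
  expect_true(ts$tracks$is_complete)
  expect_true(ts$tracks$is_real_signal)

  # 2.5 px away: not linked, track loses its real-signal status
  ts2 <- link_tracks(make_detections(c(1, 10, 10), c(2, 10, 12.5)),
                     n_cycles = 2)
  expect_true(is.na(ts2$tracks$det_2))
  expect_false(ts2$tracks$is_real_signal)
  expect_equal(ts2$orphans, 2L)

  # exactly 2.0 px: strict inequality, still not linked
  ts3 <- link_tracks(make_detections(c(1, 10, 10), c(2, 10, 12)),
                     n_cycles = 2)
  expect_true(is.na(ts3$tracks$det_2))

  # nearest of two candidates wins; the other stays orphan
  ts4 <- link_tracks(make_detections(c(1, 10, 10), c(2, 10, 10.4),
                                     c(2, 10, 11.3)),
                     n_cycles = 2)
  expect_equal(ts4$tracks$det_2, 2L)
  expect_equal(ts4$orphans, 3L)

  # one-to-one: two tracks, two detections, each claims its nearest
  ts5 <- link_tracks(make_detections(c(1, 10, 10), c(1, 10, 14),
                                     c(2, 10, 10.2), c(2, 10, 13.9)),
                     n_cycles = 2)
  expect_equal(ts5$tracks$det_2, c(3L, 4L))
})

test_that("channel calling is threshold-free with an ambiguity flag", {
  expect_equal(call_color(c(100, 5))$channel, 0L)
  expect_false(call_color(c(100, 5))$ambiguous)
  tie <- call_color(c(100, 100))
  expect_equal(tie$channel, 0L)   # argmax still reported
  expect_true(tie$ambiguous)
  # weak spots remain callable: no absolute threshold
  weak <- call_color(c(12, 3))
  expect_equal(weak$channel, 0L)
  expect_false(weak$ambiguous)
  miss <- call_color(c(NA, NA))
  expect_true(miss$missing)
  expect_true(is.na(miss$channel))
  # negative background-subtracted values in empty channels are fine
  expect_equal(call_color(c(-4, 80, -2))$channel, 1L)
})

test_that("decoding maps complete unambiguous sequences through the codebook", {
  cb <- alternating_codebook(16)
  calls <- rep(c(0L, 1L), 8)   # Quasar570 on odd cycles
  res <- decode_track(calls, rep(FALSE, 16), cb)
  expect_identical(res$target_id, "GAPDH")
  expect_identical(res$status, "decoded")
  expect_identical(decode_track(rep(c(1L, 0L), 8), rep(FALSE, 16),
                                cb)$target_id, "Ki67")

  res2 <- decode_track(rep(0L, 16), rep(FALSE, 16), cb)
  expect_identical(res2$status, "no-codebook-match")

  calls[3] <- NA
  expect_identical(decode_track(calls, rep(FALSE, 16), cb)$status,
                   "incomplete")
  expect_identical(decode_track(rep(c(0L, 1L), 8),
                                c(TRUE, rep(FALSE, 15)), cb)$status,
                   "ambiguous")
})

test_that("copy numbers count only complete decoded tracks inside cells", {
  cfg <- lossless_config(n_cycles = 3, n_channels = 2, seed = 7)
  cb <- generate_codebook(2, 3, c("A", "B", "C", "D"))
  st <- simulate_experiment(cfg, cb)
  res <- decode_stack(st, cb)
  truth_counts <- table(st$truth$cell_id, st$truth$target_id)
  for (i in seq_len(nrow(res$counts))) {
    expect_equal(res$counts$count[i],
                 unname(truth_counts[as.character(res$counts$cell_id[i]),
                                     res$counts$target_id[i]]))
  }
  expect_equal(sum(res$counts$count), nrow(st$truth))
  expect_equal(res$outside_cells, 0L)
})

test_that("incomplete tracks are excluded from counts but kept in QC", {
  # drop one cycle of one spot by hand
  det <- make_detections(c(1, 20, 20), c(2, 20, 20), c(3, 20, 20),
                         c(1, 40, 40), c(2, 40, 40))
  for (ch in c("a", "b")) det[[paste0("intensity_", ch)]] <- 100
  det$intensity_b <- c(1, 1, 1, 1, 1)
  ts <- link_tracks(det, n_cycles = 3)
  ts <- call_tracks(ts, c("a", "b"))
  cb <- generate_codebook(2, 3, c("A", "B"))
  ts <- decode_tracks(ts, cb)
  expect_identical(ts$tracks$decode_status, c("decoded", "incomplete"))
  mask <- matrix(1L, 64, 64)
  cn <- copy_number(ts, mask)
  expect_equal(sum(cn$counts$count), 1L)
  qc <- qc_metrics(ts)
  expect_equal(unname(qc$cycles_present_hist["2"]), 1L)
  expect_equal(unname(qc$cycles_present_hist["3"]), 1L)
})

test_that("single-cycle non-specific spots never decode to targets", {
  cfg <- sim_config(n_cycles = 4, n_channels = 2, seed = 19,
                    nonspecific_rate = 3, drift_per_cycle = c(0.5, 0.5))
  cb <- generate_codebook(2, 4, sprintf("T%02d", 1:4))
  st <- simulate_experiment(cfg, cb)
  res <- decode_stack(st, cb)
  dec <- res$tracks[res$tracks$decode_status == "decoded", ]
  spec <- st$truth[st$truth$target_id != "NONSPECIFIC", ]
  # every decoded track coincides with a true specific spot at the
  # colocalization scale (crowded same-channel neighbors can bias single
  # anchors by ~1 px, so 1 px would be too strict a match radius here)
  m <- chainfish:::match_points(cbind(dec$anchor_row, dec$anchor_col),
                                cbind(spec$row, spec$col), 2)
  expect_true(all(!is.na(m$j)))
  # conservation: no detection silently dropped — every detection is
  # either claimed by a track or reported as an orphan
  expect_equal(sum(res$tracks$n_present) + length(res$orphans),
               nrow(res$detections))
  # and every track has exactly one decode status
  expect_equal(sum(res$tracks$decode_status == "decoded") +
                 sum(res$tracks$decode_status != "decoded"),
               nrow(res$tracks))
})

test_that("QC fractions mirror the reappearance logic", {
  # perfect persistence: reappearance 1.0
  withr_seed(31)
  f <- simulate_reappearance(500, nonspecific_frac = 0, p_redetect = 1)
  expect_equal(f, 1.0)

  # 15% single-cycle spots: reappearance near 0.85 x 0.998
  withr_seed(32)
  f2 <- simulate_reappearance(5000, nonspecific_frac = 0.15,
                              p_redetect = 0.998)
  expected <- 0.85 * 0.998
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(f2 - expected), 4 * se)

  # survival arithmetic: fraction present in all cycles ~ p^n
  withr_seed(33)
  s <- simulate_track_survival(10000, 14, 0.998)
  expect_lt(abs(s - 0.998^14), 0.01)
})

test_that("per-cycle called intensity grows with cycle in a default run", {
  cfg <- sim_config(n_cycles = 6, n_channels = 2, seed = 23)
  cb <- generate_codebook(2, 6, sprintf("T%02d", 1:4))
  st <- simulate_experiment(cfg, cb)
  res <- decode_stack(st, cb)
  ibc <- res$qc$intensity_by_cycle
  expect_equal(nrow(ibc), 6L)
  # monotone growth while amplification is below the cap (cap 64 -> first
  # 6 cycles all amplifying)
  expect_true(all(diff(ibc$mean_called) > 0))
  # non-called channels stay near background
  expect_lt(max(abs(ibc$mean_other)), 0.1 * max(ibc$mean_called))
})
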
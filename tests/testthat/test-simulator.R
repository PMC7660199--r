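test_that("expected_amplitude follows the capped geometric law", {
  expect_equal(expected_amplitude(100, 2, 64, 1), 100)
  expect_equal(expected_amplitude(100, 2, 64, 5), 1600)
  # plateau: cap reached at cycle 4, constant afterwards
  late <- expected_amplitude(100, 2, 8, 4:16)
  expect_true(all(late == 800))
  # strictly increasing before the cap
  pre <- expected_amplitude(100, 2, 64, 1:7)
  expect_true(all(diff(pre) > 0))
})

test_that("noise-free rendering doubles the peak each cycle, in the right channels", {
  cfg <- lossless_config(n_cycles = 2, n_channels = 2, seed = 21,
                         n_cells = 1, spots_per_cell_per_target = 1)
  cb <- generate_codebook(2, 2, "T1",
                          entries = matrix(c(0L, 1L), 1))
  st <- simulate_experiment(cfg, cb)
  stopifnot(nrow(st$truth) >= 1)
  base <- cfg$camera_offset + cfg$background
  pk <- function(cyc, k) max(st$images[, , k, cyc]) - base
  # amplification 2: cycle-2 peak is exactly twice cycle-1 (same sub-pixel
  # position, so identical Gaussian sampling)
  expect_equal(pk(2, 2) / pk(1, 1), 2, tolerance = 1e-12)
  # channel exclusivity: non-designated channels hold only background
  expect_equal(max(st$images[, , 2, 1]), base, tolerance = 1e-9)
  expect_equal(max(st$images[, , 1, 2]), base, tolerance = 1e-9)
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- sim_config(n_cycles = 3, n_channels = 2, seed = 33,
                    image_size = c(128, 128), n_cells = 2, cell_radius = 26)
  cb <- generate_codebook(2, 3, c("A", "B"))
  s1 <- simulate_experiment(cfg, cb)
  s2 <- simulate_experiment(cfg, cb)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$cellmask, s2$cellmask)
})

test_that("truth records conserve specific and non-specific draws", {
  cfg <- sim_config(n_cycles = 3, n_channels = 2, seed = 5,
                    image_size = c(128, 128), n_cells = 2, cell_radius = 26,
                    nonspecific_rate = 1.5)
  cb <- generate_codebook(2, 3, c("A", "B"))
  st <- simulate_experiment(cfg, cb)
  ns <- st$truth$target_id == "NONSPECIFIC"
  expect_equal(nrow(st$truth), sum(ns) + sum(!ns))
  # non-specific spots are present in exactly one cycle
  pres <- as.matrix(st$truth[ns, paste0("present_", 1:3)])
  expect_true(all(rowSums(pres) == 1))
  # specific spots without dropout are present in the codebook channel
  # every cycle
  spec <- st$truth[!ns, ]
  for (cyc in 1:3) {
    p <- spec[[paste0("present_", cyc)]] == 1
    expect_true(all(spec[[paste0("channel_", cyc)]][p] ==
                      cb$entries[spec$target_id[p], cyc]))
  }
})

test_that("drifted spots land at the cumulative offset", {
  drift <- c(1.5, -0.5)
  cfg <- lossless_config(n_cycles = 4, n_channels = 2, seed = 17,
                         n_cells = 1, spots_per_cell_per_target = 1,
                         drift_per_cycle = drift, background = 0)
  cb <- generate_codebook(2, 4, "T1",
                          entries = matrix(c(0L, 0L, 0L, 0L), 1))
  st <- simulate_experiment(cfg, cb)
  tt <- st$truth[1, ]
  pk <- which(st$images[, , 1, 4] == max(st$images[, , 1, 4]),
              arr.ind = TRUE)[1, ]
  # peak pixel (0-based) within 1 px of true position + 3 * drift
  expect_lt(abs((pk[1] - 1) - (tt$row + 3 * drift[1])), 1)
  expect_lt(abs((pk[2] - 1) - (tt$col + 3 * drift[2])), 1)
})

test_that("mean rendered amplitude agrees with the closed form under noise", {
  # Monte Carlo: many spots, lognormal brightness with mean 1
  cfg <- sim_config(n_cycles = 2, n_channels = 1, seed = 88,
                    image_size = c(256, 256), n_cells = 4, cell_radius = 28,
                    spots_per_cell_per_target = 30, min_separation = 5,
                    nonspecific_rate = 0, dropout_prob = 0,
                    brightness_cv = 0.25)
  cb <- generate_codebook(1, 2, "T1")
  st <- simulate_experiment(cfg, cb)
  amps <- st$truth$amp_2
  n <- length(amps)
  expect_gt(n, 60)
  expected <- expected_amplitude(cfg$base_intensity, 2, 64, 2)
  se <- stats::sd(amps) / sqrt(n)
  expect_lt(abs(mean(amps) - expected), 3 * se + 1e-9)
})

test_that("background level is cycle-independent and signal grows to the cap", {
  cfg <- sim_config(n_cycles = 10, n_channels = 1, seed = 3,
                    image_size = c(96, 96), n_cells = 1, cell_radius = 20,
                    spots_per_cell_per_target = 2, saturation_cap = 16,
                    nonspecific_rate = 0, dropout_prob = 0)
  cb <- generate_codebook(1, 10, "T1")
  st <- simulate_experiment(cfg, cb)
  # background sampled far from the (single) cell
  far <- st$cellmask == 0
  # erode the cell neighborhood: exclude pixels within 12 px of the cell
  ctr <- attr(st$cellmask, "centers")[1, ]
  rr <- row(st$cellmask) - 1; cc <- col(st$cellmask) - 1
  far <- far & (sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) >
                  cfg$cell_radius + 12)
  bg <- vapply(1:10, function(cyc) mean(st$images[, , 1, cyc][far]),
               numeric(1))
  expect_true(all(abs(bg - mean(bg)) < 1))  # photon-level stationarity
  # per-cycle true amplitude grows until the cap, then plateaus
  amp_cols <- paste0("amp_", 1:10)
  mean_amp <- colMeans(as.matrix(st$truth[, amp_cols]))
  expect_true(all(diff(mean_amp[1:5]) > 0))
  expect_equal(unname(mean_amp[6]), unname(mean_amp[10]), tolerance = 1e-9)
})

test_that("stacks round-trip through TIFF/CSV files", {
  cfg <- sim_config(n_cycles = 2, n_channels = 2, seed = 4,
                    image_size = c(96, 96), n_cells = 1, cell_radius = 20,
                    spots_per_cell_per_target = 3)
  cb <- generate_codebook(2, 2, c("A", "B"),
                          channel_names = c("Quasar570", "Cy5"))
  st <- simulate_experiment(cfg, cb)
  dir <- withr::local_tempdir()
  files <- write_stack(st, dir)
  expect_equal(sum(grepl("cycle[0-9]+_", basename(files))), 4L)
  st2 <- read_stack(dir, channel_names = cb$channel_names)
  # 16-bit quantization: integers survive exactly
  expect_equal(st2$images,
               array(pmin(pmax(round(st$images), 0), 65535),
                     dim = dim(st$images)))
  expect_identical(dim(st2$cellmask), dim(st$cellmask))
  expect_equal(unclass(st2$cellmask), unclass(st$cellmask),
               ignore_attr = TRUE)
  expect_equal(nrow(st2$truth), nrow(st$truth))
})
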
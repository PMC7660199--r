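# Synthetic multi-cycle, multi-channel FISH image generator with ground
# truth. Phenomena modeled: diffraction-limited Gaussian spots at fixed
# positions, per-cycle geometric signal amplification with a crowding
# saturation cap, photobleach residuals carried into the next cycle,
# cumulative inter-cycle stage drift, single-cycle non-specific spots,
# per-cycle dropout, Poisson shot noise and Gaussian read noise.

#' Simulation configuration
#'
#' Defaults describe a conservative epifluorescence setup: 160 nm pixels,
#' two-fold amplification per cycle from the two-landing-site probe design,
#' a 1% photobleach residual, and a 0.2% per-cycle staining dropout
#' (matching the ~99.8% third-cycle reappearance such chained probes
#' achieve).
#'
#' @param image_size `c(H, W)` in pixels.
#' @param pixel_size nm per pixel (default 160, so 2 px = 320 nm).
#' @param n_cycles,n_channels stack dimensions.
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param base_intensity peak photons of a cycle-1 spot (I0).
#' @param amplification fold signal growth per cycle (a; 2 = each probe
#'   recruits two).
#' @param saturation_cap maximum amplification fold (crowding plateau).
#' @param brightness_cv lognormal sigma of the per-spot brightness factor
#'   (hybridization-efficiency variation; factor has mean 1).
#' @param background mean background photons per pixel (cycle-independent).
#' @param bleach_residual fraction of the previous cycle's amplitude left
#'   unbleached and rendered into the current cycle's images, in [0, 1).
#' @param read_noise camera read noise rms, photons.
#' @param camera_offset constant camera offset added last, counts.
#' @param shot_noise logical; apply Poisson noise to signal + background.
#' @param drift_per_cycle `c(dy, dx)` stage drift per cycle, pixels; the
#'   cumulative drift at cycle c is `(c - 1) * drift_per_cycle`.
#' @param n_cells number of cells (non-overlapping disks).
#' @param cell_radius disk radius in pixels.
#' @param spots_per_cell_per_target Poisson mean spot count per cell and
#'   target.
#' @param min_separation minimum distance between specific spots of a cell,
#'   pixels (0 disables, for crowding studies).
#' @param nonspecific_rate expected single-cycle spurious spots per cell
#'   per cycle (Poisson).
#' @param dropout_prob per-cycle probability that a spot is not stained
#'   that cycle.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(image_size = c(192L, 192L),
                       pixel_size = 160,
                       n_cycles = 16L,
                       n_channels = 2L,
                       psf_sigma = 1.3,
                       base_intensity = 150,
                       amplification = 2,
                       saturation_cap = 64,
                       brightness_cv = 0.25,
                       background = 20,
                       bleach_residual = 0.01,
                       read_noise = 3,
                       camera_offset = 100,
                       shot_noise = TRUE,
                       drift_per_cycle = c(0, 0),
                       n_cells = 3L,
                       cell_radius = 34,
                       spots_per_cell_per_target = 8,
                       min_separation = 4,
                       nonspecific_rate = 2,
                       dropout_prob = 0.002,
                       seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
              n_cycles = as.integer(n_cycles),
              n_channels = as.integer(n_channels),
              psf_sigma = psf_sigma, base_intensity = base_intensity,
              amplification = amplification, saturation_cap = saturation_cap,
              brightness_cv = brightness_cv, background = background,
              bleach_residual = bleach_residual, read_noise = read_noise,
              camera_offset = camera_offset, shot_noise = shot_noise,
              drift_per_cycle = as.numeric(drift_per_cycle),
              n_cells = as.integer(n_cells), cell_radius = cell_radius,
              spots_per_cell_per_target = spots_per_cell_per_target,
              min_separation = min_separation,
              nonspecific_rate = nonspecific_rate,
              dropout_prob = dropout_prob, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$image_size) == 2L, all(cfg$image_size >= 16L),
            length(cfg$drift_per_cycle) == 2L)
  if (cfg$amplification < 1) stop("amplification must be >= 1", call. = FALSE)
  if (cfg$saturation_cap < 1) stop("saturation_cap must be >= 1", call. = FALSE)
  if (cfg$bleach_residual < 0 || cfg$bleach_residual >= 1)
    stop("bleach_residual must be in [0, 1)", call. = FALSE)
  nonneg <- c("psf_sigma", "base_intensity", "brightness_cv", "background",
              "read_noise", "spots_per_cell_per_target", "nonspecific_rate",
              "dropout_prob", "min_separation")
  for (f in nonneg) if (cfg[[f]] < 0)
    stop(sprintf("%s must be >= 0", f), call. = FALSE)
  invisible(cfg)
}

#' Expected peak amplitude at a given cycle
#'
#' Each decoding probe presents two landing sites, so the number of bound
#' fluorophores — and the spot amplitude — grows geometrically with cycle
#' until molecular crowding caps the complex size:
#' `I0 * min(a^(cycle - 1), cap)`.
#'
#' @param I0 cycle-1 peak amplitude, photons.
#' @param a amplification fold per cycle (>= 1).
#' @param cap saturation cap on the fold (>= 1).
#' @param cycle 1-based cycle index.
#' @return expected amplitude in photons.
#' @examples
#' expected_amplitude(100, 2, 64, 5)  # 1600
#' expected_amplitude(100, 2, 8, 16)  # 800 (plateau)
#' @export
expected_amplitude <- function(I0, a, cap, cycle) {
  stopifnot(all(cycle >= 1))
  I0 * pmin(a^(cycle - 1), cap)
}

#' Simulate a full multi-cycle experiment
#'
#' Renders a seeded, ground-truthed image stack. For every specific spot
#' and cycle c, an isotropic Gaussian of sigma `psf_sigma` is added in the
#' channel given by the target's codebook entry, with amplitude
#' [expected_amplitude()] times a fixed per-spot lognormal brightness
#' factor, at the spot's position plus cumulative drift — unless that
#' cycle dropped out. A fraction `bleach_residual` of the previous cycle's
#' amplitude is rendered into the current cycle's images in the previous
#' cycle's channel. Non-specific spots appear in a single random cycle and
#' channel at cycle-1 amplitude. Background, Poisson shot noise, Gaussian
#' read noise and the camera offset are applied last.
#'
#' @param config a [sim_config()].
#' @param codebook a [generate_codebook()] result; dimensions must match
#'   the config.
#' @return list of class `cycle_stack`: `images` (array `H x W x channels x
#'   cycles`, photon-count scale), `pixel_size`, `channel_names`,
#'   `cellmask` (H x W integer labels, 0 = background), `truth`
#'   (data.frame of ground-truth records), `config`.
#' @export
simulate_experiment <- function(config, codebook) {
  if (codebook$n_channels != config$n_channels ||
      codebook$n_cycles != config$n_cycles)
    stop("codebook dimensions do not match simulation config", call. = FALSE)
  set.seed(config$seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  nC <- config$n_cycles; nK <- config$n_channels

  cellmask <- place_cells(H, W, config$n_cells, config$cell_radius)
  truth <- draw_truth(config, codebook, cellmask)

  images <- array(0, dim = c(H, W, nK, nC))
  for (i in seq_len(nrow(truth))) {
    drift0 <- config$drift_per_cycle
    for (cyc in seq_len(nC)) {
      amp <- truth[[paste0("amp_", cyc)]][i]
      chan <- truth[[paste0("channel_", cyc)]][i]
      pos <- c(truth$row[i], truth$col[i]) + (cyc - 1) * drift0
      if (!is.na(chan) && amp > 0)
        images[, , chan + 1L, cyc] <-
          add_gaussian(images[, , chan + 1L, cyc], pos, amp, config$psf_sigma)
      # photobleach residual of the previous cycle's stain
      if (cyc > 1L && config$bleach_residual > 0) {
        amp_prev <- truth[[paste0("amp_", cyc - 1L)]][i]
        chan_prev <- truth[[paste0("channel_", cyc - 1L)]][i]
        if (!is.na(chan_prev) && amp_prev > 0)
          images[, , chan_prev + 1L, cyc] <-
            add_gaussian(images[, , chan_prev + 1L, cyc], pos,
                         config$bleach_residual * amp_prev, config$psf_sigma)
      }
    }
  }

  images <- images + config$background
  if (config$shot_noise) {
    n <- length(images)
    images <- array(stats::rpois(n, lambda = images), dim = dim(images))
  }
  if (config$read_noise > 0)
    images <- images + array(stats::rnorm(length(images),
                                          sd = config$read_noise),
                             dim = dim(images))
  images <- pmax(images + config$camera_offset, 0)

  structure(list(images = images, pixel_size = config$pixel_size,
                 channel_names = codebook$channel_names,
                 cellmask = cellmask, truth = truth, config = config),
            class = "cycle_stack")
}

#' @export
print.cycle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("cycle_stack: %d x %d px, %d channels (%s), %d cycles, %d truth records\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              d[4], if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

# non-overlapping disk cells on a labeled mask; deterministic under the
# caller's RNG state
place_cells <- function(H, W, n_cells, radius) {
  mask <- matrix(0L, H, W)
  if (n_cells == 0L) return(mask)
  centers <- matrix(NA_real_, 0, 2)
  margin <- radius + 2
  attempts <- 0L
  # coordinates are 0-based with pixel centers at integers
  while (nrow(centers) < n_cells && attempts < 5000L) {
    attempts <- attempts + 1L
    p <- c(stats::runif(1, margin, H - 1 - margin),
           stats::runif(1, margin, W - 1 - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, p)^2)) > 2 * radius + 4))
      centers <- rbind(centers, p)
  }
  if (nrow(centers) < n_cells)
    stop("could not place non-overlapping cells; reduce n_cells or cell_radius",
         call. = FALSE)
  rr <- row(mask) - 1L; cc <- col(mask) - 1L
  for (k in seq_len(n_cells)) {
    inside <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= radius^2
    mask[inside] <- k
  }
  attr(mask, "centers") <- centers
  mask
}

# sample spot positions and per-cycle staining truth
draw_truth <- function(config, codebook, cellmask) {
  centers <- attr(cellmask, "centers")
  nC <- config$n_cycles
  targets <- rownames(codebook$entries)
  rows <- list()
  sid <- 0L

  sample_in_cell <- function(center, existing, min_sep) {
    for (try in seq_len(200L)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- config$cell_radius * sqrt(stats::runif(1)) * 0.92
      p <- center + rad * c(cos(ang), sin(ang))
      if (min_sep <= 0 || nrow(existing) == 0 ||
          all(sqrt(rowSums(sweep(existing, 2, p)^2)) >= min_sep))
        return(p)
    }
    p  # accept a crowded position rather than fail
  }

  for (cell in seq_len(config$n_cells)) {
    placed <- matrix(NA_real_, 0, 2)
    for (tg in targets) {
      n_spots <- stats::rpois(1, config$spots_per_cell_per_target)
      colseq <- codebook$entries[tg, ]
      for (s in seq_len(n_spots)) {
        p <- sample_in_cell(centers[cell, ], placed, config$min_separation)
        placed <- rbind(placed, p)
        sid <- sid + 1L
        bright <- stats::rlnorm(1, meanlog = -config$brightness_cv^2 / 2,
                                sdlog = config$brightness_cv)
        present <- stats::runif(nC) >= config$dropout_prob
        amps <- ifelse(present,
                       expected_amplitude(config$base_intensity,
                                          config$amplification,
                                          config$saturation_cap,
                                          seq_len(nC)) * bright, 0)
        rows[[sid]] <- truth_row(sid, cell, tg, p, colseq, present, amps, nC)
      }
    }
    # single-cycle non-specific spots
    for (cyc in seq_len(nC)) {
      n_ns <- stats::rpois(1, config$nonspecific_rate)
      for (s in seq_len(n_ns)) {
        p <- sample_in_cell(centers[cell, ], placed, config$min_separation)
        placed <- rbind(placed, p)
        sid <- sid + 1L
        bright <- stats::rlnorm(1, meanlog = -config$brightness_cv^2 / 2,
                                sdlog = config$brightness_cv)
        chan <- sample.int(config$n_channels, 1) - 1L
        colseq <- rep(NA_integer_, nC); colseq[cyc] <- chan
        present <- seq_len(nC) == cyc
        amps <- ifelse(present, config$base_intensity * bright, 0)
        rows[[sid]] <- truth_row(sid, cell, "NONSPECIFIC", p, colseq,
                                 present, amps, nC)
      }
    }
  }
  if (length(rows) == 0L) return(empty_truth(nC))
  do.call(rbind, rows)
}

truth_row <- function(sid, cell, target, pos, colseq, present, amps, nC) {
  rec <- data.frame(spot_id = sid, cell_id = cell, target_id = target,
                    row = pos[1], col = pos[2],
                    color_seq = paste(ifelse(is.na(colseq), ".", colseq),
                                      collapse = "-"),
                    stringsAsFactors = FALSE)
  for (cyc in seq_len(nC)) {
    rec[[paste0("present_", cyc)]] <- as.integer(present[cyc])
    rec[[paste0("channel_", cyc)]] <-
      if (present[cyc]) as.integer(colseq[cyc]) else NA_integer_
    rec[[paste0("amp_", cyc)]] <- amps[cyc]
  }
  rec
}

empty_truth <- function(nC) {
  rec <- data.frame(spot_id = integer(0), cell_id = integer(0),
                    target_id = character(0), row = numeric(0),
                    col = numeric(0), color_seq = character(0))
  for (cyc in seq_len(nC)) {
    rec[[paste0("present_", cyc)]] <- integer(0)
    rec[[paste0("channel_", cyc)]] <- integer(0)
    rec[[paste0("amp_", cyc)]] <- numeric(0)
  }
  rec
}

# add an isotropic Gaussian (peak height `amp`) at sub-pixel position
# `pos` = c(row, col), 0-based pixel centers at integers
add_gaussian <- function(img, pos, amp, sigma) {
  H <- nrow(img); W <- ncol(img)
  half <- ceiling(5 * sigma)
  r0 <- max(0L, floor(pos[1]) - half); r1 <- min(H - 1L, ceiling(pos[1]) + half)
  c0 <- max(0L, floor(pos[2]) - half); c1 <- min(W - 1L, ceiling(pos[2]) + half)
  if (r0 > r1 || c0 > c1) return(img)
  rs <- r0:r1; cs <- c0:c1
  g <- amp * outer(exp(-(rs - pos[1])^2 / (2 * sigma^2)),
                   exp(-(cs - pos[2])^2 / (2 * sigma^2)))
  img[rs + 1L, cs + 1L] <- img[rs + 1L, cs + 1L] + g
  img
}

#' Write a cycle stack to disk
#'
#' One 16-bit TIFF per cycle per channel (`cycle{c}_{channel}.tif`), a
#' 16-bit label image `cellmask.tif`, `truth.csv` and a YAML echo of the
#' configuration.
#'
#' @param stack a `cycle_stack`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$images)
  files <- character(0)
  for (cyc in seq_len(d[4])) for (k in seq_len(d[3])) {
    f <- file.path(dir, sprintf("cycle%02d_%s.tif", cyc,
                                stack$channel_names[k]))
    img <- pmin(pmax(round(stack$images[, , k, cyc]), 0), 65535)
    tiff::writeTIFF(img / 65535, f, bits.per.sample = 16L,
                    compression = "none")
    files <- c(files, f)
  }
  if (!is.null(stack$cellmask)) {
    f <- file.path(dir, "cellmask.tif")
    tiff::writeTIFF(unclass(stack$cellmask) / 65535, f,
                    bits.per.sample = 16L, compression = "none")
    files <- c(files, f)
  }
  if (!is.null(stack$truth)) {
    f <- file.path(dir, "truth.csv")
    utils::write.csv(stack$truth, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(stack$config)) {
    f <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(stack$config), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a cycle stack from a directory of TIFFs
#'
#' Expects the [write_stack()] layout: `cycle{c}_{channel}.tif` images,
#' optional `cellmask.tif`, `truth.csv` and `config.yaml`.
#'
#' @param dir input directory.
#' @param channel_names optional; inferred from file names when NULL
#'   (alphabetical within each cycle unless `config.yaml` is present).
#' @return a `cycle_stack`.
#' @export
read_stack <- function(dir, channel_names = NULL) {
  fs <- list.files(dir, pattern = "^cycle[0-9]+_.+\\.tif$")
  if (length(fs) == 0L) stop("no cycle TIFFs found in ", dir, call. = FALSE)
  cyc <- as.integer(sub("^cycle([0-9]+)_.*$", "\\1", fs))
  chan <- sub("^cycle[0-9]+_(.+)\\.tif$", "\\1", fs)
  cfg <- NULL
  if (file.exists(file.path(dir, "config.yaml")))
    cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  if (is.null(channel_names)) channel_names <- sort(unique(chan))
  n_cycles <- max(cyc)
  probe <- tiff::readTIFF(file.path(dir, fs[1]))
  H <- nrow(probe); W <- ncol(probe)
  images <- array(0, dim = c(H, W, length(channel_names), n_cycles))
  for (i in seq_along(fs)) {
    k <- match(chan[i], channel_names)
    if (is.na(k)) stop("unexpected channel name in ", fs[i], call. = FALSE)
    images[, , k, cyc[i]] <-
      round(tiff::readTIFF(file.path(dir, fs[i])) * 65535)
  }
  cellmask <- NULL
  if (file.exists(file.path(dir, "cellmask.tif")))
    cellmask <- matrix(as.integer(round(
      tiff::readTIFF(file.path(dir, "cellmask.tif")) * 65535)), H, W)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv")))
    truth <- utils::read.csv(file.path(dir, "truth.csv"),
                             stringsAsFactors = FALSE)
  ps <- if (!is.null(cfg)) cfg$pixel_size else NA_real_
  structure(list(images = images, pixel_size = ps,
                 channel_names = channel_names, cellmask = cellmask,
                 truth = truth, config = cfg),
            class = "cycle_stack")
}
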
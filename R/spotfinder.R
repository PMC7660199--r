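# Spot detection, sub-pixel localization, aperture photometry and
# cycle-to-cycle drift registration. Coordinates are 0-based (row, col)
# with pixel centers at integers; sub-pixel positions are real-valued.

#' Detect diffraction-limited spots in a single image
#'
#' Scale-normalized Laplacian-of-Gaussian filtering at scale `psf_sigma`,
#' local maxima above `min_snr` times the robust (MAD) background rms of
#' the response, sub-pixel refinement by least-squares fit of a 2D
#' Gaussian (fixed sigma, free amplitude/offset/center) in a 7x7 window,
#' with an intensity-weighted centroid as fallback if the fit fails or
#' wanders. Detections closer than 2 px are merged keeping the brighter.
#'
#' @param image numeric matrix (photon counts or camera counts).
#' @param psf_sigma expected spot sigma in pixels.
#' @param min_snr detection threshold in units of background response rms.
#' @return data.frame with `row`, `col` (sub-pixel, 0-based), `peak_snr`
#'   (LoG response over robust background rms); zero rows when nothing is
#'   found.
#' @export
detect_spots <- function(image, psf_sigma, min_snr = 5) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0,
            psf_sigma > 0)
  resp <- log_response(image, psf_sigma)
  # center the response so flat regions sit at zero (the truncated kernel
  # does not sum exactly to zero)
  resp <- resp - stats::median(resp)
  bg_rms <- stats::mad(resp, center = 0)
  # guards for (near-)noise-free images where the MAD degenerates: filter
  # ripple around real spots and FFT round-off on flat channels must not
  # register as signal
  bg_rms <- max(bg_rms, 1e-3 * max(resp), 1e-8 * max(abs(image)),
                .Machine$double.eps)
  if (!is.finite(bg_rms))
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_snr = numeric(0)))

  mx <- local_max3(resp)
  cand <- which(mx & resp > min_snr * bg_rms, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_snr = numeric(0)))
  vals <- resp[cand]
  # enforce 2 px minimum separation, brighter wins
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= 4)
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]

  # neighbor-subtracted refinement: close same-channel spots bias a plain
  # Gaussian fit, so each candidate is fit on the image minus the modeled
  # tails of all other candidates
  med <- stats::median(image)
  amp_est <- image[cand] - med
  pos <- t(vapply(seq_len(nrow(cand)), function(i) {
    img_i <- subtract_neighbors(image, cand, amp_est, i, psf_sigma)
    refine_subpixel(img_i, cand[i, 1], cand[i, 2], psf_sigma)
  }, numeric(2)))
  data.frame(row = pos[, 1], col = pos[, 2], peak_snr = vals / bg_rms)
}

# negated, scale-normalized LoG response (blobs positive)
log_response <- function(image, sigma) {
  half <- max(2L, ceiling(4 * sigma))
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  # second-derivative-of-Gaussian 1D kernels; LoG = gxx*gy + gx*gyy
  g2 <- ((x^2 - sigma^2) / sigma^4) * exp(-x^2 / (2 * sigma^2))
  g2 <- g2 / sum(exp(-x^2 / (2 * sigma^2)))
  kern <- -sigma^2 * (outer(g2, g) + outer(g, g2))
  EBImage::filter2(image, kern, boundary = "replicate")
}

# strict-ish 3x3 local maxima: >= all 8 neighbors and > at least one,
# which rejects flat plateaus (e.g. constant background regions)
local_max3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- x
  ge_all <- matrix(TRUE, H, W)
  gt_any <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
    ge_all <- ge_all & (x >= nb)
    gt_any <- gt_any | (x > nb)
  }
  ge_all & gt_any & is.finite(x)
}

# remove the modeled Gaussian tails of all candidates except `i` (peak
# positions and amplitudes are the integer-pixel estimates)
subtract_neighbors <- function(image, cand, amp_est, i, sigma,
                               reach = 12) {
  others <- which(seq_len(nrow(cand)) != i &
                    abs(cand[, 1] - cand[i, 1]) <= reach &
                    abs(cand[, 2] - cand[i, 2]) <= reach)
  if (length(others) == 0L) return(image)
  for (j in others)
    image <- add_gaussian(image, c(cand[j, 1] - 1L, cand[j, 2] - 1L),
                          -amp_est[j], sigma)
  image
}

# sub-pixel refinement around an integer candidate (1-based matrix index);
# returns 0-based (row, col)
refine_subpixel <- function(image, ri, ci, sigma, half = 3L) {
  H <- nrow(image); W <- ncol(image)
  r0 <- max(1L, ri - half); r1 <- min(H, ri + half)
  c0 <- max(1L, ci - half); c1 <- min(W, ci + half)
  win <- image[r0:r1, c0:c1]
  rows0 <- (r0:r1) - 1L; cols0 <- (c0:c1) - 1L   # 0-based coordinates
  fit <- gauss2d_fit(win, rows0, cols0, ri - 1L, ci - 1L, sigma)
  if (!is.null(fit) &&
      abs(fit[1] - (ri - 1L)) <= half && abs(fit[2] - (ci - 1L)) <= half)
    return(fit)
  # fallback: background-subtracted intensity-weighted centroid
  w <- pmax(win - stats::median(win), 0)
  if (sum(w) <= 0) return(c(ri - 1, ci - 1))
  c(sum(rows0 * rowSums(w)) / sum(w), sum(cols0 * colSums(w)) / sum(w))
}

# least-squares 2D Gaussian with fixed sigma: A*exp(...) + b
gauss2d_fit <- function(win, rows0, cols0, r_init, c_init, sigma) {
  b0 <- stats::median(win)
  A0 <- max(win) - b0
  if (A0 <= 0) return(NULL)
  obj <- function(p) {
    model <- p[3] * outer(exp(-(rows0 - p[1])^2 / (2 * sigma^2)),
                          exp(-(cols0 - p[2])^2 / (2 * sigma^2))) + p[4]
    sum((model - win)^2)
  }
  res <- try(stats::optim(c(r_init, c_init, A0, b0), obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(res, "try-error") || res$convergence != 0) return(NULL)
  res$par[1:2]
}

#' Aperture photometry at a position, all channels
#'
#' For each channel of the given cycle: the pixel sum over a disk of
#' radius `aperture` centered at `position`, minus the disk area times the
#' median of an annulus (`annulus[1]`–`annulus[2]` px). Values can be
#' negative in channels holding only background. Positions closer than
#' the aperture radius to the border are edge-flagged and return `NA`s;
#' the background annulus is clipped to the image where needed.
#'
#' @param stack a `cycle_stack`.
#' @param cycle 1-based cycle index.
#' @param position `c(row, col)`, 0-based sub-pixel, cycle-local frame.
#' @param aperture disk radius, px (default 3).
#' @param annulus inner/outer background annulus radii, px (default
#'   `c(6, 9)`).
#' @return list: `intensity` (numeric vector, one per channel),
#'   `edge_flag` (logical).
#' @export
measure_intensities <- function(stack, cycle, position,
                                aperture = 3, annulus = c(6, 9)) {
  d <- dim(stack$images)
  H <- d[1]; W <- d[2]; nK <- d[3]
  margin <- aperture
  if (position[1] < margin || position[1] > H - 1 - margin ||
      position[2] < margin || position[2] > W - 1 - margin)
    return(list(intensity = rep(NA_real_, nK), edge_flag = TRUE))

  ri <- round(position[1]); ci <- round(position[2])
  half <- ceiling(annulus[2])
  rs <- max(0L, ri - half):min(H - 1L, ri + half)
  cs <- max(0L, ci - half):min(W - 1L, ci + half)
  dist <- sqrt(outer((rs - position[1])^2, (cs - position[2])^2, "+"))
  disk <- dist <= aperture
  ann <- dist >= annulus[1] & dist <= annulus[2]
  if (!any(ann)) ann <- dist > aperture   # tiny images: use what is there
  out <- numeric(nK)
  for (k in seq_len(nK)) {
    win <- stack$images[rs + 1L, cs + 1L, k, cycle]
    out[k] <- sum(win[disk]) - sum(disk) * stats::median(win[ann])
  }
  list(intensity = out, edge_flag = FALSE)
}

#' Estimate per-cycle drift offsets relative to the first cycle
#'
#' Translation-only registration by phase cross-correlation between each
#' cycle's channel-summed image and the reference cycle's, refined to 0.1
#' px by local upsampled discrete Fourier transform. The returned offset
#' for cycle c is the apparent displacement of features relative to the
#' reference, so `aligned = position - offset` maps a cycle-local
#' position into the reference (cycle-1) frame.
#'
#' @param stack a `cycle_stack`.
#' @param reference_cycle reference cycle (default 1).
#' @return data.frame with `cycle`, `dy`, `dx`, `low_confidence`
#'   (TRUE for degenerate/flat images, where the offset is forced to 0).
#' @export
register_cycles <- function(stack, reference_cycle = 1L) {
  d <- dim(stack$images)
  nC <- d[4]
  ref <- channel_sum(stack, reference_cycle)
  out <- data.frame(cycle = seq_len(nC), dy = 0, dx = 0,
                    low_confidence = FALSE)
  for (cyc in seq_len(nC)) {
    if (cyc == reference_cycle) next
    mov <- channel_sum(stack, cyc)
    if (stats::sd(mov) == 0 || stats::sd(ref) == 0) {
      out$low_confidence[cyc] <- TRUE
      next
    }
    sh <- phase_correlate(ref, mov, upsample = 10L)
    out$dy[cyc] <- sh[1]; out$dx[cyc] <- sh[2]
  }
  out
}

channel_sum <- function(stack, cycle) {
  d <- dim(stack$images)
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + stack$images[, , k, cycle]
  m
}

#' Sub-pixel translation between two images by phase correlation
#'
#' Returns `c(dy, dx)` such that `mov` looks like `ref` displaced by
#' `(dy, dx)` (features of `ref` at (r, c) appear in `mov` at
#' (r + dy, c + dx)). Coarse estimate from the cross-correlation peak,
#' refined on an upsampled DFT grid (step `1/upsample` px).
#'
#' @param ref,mov numeric matrices of identical size.
#' @param upsample sub-pixel refinement factor (10 = 0.1 px grid).
#' @return numeric `c(dy, dx)`.
#' @export
phase_correlate <- function(ref, mov, upsample = 10L) {
  stopifnot(all(dim(ref) == dim(mov)))
  nr <- nrow(ref); nc <- ncol(ref)
  F1 <- stats::fft(ref); F2 <- stats::fft(mov)
  prod <- F2 * Conj(F1)
  cc <- Re(stats::fft(prod, inverse = TRUE)) / (nr * nc)
  pk <- which.max(cc)
  pr <- (pk - 1L) %% nr; pc <- (pk - 1L) %/% nr
  if (pr > nr / 2) pr <- pr - nr
  if (pc > nc / 2) pc <- pc - nc
  if (upsample <= 1L) return(c(pr, pc))
  # refine within +/- 1 px of the coarse peak on the upsampled grid
  usfac <- as.integer(upsample)
  span <- ceiling(usfac * 1.5)
  rgrid <- pr + ((-span):span) / usfac
  cgrid <- pc + ((-span):span) / usfac
  cc_up <- Mod(upsampled_xcorr(prod, rgrid, cgrid))
  pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
  c(rgrid[pk2[1]], cgrid[pk2[2]])
}

# evaluate the inverse DFT of `spec` (an nr x nc spectrum) on arbitrary
# real shift grids via matrix-multiply DFT
upsampled_xcorr <- function(spec, rgrid, cgrid) {
  nr <- nrow(spec); nc <- ncol(spec)
  fr <- c(0:ceiling(nr / 2 - 1), -(floor(nr / 2)):-1)
  fc <- c(0:ceiling(nc / 2 - 1), -(floor(nc / 2)):-1)
  kr <- exp(2i * pi * outer(rgrid, fr) / nr)
  kc <- exp(2i * pi * outer(fc, cgrid) / nc)
  kr %*% spec %*% kc
}

#' Detect and measure spots across a whole stack
#'
#' Runs [detect_spots()] per channel per cycle, merges detections of the
#' same cycle lying within `merge_radius` px (keeping the position of the
#' brighter), measures all-channel intensities at each merged position,
#' and maps positions into the cycle-1 frame using [register_cycles()]
#' offsets.
#'
#' @param stack a `cycle_stack`.
#' @param psf_sigma spot sigma in px (defaults to the stack config's).
#' @param min_snr detection threshold (default 5).
#' @param offsets optional precomputed [register_cycles()] result.
#' @param merge_radius cross-channel merge radius, px (default 1).
#' @return list: `detections` (data.frame: `spot_id`, `cycle`, `row`,
#'   `col`, `aligned_row`, `aligned_col`, one `intensity_<channel>` column
#'   per channel, `peak_snr`, `edge_flag`), `offsets`.
#' @export
detect_stack <- function(stack, psf_sigma = NULL, min_snr = 5,
                         offsets = NULL, merge_radius = 1) {
  if (is.null(psf_sigma)) {
    psf_sigma <- stack$config$psf_sigma
    if (is.null(psf_sigma)) stop("psf_sigma required", call. = FALSE)
  }
  if (is.null(offsets)) offsets <- register_cycles(stack)
  d <- dim(stack$images)
  nC <- d[4]; nK <- d[3]
  rows <- list()
  sid <- 0L
  for (cyc in seq_len(nC)) {
    per_chan <- lapply(seq_len(nK), function(k)
      detect_spots(stack$images[, , k, cyc], psf_sigma, min_snr))
    merged <- merge_channel_detections(per_chan, merge_radius)
    if (nrow(merged) == 0L) next
    for (i in seq_len(nrow(merged))) {
      sid <- sid + 1L
      pos <- c(merged$row[i], merged$col[i])
      meas <- measure_intensities(stack, cyc, pos)
      rec <- data.frame(spot_id = sid, cycle = cyc,
                        row = pos[1], col = pos[2],
                        aligned_row = pos[1] - offsets$dy[cyc],
                        aligned_col = pos[2] - offsets$dx[cyc],
                        peak_snr = merged$peak_snr[i],
                        edge_flag = meas$edge_flag)
      for (k in seq_len(nK))
        rec[[paste0("intensity_", stack$channel_names[k])]] <-
          meas$intensity[k]
      rows[[sid]] <- rec
    }
  }
  detections <- if (length(rows)) do.call(rbind, rows) else
    empty_detections(stack$channel_names)
  rownames(detections) <- NULL
  list(detections = detections, offsets = offsets)
}

empty_detections <- function(channel_names) {
  rec <- data.frame(spot_id = integer(0), cycle = integer(0),
                    row = numeric(0), col = numeric(0),
                    aligned_row = numeric(0), aligned_col = numeric(0),
                    peak_snr = numeric(0), edge_flag = logical(0))
  for (ch in channel_names) rec[[paste0("intensity_", ch)]] <- numeric(0)
  rec
}

# merge per-channel detection tables of one cycle; brighter (higher LoG
# SNR) detection supplies the position
merge_channel_detections <- function(per_chan, radius) {
  all <- do.call(rbind, per_chan)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      peak_snr = numeric(0)))
  all <- all[order(all$peak_snr, decreasing = TRUE), , drop = FALSE]
  keep <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- all[keep, , drop = FALSE]
    d2 <- (prev$row - all$row[i])^2 + (prev$col - all$col[i])^2
    keep[i] <- all(d2 > radius^2)
  }
  all[keep, c("row", "col", "peak_snr"), drop = FALSE]
}
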
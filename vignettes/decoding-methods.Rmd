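---
title: "Encoding, simulating and decoding chained-probe sequential FISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding, simulating and decoding chained-probe sequential FISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainfish)
```

## The encoding model

Sequential FISH identifies each nucleic acid molecule by the ordered list
of fluorescence channels it shows across hybridization cycles. With $M$
fluorophores imaged per cycle and $N$ cycles, every molecule carries one
of $M^N$ possible color sequences, so a codebook of up to $M^N$ targets
can be read out: $2^{16} = 65{,}536$, $3^9 = 19{,}683$, $4^8 = 65{,}536$.
`capacity()` evaluates this in exact integer arithmetic (decimal digit
vectors) because the products quickly leave the range where doubles are
exact.

The scheme uses *raw* sequences — no error-correcting construction — so
`min_pairwise_hamming()` is a reporting metric only; a full codebook
always has distance 1. Targets are assigned sequences lexicographically
for determinism; an explicit entry table overrides this, which is how the
two-gene alternating-dye scheme (gene 1 in channel 0 on odd cycles and
channel 1 on even cycles, gene 2 the complement) is expressed.

## Probe chaining and geometric amplification

Each target is tiled by unlabeled 45-nt *pre-decoding* probes: a 20-nt
target-binding sequence, a 5T spacer, and a shared 20-nt landing site.
Labeled 70-nt *decoding* probes carry the reverse complement of the
previous tier's landing site followed by two identical copies of the next
landing site (each behind a 5T spacer). Every bound probe therefore
recruits two probes in the next cycle, and the staining intensity grows
geometrically with cycle number while the background does not.

Landing sites are drawn from a pool of validated orthogonal 20-mers, one
per target per cycle, so `pool_requirement(n_targets, n_cycles) =
n_targets * n_cycles` — profiling 30,000 targets over 8 cycles consumes
240,000 orthogonal sequences. One open design point: the final cycle's
probe still needs two 20-nt recruiting segments to keep the uniform 70-nt
architecture, but its landing is never used; we reuse that cycle's own
draw rather than spending an extra pool sequence, which keeps the
consumption arithmetic exactly $N$ per target. `crosshyb_screen()` flags
ordered pairs whose longest contiguous complementary run reaches a
configurable cutoff (default 12 nt — a conservative screening value; the
pool is assumed pre-validated, so this is a sanity check, not a designer).
Target-binding sequences themselves are user input (they come from
dedicated designers) and are validated only for length and alphabet.

## What the simulator emulates

`simulate_experiment()` renders seeded, ground-truthed stacks with the
phenomena that matter for decoding:

* **Diffraction-limited spots.** Isotropic Gaussians (default
  `psf_sigma = 1.3` px at 160 nm pixels, i.e. a ~210 nm sigma — typical
  for a high-NA epifluorescence setup). Positions are fixed across
  cycles; molecules are crosslinked in place.
* **Geometric amplification with a crowding cap.** Peak amplitude at
  cycle $c$ is $I_0 \min(a^{c-1}, \text{cap})$ with defaults $I_0 = 150$
  photons, $a = 2$ (two landing sites per probe) and cap 64: the probe
  complex eventually saturates in the crowded cellular environment and
  the intensity plateaus.
* **Per-spot brightness variation.** A lognormal factor (sigma 0.25,
  mean 1) fixed per molecule models hybridization-efficiency differences,
  bound proteins and secondary structure — the reason threshold-based
  calling fails and intensity *comparison* is used instead.
* **Photobleach residuals.** A fraction `bleach_residual` (default 0.01:
  photobleaching removes almost all signal) of the previous cycle's
  amplitude is rendered into the current cycle in the previous cycle's
  channel.
* **Drift.** Cumulative per-cycle stage drift `(dy, dx)`; cycle $c$
  positions are shifted by $(c-1)$ times the per-cycle drift.
* **Single-cycle non-specific spots.** Poisson-distributed per cell per
  cycle (default mean 2), one random channel, present in exactly one
  cycle — these are what the first-two-cycles rule rejects.
* **Dropout.** Each spot independently fails to stain in a cycle with
  probability 0.002, the complement of the ~99.8% third-cycle
  reappearance chained probes achieve.
* **Camera model.** Poisson shot noise on signal plus background (default
  20 photons/px), Gaussian read noise (3 photons rms), constant offset
  100 counts added last; 16-bit TIFF output.

Cells are non-overlapping disks (default 3 cells of radius 34 px in a
192 px field) with spots placed uniformly inside at a minimum separation
of 4 px by default, so the default conditions are free of unresolvable
pairs by construction; set `min_separation = 0` for crowding studies.
Default cycle/channel counts are 16 and 2, the deepest configuration used
for RNA readout. What the simulator does **not** emulate: real PSF
structure (Airy rings, aberrations), autofluorescence texture,
illumination flatness, 3D defocus (stacks are single-plane 2D) and
optical crowding beyond simple proximity. Passing tests on this generator
therefore demonstrate the correctness of the decoding logic under
controlled, realistic-scale noise — not performance on real tissue
images.

## Detection, photometry and registration

`detect_spots()` computes a scale-normalized Laplacian-of-Gaussian
response at the PSF scale, takes local maxima above `min_snr` (default 5)
times the robust (MAD) response rms, and enforces a 2 px minimum
separation keeping the brighter candidate. Sub-pixel positions come from
a least-squares 2D Gaussian fit (fixed sigma, free center, amplitude and
offset) in a 7×7 window, with an intensity-weighted centroid fallback.
Before each fit the modeled Gaussian tails of all *other* candidates are
subtracted from the window: without this, a same-channel neighbor 4–5 px
away biases the fitted center by over a pixel, enough to break
track-to-truth matching even though decoding itself is unaffected. Two
numerical guards matter on synthetic data: the LoG response is
median-centered (a truncated kernel does not sum exactly to zero), and
the noise floor is bounded below relative to both the response and the
image scale so that FFT round-off on noise-free or empty channels never
registers as signal.

Photometry (`measure_intensities()`) is classical aperture photometry:
disk of radius 3 px minus disk-area times the median of a 6–9 px annulus,
per channel, at one shared position — so a spot detected in any channel
yields a full intensity vector. Values in empty channels scatter around
zero and may be negative; that is intended, the caller compares, it does
not threshold.

Registration (`register_cycles()`) estimates a translation per cycle by
phase cross-correlation between channel-summed images, refined on an
upsampled DFT grid to 0.1 px. We use whole-image correlation rather than
a single fiducial spot: it recovers the same translation, uses all
molecules as fiducials, and has no single point of failure. Flat images
return a zero offset with a low-confidence flag. The offset is defined so
that `aligned = position - offset` maps cycle-local coordinates into the
cycle-1 frame.

## Linking, calling, decoding

`link_tracks()` seeds tracks from cycle-1 detections and extends each
cycle greedily in ascending distance with a strict 2.0 px radius (320 nm
at 160 nm pixels), one-to-one, ties broken by track creation order. A
globally optimal assignment would change nothing at single-molecule
densities and would cost determinism. Detections in later cycles that no
track claims are reported as orphans but never start tracks — a spot
absent from cycle 1 can never satisfy the real-signal rule, and keeping
the orphan count visible is itself a QC signal.

Channel calling is threshold-free: `call_color()` returns the argmax of
the intensity vector, flagged ambiguous when the best channel is not at
least 1.5 times the runner-up (the scheme gives no tie rule, so ambiguous
cycles make a track undecodable rather than guessed). Weak spots remain
callable — that is the point of comparing channels instead of
thresholding them.

Two flags implement the published counting rules separately:
`is_real_signal` (present in cycles 1 and 2 — rejects single-cycle
non-specific binders) and `is_complete` (present in every cycle — the
copy-number rule). `copy_number()` counts only complete, decoded tracks,
assigned to cells by anchor position against a label mask; the mask is an
explicit input because cell delineation is outside this package's scope
(the simulator provides one). `qc_metrics()` reports the reappearance
fractions, the cycles-present histogram and per-cycle intensity
summaries that mirror the published validation figures.

## Problem sizes and determinism

All stochastic tests run under fixed seeds on desk-scale problems:
192–256 px fields, 2–16 cycles, tens of spots for end-to-end runs,
thousands of Bernoulli tracks for the persistence statistics (10,000
tracks × 14 cycles; 5,000 spots for the reappearance check). These sizes
make binomial standard errors small relative to the margins being tested
while keeping the whole suite interactive. The simulator is bit-exact
reproducible from its config and seed; the linking, calling and decoding
stages are fully deterministic.

## Known limitations

* The detector assumes isolated or moderately spaced spots; overlapping
  pairs closer than ~3 px are merged, consistent with the crowding limit
  the chained-probe design itself has.
* Registration is translation-only, which matches stage drift; rotation
  or scale changes are out of scope.
* Decoding is exact-match against the codebook (no Hamming-ball
  correction), faithful to the raw-sequence design.
* Copy numbers depend on the supplied cell mask; mis-segmentation
  propagates directly into per-cell counts.
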
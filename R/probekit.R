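# Probe assembly for chained sequential FISH.
#
# Architecture: an unlabeled 45-nt pre-decoding probe carries a 20-nt
# target-binding sequence and a 20-nt landing site, separated by a 5T
# spacer. Each fluorophore-labeled decoding probe is 70 nt: a 20-nt segment
# binding the previous tier's landing site, then two identical 20-nt
# landing sites (each preceded by a 5T spacer) that together recruit two
# probes in the next cycle — the source of the geometric signal growth.

SPACER_5T <- "TTTTT"

assert_oligo <- function(seq, len = NULL, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(sprintf("%s contains characters outside {A,C,G,T}", what), call. = FALSE)
  if (!is.null(len) && nchar(seq) != len)
    stop(sprintf("%s must be exactly %d nt (got %d)", what, len, nchar(seq)),
         call. = FALSE)
  invisible(seq)
}

#' Watson-Crick reverse complement
#'
#' Thin wrapper over [Biostrings::reverseComplement()] restricted to
#' unambiguous DNA; validates the alphabet first.
#'
#' @param seq a single uppercase string over \{A,C,G,T\}.
#' @return the reverse complement, same length.
#' @examples
#' reverse_complement("ACGT")   # "ACGT"
#' reverse_complement("AAAAA")  # "TTTTT"
#' @export
reverse_complement <- function(seq) {
  assert_oligo(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Assemble a 45-nt pre-decoding probe
#'
#' `target_binding + TTTTT + landing`, both segments exactly 20 nt.
#'
#' @param target_binding 20-nt sequence complementary to the nucleic acid
#'   target (designed externally; validated here for length/alphabet only).
#' @param landing 20-nt landing site recruiting the cycle-1 decoding probe.
#' @return list of class `predecoding_probe` with `target_binding`,
#'   `landing`, `full_sequence` (45 nt).
#' @export
assemble_predecoding <- function(target_binding, landing) {
  assert_oligo(target_binding, 20L, "target_binding")
  assert_oligo(landing, 20L, "landing")
  structure(list(target_binding = target_binding,
                 landing = landing,
                 full_sequence = paste0(target_binding, SPACER_5T, landing)),
            class = "predecoding_probe")
}

#' Assemble a 70-nt decoding probe
#'
#' The probe binds the previous tier via the reverse complement of that
#' tier's landing site, and presents two identical copies of the next
#' landing site (`prev_binding + TTTTT + next_landing + TTTTT +
#' next_landing`), so each bound probe recruits two probes in the following
#' cycle.
#'
#' @param prev_landing 20-nt landing site of the previous tier.
#' @param next_landing 20-nt landing site this probe presents (twice).
#' @param cycle 1-based cycle index this probe is applied in.
#' @param channel 0-based fluorophore channel index of this probe's label.
#' @return list of class `decoding_probe` with `cycle_index`, `channel`,
#'   `prev_binding`, `next_landing`, `full_sequence` (70 nt).
#' @export
assemble_decoding <- function(prev_landing, next_landing, cycle, channel) {
  assert_oligo(prev_landing, 20L, "prev_landing")
  assert_oligo(next_landing, 20L, "next_landing")
  prev_binding <- reverse_complement(prev_landing)
  structure(list(cycle_index = as.integer(cycle),
                 channel = as.integer(channel),
                 prev_binding = prev_binding,
                 next_landing = next_landing,
                 full_sequence = paste0(prev_binding, SPACER_5T,
                                        next_landing, SPACER_5T, next_landing)),
            class = "decoding_probe")
}

#' Create an orthogonal sequence pool
#'
#' A validated pool of mutually orthogonal 20-nt sequences from which
#' landing sites are drawn; `consumed` tracks how many have been used.
#' One landing site is drawn per target per cycle, so profiling
#' `n_targets` over `n_cycles` cycles consumes
#' `n_targets * n_cycles` sequences (e.g. 30,000 targets x 8 cycles =
#' 240,000).
#'
#' @param sequences character vector of unique 20-nt sequences.
#' @return environment of class `orthogonal_pool` with `sequences` and
#'   `consumed` (mutable draw counter).
#' @export
orthogonal_pool <- function(sequences) {
  sequences <- as.character(sequences)
  for (s in sequences) assert_oligo(s, 20L, "pool sequence")
  if (anyDuplicated(sequences))
    stop("orthogonal pool sequences must be unique", call. = FALSE)
  pool <- new.env(parent = emptyenv())
  pool$sequences <- sequences
  pool$consumed <- 0L
  class(pool) <- "orthogonal_pool"
  pool
}

#' @export
print.orthogonal_pool <- function(x, ...) {
  cat(sprintf("orthogonal pool: %d/%d sequences consumed\n",
              x$consumed, length(x$sequences)))
  invisible(x)
}

pool_draw <- function(pool, n) {
  remaining <- length(pool$sequences) - pool$consumed
  if (n > remaining)
    stop(sprintf("orthogonal pool exhausted: need %d sequences, %d remain",
                 n, remaining), call. = FALSE)
  idx <- pool$consumed + seq_len(n)
  pool$consumed <- pool$consumed + as.integer(n)
  pool$sequences[idx]
}

#' Orthogonal sequences required for an experiment
#'
#' One landing site per target per cycle: `n_targets * n_cycles`.
#'
#' @param n_targets number of targets profiled.
#' @param n_cycles number of hybridization cycles.
#' @return the required pool size (numeric, exact).
#' @examples
#' pool_requirement(30000, 8)  # 240000
#' @export
pool_requirement <- function(n_targets, n_cycles) {
  if (!is.finite(n_targets) || !is.finite(n_cycles) ||
      n_targets < 1 || n_cycles < 1)
    stop("pool_requirement(): counts must be positive", call. = FALSE)
  as.numeric(n_targets) * as.numeric(n_cycles)
}

#' Build the full probe series for one target
#'
#' Draws `n_cycles` landing sites from the pool: the first doubles as the
#' pre-decoding landing (so the cycle-1 decoding probe binds the
#' pre-decoding tier), and each decoding probe at cycle c binds the landing
#' of tier c-1 and presents the landing for cycle c+1 (the last cycle's
#' probe presents a terminal landing that is never used but keeps the
#' 70-nt architecture uniform — it is the cycle-c draw itself reused, not
#' an extra draw).
#'
#' @param target_id target identifier.
#' @param color_sequence integer vector of 0-based channel indices, one per
#'   cycle (the target's codebook entry).
#' @param target_binding_sites character vector of 20-nt target-binding
#'   sequences (real designs tile >30 per transcript).
#' @param pool an [orthogonal_pool()]; consumed by `length(color_sequence)`.
#' @return list of class `probe_series` with `target_id`, `pre_decoding`
#'   (list of `predecoding_probe`), `decoding` (list of `decoding_probe`,
#'   one per cycle).
#' @export
build_probe_series <- function(target_id, color_sequence,
                               target_binding_sites, pool) {
  n_cycles <- length(color_sequence)
  if (n_cycles < 1L) stop("color_sequence must be non-empty", call. = FALSE)
  if (length(target_binding_sites) < 1L)
    stop("need at least one target-binding site", call. = FALSE)
  landings <- pool_draw(pool, n_cycles)

  pre <- lapply(target_binding_sites, function(tb)
    assemble_predecoding(tb, landings[1L]))

  dec <- vector("list", n_cycles)
  for (c in seq_len(n_cycles)) {
    prev_landing <- landings[c]
    # terminal cycle presents its own landing again; no further draw
    next_landing <- if (c < n_cycles) landings[c + 1L] else landings[c]
    dec[[c]] <- assemble_decoding(prev_landing, next_landing,
                                  cycle = c, channel = color_sequence[c])
  }
  structure(list(target_id = as.character(target_id),
                 pre_decoding = pre, decoding = dec),
            class = "probe_series")
}

#' Screen a sequence set for cross-hybridization
#'
#' Flags every ordered pair (i, j), i != j, whose longest contiguous
#' complementary run — the longest common substring between sequence i and
#' the reverse complement of sequence j, at any offset — is at least
#' `max_run` bases.
#'
#' @param sequences character vector (>= 2) of probe/landing sequences.
#' @param max_run minimum complementary run length to flag (default 12, a
#'   conservative screening cutoff; configurable).
#' @return data.frame with columns `i`, `j` (1-based indices), `run`
#'   (longest complementary run), one row per flagged ordered pair.
#' @export
crosshyb_screen <- function(sequences, max_run = 12L) {
  sequences <- as.character(sequences)
  if (length(sequences) < 2L)
    stop("crosshyb_screen() needs >= 2 sequences", call. = FALSE)
  for (s in sequences) assert_oligo(s)
  n <- length(sequences)
  rcs <- vapply(sequences, reverse_complement, character(1L))
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    run <- longest_common_substring(sequences[i], rcs[j])
    if (run >= max_run)
      out[[length(out) + 1L]] <- data.frame(i = i, j = j, run = run)
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(0), j = integer(0), run = integer(0)))
  do.call(rbind, out)
}

longest_common_substring <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  na <- length(av); nb <- length(bv)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(bv == av[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

#' Export assembled probes as FASTA
#'
#' Record ids: `<target>_predec_<k>` for pre-decoding probes and
#' `<target>_dec_cycle<N>_<channel>` for decoding probes.
#'
#' @param series_list list of `probe_series` objects.
#' @param path output FASTA path.
#' @param channel_names optional fluorophore names used in decoding-probe
#'   record ids (falls back to the 0-based channel index).
#' @export
write_probes_fasta <- function(series_list, path, channel_names = NULL) {
  if (inherits(series_list, "probe_series")) series_list <- list(series_list)
  ids <- character(0); seqs <- character(0)
  for (ps in series_list) {
    for (k in seq_along(ps$pre_decoding)) {
      ids <- c(ids, sprintf("%s_predec_%d", ps$target_id, k))
      seqs <- c(seqs, ps$pre_decoding[[k]]$full_sequence)
    }
    for (dp in ps$decoding) {
      chan <- if (!is.null(channel_names)) channel_names[dp$channel + 1L]
              else as.character(dp$channel)
      ids <- c(ids, sprintf("%s_dec_cycle%d_%s", ps$target_id,
                            dp$cycle_index, chan))
      seqs <- c(seqs, dp$full_sequence)
    }
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an orthogonal pool from FASTA or plain text
#'
#' @param path FASTA file (`.fa`/`.fasta`) or one-sequence-per-line text.
#' @return an [orthogonal_pool()].
#' @export
read_pool <- function(path) {
  ext <- tolower(tools::file_ext(path))
  seqs <- if (ext %in% c("fa", "fasta", "fna")) {
    as.character(Biostrings::readDNAStringSet(path))
  } else {
    x <- readLines(path)
    x[nzchar(trimws(x))]
  }
  orthogonal_pool(toupper(trimws(unname(seqs))))
}
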
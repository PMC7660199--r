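#' Multiplexing capacity of a combinatorial color code
#'
#' With `n_channels` fluorophores imaged per hybridization cycle and
#' `n_cycles` cycles, each molecule displays one of
#' `n_channels ^ n_cycles` distinct color sequences, so that many targets
#' can in principle be distinguished (e.g. 2 colors and 16 cycles give
#' 65,536; 3 colors and 9 cycles give 19,683).
#'
#' The power is evaluated in exact integer arithmetic (decimal digit
#' vectors), so values beyond the 2^53 exact-double range (e.g. 4^30) are
#' still exact.
#'
#' @param n_channels number of fluorescence channels per cycle (>= 1).
#' @param n_cycles number of hybridization cycles (>= 1).
#' @return The exact value of `n_channels ^ n_cycles`: a numeric scalar when
#'   exactly representable as a double, otherwise a character string of the
#'   exact decimal digits.
#' @examples
#' capacity(2, 16)  # 65536
#' capacity(3, 9)   # 19683
#' capacity(4, 30)  # exact, returned as a string
#' @export
capacity <- function(n_channels, n_cycles) {
  stopifnot(length(n_channels) == 1L, length(n_cycles) == 1L)
  if (!is.finite(n_channels) || !is.finite(n_cycles) ||
      n_channels < 1 || n_cycles < 1 ||
      n_channels != floor(n_channels) || n_cycles != floor(n_cycles)) {
    stop("capacity(): n_channels and n_cycles must be positive integers",
         call. = FALSE)
  }
  digits <- bigint_pow(as.integer(n_channels), as.integer(n_cycles))
  bigint_collapse(digits)
}

# exact non-negative integer power as little-endian base-10 digit vector
bigint_pow <- function(base, exponent) {
  result <- 1L
  b <- bigint_from_int(base)
  for (i in seq_len(exponent)) {
    result <- bigint_mul(if (i == 1L) b else result, if (i == 1L) bigint_from_int(1L) else b)
  }
  result
}

bigint_from_int <- function(x) {
  if (x == 0L) return(0L)
  d <- integer(0)
  while (x > 0L) {
    d <- c(d, x %% 10L)
    x <- x %/% 10L
  }
  d
}

bigint_mul <- function(a, b) {
  res <- integer(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0L) next
    res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
  }
  carry <- 0L
  for (k in seq_along(res)) {
    v <- res[k] + carry
    res[k] <- v %% 10L
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    res <- c(res, carry %% 10L)
    carry <- carry %/% 10L
  }
  while (length(res) > 1L && res[length(res)] == 0L) res <- res[-length(res)]
  res
}

bigint_collapse <- function(digits) {
  s <- paste(rev(digits), collapse = "")
  # exact in a double iff < 2^53
  if (nchar(s) <= 15L) return(as.numeric(s))
  v <- suppressWarnings(as.numeric(s))
  if (!is.na(v) && v < 2^53 && sprintf("%.0f", v) == s) v else s
}

#' Construct a color-sequence codebook
#'
#' A codebook maps target identifiers to length-`n_cycles` color sequences
#' over `n_channels` channels (0-based channel indices). Targets are
#' assigned sequences in lexicographic order of the sequences and input
#' order of the targets, which makes generation deterministic. An explicit
#' `entries` matrix overrides the lexicographic assignment; this is how
#' non-lexicographic schemes (e.g. two genes alternating between two dyes
#' across 16 cycles) are expressed.
#'
#' @param n_channels number of fluorescence channels per cycle.
#' @param n_cycles number of hybridization cycles.
#' @param target_ids character vector of unique target identifiers.
#' @param channel_names optional character vector of fluorophore names, one
#'   per channel (e.g. `c("Alexa488", "Quasar570", "Cy5")`).
#' @param entries optional integer matrix (`length(target_ids)` rows x
#'   `n_cycles` columns) of 0-based channel indices giving each target's
#'   color sequence explicitly.
#' @return An object of class `codebook`: a list with `n_channels`,
#'   `n_cycles`, `channel_names` and `entries` (integer matrix, rownames =
#'   target ids, 0-based channel index per cycle).
#' @examples
#' cb <- generate_codebook(2, 2, c("A", "B", "C", "D"))
#' cb$entries
#' @export
generate_codebook <- function(n_channels, n_cycles, target_ids,
                              channel_names = NULL, entries = NULL) {
  if (n_channels < 1 || n_cycles < 1)
    stop("n_channels and n_cycles must be >= 1", call. = FALSE)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(target_ids))
    stop("duplicate target ids", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(n_channels) - 1L)
  if (length(channel_names) != n_channels)
    stop("channel_names must have one entry per channel", call. = FALSE)

  n <- length(target_ids)
  if (is.null(entries)) {
    cap <- capacity(n_channels, n_cycles)
    # a capacity too large for a double always exceeds any vector length
    if (!is.character(cap) && n > cap)
      stop(sprintf("capacity exceeded: %d targets > %s sequences", n,
                   format(cap, big.mark = ",")), call. = FALSE)
    entries <- lexicographic_sequences(n_channels, n_cycles, n)
  } else {
    entries <- as.matrix(entries)
    storage.mode(entries) <- "integer"
    if (nrow(entries) != n || ncol(entries) != n_cycles)
      stop("entries must be length(target_ids) x n_cycles", call. = FALSE)
  }
  rownames(entries) <- target_ids
  colnames(entries) <- paste0("cycle_", seq_len(n_cycles))
  cb <- structure(list(n_channels = as.integer(n_channels),
                       n_cycles = as.integer(n_cycles),
                       channel_names = as.character(channel_names),
                       entries = entries),
                  class = "codebook")
  validate_codebook(cb)
  cb
}

# first n color sequences in lexicographic order, as 0-based indices
lexicographic_sequences <- function(n_channels, n_cycles, n) {
  out <- matrix(0L, nrow = n, ncol = n_cycles)
  if (n == 0L) return(out)
  seq0 <- integer(n_cycles)
  for (i in seq_len(n)) {
    out[i, ] <- seq0
    # increment rightmost position, base n_channels
    j <- n_cycles
    while (j >= 1L) {
      seq0[j] <- seq0[j] + 1L
      if (seq0[j] < n_channels) break
      seq0[j] <- 0L
      j <- j - 1L
    }
  }
  out
}

validate_codebook <- function(cb) {
  e <- cb$entries
  if (any(e < 0L) || any(e >= cb$n_channels))
    stop("codebook entries contain channel indices out of range", call. = FALSE)
  keys <- apply(e, 1L, paste, collapse = ",")
  if (anyDuplicated(keys))
    stop("codebook entries are not distinct", call. = FALSE)
  invisible(cb)
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d targets, %d channels x %d cycles (capacity %s)\n",
              nrow(x$entries), x$n_channels, x$n_cycles,
              format(capacity(x$n_channels, x$n_cycles), big.mark = ",")))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  utils::head(x$entries)
  invisible(x)
}

#' Minimum pairwise Hamming distance of a codebook
#'
#' Reporting-only QC metric: the smallest number of cycles in which any two
#' targets' color sequences differ. The encoding itself uses raw sequences
#' without error correction, so a distance of 1 is normal for a full book.
#'
#' @param codebook a `codebook` object with at least two entries.
#' @return integer minimum Hamming distance over all entry pairs.
#' @export
min_pairwise_hamming <- function(codebook) {
  e <- codebook$entries
  n <- nrow(e)
  if (n < 2L) stop("min_pairwise_hamming() needs >= 2 entries", call. = FALSE)
  best <- ncol(e)
  for (i in seq_len(n - 1L)) {
    d <- rowSums(e[(i + 1L):n, , drop = FALSE] !=
                   matrix(e[i, ], nrow = n - i, ncol = ncol(e), byrow = TRUE))
    best <- min(best, d)
    if (best == 1L) break
  }
  as.integer(best)
}

#' Write a codebook to CSV
#'
#' Columns: `target_id`, `cycle_1` .. `cycle_N`, with the fluorophore name
#' (not the index) per cycle.
#'
#' @param codebook a `codebook` object.
#' @param path output CSV path.
#' @export
write_codebook <- function(codebook, path) {
  e <- codebook$entries
  df <- data.frame(target_id = rownames(e), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(e)))
    df[[paste0("cycle_", j)]] <- codebook$channel_names[e[, j] + 1L]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a codebook from CSV
#'
#' Inverse of [write_codebook()]. Channel names are taken from `channel_names`
#' if given, otherwise from the sorted set of names appearing in the file.
#'
#' @param path CSV path with columns `target_id`, `cycle_1..cycle_N`.
#' @param channel_names optional channel name vector fixing the channel order.
#' @return a `codebook` object.
#' @export
read_codebook <- function(path, channel_names = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"target_id" %in% names(df))
    stop("codebook CSV must have a target_id column", call. = FALSE)
  cyc_cols <- grep("^cycle_[0-9]+$", names(df), value = TRUE)
  cyc_cols <- cyc_cols[order(as.integer(sub("cycle_", "", cyc_cols)))]
  if (length(cyc_cols) == 0L)
    stop("codebook CSV must have cycle_1..cycle_N columns", call. = FALSE)
  seen <- unique(unlist(df[cyc_cols], use.names = FALSE))
  if (is.null(channel_names)) channel_names <- sort(seen)
  if (!all(seen %in% channel_names))
    stop("codebook CSV contains channel names not in channel_names", call. = FALSE)
  entries <- vapply(cyc_cols, function(cc)
    match(df[[cc]], channel_names) - 1L, integer(nrow(df)))
  entries <- matrix(entries, nrow = nrow(df),
                    dimnames = list(df$target_id, cyc_cols))
  generate_codebook(length(channel_names), length(cyc_cols), df$target_id,
                    channel_names = channel_names, entries = entries)
}

#' Look up a color sequence in a codebook
#'
#' @param codebook a `codebook` object.
#' @param color_sequence integer vector of 0-based channel indices,
#'   length `n_cycles`.
#' @return the matching target id, or `NA_character_` when absent.
#' @export
lookup_sequence <- function(codebook, color_sequence) {
  if (length(color_sequence) != codebook$n_cycles) return(NA_character_)
  key <- paste(as.integer(color_sequence), collapse = ",")
  keys <- apply(codebook$entries, 1L, paste, collapse = ",")
  hit <- match(key, keys)
  if (is.na(hit)) NA_character_ else rownames(codebook$entries)[hit]
}
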
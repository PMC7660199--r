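test_that("reverse_complement is correct and an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAAA"), "TTTTT")
  expect_error(reverse_complement("ACGU"), "outside")
  for (s in random_oligos(10, len = 25, seed = 5))
    expect_identical(reverse_complement(reverse_complement(s)), s)
})

test_that("pre-decoding probes are 45 nt with a literal 5T spacer", {
  p <- assemble_predecoding(strrep("A", 20), strrep("C", 20))
  expect_identical(p$full_sequence,
                   paste0(strrep("A", 20), "TTTTT", strrep("C", 20)))
  expect_equal(nchar(p$full_sequence), 45L)
  expect_error(assemble_predecoding(strrep("A", 19), strrep("C", 20)),
               "exactly 20")
  for (i in 1:5) {
    segs <- random_oligos(2, seed = 100 + i)
    expect_equal(nchar(assemble_predecoding(segs[1], segs[2])$full_sequence),
                 45L)
  }
})

test_that("decoding probes are 70 nt with two identical recruiting segments", {
  d <- assemble_decoding(strrep("A", 20), strrep("G", 20), 2, 1)
  expect_identical(d$prev_binding, strrep("T", 20))
  expect_equal(nchar(d$full_sequence), 70L)
  # the two next-cycle landing copies are identical ("shared sequences")
  seg2 <- substr(d$full_sequence, 26, 45)
  seg3 <- substr(d$full_sequence, 51, 70)
  expect_identical(seg2, seg3)
  expect_identical(seg2, d$next_landing)
  for (i in 1:5) {
    segs <- random_oligos(2, seed = 200 + i)
    dd <- assemble_decoding(segs[1], segs[2], 1, 0)
    expect_equal(nchar(dd$full_sequence), 70L)
    expect_identical(dd$prev_binding, reverse_complement(segs[1]))
  }
})

test_that("probe series chain across cycles by exact 20/20 hybridization", {
  pool <- orthogonal_pool(random_oligos(40, seed = 3))
  tb <- random_oligos(3, seed = 4)
  colseq <- c(0L, 1L, 0L, 2L, 1L, 0L, 2L, 2L)
  ps <- build_probe_series("GAPDH", colseq, tb, pool)

  expect_equal(pool$consumed, 8L)
  expect_length(ps$pre_decoding, 3L)
  expect_length(ps$decoding, 8L)
  # cycle-1 probe binds the shared pre-decoding landing site
  landings <- unique(vapply(ps$pre_decoding, function(p) p$landing, ""))
  expect_length(landings, 1L)
  expect_identical(ps$decoding[[1]]$prev_binding,
                   reverse_complement(landings))
  # cycle c+1 binds the landing presented by cycle c
  for (c in 1:7)
    expect_identical(ps$decoding[[c + 1]]$prev_binding,
                     reverse_complement(ps$decoding[[c]]$next_landing))
  # channels follow the color sequence
  expect_identical(vapply(ps$decoding, function(d) d$channel, integer(1)),
                   colseq)
  # all lengths exact
  expect_true(all(vapply(ps$pre_decoding,
                         function(p) nchar(p$full_sequence), 0) == 45))
  expect_true(all(vapply(ps$decoding,
                         function(d) nchar(d$full_sequence), 0) == 70))
})

test_that("pool accounting is one draw per target per cycle", {
  expect_equal(pool_requirement(30000, 8), 240000)
  expect_equal(pool_requirement(1, 1), 1)
  expect_equal(pool_requirement(2, 16), 32)
  expect_error(pool_requirement(0, 8), "positive")

  pool <- orthogonal_pool(random_oligos(25, seed = 8))
  for (k in 1:3)
    build_probe_series(paste0("t", k), c(0L, 1L, 0L, 1L),
                       random_oligos(1, seed = 50 + k), pool)
  expect_equal(pool$consumed, 12L)  # 3 targets x 4 cycles

  small <- orthogonal_pool(random_oligos(5, seed = 9))
  expect_error(build_probe_series("t", rep(0L, 8),
                                  random_oligos(1, seed = 10), small),
               "exhausted")
})

test_that("cross-hybridization screening matches a quadratic substring oracle", {
  s <- random_oligos(1, seed = 11)
  pair <- c(s, reverse_complement(s))
  rep1 <- crosshyb_screen(pair, max_run = 12)
  expect_equal(nrow(rep1), 2L)          # both ordered directions
  expect_true(all(rep1$run == 20L))

  expect_equal(nrow(crosshyb_screen(c(strrep("A", 20), strrep("A", 20)),
                                    max_run = 12)), 0L)

  # oracle: enumerate all substrings of s1, test presence in revcomp(s2)
  oracle_run <- function(s1, s2) {
    rc2 <- reverse_complement(s2)
    best <- 0L
    for (len in seq_len(nchar(s1))) {
      hit <- FALSE
      for (st in seq_len(nchar(s1) - len + 1L))
        if (grepl(substr(s1, st, st + len - 1L), rc2, fixed = TRUE)) {
          hit <- TRUE; break
        }
      if (hit) best <- len else break
    }
    best
  }
  seqs <- random_oligos(6, len = 18, seed = 12)
  rep2 <- crosshyb_screen(seqs, max_run = 5)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    run <- oracle_run(seqs[i], seqs[j])
    flagged <- any(rep2$i == i & rep2$j == j)
    expect_identical(flagged, run >= 5L)
    if (flagged) expect_equal(rep2$run[rep2$i == i & rep2$j == j], run)
  }
})

test_that("FASTA export round-trips through the pool reader", {
  pool <- orthogonal_pool(random_oligos(10, seed = 13))
  ps <- build_probe_series("Ki67", c(1L, 0L), random_oligos(2, seed = 14),
                           pool)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_probes_fasta(ps, path, channel_names = c("Quasar570", "Cy5"))
  recs <- Biostrings::readDNAStringSet(path)
  expect_equal(length(recs), 4L)  # 2 pre-decoding + 2 decoding
  expect_true(all(grepl("^Ki67_(predec_[12]|dec_cycle[12]_(Quasar570|Cy5))$",
                        names(recs))))
  expect_equal(unname(nchar(as.character(recs))), c(45L, 45L, 70L, 70L))

  # pool reader accepts plain one-sequence-per-line text
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(random_oligos(4, seed = 15), txt)
  p2 <- read_pool(txt)
  expect_equal(length(p2$sequences), 4L)
  expect_equal(p2$consumed, 0L)
})
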
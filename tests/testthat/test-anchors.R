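anchor_fixture <- function() {
  seqs <- SequenceSet(c(alpha = "MKVLITA", beta = "MKVLSTA",
                        gamma = "GMKVLTT"), alphabet = "protein")
  cols <- ColumnSet(list(rbind(c(0, 0), c(1, 0), c(2, 1)),
                         rbind(c(0, 1), c(1, 1), c(2, 2)),
                         rbind(c(0, 3), c(1, 3))),
                    seqIds = seqIds(seqs))
  list(seqs = seqs, cols = cols)
}

test_that("segments are the maximal diagonal runs of column pairs", {
  ## two consecutive column pairs merge into one length-2 segment
  cs <- ColumnSet(list(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1), c(1, 1))),
                  seqIds = c("a", "b"))
  segs <- extractSegments(cs)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$length, 2L)
  expect_equal(c(segs$startA, segs$startB), c(0L, 0L))

  ## a positional gap breaks the run
  cs2 <- ColumnSet(list(rbind(c(0, 0), c(1, 0)), rbind(c(0, 2), c(1, 2))),
                   seqIds = c("a", "b"))
  segs2 <- extractSegments(cs2)
  expect_equal(nrow(segs2), 2L)
  expect_true(all(segs2$length == 1L))

  ## one 3-sequence column expands to one segment per sequence pair
  cs3 <- ColumnSet(list(rbind(c(0, 3), c(1, 5), c(2, 7))),
                   seqIds = c("a", "b", "c"))
  segs3 <- extractSegments(cs3)
  expect_equal(nrow(segs3), 3L)
  expect_equal(paste(segs3$seqA, segs3$seqB), c("0 1", "0 2", "1 2"))
  expect_true(all(segs3$length == 1L))
})

test_that("segment coverage round-trips the within-column pairs", {
  set.seed(21)
  for (rep in 1:25) {
    cs <- random_columnset(nseq = 4L)
    segs <- extractSegments(cs)
    ## site pairs covered by segments
    covered <- character(0)
    if (nrow(segs)) for (i in seq_len(nrow(segs))) {
      t <- seq_len(segs$length[i]) - 1L
      covered <- c(covered, paste(segs$seqA[i], segs$startA[i] + t,
                                  segs$seqB[i], segs$startB[i] + t))
    }
    ## within-column pairs
    want <- character(0)
    for (m in columns(cs)) {
      if (nrow(m) < 2L) next
      pr <- utils::combn(nrow(m), 2L)
      want <- c(want, paste(m[pr[1L, ], 1L], m[pr[1L, ], 2L],
                            m[pr[2L, ], 1L], m[pr[2L, ], 2L]))
    }
    expect_setequal(covered, want)
    expect_equal(anyDuplicated(covered), 0L)
    ## maximality: no two segments of one pair are adjacent on a diagonal
    if (nrow(segs) >= 2L) {
      key <- paste(segs$seqA, segs$seqB, segs$startA - segs$startB)
      for (kk in unique(key)) {
        q <- segs[key == kk, ]
        if (nrow(q) < 2L) next
        q <- q[order(q$startA), ]
        expect_true(all(q$startA[-1L] > (q$startA + q$length)[-nrow(q)]))
      }
    }
  }
})

test_that("weighting schemes follow the published rules exactly", {
  fx <- anchor_fixture()
  segs <- extractSegments(fx$cols)
  w1 <- weightSegments(segs, "length10")
  expect_equal(w1$weight, 10 * w1$length)
  expect_equal(w1$weight[w1$length == 2L][1], 20)
  w2 <- weightSegments(segs, "tcoffee_uniform", nSeqs = 5)
  expect_true(all(w2$weight == 500))
  expect_error(weightSegments(segs, "tcoffee_uniform"), "nSeqs")
  expect_error(weightSegments(segs, "no_such_scheme"))
})

test_that("anchor writers byte-match their golden files and are deterministic", {
  fx <- anchor_fixture()
  segs <- extractSegments(fx$cols)

  f <- tempfile()
  writeDialignAnchors(weightSegments(segs, "length10"), fx$seqs, f)
  expect_identical(readLines(f), readLines(test_path("golden", "dialign.anc")))

  writeBallastAnchors(weightSegments(segs, "length10"), fx$seqs, f)
  expect_identical(readLines(f), readLines(test_path("golden", "ballast.anc")))

  writeTcoffeeLib(weightSegments(segs, "tcoffee_uniform", nSeqs = 3),
                  fx$seqs, f)
  expect_identical(readLines(f), readLines(test_path("golden", "tcoffee.lib")))

  ## determinism: a second run is byte-identical
  f2 <- tempfile()
  writeTcoffeeLib(weightSegments(segs, "tcoffee_uniform", nSeqs = 3),
                  fx$seqs, f2)
  expect_identical(readLines(f2), readLines(f))

  ## empty segment sets
  writeDialignAnchors(weightSegments(extractSegments(
    ColumnSet(list(), seqIds = seqIds(fx$seqs))), "length10"), fx$seqs, f)
  expect_identical(readLines(f), character(0))
  writeTcoffeeLib(weightSegments(extractSegments(
    ColumnSet(list(), seqIds = seqIds(fx$seqs))), "tcoffee_uniform",
    nSeqs = 3), fx$seqs, f)
  lines <- readLines(f)
  expect_equal(lines[1], "! TC_LIB_FORMAT_01")
  expect_equal(lines[length(lines)], "! SEQ_1_TO_N")
  expect_length(lines, 6L)   # header + count + 3 sequences + terminator
})

test_that("unweighted segments are refused by the writers", {
  fx <- anchor_fixture()
  segs <- extractSegments(fx$cols)
  expect_error(writeDialignAnchors(segs, fx$seqs, tempfile()), "weighted")
})
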
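test_that("succession graph edges and weights follow the definition", {
  ## crossing pair: a 2-cycle of weight 1 each
  cs <- ColumnSet(list(rbind(c(0, 0), c(1, 1)), rbind(c(0, 1), c(1, 0))),
                  seqIds = c("a", "b"))
  e <- sgEdges(buildSuccessionGraph(cs))
  inter <- e[!(e$from %in% c("v_start", "v_end") |
                 e$to %in% c("v_start", "v_end")), ]
  expect_equal(nrow(inter), 2L)
  expect_setequal(paste(inter$from, inter$to), c("C1 C2", "C2 C1"))
  expect_true(all(inter$weight == 1L))

  ## parallel pair: one edge of weight 2
  cs2 <- ColumnSet(list(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1), c(1, 1))),
                   seqIds = c("a", "b"))
  e2 <- sgEdges(buildSuccessionGraph(cs2))
  inter2 <- e2[e2$from == "C1" & e2$to == "C2", ]
  expect_equal(inter2$weight, 2L)
  expect_false(any(e2$from == "C2" & e2$to == "C1"))

  ## single column: only the marker wiring
  cs3 <- ColumnSet(list(rbind(c(0, 0), c(1, 0))), seqIds = c("a", "b"))
  e3 <- sgEdges(buildSuccessionGraph(cs3))
  expect_setequal(paste(e3$from, e3$to), c("v_start C1", "C1 v_end"))
})

test_that("consistency equals succession-graph acyclicity and the order oracle", {
  cs <- ColumnSet(list(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1), c(1, 1))),
                  seqIds = c("a", "b"))
  expect_true(isConsistent(cs))
  expect_true(oracle_consistent(cs))
  crossed <- ColumnSet(list(rbind(c(0, 0), c(1, 1)), rbind(c(0, 1), c(1, 0))),
                       seqIds = c("a", "b"))
  expect_false(isConsistent(crossed))
  expect_false(oracle_consistent(crossed))
  set.seed(5)
  for (rep in 1:60) {
    cs <- random_columnset()
    expect_equal(isConsistent(cs), oracle_consistent(cs))
  }
})

test_that("dagify finds the smallest acyclic threshold and reconnects", {
  mk <- function(edges, verts) new("SuccessionGraph", edges = edges,
                                   vertices = verts)
  ## 2-cycle with weights 2 and 1: drop the light edge
  e <- data.frame(from = c("C1", "C2", "v_start", "C2"),
                  to = c("C2", "C1", "C1", "v_end"),
                  weight = c(2L, 1L, 1L, 1L))
  d <- dagify(mk(e, c("C1", "C2", "v_start", "v_end")))
  expect_equal(kStar(d), 1L)
  expect_equal(paste(d@removedEdges$from, d@removedEdges$to), "C2 C1")

  ## already acyclic: k* = 0, nothing removed
  e2 <- data.frame(from = c("C1", "v_start", "C2"),
                   to = c("C2", "C1", "v_end"), weight = c(1L, 1L, 1L))
  d2 <- dagify(mk(e2, c("C1", "C2", "v_start", "v_end")))
  expect_equal(kStar(d2), 0L)
  expect_equal(nrow(d2@removedEdges), 0L)

  ## symmetric 2-cycle: both edges go, both columns rewired to the markers
  e3 <- data.frame(from = c("C1", "C2", "v_start", "v_start", "C1", "C2"),
                   to = c("C2", "C1", "C1", "C2", "v_end", "v_end"),
                   weight = c(1L, 1L, 1L, 1L, 1L, 1L))
  d3 <- dagify(mk(e3, c("C1", "C2", "v_start", "v_end")))
  expect_equal(kStar(d3), 1L)
  expect_equal(nrow(d3@removedEdges), 2L)
  kept <- paste(d3@keptEdges$from, d3@keptEdges$to)
  expect_true(all(c("v_start C1", "v_start C2", "C1 v_end", "C2 v_end")
                  %in% kept))
})

test_that("the three-sequence swapped-column instance resolves as derived by hand", {
  cs <- worked_example_columns()
  g <- buildSuccessionGraph(cs)
  e <- sgEdges(g)
  expect_equal(e$weight[e$from == "C2" & e$to == "C3"], 2L)
  expect_equal(e$weight[e$from == "C3" & e$to == "C2"], 1L)
  tr <- resolveColumns(cs)
  expect_equal(kStar(tr), 1L)
  rem <- removedSites(tr)
  expect_equal(nrow(rem), 1L)
  expect_equal(rem$seq, 1L)
  expect_equal(rem$pos, 1L)
  expect_equal(rem$column, 3L)     # column C loses its site in sequence 1
  out <- columns(tr)
  expect_equal(vapply(columns(out), nrow, integer(1)), c(3L, 3L, 2L))
  expect_true(isConsistent(out))
  ## sequence 1 kept the chain A, B
  expect_equal(tr@chains[["1"]], c(1L, 2L))
})

test_that("resolution is idempotent and leaves consistent inputs untouched", {
  cs <- ColumnSet(list(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1), c(1, 1))),
                  seqIds = c("a", "b"))
  tr <- resolveColumns(cs)
  expect_equal(kStar(tr), 0L)
  expect_equal(nrow(removedSites(tr)), 0L)
  expect_equal(columnset_signature(columns(tr)), columnset_signature(cs))
  set.seed(6)
  for (rep in 1:40) {
    cs <- random_columnset()
    out1 <- consistentColumns(cs)
    expect_true(isConsistent(out1))
    out2 <- consistentColumns(out1)
    expect_equal(columnset_signature(out2), columnset_signature(out1))
  }
})

test_that("sequence processing order does not change the removed sites", {
  set.seed(8)
  for (rep in 1:15) {
    cs <- random_columnset(nseq = 4L)
    base <- resolveColumns(cs)
    touched <- sort(unique(do.call(rbind, columns(cs))[, 1L]))
    for (p in 1:3) {
      perm <- sample(touched)
      tr <- resolveColumns(cs, sequenceOrder = perm)
      expect_equal(tr@removedSites[order(tr@removedSites$seq,
                                         tr@removedSites$pos), ],
                   base@removedSites[order(base@removedSites$seq,
                                           base@removedSites$pos), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("per-sequence site loss equals the columns left off the chosen chain", {
  set.seed(9)
  for (rep in 1:20) {
    cs <- random_columnset()
    tr <- resolveColumns(cs)
    flat <- do.call(rbind, Map(function(m, i) cbind(m, col = i),
                               columns(cs), seq_len(nColumns(cs))))
    for (s in names(tr@chains)) {
      cs_s <- sum(flat[, 1L] == as.integer(s))
      lost <- sum(removedSites(tr)$seq == as.integer(s))
      expect_equal(lost, cs_s - length(tr@chains[[s]]))
      ## never removes a site whose column lies on the chosen chain
      expect_false(any(removedSites(tr)$column[removedSites(tr)$seq ==
                                                 as.integer(s)] %in%
                         tr@chains[[s]]))
    }
  }
})

test_that("empty input resolves to empty output", {
  cs <- ColumnSet(list(), seqIds = c("a", "b"))
  out <- consistentColumns(cs)
  expect_equal(nColumns(out), 0L)
  expect_true(isConsistent(out))
})
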
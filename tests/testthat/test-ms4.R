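tree_of <- function(chrs, ids = sprintf("s%d", seq_along(chrs)), nMax = NULL) {
  s <- SequenceSet(chrs, ids = ids)
  buildPartitionTree(nldAll(s, nMax = nMax), s)
}

test_that("partition tree has the site space as root and inclusion as parenthood", {
  tr <- tree_of(c("AB", "CD"))
  nd <- treeNodes(tr)
  expect_equal(nd$level[1], 0L)
  expect_equal(nd$size[1], 4L)
  expect_equal(sum(nd$level == 1L), 4L)          # four singleton children
  expect_true(all(nd$parent[nd$level == 1L] == nd$id[1]))

  tr2 <- tree_of(c("ACGT", "ACGT"))
  nd2 <- treeNodes(tr2)
  expect_equal(sum(nd2$level == 1L), 4L)
  expect_true(all(nd2$size[nd2$level >= 1L] == 2L))
  ## identical classes across levels give chains, one node per level
  expect_equal(as.integer(table(nd2$level)), c(1L, 4L, 4L, 4L, 4L))

  ## single sequence: ambiguous level-1 class splits into singletons
  tr3 <- tree_of("AA")
  nd3 <- treeNodes(tr3)
  expect_equal(nd3$size[nd3$level == 1L], 2L)
  expect_true(nd3$ambiguous[nd3$level == 1L])
  expect_equal(sum(nd3$level == 2L), 2L)
})

test_that("every site lies on one root-to-leaf chain per level", {
  set.seed(7)
  for (rep in 1:10) {
    s <- random_seqset(nseq = 3L, maxlen = 15L)
    tr <- buildPartitionTree(nldAll(s), s)
    L <- sum(seqLengths(s))
    for (m in tr@memberships) {
      expect_length(m, L)
      expect_true(all(m >= 1L & m <= L))
    }
    ## child members are a subset of parent members, for every node
    nd <- treeNodes(tr)
    for (i in which(nd$level >= 1L)) {
      child <- nodeMembers(tr, nd$id[i])
      parent <- nodeMembers(tr, nd$parent[i])
      expect_true(all(paste(child[, 1], child[, 2]) %in%
                        paste(parent[, 1], parent[, 2])))
    }
  }
})

test_that("MS4 selection takes the topmost non-ambiguous frontier", {
  tr <- tree_of(c("ACGT", "ACGT"))
  cs <- selectColumns(tr, sMin = 2)
  expect_equal(nColumns(cs), 4L)
  for (t in 0:3)
    expect_equal(unname(columns(cs)[[t + 1]]),
                 unname(cbind(seq = 0:1, pos = t)), ignore_attr = TRUE)

  ## exhaustive node-scan oracle on a repeat-rich input
  tr2 <- tree_of(c("GATTACA", "GATTACA"))
  cs2 <- selectColumns(tr2, sMin = 2)
  nd <- treeNodes(tr2)
  parentAmb <- nd$ambiguous[match(nd$parent, nd$id)]
  expected <- nd[nd$level >= 1 & !nd$ambiguous & !is.na(parentAmb) &
                   parentAmb & nd$size >= 2 & nd$nseq >= 2, ]
  expect_equal(nColumns(cs2), nrow(expected))
  for (m in columns(cs2)) {
    expect_false(isAmbiguous(m))
    expect_true(nrow(m) >= 2L)
  }
  ## no selected class contains another (frontier disjointness)
  allSites <- do.call(rbind, columns(cs2))
  expect_equal(nrow(unique(allSites)), nrow(allSites))
})

test_that("spanning threshold filters and is anti-monotone", {
  tr <- tree_of(c("ACGT", "ACGT"))
  expect_equal(nColumns(selectColumns(tr, sMin = 3)), 0L)
  expect_error(selectColumns(tr, sMin = 1), "sMin")
  set.seed(12)
  for (rep in 1:10) {
    s <- random_seqset(nseq = 4L, maxlen = 20L, alphabet_size = 4L)
    tr <- buildPartitionTree(nldAll(s), s)
    c2 <- columnset_signature(selectColumns(tr, sMin = 2))
    c3 <- columnset_signature(selectColumns(tr, sMin = 3))
    keys2 <- vapply(c2, function(m) paste(m, collapse = ","), character(1))
    keys3 <- vapply(c3, function(m) paste(m, collapse = ","), character(1))
    expect_true(all(keys3 %in% keys2))
    ## repetition exclusion
    for (m in c2) expect_false(isAmbiguous(m))
  }
})

test_that("single-sequence input yields no multi-sequence columns", {
  tr <- tree_of("AA")
  expect_equal(nColumns(selectColumns(tr, sMin = 2)), 0L)
})
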
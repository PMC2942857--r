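#' @include nld.R
NULL

#' Build the partition tree across word lengths
#'
#' Stacks the N-local decodings for successive N into a rooted tree: the
#' root is the whole site space (level 0), and a level-(N+1) class is the
#' child of the level-N class that contains it.  Classes identical across
#' consecutive levels give chains of distinct nodes (no node merging);
#' selection later operates on the shallowest node of a chain.
#'
#' @param partitions list of [NldPartition] for consecutive N = 1..K of one
#'   sequence set, as produced by [nldAll()].
#' @param seqs optional [SequenceSet]; when supplied, node labels carry the
#'   representative residue for display (labels have no semantics).
#' @return a [PartitionTree].
#' @export
buildPartitionTree <- function(partitions, seqs = NULL) {
  if (!length(partitions))
    stop("at least one partition is required")
  Ns <- vapply(partitions, function(p) p@N, integer(1))
  if (!identical(Ns, seq_along(partitions)))
    stop("partitions must be the consecutive levels N = 1..K")
  lens <- partitions[[1L]]@lengths
  L <- sum(lens)
  mships <- c(list(rep.int(1L, L)), lapply(partitions, function(p) p@membership))
  so <- .seq_of(lens)
  po <- .pos_of(lens)
  res <- if (!is.null(seqs)) {
    unlist(strsplit(unname(sequences(seqs)), ""), use.names = FALSE)
  } else NULL
  seqids <- if (!is.null(seqs)) seqIds(seqs) else paste0("seq", seq_along(lens))

  nodes <- vector("list", length(mships))
  idmap <- vector("list", length(mships))   # per level: rep gid -> node id
  nextId <- 1L
  for (lvl in seq_along(mships) - 1L) {
    m <- mships[[lvl + 1L]]
    reps <- sort(unique(m))
    ids <- seq.int(nextId, length.out = length(reps))
    nextId <- nextId + length(reps)
    idmap[[lvl + 1L]] <- stats::setNames(ids, reps)
    size <- tabulate(match(m, reps), nbins = length(reps))
    amb <- vapply(split(so, m), anyDuplicated, integer(1)) > 0L
    nseq <- vapply(split(so, m), function(s) length(unique(s)), integer(1))
    if (lvl == 0L) {
      parent <- NA_integer_
      label <- "ROOT_0"
    } else {
      prep <- mships[[lvl]][reps]     # parent class of the representative
      ## refinement check: every member of a class must share that parent
      stopifnot(all(vapply(split(mships[[lvl]], m), function(z)
        length(unique(z)), integer(1)) == 1L))
      parent <- unname(idmap[[lvl]][as.character(prep)])
      label <- if (!is.null(res)) {
        sprintf("%s%d.%d_%d", res[reps], so[reps], po[reps], lvl)
      } else sprintf("N%d.%d", lvl, reps)
    }
    nodes[[lvl + 1L]] <- data.frame(
      id = ids, level = lvl, rep = reps, parent = parent,
      size = size, nseq = unname(nseq), ambiguous = unname(amb),
      label = label, stringsAsFactors = FALSE)
  }
  new("PartitionTree", nodes = do.call(rbind, nodes), memberships = mships,
      lengths = lens, seqIds = seqids)
}

#' Node table of a partition tree
#' @param tree a [PartitionTree].
#' @return the node data.frame (id, level, rep, parent, size, nseq,
#'   ambiguous, label).
#' @export
treeNodes <- function(tree) {
  stopifnot(is(tree, "PartitionTree"))
  tree@nodes
}

#' Member sites of a tree node
#' @param tree a [PartitionTree].
#' @param id node id.
#' @return 2-column (seq, pos) integer matrix, 0-based.
#' @export
nodeMembers <- function(tree, id) {
  nd <- tree@nodes[match(id, tree@nodes$id), ]
  if (anyNA(nd$id)) stop("unknown node id")
  m <- tree@memberships[[nd$level + 1L]]
  .sites_matrix(which(m == nd$rep), tree@lengths)
}

#' Select MS4 partial columns from a partition tree
#'
#' Selects the non-ambiguous frontier of the tree: nodes that are
#' non-ambiguous while their direct ancestor is ambiguous.  Singleton
#' classes are discarded (a one-site column anchors nothing), and only
#' classes touching at least `sMin` distinct sequences are kept.  The
#' selected classes are pairwise disjoint by construction (every ancestor
#' of a selected node is ambiguous, so no selected node dominates
#' another); column ids are assigned in order of leftmost site.
#'
#' @param tree a [PartitionTree].
#' @param sMin minimum number of sequences a column must span (>= 2).
#' @return a [ColumnSet].
#' @export
selectColumns <- function(tree, sMin = 6L) {
  stopifnot(is(tree, "PartitionTree"))
  if (!is.numeric(sMin) || length(sMin) != 1L || sMin < 2)
    stop("sMin must be a single number >= 2")
  sMin <- as.integer(sMin)
  nd <- tree@nodes
  parentAmb <- nd$ambiguous[match(nd$parent, nd$id)]
  sel <- nd[nd$level >= 1L & !nd$ambiguous & !is.na(parentAmb) & parentAmb &
              nd$size >= 2L & nd$nseq >= sMin, , drop = FALSE]
  sel <- sel[order(sel$rep), , drop = FALSE]  # leftmost site = representative
  cols <- lapply(seq_len(nrow(sel)), function(i) {
    m <- tree@memberships[[sel$level[i] + 1L]]
    .sites_matrix(which(m == sel$rep[i]), tree@lengths)
  })
  ColumnSet(cols, seqIds = tree@seqIds, sMin = sMin)
}

setMethod("show", "PartitionTree", function(object) {
  nd <- object@nodes
  cat("PartitionTree:", nrow(nd), "nodes over",
      length(object@memberships) - 1L, "word-length level(s),",
      sum(object@lengths), "sites\n")
  tab <- table(nd$level)
  cat("  nodes per level:", paste(tab, collapse = " "), "\n")
})
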
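#' @import methods
NULL

## Gap characters are rejected on input everywhere: the detector works on
## unaligned sequences, and alignment rows are handled by the Alignment class.
.GAP_CHARS <- c("-", ".")

.ALPHABETS <- list(
  protein = strsplit("ACDEFGHIKLMNPQRSTVWYBJOUXZ*", "")[[1]],
  dna     = c("A", "C", "G", "T", "N")
)

#' SequenceSet: a collection of unaligned sequences
#'
#' Holds `n` uppercase residue strings over a declared alphabet, with unique
#' non-empty identifiers.  This is the input object of the whole anchor
#' pipeline; all positions derived from it ("sites") are 0-based internally,
#' while every exported file format is 1-based.
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot seqs character vector of uppercase residue strings (no gaps).
#' @slot alphabet one of `"protein"`, `"dna"`, `"raw"`.
#' @export
setClass("SequenceSet",
  slots = c(ids = "character", seqs = "character", alphabet = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@ids) != length(object@seqs))
      msg <- c(msg, "ids and seqs must have equal length")
    if (anyDuplicated(object@ids) || any(!nzchar(object@ids)))
      msg <- c(msg, "identifiers must be unique and non-empty")
    if (any(!nzchar(object@seqs)))
      msg <- c(msg, "every sequence must be non-empty")
    if (length(object@alphabet) != 1L ||
        !object@alphabet %in% c("protein", "dna", "raw"))
      msg <- c(msg, "alphabet must be one of 'protein', 'dna', 'raw'")
    if (length(msg)) msg else TRUE
  })

#' NldPartition: the N-local decoding of a site space
#'
#' Partition of all sites of a [SequenceSet] induced by the transitive
#' closure of the "same length-N word at the same relative position"
#' relation.  Classes are encoded by a membership vector over global site
#' ids (1..L in sequence-major order); each class is represented by its
#' smallest member, so enumeration order is reproducible.
#'
#' @slot N integer word length.
#' @slot membership integer vector of length L; `membership[g]` is the
#'   global site id of the representative of the class containing site g.
#' @slot lengths integer per-sequence residue counts of the parent set.
#' @export
setClass("NldPartition",
  slots = c(N = "integer", membership = "integer", lengths = "integer"),
  validity = function(object) {
    L <- sum(object@lengths)
    if (length(object@membership) != L)
      return("membership must cover every site")
    if (any(object@membership < 1L | object@membership > L))
      return("membership values must be global site ids")
    TRUE
  })

#' PartitionTree: NLD classes across word lengths, as a rooted tree
#'
#' Nodes are the equivalence classes for N = 0 (the root: the whole site
#' space) through the deepest computed level; a child class is included in
#' its parent.  Classes that stay identical across consecutive N form
#' chains of distinct nodes.
#'
#' @slot nodes data.frame with columns `id`, `level`, `rep` (representative
#'   global site id), `parent` (node id, NA for root), `size`, `nseq`,
#'   `ambiguous`, `label`.
#' @slot memberships list of integer membership vectors, one per level
#'   (level 0 first).
#' @slot lengths integer per-sequence lengths.
#' @slot seqIds character sequence identifiers.
#' @export
setClass("PartitionTree",
  slots = c(nodes = "data.frame", memberships = "list",
            lengths = "integer", seqIds = "character"))

#' ColumnSet: a set of disjoint partial alignment columns
#'
#' Each column is a non-ambiguous set of sites (at most one per sequence),
#' stored as a 2-column integer matrix with columns `seq` and `pos`
#' (both 0-based), rows sorted by `seq`.  Columns are pairwise disjoint;
#' the column id is its position in the list.
#'
#' @slot columns list of 2-column integer matrices.
#' @slot seqIds character identifiers of the underlying sequences.
#' @slot sMin integer spanning threshold used at selection (NA when the set
#'   did not come from MS4 selection).
#' @export
setClass("ColumnSet",
  slots = c(columns = "list", seqIds = "character", sMin = "integer"),
  validity = function(object) {
    n <- length(object@seqIds)
    keys <- character(0)
    for (m in object@columns) {
      if (!is.matrix(m) || ncol(m) != 2L)
        return("each column must be a 2-column (seq, pos) matrix")
      if (nrow(m) && (any(m[, 1L] < 0L) || any(m[, 1L] >= n) || any(m[, 2L] < 0L)))
        return("site coordinates out of range")
      if (anyDuplicated(m[, 1L]))
        return("ambiguous column: two sites in one sequence")
      keys <- c(keys, paste(m[, 1L], m[, 2L]))
    }
    if (anyDuplicated(keys))
      return("columns must be pairwise disjoint")
    TRUE
  })

#' SuccessionGraph: left-to-right precedence between partial columns
#'
#' Directed graph on column ids `"C1"..."Ck"` plus the markers `v_start`
#' and `v_end`.  An inter-column edge (C, C') exists iff some sequence
#' carries both columns with C strictly left of C'; its weight is the
#' number of such sequences.  `v_start` points to every column that is
#' leftmost in at least one sequence (dually for `v_end`).
#'
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @slot vertices character vector of all vertex names (columns + markers).
#' @export
setClass("SuccessionGraph",
  slots = c(edges = "data.frame", vertices = "character"),
  validity = function(object) {
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% names(e)))
      return("edges must have from/to/weight columns")
    if (nrow(e)) {
      if (any(e$from == e$to)) return("self-loops are not allowed")
      if (any(e$to == "v_start")) return("v_start cannot have incoming edges")
      if (any(e$from == "v_end")) return("v_end cannot have outgoing edges")
      if (!all(c(e$from, e$to) %in% object@vertices))
        return("edge endpoints must be declared vertices")
    }
    TRUE
  })

#' DagifyResult: outcome of the feedback-arc-set heuristic
#'
#' @slot kStar integer: smallest threshold k >= 0 such that keeping
#'   inter-column edges of weight > k (marker edges always kept) is acyclic.
#' @slot keptEdges data.frame of surviving edges, including the
#'   reconnection edges added so every column has a predecessor and a
#'   successor.
#' @slot removedEdges data.frame of discarded inter-column edges (all of
#'   weight <= kStar).
#' @slot vertices character vertex names.
#' @export
setClass("DagifyResult",
  slots = c(kStar = "integer", keptEdges = "data.frame",
            removedEdges = "data.frame", vertices = "character"))

#' ResolutionTrace: full record of an inconsistency-removal run
#'
#' @slot chains list, one per sequence touched by any column, of the kept
#'   column ids in order (the longest path for that sequence).
#' @slot removedSites data.frame with columns `seq`, `pos` (0-based) and
#'   `column` (input column id) for every trimmed site.
#' @slot columns the final consistent [ColumnSet] (columns reduced below 2
#'   sites are dropped).
#' @slot kStar integer threshold chosen by [dagify()].
#' @export
setClass("ResolutionTrace",
  slots = c(chains = "list", removedSites = "data.frame",
            columns = "ColumnSet", kStar = "integer"))

#' Alignment: a gapped multiple alignment
#'
#' Rows of equal gapped width over uppercase residues with `-` or `.` as
#' gap characters.  Ungapping a row reproduces the underlying sequence.
#'
#' @slot ids character row identifiers.
#' @slot rows character gapped rows.
#' @export
setClass("Alignment",
  slots = c(ids = "character", rows = "character"),
  validity = function(object) {
    if (length(object@ids) != length(object@rows))
      return("ids and rows must have equal length")
    if (anyDuplicated(object@ids))
      return("row identifiers must be unique")
    if (length(object@rows) && length(unique(nchar(object@rows))) != 1L)
      return("all rows must have the same gapped width")
    TRUE
  })
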
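#' @include AllClasses.R
NULL

#' Number of sequences in a SequenceSet
#' @param x a [SequenceSet].
#' @return integer count.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Sequence identifiers
#' @param x a [SequenceSet], [ColumnSet] or [Alignment].
#' @return character vector.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Per-sequence residue counts
#' @param x a [SequenceSet].
#' @return integer vector.
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' Residue strings
#' @param x a [SequenceSet].
#' @return character vector of uppercase residues.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Site classes of a partition or tree node
#' @param x an [NldPartition].
#' @return list of 2-column (seq, pos) integer matrices, 0-based, ordered
#'   by representative (smallest member first).
#' @export
setGeneric("siteClasses", function(x) standardGeneric("siteClasses"))

#' Ambiguity predicate for a set of sites
#'
#' A site set is ambiguous iff it contains a repetition: some sequence
#' contributes at least two members.  An ambiguous set can never be (part
#' of) an alignment column.
#'
#' @param x a 2-column (seq, pos) matrix of sites.
#' @return logical scalar.
#' @export
setGeneric("isAmbiguous", function(x) standardGeneric("isAmbiguous"))

#' Columns of a ColumnSet
#' @param x a [ColumnSet].
#' @return list of 2-column (seq, pos) integer matrices.
#' @export
setGeneric("columns", function(x) standardGeneric("columns"))

#' Number of columns
#' @param x a [ColumnSet].
#' @return integer count.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' Edge table of a succession graph
#' @param x a [SuccessionGraph] or [DagifyResult].
#' @return data.frame with columns from, to, weight.
#' @export
setGeneric("sgEdges", function(x) standardGeneric("sgEdges"))

#' Chosen threshold of the feedback-arc-set heuristic
#' @param x a [DagifyResult] or [ResolutionTrace].
#' @return integer k*.
#' @export
setGeneric("kStar", function(x) standardGeneric("kStar"))

#' Sites removed during inconsistency resolution
#' @param x a [ResolutionTrace].
#' @return data.frame with columns seq, pos (0-based) and column.
#' @export
setGeneric("removedSites", function(x) standardGeneric("removedSites"))
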
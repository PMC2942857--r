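#' @include synthetic.R
NULL

#' Run the full anchor-detection pipeline
#'
#' Reads (or accepts) unaligned sequences, computes the N-local decodings,
#' builds the partition tree, selects the MS4 partial columns spanning at
#' least `sMin` sequences, and - in `"consistent"` mode - removes
#' order-inconsistencies so that the output admits a multiple alignment.
#'
#' @param input FASTA file path or a [SequenceSet].
#' @param sMin spanning threshold (default 6, a good overall setting
#'   across benchmark families).
#' @param mode `"consistent"` (default) to run the resolution step, or
#'   `"raw"` for the unfiltered MS4 columns.
#' @param nMax optional cap on the word length.
#' @param alphabet alphabet for FASTA input (ignored when `input` is
#'   already a [SequenceSet]).
#' @return list with elements `seqs`, `rawColumns`, `columns` (the
#'   requested output set), `kStar`, `removedSites`, `consistent` (is the
#'   output set consistent?), `nStop` (deepest word length computed),
#'   `widest` (the widest columns and their spans, useful to spot a wide
#'   but wrong similarity dominating a dataset) and `timings` (seconds
#'   per stage).
#' @export
anchorPipeline <- function(input, sMin = 6L, mode = c("consistent", "raw"),
                           nMax = NULL, alphabet = c("protein", "dna", "raw")) {
  mode <- match.arg(mode)
  seqs <- if (is(input, "SequenceSet")) input
          else readFasta(input, alphabet = match.arg(alphabet))
  t0 <- proc.time()[["elapsed"]]
  parts <- nldAll(seqs, nMax = nMax)
  t1 <- proc.time()[["elapsed"]]
  tree <- buildPartitionTree(parts, seqs)
  raw <- selectColumns(tree, sMin = sMin)
  t2 <- proc.time()[["elapsed"]]
  if (mode == "consistent") {
    trace <- resolveColumns(raw)
    out <- trace@columns
    ks <- trace@kStar
    rem <- trace@removedSites
  } else {
    out <- raw
    ks <- NA_integer_
    rem <- data.frame(seq = integer(0), pos = integer(0), column = integer(0))
  }
  t3 <- proc.time()[["elapsed"]]
  widest <- if (nColumns(out)) {
    nseq <- vapply(columns(out), function(m) length(unique(m[, 1L])), integer(1))
    o <- order(-nseq)[seq_len(min(5L, length(nseq)))]
    data.frame(column = o, nseq = nseq[o],
               minPos = vapply(columns(out)[o], function(m) min(m[, 2L]), integer(1)),
               maxPos = vapply(columns(out)[o], function(m) max(m[, 2L]), integer(1)))
  } else data.frame(column = integer(0), nseq = integer(0),
                    minPos = integer(0), maxPos = integer(0))
  list(seqs = seqs, rawColumns = raw, columns = out, kStar = ks,
       removedSites = rem, consistent = isConsistent(out),
       nStop = length(parts), widest = widest,
       timings = c(nld = t1 - t0, select = t2 - t1, consistency = t3 - t2))
}

#' Score a test alignment against a reference
#'
#' Convenience wrapper computing sensitivity (SP, TC) and specificity
#' (argument-swapped SP, TC) in one call.
#'
#' @param test,ref [Alignment] objects or aligned-FASTA file paths.
#' @param core core-column mask on the reference: `"all"` or 1-based
#'   column indices.
#' @return list with elements `sp`, `tc`, `spSpec`, `tcSpec`.
#' @export
scoreAlignments <- function(test, ref, core = "all") {
  if (is.character(test)) test <- readAlignment(test)
  if (is.character(ref)) ref <- readAlignment(ref)
  spec <- alignmentSpecificity(test, ref, core)
  list(sp = spScore(test, ref, core), tc = tcScore(test, ref, core),
       spSpec = unname(spec["spSpec"]), tcSpec = unname(spec["tcSpec"]))
}
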
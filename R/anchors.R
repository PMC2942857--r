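#' @include consistency.R
NULL

.empty_segments <- function() {
  data.frame(seqA = integer(0), seqB = integer(0), startA = integer(0),
             startB = integer(0), length = integer(0), weight = numeric(0))
}

#' Extract pairwise anchor segments from partial columns
#'
#' Anchor-aware aligners consume pairs of matching segments, so the
#' columns are unrolled: for every unordered sequence pair, every maximal
#' run of consecutive site pairs (a, p+t) / (b, p'+t) such that each pair
#' belongs to some partial column is emitted once.  Consecutive pairs may
#' come from different columns; runs are diagonal (both positions advance
#' by one).
#'
#' @param cols a [ColumnSet].
#' @return data.frame with columns `seqA`, `seqB` (0-based, seqA < seqB),
#'   `startA`, `startB` (0-based), `length`, `weight` (NA until
#'   [weightSegments()] is applied), sorted by (seqA, seqB, startA).
#' @export
extractSegments <- function(cols) {
  stopifnot(is(cols, "ColumnSet"))
  prs <- list()
  for (m in cols@columns) {
    r <- nrow(m)
    if (r < 2L) next
    idx <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
    prs[[length(prs) + 1L]] <- data.frame(
      a = m[idx[, "row"], 1L], b = m[idx[, "col"], 1L],
      pa = m[idx[, "row"], 2L], pb = m[idx[, "col"], 2L])
  }
  if (!length(prs)) return(.empty_segments())
  p <- do.call(rbind, prs)
  ## columns are stored sorted by seq, so a < b always holds
  p <- p[order(p$a, p$b, p$pa), , drop = FALSE]
  key <- paste(p$a, p$b, p$pa - p$pb)
  segs <- lapply(split(seq_len(nrow(p)), key), function(ii) {
    q <- p[ii, , drop = FALSE]          # same pair, same diagonal
    run <- cumsum(c(1L, diff(q$pa) != 1L))
    do.call(rbind, lapply(split(seq_len(nrow(q)), run), function(jj) {
      data.frame(seqA = q$a[jj[1L]], seqB = q$b[jj[1L]],
                 startA = q$pa[jj[1L]], startB = q$pb[jj[1L]],
                 length = length(jj), weight = NA_real_)
    }))
  })
  out <- do.call(rbind, segs)
  out <- out[order(out$seqA, out$seqB, out$startA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach weights to anchor segments
#'
#' Two schemes are supported: `length10` gives each segment 10 times its
#' length (used for ClustalW/DIALIGN anchors), and `tcoffee_uniform`
#' gives every segment the same weight 100 * M where M is the number of
#' sequences in the dataset (used for T-Coffee library entries).
#'
#' @param segs segment data.frame from [extractSegments()].
#' @param scheme `"length10"` or `"tcoffee_uniform"`.
#' @param nSeqs number of sequences M (required by `tcoffee_uniform`).
#' @return the segments with the `weight` column filled.
#' @export
weightSegments <- function(segs, scheme = c("length10", "tcoffee_uniform"),
                           nSeqs = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "length10") {
    segs$weight <- 10 * segs$length
  } else {
    if (is.null(nSeqs) || nSeqs < 1)
      stop("scheme 'tcoffee_uniform' requires nSeqs >= 1")
    segs$weight <- rep.int(100 * as.integer(nSeqs), nrow(segs))
  }
  segs
}

.check_weighted <- function(segs) {
  if (nrow(segs) && anyNA(segs$weight))
    stop("segments must be weighted first; see weightSegments()")
}

.fmt_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         format(x, trim = TRUE))
}

#' Write anchors in the DIALIGN anchor-file format
#'
#' One line per segment: `seq_a seq_b start_a start_b length weight`, with
#' 1-based sequence numbers in FASTA input order and 1-based positions,
#' space-separated, in (seqA, seqB, startA) order.
#'
#' @param segs weighted segments from [weightSegments()].
#' @param seqs the [SequenceSet] the segments refer to.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeDialignAnchors <- function(segs, seqs, path) {
  .check_weighted(segs)
  lines <- sprintf("%d %d %d %d %d %s",
                   segs$seqA + 1L, segs$seqB + 1L,
                   segs$startA + 1L, segs$startB + 1L,
                   segs$length, .fmt_num(segs$weight))
  writeLines(lines, path)
  invisible(path)
}

#' Write anchors as a BALLAST-style anchor list
#'
#' The exact grammar used by DbClustal is not standardised, so this writer
#' freezes a fixed, versioned dialect: a header line `QUERY <id>` naming
#' the first (query) sequence, then one record per segment carrying both
#' sequence identifiers, 1-based start positions, the run length and the
#' integer weight, space-separated:
#' `<idA> <idB> <startA> <startB> <length> <weight>`.
#'
#' @inheritParams writeDialignAnchors
#' @return invisibly, `path`.
#' @export
writeBallastAnchors <- function(segs, seqs, path) {
  stopifnot(is(seqs, "SequenceSet"))
  .check_weighted(segs)
  ids <- seqIds(seqs)
  lines <- c(sprintf("QUERY %s", ids[1L]),
             sprintf("%s %s %d %d %d %s",
                     ids[segs$seqA + 1L], ids[segs$seqB + 1L],
                     segs$startA + 1L, segs$startB + 1L,
                     segs$length, .fmt_num(segs$weight)))
  writeLines(lines, path)
  invisible(path)
}

#' Write anchors as a T-Coffee library file (TC_LIB_FORMAT_01)
#'
#' Header line `! TC_LIB_FORMAT_01`, the sequence count, one
#' `name length residues` line per sequence, then for each sequence pair
#' with at least one segment a `#a b` block (1-based pair) with one
#' `res_a res_b weight` line per constrained residue pair (1-based,
#' expanded from the segments), terminated by `! SEQ_1_TO_N`.
#'
#' @inheritParams writeDialignAnchors
#' @details Segments are expected to carry the uniform T-Coffee weight
#'   (see [weightSegments()] scheme `tcoffee_uniform`).
#' @return invisibly, `path`.
#' @export
writeTcoffeeLib <- function(segs, seqs, path) {
  stopifnot(is(seqs, "SequenceSet"))
  .check_weighted(segs)
  ids <- seqIds(seqs)
  resid <- unname(sequences(seqs))
  lines <- c("! TC_LIB_FORMAT_01",
             sprintf("%d", length(ids)),
             sprintf("%s %d %s", ids, nchar(resid), resid))
  if (nrow(segs)) {
    segs <- segs[order(segs$seqA, segs$seqB, segs$startA), , drop = FALSE]
    pk <- paste(segs$seqA, segs$seqB)
    for (key in unique(pk)) {
      q <- segs[pk == key, , drop = FALSE]
      lines <- c(lines, sprintf("#%d %d", q$seqA[1L] + 1L, q$seqB[1L] + 1L))
      for (i in seq_len(nrow(q))) {
        t <- seq_len(q$length[i]) - 1L
        lines <- c(lines, sprintf("%d %d %s", q$startA[i] + 1L + t,
                                  q$startB[i] + 1L + t,
                                  .fmt_num(rep.int(q$weight[i], length(t)))))
      }
    }
  }
  lines <- c(lines, "! SEQ_1_TO_N")
  writeLines(lines, path)
  invisible(path)
}
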
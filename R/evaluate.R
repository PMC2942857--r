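#' @include anchors.R
NULL

.is_gap <- function(ch) {
  r <- ch %in% .GAP_CHARS
  if (is.matrix(ch)) dim(r) <- dim(ch)
  r
}

#' Construct an Alignment from gapped rows
#'
#' @param rows character vector of gapped rows of equal width; names are
#'   used as identifiers when `ids` is missing.
#' @param ids character row identifiers.
#' @return an [Alignment].
#' @export
Alignment <- function(rows, ids = names(rows)) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  new("Alignment", ids = as.character(ids), rows = toupper(as.character(rows)))
}

#' Read a multiple alignment from aligned FASTA
#'
#' @param path aligned FASTA file; all records must have equal gapped
#'   width.  `-` and `.` are gap characters.
#' @return an [Alignment].
#' @export
readAlignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L)
    stop("empty file: ", path, " contains no FASTA records")
  Alignment(as.character(ss), ids = sub("\\s.*$", "", names(ss)))
}

#' Gapped width of an alignment
#' @param x an [Alignment].
#' @return integer column count.
#' @export
alnWidth <- function(x) {
  stopifnot(is(x, "Alignment"))
  if (!length(x@rows)) 0L else nchar(x@rows[1L])
}

#' Ungapped sequences underlying an alignment
#' @param x an [Alignment].
#' @return named character vector.
#' @export
ungapped <- function(x) {
  stopifnot(is(x, "Alignment"))
  stats::setNames(gsub("[-.]", "", x@rows), x@ids)
}

setMethod("show", "Alignment", function(object) {
  cat("Alignment:", length(object@rows), "row(s),",
      alnWidth(object), "column(s)\n")
})

## chars matrix (rows x columns) of an alignment
.aln_chars <- function(aln) {
  do.call(rbind, strsplit(aln@rows, ""))
}

## For each row: vector mapping ungapped position (1-based) -> column index
.aln_colmap <- function(aln) {
  ch <- .aln_chars(aln)
  lapply(seq_len(nrow(ch)), function(i) which(!.is_gap(ch[i, ])))
}

## Reorder test rows to ref's row order and verify both alignments carry
## the same sequences.
.match_rows <- function(test, ref) {
  if (!setequal(test@ids, ref@ids))
    stop("sequence mismatch: test and reference carry different identifiers")
  test <- Alignment(test@rows[match(ref@ids, test@ids)],
                    ids = ref@ids)
  if (!identical(unname(ungapped(test)), unname(ungapped(ref))))
    stop("sequence mismatch: ungapped residues differ between test and reference")
  test
}

.resolve_core <- function(ref, core) {
  w <- alnWidth(ref)
  if (identical(core, "all")) return(seq_len(w))
  core <- as.integer(core)
  if (!length(core) || any(is.na(core)) || any(core < 1L) || any(core > w))
    stop("core mask indices must lie in 1..", w)
  sort(unique(core))
}

## For each core column of ref: the test columns occupied by its residues.
.test_cols_per_ref_col <- function(test, ref, coreCols) {
  refCh <- .aln_chars(ref)
  cmTest <- .aln_colmap(test)
  ucount <- apply(!.is_gap(refCh), 1L, cumsum)
  if (is.null(dim(ucount))) ucount <- matrix(ucount, ncol = nrow(refCh))
  ## ucount is columns x rows after apply(); index as [col, row]
  lapply(coreCols, function(cc) {
    rowsHit <- which(!.is_gap(refCh[, cc]))
    vapply(rowsHit, function(i) cmTest[[i]][ucount[cc, i]], integer(1))
  })
}

#' Sum-of-pairs score of a test alignment against a reference
#'
#' The percentage of residue pairs aligned together in the core columns
#' of the reference that are also aligned together (placed in one column)
#' in the test alignment.
#'
#' @param test,ref [Alignment] objects over the same sequences.
#' @param core core-column mask: `"all"` or a vector of 1-based reference
#'   column indices.
#' @return percentage in `[0, 100]`.
#' @export
spScore <- function(test, ref, core = "all") {
  test <- .match_rows(test, ref)
  coreCols <- .resolve_core(ref, core)
  tcols <- .test_cols_per_ref_col(test, ref, coreCols)
  num <- 0; den <- 0
  for (v in tcols) {
    m <- length(v)
    if (m < 2L) next
    den <- den + m * (m - 1) / 2
    tb <- table(v)
    num <- num + sum(tb * (tb - 1) / 2)
  }
  if (den == 0)
    stop("undefined score: no residue pairs in the core columns")
  100 * num / den
}

#' Total-column score of a test alignment against a reference
#'
#' The percentage of core reference columns whose full residue set is
#' aligned as one column in the test: a single misplaced residue zeroes
#' the column's contribution.
#'
#' @inheritParams spScore
#' @details With `core = "all"`, columns holding fewer than two residues
#'   contribute no alignment constraint and are excluded from the
#'   denominator.  With an explicit mask, every masked column counts
#'   (columns with at most one residue are vacuously reproduced).
#' @return percentage in `[0, 100]`.
#' @export
tcScore <- function(test, ref, core = "all") {
  test <- .match_rows(test, ref)
  explicit <- !identical(core, "all")
  coreCols <- .resolve_core(ref, core)
  tcols <- .test_cols_per_ref_col(test, ref, coreCols)
  num <- 0L; den <- 0L
  for (v in tcols) {
    m <- length(v)
    if (!explicit && m < 2L) next
    den <- den + 1L
    if (m <= 1L || length(unique(v)) == 1L) num <- num + 1L
  }
  if (den == 0L)
    stop("undefined score: no scorable core columns")
  100 * num / den
}

#' Specificity of a test alignment (argument-swapped scoring)
#'
#' While [spScore()]/[tcScore()] measure sensitivity (how much of the
#' reference core the test reproduces), specificity measures the
#' proportion of correct pairs (or columns) among those the test itself
#' aligns, restricted to core residues.  It is computed by swapping the
#' roles of test and reference in the scorers, with the core mask
#' transported onto the test: the transported mask is the set of test
#' columns containing at least one residue from a reference core column.
#'
#' @inheritParams spScore
#' @return named numeric vector `c(spSpec = ..., tcSpec = ...)`.
#' @export
alignmentSpecificity <- function(test, ref, core = "all") {
  test <- .match_rows(test, ref)
  coreCols <- .resolve_core(ref, core)
  tcols <- .test_cols_per_ref_col(test, ref, coreCols)
  coreT <- sort(unique(unlist(tcols)))
  if (!length(coreT))
    stop("undefined score: no core residues appear in the test alignment")
  c(spSpec = spScore(ref, test, coreT),
    tcSpec = tcScore(ref, test, coreT))
}
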
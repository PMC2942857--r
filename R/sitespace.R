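#' @include AllGenerics.R
NULL

## ---- internal site arithmetic -------------------------------------------
## Global site ids run 1..L in sequence-major order.  seq/pos are 0-based.

.offsets <- function(lengths) c(0L, cumsum(lengths))

.seq_of <- function(lengths) rep.int(seq_along(lengths) - 1L, lengths)

.pos_of <- function(lengths) {
  unlist(lapply(lengths, function(l) seq_len(l) - 1L), use.names = FALSE)
}

.gid <- function(seq0, pos0, lengths) .offsets(lengths)[seq0 + 1L] + pos0 + 1L

.sites_matrix <- function(gids, lengths) {
  so <- .seq_of(lengths); po <- .pos_of(lengths)
  cbind(seq = so[gids], pos = po[gids])
}

.alphabet_chars <- function(alphabet) .ALPHABETS[[alphabet]]

#' Construct a SequenceSet
#'
#' Case-folds to uppercase and validates residues against the declared
#' alphabet.  Gap characters (`-`, `.`) are always rejected: the anchor
#' pipeline consumes unaligned sequences.
#'
#' @param seqs character vector of residue strings; names are used as
#'   identifiers when `ids` is missing.
#' @param ids character identifiers, unique and non-empty.
#' @param alphabet `"protein"`, `"dna"` or `"raw"` (any printable
#'   non-whitespace character except gaps).
#' @return a [SequenceSet].
#' @examples
#' SequenceSet(c(a = "acgt", b = "GG"), alphabet = "dna")
#' @export
SequenceSet <- function(seqs, ids = names(seqs), alphabet = c("raw", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0L)
    stop("empty sequence set: no records")
  if (is.null(ids))
    ids <- paste0("seq", seq_along(seqs))
  if (any(!nzchar(seqs)))
    stop("empty sequence: record ", ids[which(!nzchar(seqs))[1L]],
         " has no residues")
  if (anyDuplicated(ids))
    stop("duplicate identifier: ", ids[anyDuplicated(ids)])
  seqs <- toupper(as.character(seqs))
  chars <- unique(unlist(strsplit(seqs, ""), use.names = FALSE))
  if (any(chars %in% .GAP_CHARS))
    stop("gap character ('-' or '.') found: input must be unaligned")
  if (alphabet == "raw") {
    bad <- chars[grepl("[[:space:][:cntrl:]]", chars)]
  } else {
    bad <- setdiff(chars, .alphabet_chars(alphabet))
  }
  if (length(bad))
    stop("character(s) outside the '", alphabet, "' alphabet: ",
         paste(bad, collapse = " "))
  new("SequenceSet", ids = as.character(ids), seqs = seqs, alphabet = alphabet)
}

#' Read unaligned sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param alphabet declared alphabet, see [SequenceSet()].
#' @return a [SequenceSet] with records in file order, residues uppercased.
#' @details Distinct diagnostics are raised for an empty file, duplicate
#'   identifiers, gap characters (the input must be unaligned) and
#'   characters outside the declared alphabet.
#' @export
readFasta <- function(path, alphabet = c("raw", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L)
    stop("empty file: ", path, " contains no FASTA records")
  ids <- sub("\\s.*$", "", names(ss))  # first token of the header
  SequenceSet(as.character(ss), ids = ids, alphabet = alphabet)
}

#' Write a SequenceSet as FASTA
#' @param x a [SequenceSet].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
  stopifnot(is(x, "SequenceSet"))
  ss <- Biostrings::BStringSet(stats::setNames(x@seqs, x@ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Enumerate the site space
#'
#' The site space of a sequence collection is the set of all positions
#' (seq, pos), 0-based, ordered sequence-major then by position; its
#' cardinality is the sum of the sequence lengths.
#'
#' @param seqs a [SequenceSet].
#' @return integer matrix with columns `seq` and `pos`.
#' @export
siteSpace <- function(seqs) {
  stopifnot(is(seqs, "SequenceSet"))
  lens <- seqLengths(seqs)
  cbind(seq = .seq_of(lens), pos = .pos_of(lens))
}

## ---- accessors -----------------------------------------------------------

#' @rdname nSequences
#' @export
setMethod("nSequences", "SequenceSet", function(x) length(x@ids))

#' @rdname seqIds
#' @export
setMethod("seqIds", "SequenceSet", function(x) x@ids)

#' @rdname seqIds
#' @export
setMethod("seqIds", "ColumnSet", function(x) x@seqIds)

#' @rdname seqIds
#' @export
setMethod("seqIds", "Alignment", function(x) x@ids)

#' @rdname seqLengths
#' @export
setMethod("seqLengths", "SequenceSet", function(x) {
  stats::setNames(nchar(x@seqs), x@ids)
})

#' @rdname sequences
#' @export
setMethod("sequences", "SequenceSet", function(x) stats::setNames(x@seqs, x@ids))

#' @rdname isAmbiguous
#' @export
setMethod("isAmbiguous", "matrix", function(x) {
  nrow(x) > 0L && anyDuplicated(x[, 1L]) > 0L
})

setMethod("show", "SequenceSet", function(object) {
  cat("SequenceSet of", length(object@ids), "sequences (",
      object@alphabet, "alphabet ), total length",
      sum(nchar(object@seqs)), "\n")
  n <- min(5L, length(object@ids))
  for (i in seq_len(n))
    cat(" ", object@ids[i], " (", nchar(object@seqs[i]), " residues)\n", sep = "")
  if (length(object@ids) > n) cat("  ...\n")
})

## ---- ColumnSet -----------------------------------------------------------

#' Construct a ColumnSet
#'
#' @param columns list of 2-column (seq, pos) integer matrices, 0-based.
#' @param seqIds character identifiers of the underlying sequences.
#' @param sMin integer spanning threshold recorded with the set (NA when
#'   not applicable).
#' @return a [ColumnSet]; columns are stored with rows sorted by sequence.
#' @export
ColumnSet <- function(columns, seqIds, sMin = NA_integer_) {
  columns <- lapply(columns, function(m) {
    m <- matrix(as.integer(m), ncol = 2L,
                dimnames = list(NULL, c("seq", "pos")))
    m[order(m[, 1L]), , drop = FALSE]
  })
  new("ColumnSet", columns = columns, seqIds = as.character(seqIds),
      sMin = as.integer(sMin))
}

#' @rdname columns
#' @export
setMethod("columns", "ColumnSet", function(x) x@columns)

#' @rdname nColumns
#' @export
setMethod("nColumns", "ColumnSet", function(x) length(x@columns))

#' @describeIn nColumns `length()` counts columns too.
#' @param x a [ColumnSet].
#' @export
setMethod("length", "ColumnSet", function(x) length(x@columns))

setMethod("show", "ColumnSet", function(object) {
  k <- length(object@columns)
  cat("ColumnSet:", k, "partial column(s) over",
      length(object@seqIds), "sequence(s)")
  if (!is.na(object@sMin)) cat(", s_min =", object@sMin)
  cat("\n")
  if (k) {
    sizes <- vapply(object@columns, nrow, integer(1))
    cat("  column sizes:", paste(utils::head(sizes, 10L), collapse = " "),
        if (k > 10L) "..." else "", "\n")
  }
})

## ---- partial-column text format -----------------------------------------
## Interchange format: one column per line, whitespace-separated
## `seqid:pos` tokens with 1-based positions.

#' Write a ColumnSet in the partial-column text format
#'
#' One column per line; each site is a `seqid:pos` token with 1-based
#' position.
#'
#' @param cols a [ColumnSet].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeColumns <- function(cols, path) {
  stopifnot(is(cols, "ColumnSet"))
  lines <- vapply(cols@columns, function(m) {
    paste(sprintf("%s:%d", cols@seqIds[m[, 1L] + 1L], m[, 2L] + 1L),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ColumnSet from the partial-column text format
#'
#' @param path input file path.
#' @param seqs optional [SequenceSet] supplying the sequence universe; when
#'   absent, sequence identifiers are collected in order of first
#'   appearance.
#' @return a [ColumnSet].
#' @export
readColumns <- function(path, seqs = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  pieces <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^(.*):([0-9]+)$", tk))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) stop("malformed column token: ", tk[bad][1L])
    list(id = vapply(m, `[`, character(1), 2L),
         pos = as.integer(vapply(m, `[`, character(1), 3L)) - 1L)
  })
  ids <- if (is.null(seqs)) unique(unlist(lapply(pieces, `[[`, "id")))
         else seqIds(seqs)
  cols <- lapply(pieces, function(p) {
    sx <- match(p$id, ids) - 1L
    if (anyNA(sx)) stop("unknown sequence identifier: ",
                        p$id[which(is.na(sx))[1L]])
    cbind(seq = sx, pos = p$pos)
  })
  ColumnSet(cols, seqIds = ids)
}
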
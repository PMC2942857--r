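#' @include sitespace.R
NULL

#' N-local decoding of a sequence collection
#'
#' Clusters sites by shared word context.  A word w of length N occurs at
#' position i relative to a site (s, p) when the substring of sequence s
#' starting at p - i and of length N equals w.  Two sites are directly
#' related when an identical length-N word occurs at the same relative
#' position for both; a single word occurrence pair induces N instances of
#' the relation, one per offset.  The N-local decoding is the partition of
#' the site space induced by the transitive closure of this relation:
#' sites are clustered when a chain of identical-word occurrences connects
#' them.
#'
#' Implemented by hashing all length-N windows (words never span sequence
#' boundaries) and merging, for every repeated word and every offset
#' 0 <= i < N, the sites at that offset across all occurrences with a
#' union-find structure.  Representatives are the smallest member in
#' sequence-major order, so class enumeration is reproducible.
#'
#' @param seqs a [SequenceSet].
#' @param N word length, between 1 and the longest sequence.
#' @return an [NldPartition].
#' @examples
#' s <- SequenceSet(c(a = "ACGT", b = "ACGT"), alphabet = "dna")
#' siteClasses(nldPartition(s, 4))   # four classes {(0,p),(1,p)}
#' @export
nldPartition <- function(seqs, N) {
  stopifnot(is(seqs, "SequenceSet"))
  lens <- unname(seqLengths(seqs))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N > max(lens))
    stop("word length N must satisfy 1 <= N <= ", max(lens))
  N <- as.integer(N)
  L <- sum(lens)
  off <- .offsets(lens)
  ss <- unname(sequences(seqs))

  words <- character(0)
  gids <- integer(0)
  for (i in seq_along(ss)) {
    l <- lens[i]
    if (l < N) next
    starts <- seq_len(l - N + 1L)
    words <- c(words, substring(ss[i], starts, starts + N - 1L))
    gids <- c(gids, off[i] + starts)
  }

  parent <- seq_len(L)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }

  if (length(gids)) {
    for (g in split(gids, words)) {
      if (length(g) < 2L) next
      for (i in 0:(N - 1L)) {
        a <- find(g[1L] + i)
        for (j in 2:length(g)) {
          b <- find(g[j] + i)
          if (a != b) {
            ## union by minimum: the root of a class is its smallest site
            if (a < b) parent[b] <- a else { parent[a] <- b; a <- b }
          }
        }
      }
    }
  }
  membership <- vapply(seq_len(L), find, integer(1))
  new("NldPartition", N = N, membership = membership, lengths = lens)
}

#' All N-local decodings up to the trivial level
#'
#' Computes the partitions for N = 1, 2, ... and stops at the first N
#' where every class is a singleton (larger N cannot merge anything), at
#' `nMax`, or at the longest sequence length, whichever comes first.
#'
#' @param seqs a [SequenceSet].
#' @param nMax optional cap on the word length.
#' @return list of [NldPartition], element i holding the level-i partition.
#' @export
nldAll <- function(seqs, nMax = NULL) {
  stopifnot(is(seqs, "SequenceSet"))
  maxlen <- max(seqLengths(seqs))
  stopN <- if (is.null(nMax)) maxlen else min(as.integer(nMax), maxlen)
  out <- vector("list", 0L)
  for (N in seq_len(stopN)) {
    p <- nldPartition(seqs, N)
    out[[N]] <- p
    if (all(p@membership == seq_along(p@membership))) break
  }
  out
}

#' @rdname siteClasses
#' @export
setMethod("siteClasses", "NldPartition", function(x) {
  groups <- split(seq_along(x@membership), x@membership)
  groups <- groups[order(as.integer(names(groups)))]
  lapply(groups, .sites_matrix, lengths = x@lengths)
})

#' Number of classes of a partition
#' @param x an [NldPartition].
#' @return integer count (singletons included).
#' @export
nClasses <- function(x) {
  stopifnot(is(x, "NldPartition"))
  length(unique(x@membership))
}

setMethod("show", "NldPartition", function(object) {
  k <- length(unique(object@membership))
  cat("NldPartition (N =", object@N, "):", k, "classes over",
      length(object@membership), "sites\n")
})
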
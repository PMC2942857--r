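#' @include evaluate.R
NULL

.SAMPLE_ALPHABETS <- list(protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          dna = c("A", "C", "G", "T"))

#' Specification for a planted-motif sequence set
#'
#' Describes a seeded fixture: `nSeqs` background sequences with exact
#' motif copies planted at random non-overlapping offsets in their carrier
#' sequences.  Optional swap directives transpose the order of two motifs
#' in chosen sequences, creating succession cycles for the consistency
#' engine to resolve.
#'
#' @param motifs character vector of motif strings (uppercase residues).
#' @param nSeqs number of sequences.
#' @param lengthRange integer range (min, max) of the sequence lengths.
#' @param alphabet `"protein"` (20 standard residues) or `"dna"`.
#' @param carriers list, one integer vector of 1-based carrier sequence
#'   indices per motif; defaults to all sequences for every motif.
#' @param swaps list of swap directives, each a list with elements
#'   `first`, `second` (motif indices) and `seqs` (1-based sequence
#'   indices in which the order of the two motifs is transposed).
#' @param seed RNG seed; generation is deterministic under a fixed seed.
#' @return a `plantSpec` list, input to [generatePlanted()].
#' @export
plantSpec <- function(motifs, nSeqs = 4L, lengthRange = c(80L, 120L),
                      alphabet = c("protein", "dna"), carriers = NULL,
                      swaps = NULL, seed = 1L) {
  alphabet <- match.arg(alphabet)
  motifs <- toupper(as.character(motifs))
  if (!length(motifs) || any(!nzchar(motifs)))
    stop("at least one non-empty motif is required")
  if (is.null(carriers))
    carriers <- rep(list(seq_len(nSeqs)), length(motifs))
  if (length(carriers) != length(motifs))
    stop("one carrier set per motif is required")
  structure(list(motifs = motifs, nSeqs = as.integer(nSeqs),
                 lengthRange = as.integer(lengthRange), alphabet = alphabet,
                 carriers = lapply(carriers, as.integer),
                 swaps = swaps, seed = as.integer(seed)),
            class = "plantSpec")
}

## Restore the caller's RNG state on exit.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a planted-motif sequence set with its ground truth
#'
#' Backgrounds are sampled i.i.d. from the alphabet; motif copies are
#' planted exactly, pairwise non-overlapping, in catalogue order (swapped
#' where a directive applies).  A sequence is re-sampled (up to a retry
#' cap) when any motif occurs somewhere other than its planted offsets,
#' so planted occurrences are the only multi-sequence repeats,
#' best-effort.  The truth columns are computed from the final sequences:
#' one column per motif offset across its carriers (motifs carried by a
#' single sequence yield no truth column).
#'
#' @param spec a [plantSpec()].
#' @return list with elements `seqs` (a [SequenceSet]), `truth` (a
#'   [ColumnSet] of the planted columns, ordered by leftmost site) and
#'   `layout` (data.frame motif / seq / start, 0-based starts).
#' @export
generatePlanted <- function(spec) {
  stopifnot(inherits(spec, "plantSpec"))
  ab <- .SAMPLE_ALPHABETS[[spec$alphabet]]
  nm <- length(spec$motifs)
  mlen <- nchar(spec$motifs)

  .with_seed(spec$seed, {
    seqsChr <- character(spec$nSeqs)
    layout <- data.frame(motif = integer(0), seq = integer(0),
                         start = integer(0))
    for (s in seq_len(spec$nSeqs)) {
      mine <- which(vapply(spec$carriers, function(k) s %in% k, logical(1)))
      ord <- mine
      for (sw in spec$swaps) {
        if (s %in% sw$seqs) {
          i <- match(sw$first, ord); j <- match(sw$second, ord)
          if (!is.na(i) && !is.na(j)) ord[c(i, j)] <- ord[c(j, i)]
        }
      }
      need <- sum(mlen[ord])
      if (need > max(spec$lengthRange))
        stop("infeasible spec: motifs (", need,
             " residues) do not fit in sequence length ",
             max(spec$lengthRange))
      ok <- FALSE
      for (try in seq_len(50L)) {
        lo <- max(spec$lengthRange[1L], need)
        len <- lo + sample.int(spec$lengthRange[2L] - lo + 1L, 1L) - 1L
        bg <- len - need
        gaps <- as.integer(stats::rmultinom(1L, bg, rep(1, length(ord) + 1L)))
        chunks <- character(0)
        starts <- integer(length(ord))
        at <- 0L
        for (t in seq_along(ord)) {
          chunks <- c(chunks, paste(sample(ab, gaps[t], replace = TRUE),
                                    collapse = ""))
          at <- at + gaps[t]
          starts[t] <- at
          chunks <- c(chunks, spec$motifs[ord[t]])
          at <- at + mlen[ord[t]]
        }
        chunks <- c(chunks, paste(sample(ab, gaps[length(gaps)],
                                         replace = TRUE), collapse = ""))
        cand <- paste(chunks, collapse = "")
        ## collision screen: every motif must occur exactly at its planted
        ## offsets in this sequence and nowhere else
        clean <- TRUE
        for (mi in seq_len(nm)) {
          occ <- gregexpr(spec$motifs[mi], cand, fixed = TRUE)[[1L]]
          occ <- if (occ[1L] == -1L) integer(0) else as.integer(occ) - 1L
          want <- if (mi %in% ord) starts[match(mi, ord)] else integer(0)
          if (!identical(sort(occ), sort(want))) { clean <- FALSE; break }
        }
        if (clean) { ok <- TRUE; break }
      }
      ## best-effort: after the retry cap, accept the last candidate
      seqsChr[s] <- cand
      if (length(ord))
        layout <- rbind(layout, data.frame(motif = ord, seq = s - 1L,
                                           start = starts))
      invisible(ok)
    }
    seqs <- SequenceSet(seqsChr, ids = sprintf("seq%d", seq_len(spec$nSeqs)),
                        alphabet = if (spec$alphabet == "protein") "protein"
                                   else "dna")
    cols <- list()
    for (mi in seq_len(nm)) {
      sub <- layout[layout$motif == mi, , drop = FALSE]
      if (nrow(sub) < 2L) next
      for (t in seq_len(mlen[mi]) - 1L) {
        cols[[length(cols) + 1L]] <- cbind(seq = sub$seq,
                                           pos = sub$start + t)
      }
    }
    if (length(cols)) {
      left <- vapply(cols, function(m)
        min(.gid(m[, 1L], m[, 2L], unname(seqLengths(seqs)))), integer(1))
      cols <- cols[order(left)]
    }
    list(seqs = seqs,
         truth = ColumnSet(cols, seqIds = seqIds(seqs)),
         layout = layout)
  })
}
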
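## Independent oracles and random-instance generators shared across tests.
## The oracles deliberately take different computational routes from the
## implementation: the NLD oracle materialises the direct relation edge by
## edge and asks an off-the-shelf connected-components routine for its
## transitive closure, and the consistency oracle runs a hand-rolled
## Warshall closure over the site order, whereas the package uses
## union-find and succession-graph acyclicity respectively.

## ---- NLD oracle ----------------------------------------------------------

## Canonical membership (smallest global site id per class) of the N-local
## decoding, via explicit relation edges + graph components.
oracle_nld_membership <- function(chrs, N) {
  lens <- nchar(chrs)
  L <- sum(lens)
  off <- c(0L, cumsum(lens))
  from <- integer(0); to <- integer(0)
  words <- character(0); gids <- integer(0)
  for (i in seq_along(chrs)) {
    if (lens[i] < N) next
    starts <- seq_len(lens[i] - N + 1L)
    words <- c(words, substring(chrs[i], starts, starts + N - 1L))
    gids <- c(gids, off[i] + starts)
  }
  for (g in split(gids, words)) {
    m <- length(g)
    if (m < 2L) next
    pr <- utils::combn(m, 2L)
    for (i in 0:(N - 1L)) {
      from <- c(from, g[pr[1L, ]] + i)
      to <- c(to, g[pr[2L, ]] + i)
    }
  }
  if (!length(from)) return(seq_len(L))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE, vertices = data.frame(name = as.character(seq_len(L))))
  comp <- igraph::components(gr)$membership
  ids <- as.integer(names(comp))
  memb <- integer(L)
  for (cl in split(ids, comp)) memb[cl] <- min(cl)
  memb
}

nld_membership <- function(p) {
  ## canonical form of an NldPartition (representatives are already minima)
  p@membership
}

random_seqset <- function(nseq = NULL, maxlen = 40L, alphabet_size = NULL) {
  if (is.null(nseq)) nseq <- sample(2:8, 1L)
  if (is.null(alphabet_size)) alphabet_size <- sample(c(2L, 4L, 20L), 1L)
  ab <- LETTERS[seq_len(alphabet_size)]
  chrs <- vapply(seq_len(nseq), function(i)
    paste(sample(ab, sample(3:maxlen, 1L), replace = TRUE), collapse = ""),
    character(1))
  SequenceSet(chrs, ids = sprintf("s%d", seq_len(nseq)), alphabet = "raw")
}

## ---- consistency oracle --------------------------------------------------

## Order-theoretic consistency check: close the union of the per-sequence
## successor order and the column equivalence under transitivity (Warshall)
## and verify the closure restricted to each sequence coincides with the
## left-to-right order, i.e. never relates a site to a strictly earlier
## site of the same sequence.
oracle_consistent <- function(cols) {
  cm <- columns(cols)
  if (!length(cm)) return(TRUE)
  sites <- unique(do.call(rbind, cm))
  key <- paste(sites[, 1L], sites[, 2L])
  n <- nrow(sites)
  adj <- matrix(FALSE, n, n)
  ## successor edges along each sequence (restricted to column sites)
  for (s in unique(sites[, 1L])) {
    ii <- which(sites[, 1L] == s)
    ii <- ii[order(sites[ii, 2L])]
    if (length(ii) >= 2L)
      for (t in seq_len(length(ii) - 1L)) adj[ii[t], ii[t + 1L]] <- TRUE
  }
  ## column equivalence, both directions
  for (m in cm) {
    ii <- match(paste(m[, 1L], m[, 2L]), key)
    for (a in ii) for (b in ii) if (a != b) adj[a, b] <- TRUE
  }
  for (k in seq_len(n))
    adj <- adj | (adj[, k] %o% adj[k, ])
  for (s in unique(sites[, 1L])) {
    ii <- which(sites[, 1L] == s)
    for (a in ii) for (b in ii)
      if (sites[a, 2L] < sites[b, 2L] && adj[b, a]) return(FALSE)
  }
  TRUE
}

## Random disjoint non-ambiguous column sets; cyclic instances arise
## naturally from the unconstrained position draws.
random_columnset <- function(nseq = NULL, maxpos = NULL, ncol_max = 6L) {
  if (is.null(nseq)) nseq <- sample(2:5, 1L)
  if (is.null(maxpos)) maxpos <- sample(4:12, 1L)
  free <- lapply(seq_len(nseq), function(s) sample(seq_len(maxpos) - 1L))
  cols <- list()
  for (j in seq_len(sample(seq_len(ncol_max), 1L))) {
    span <- sample(seq_len(nseq), sample(2:nseq, 1L))
    avail <- vapply(free[span], length, integer(1)) > 0L
    span <- span[avail]
    if (length(span) < 2L) next
    m <- cbind(seq = span - 1L,
               pos = vapply(span, function(s) {
                 p <- free[[s]][1L]
                 free[[s]] <<- free[[s]][-1L]
                 p
               }, integer(1)))
    cols[[length(cols) + 1L]] <- m
  }
  ColumnSet(cols, seqIds = sprintf("s%d", seq_len(nseq)))
}

columnset_signature <- function(cols) {
  lapply(columns(cols), function(m) m[order(m[, 1L]), , drop = FALSE])
}

sg_is_acyclic <- function(cols) isConsistent(cols)

## ---- alignment generators and scorer oracles -----------------------------

## A random alignment of given ungapped sequences: each row scatters its
## residues over a common width.
random_alignment_of <- function(chrs, width = NULL) {
  lens <- nchar(chrs)
  if (is.null(width)) width <- max(lens) + sample(0:4, 1L)
  rows <- vapply(seq_along(chrs), function(i) {
    slots <- sort(sample(seq_len(width), lens[i]))
    r <- rep("-", width)
    r[slots] <- strsplit(chrs[i], "")[[1L]]
    paste(r, collapse = "")
  }, character(1))
  Alignment(rows, ids = sprintf("s%d", seq_along(chrs)))
}

random_alignment_pair <- function(nseq = 3L, len_range = c(4L, 10L),
                                  alphabet = LETTERS[1:4]) {
  chrs <- vapply(seq_len(nseq), function(i)
    paste(sample(alphabet, sample(len_range[1L]:len_range[2L], 1L),
                 replace = TRUE), collapse = ""), character(1))
  list(ref = random_alignment_of(chrs), test = random_alignment_of(chrs))
}

## Explicit site-pair sets for the brute-force scorer oracles.
aln_site_pairs <- function(aln, cols_keep = NULL) {
  ch <- do.call(rbind, strsplit(aln@rows, ""))
  if (is.null(cols_keep)) cols_keep <- seq_len(ncol(ch))
  u <- apply(ch != "-" & ch != ".", 1L, cumsum)
  if (is.null(dim(u))) u <- matrix(u, ncol = nrow(ch))
  out <- character(0)
  for (cc in cols_keep) {
    rows <- which(ch[, cc] != "-" & ch[, cc] != ".")
    if (length(rows) < 2L) next
    pr <- utils::combn(rows, 2L)
    out <- c(out, paste(pr[1L, ], u[cc, pr[1L, ]],
                        pr[2L, ], u[cc, pr[2L, ]]))
  }
  out
}

oracle_sp <- function(test, ref, core_cols) {
  refp <- aln_site_pairs(ref, core_cols)
  testp <- aln_site_pairs(test)
  if (!length(refp)) return(NA_real_)
  100 * sum(refp %in% testp) / length(refp)
}

oracle_tc <- function(test, ref, core_cols, explicit = FALSE) {
  refch <- do.call(rbind, strsplit(ref@rows, ""))
  testch <- do.call(rbind, strsplit(test@rows, ""))
  uref <- apply(refch != "-" & refch != ".", 1L, cumsum)
  if (is.null(dim(uref))) uref <- matrix(uref, ncol = nrow(refch))
  utest <- lapply(seq_len(nrow(testch)),
                  function(i) which(testch[i, ] != "-" & testch[i, ] != "."))
  num <- 0L; den <- 0L
  for (cc in core_cols) {
    rows <- which(refch[, cc] != "-" & refch[, cc] != ".")
    if (!explicit && length(rows) < 2L) next
    den <- den + 1L
    tc <- vapply(rows, function(i) utest[[i]][uref[cc, i]], integer(1))
    if (length(tc) <= 1L || length(unique(tc)) == 1L) num <- num + 1L
  }
  if (!den) return(NA_real_)
  100 * num / den
}

## ---- small shared fixtures ----------------------------------------------

worked_example_columns <- function() {
  ## three sequences; seq1 carries B and C in swapped order
  A <- rbind(c(0, 0), c(1, 0), c(2, 0))
  B <- rbind(c(0, 1), c(1, 2), c(2, 1))
  C <- rbind(c(0, 2), c(1, 1), c(2, 2))
  ColumnSet(list(A, B, C), seqIds = c("s0", "s1", "s2"))
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
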
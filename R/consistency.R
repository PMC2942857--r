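#' @include ms4.R
NULL

.MARKERS <- c("v_start", "v_end")

.col_vertex <- function(i) paste0("C", i)

.empty_edges <- function() {
  data.frame(from = character(0), to = character(0), weight = integer(0),
             stringsAsFactors = FALSE)
}

## Flat (column, seq, pos) table of a ColumnSet.
.flat_sites <- function(cols) {
  k <- length(cols@columns)
  if (!k) return(data.frame(col = integer(0), seq = integer(0),
                            pos = integer(0)))
  do.call(rbind, lapply(seq_len(k), function(i) {
    m <- cols@columns[[i]]
    data.frame(col = rep.int(i, nrow(m)), seq = m[, 1L], pos = m[, 2L])
  }))
}

.sg_igraph <- function(edges, vertices) {
  igraph::graph_from_data_frame(edges[, c("from", "to"), drop = FALSE],
                                directed = TRUE,
                                vertices = data.frame(name = vertices))
}

.is_acyclic <- function(edges, vertices) {
  if (!nrow(edges)) return(TRUE)
  igraph::is_dag(.sg_igraph(edges, vertices))
}

#' Build the succession graph of a column set
#'
#' Vertices are the column ids plus the markers `v_start` and `v_end`.
#' There is an edge (C, C') iff some sequence carries both columns with
#' the site of C strictly left of the site of C'; the weight is the number
#' of such sequences.  `v_start` points to every column that is leftmost
#' (has no predecessor column) in at least one sequence; dually columns
#' that are rightmost somewhere point to `v_end`.
#'
#' @param cols a [ColumnSet] of non-ambiguous, pairwise disjoint columns.
#' @return a [SuccessionGraph].
#' @export
buildSuccessionGraph <- function(cols) {
  stopifnot(is(cols, "ColumnSet"))
  if (any(vapply(cols@columns, isAmbiguous, logical(1))))
    stop("contract violation: ambiguous column in input")
  k <- length(cols@columns)
  verts <- c(.col_vertex(seq_len(k)), .MARKERS)
  flat <- .flat_sites(cols)
  from <- character(0); to <- character(0)
  for (s in unique(flat$seq)) {
    sub <- flat[flat$seq == s, , drop = FALSE]
    ord <- sub$col[order(sub$pos)]
    m <- length(ord)
    if (m >= 2L) {
      idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      from <- c(from, .col_vertex(ord[idx[, "row"]]))
      to <- c(to, .col_vertex(ord[idx[, "col"]]))
    }
    from <- c(from, "v_start", .col_vertex(ord[m]))
    to <- c(to, .col_vertex(ord[1L]), "v_end")
  }
  if (length(from)) {
    tab <- table(paste(from, to, sep = "\r"))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    e <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                    to = vapply(parts, `[`, character(1), 2L),
                    weight = as.integer(tab), stringsAsFactors = FALSE)
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  } else e <- .empty_edges()
  new("SuccessionGraph", edges = e, vertices = verts)
}

#' @rdname sgEdges
#' @export
setMethod("sgEdges", "SuccessionGraph", function(x) x@edges)

setMethod("show", "SuccessionGraph", function(object) {
  inter <- object@edges[!(object@edges$from %in% .MARKERS |
                            object@edges$to %in% .MARKERS), , drop = FALSE]
  cat("SuccessionGraph:", length(object@vertices) - 2L, "column vertices,",
      nrow(inter), "inter-column edge(s)\n")
})

#' Is a column set consistent with some multiple alignment?
#'
#' A set of partial columns is consistent when the joint order induced by
#' the columns and the left-to-right order of each sequence restricts to
#' the original order on every sequence; equivalently, when the succession
#' graph restricted to inter-column edges is acyclic.
#'
#' @param cols a [ColumnSet].
#' @return logical scalar.
#' @export
isConsistent <- function(cols) {
  g <- buildSuccessionGraph(cols)
  inter <- g@edges[!(g@edges$from %in% .MARKERS |
                       g@edges$to %in% .MARKERS), , drop = FALSE]
  .is_acyclic(inter, g@vertices)
}

#' Break succession-graph cycles by weight thresholding
#'
#' Heuristic for the (NP-hard) minimum weighted feedback arc set: find the
#' smallest threshold k >= 0 such that keeping only inter-column edges of
#' weight > k (edges incident to `v_start`/`v_end` are always kept) yields
#' an acyclic graph, and discard the rest.  An already-acyclic graph
#' returns k* = 0 with nothing removed: discarding edges only weakens the
#' induced order and would cause needless site loss downstream.  The
#' filtered graph may be disconnected, so it is reconnected by adding
#' `v_start -> u` for every column without a predecessor and `u -> v_end`
#' for every column without a successor.
#'
#' @param g a [SuccessionGraph].
#' @return a [DagifyResult].
#' @export
dagify <- function(g) {
  stopifnot(is(g, "SuccessionGraph"))
  e <- g@edges
  interIdx <- !(e$from == "v_start" | e$to == "v_end")
  candidates <- c(0L, sort(unique(e$weight[interIdx])))
  kStar <- NA_integer_
  kept <- e
  for (k in candidates) {
    keep <- !interIdx | e$weight > k
    if (.is_acyclic(e[keep, , drop = FALSE], g@vertices)) {
      kStar <- as.integer(k)
      kept <- e[keep, , drop = FALSE]
      break
    }
  }
  removed <- e[interIdx & e$weight <= kStar, , drop = FALSE]
  ## reconnect so that every column is reachable from v_start and reaches v_end
  colVerts <- setdiff(g@vertices, .MARKERS)
  noIn <- setdiff(colVerts, kept$to)
  noOut <- setdiff(colVerts, kept$from)
  if (length(noIn))
    kept <- rbind(kept, data.frame(from = "v_start", to = noIn,
                                   weight = 0L, stringsAsFactors = FALSE))
  if (length(noOut))
    kept <- rbind(kept, data.frame(from = noOut, to = "v_end",
                                   weight = 0L, stringsAsFactors = FALSE))
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  new("DagifyResult", kStar = kStar, keptEdges = kept,
      removedEdges = removed, vertices = g@vertices)
}

#' @rdname kStar
#' @export
setMethod("kStar", "DagifyResult", function(x) x@kStar)

#' @rdname kStar
#' @export
setMethod("kStar", "ResolutionTrace", function(x) x@kStar)

#' @rdname sgEdges
#' @export
setMethod("sgEdges", "DagifyResult", function(x) x@keptEdges)

setMethod("show", "DagifyResult", function(object) {
  cat("DagifyResult: k* =", object@kStar, "(",
      nrow(object@removedEdges), "edge(s) removed )\n")
})

## Lexicographic order on integer id vectors (equal lengths in our use).
.lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Remove order-inconsistencies from a column set
#'
#' Runs the full resolution procedure: build the succession graph, break
#' its cycles with [dagify()], take the transitive closure of the
#' resulting DAG, and for each sequence keep the columns on a longest
#' start-to-end chain compatible with both the closure order and the
#' sequence's own left-to-right order; columns off the chain lose their
#' site in that sequence.  Columns left with fewer than two sites are
#' dropped.  The succession graph of the output is guaranteed acyclic
#' (asserted internally).
#'
#' Each sequence's computation reads only the closure and that sequence's
#' site order, so the processing order of sequences is immaterial;
#' `sequenceOrder` exists so this can be demonstrated.  Ties among
#' maximal-length chains are broken deterministically: prefer the chain
#' whose columns carry the most sites in the input set, then the
#' lexicographically smallest column-id sequence.
#'
#' @param cols a [ColumnSet] of non-ambiguous, pairwise disjoint columns.
#' @param sequenceOrder optional permutation of the touched 0-based
#'   sequence indices; the result is identical for every permutation.
#' @return a [ResolutionTrace].
#' @export
resolveColumns <- function(cols, sequenceOrder = NULL) {
  stopifnot(is(cols, "ColumnSet"))
  k <- length(cols@columns)
  g <- buildSuccessionGraph(cols)
  d <- dagify(g)

  removed <- data.frame(seq = integer(0), pos = integer(0),
                        column = integer(0))
  chains <- list()
  if (k) {
    ig <- .sg_igraph(d@keptEdges, d@vertices)
    dm <- igraph::distances(ig, mode = "out", weights = NA)
    reach <- is.finite(dm) & dm > 0   # (u,v) in the closure E+
    sizes <- vapply(cols@columns, nrow, integer(1))
    flat <- .flat_sites(cols)
    touched <- sort(unique(flat$seq))
    ord <- if (is.null(sequenceOrder)) touched else as.integer(sequenceOrder)
    if (!setequal(ord, touched))
      stop("sequenceOrder must be a permutation of the touched sequences")

    for (s in ord) {
      sub <- flat[flat$seq == s, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      idv <- sub$col
      m <- length(idv)
      vn <- .col_vertex(idv)
      ## longest v_start -> v_end path in the chain graph of this sequence:
      ## DP over the sequence order, edges are closure pairs.
      len <- integer(m); wt <- numeric(m); paths <- vector("list", m)
      for (j in seq_len(m)) {
        len[j] <- 1L; wt[j] <- sizes[idv[j]]; paths[[j]] <- idv[j]
        if (j > 1L) for (i in seq_len(j - 1L)) {
          if (!reach[vn[i], vn[j]]) next
          cl <- len[i] + 1L; cw <- wt[i] + sizes[idv[j]]
          if (cl > len[j] || (cl == len[j] && (cw > wt[j] ||
                (cw == wt[j] && .lex_less(c(paths[[i]], idv[j]), paths[[j]]))))) {
            len[j] <- cl; wt[j] <- cw; paths[[j]] <- c(paths[[i]], idv[j])
          }
        }
      }
      best <- 0L
      for (j in seq_len(m)) {
        if (best == 0L || len[j] > len[best] ||
            (len[j] == len[best] && (wt[j] > wt[best] ||
              (wt[j] == wt[best] && .lex_less(paths[[j]], paths[[best]])))))
          best <- j
      }
      chain <- if (m) paths[[best]] else integer(0)
      chains[[as.character(s)]] <- chain
      drop <- setdiff(idv, chain)
      if (length(drop)) {
        dsub <- sub[match(drop, sub$col), , drop = FALSE]
        removed <- rbind(removed, data.frame(seq = s, pos = dsub$pos,
                                             column = dsub$col))
      }
    }
  }

  newCols <- lapply(seq_len(k), function(i) {
    m <- cols@columns[[i]]
    rm <- removed[removed$column == i, , drop = FALSE]
    if (nrow(rm)) {
      keep <- !(paste(m[, 1L], m[, 2L]) %in% paste(rm$seq, rm$pos))
      m <- m[keep, , drop = FALSE]
    }
    m
  })
  newCols <- newCols[vapply(newCols, nrow, integer(1)) >= 2L]
  out <- ColumnSet(newCols, seqIds = cols@seqIds, sMin = cols@sMin)
  stopifnot(isConsistent(out))   # resolution must always end acyclic
  rownames(removed) <- NULL
  new("ResolutionTrace", chains = chains, removedSites = removed,
      columns = out, kStar = d@kStar)
}

#' @rdname removedSites
#' @export
setMethod("removedSites", "ResolutionTrace", function(x) x@removedSites)

#' @rdname columns
#' @export
setMethod("columns", "ResolutionTrace", function(x) x@columns)

setMethod("show", "ResolutionTrace", function(object) {
  cat("ResolutionTrace: k* =", object@kStar, ",",
      nrow(object@removedSites), "site(s) removed,",
      length(object@columns@columns), "column(s) kept\n")
})

#' Consistent partial columns
#'
#' Wrapper around [resolveColumns()] returning only the final consistent
#' column set.
#'
#' @param cols a [ColumnSet].
#' @return a [ColumnSet] whose succession graph is acyclic.
#' @export
consistentColumns <- function(cols) {
  resolveColumns(cols)@columns
}
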
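#' Construct an allele graph from explicit vertex read sets
#'
#' Low-level constructor used by [build_graph()] and by tests/examples that
#' need full control over the graph. Vertices at consecutive positions are
#' connected by an edge iff their read sets intersect; the edge carries that
#' intersection. Per vertex, the set of "new" reads (reads starting strictly
#' after the previous candidate position) is precomputed for the dynamic
#' program.
#'
#' @param positions Strictly increasing integer vector of 0-based reference
#'   coordinates of the candidate positions.
#' @param vertices List (one element per position) of vertex lists; each
#'   vertex is a list with `allele` (base string), `is_ref` (logical) and
#'   `reads` (non-empty character vector of read ids).
#' @param read_starts Named integer vector: 0-based alignment start per read
#'   id occurring in any vertex.
#'
#' @return Object of class `haplotag_graph`: a list with `positions`,
#'   `vertices`, `steps` (per position `n >= 2`, the edge structure from
#'   position `n-1`: logical matrices `exists` and `artificial`, and a
#'   list-matrix `reads` of edge read sets) and `new_reads`.
#' @export
haplotag_graph <- function(positions, vertices, read_starts) {
  positions <- as.integer(positions)
  P <- length(positions)
  stopifnot(length(vertices) == P)
  if (P > 1L && any(diff(positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  for (n in seq_len(P)) {
    if (length(vertices[[n]]) == 0L) stop("position ", n, " has no vertices")
    if (sum(vapply(vertices[[n]], function(v) isTRUE(v$is_ref), logical(1))) > 1L) {
      stop("more than one reference vertex at position ", n)
    }
    for (v in vertices[[n]]) {
      if (length(v$reads) == 0L) stop("vertex with empty read set at position ", n)
    }
  }
  all_reads <- unique(unlist(lapply(vertices, function(g) {
    unlist(lapply(g, `[[`, "reads"))
  })))
  if (!all(all_reads %in% names(read_starts))) {
    stop("read_starts missing entries for some supporting reads")
  }

  steps <- vector("list", P)
  for (n in seq_len(P)[-1L]) {
    prev <- vertices[[n - 1L]]
    cur <- vertices[[n]]
    K0 <- length(prev); K1 <- length(cur)
    exists <- matrix(FALSE, K0, K1)
    reads <- matrix(list(character(0)), K0, K1)
    for (k in seq_len(K0)) {
      for (i in seq_len(K1)) {
        shared <- intersect(prev[[k]]$reads, cur[[i]]$reads)
        if (length(shared) > 0L) {
          exists[k, i] <- TRUE
          reads[[k, i]] <- shared
        }
      }
    }
    steps[[n]] <- list(exists = exists, artificial = exists & FALSE, reads = reads)
  }

  new_reads <- vector("list", P)
  for (n in seq_len(P)) {
    new_reads[[n]] <- lapply(vertices[[n]], function(v) {
      if (n == 1L) character(0)
      else v$reads[read_starts[v$reads] > positions[n - 1L]]
    })
  }

  structure(
    list(positions = positions, vertices = vertices, steps = steps,
         new_reads = new_reads),
    class = "haplotag_graph"
  )
}

#' Build the allele graph for a window
#'
#' One vertex per allele with adequate support at each retained heterozygous
#' candidate position: every alternate allele (already supported by at least
#' `min_alt_support` reads) gets a vertex, and the reference allele gets one
#' iff it is supported by at least `min_ref_support` reads. Within a position
#' the reference vertex comes first, then alternate alleles lexicographically;
#' this ordering is the canonical vertex order used by the dynamic program.
#'
#' @param het_candidates Candidates from [select_het_snp_candidates()],
#'   sorted by position.
#' @param reads The `aligned_reads` data frame the candidates came from
#'   (alignment starts are needed to track reads entering the graph).
#' @param config A [candidate_filter_config()].
#'
#' @return A `haplotag_graph` (zero positions if no candidate yields a
#'   vertex).
#' @export
build_graph <- function(het_candidates, reads,
                        config = candidate_filter_config()) {
  groups <- list()
  positions <- integer(0)
  for (cd in het_candidates) {
    vs <- list()
    ref_sup <- cd$support[[cd$ref]]
    if (length(ref_sup) >= config$min_ref_support) {
      vs[[length(vs) + 1L]] <- list(allele = cd$ref, is_ref = TRUE, reads = ref_sup)
    }
    for (alt in sort(cd$alts)) {
      alt_sup <- cd$support[[alt]]
      if (length(alt_sup) >= config$min_alt_support) {
        vs[[length(vs) + 1L]] <- list(allele = alt, is_ref = FALSE, reads = alt_sup)
      }
    }
    if (length(vs) > 0L) {
      groups[[length(groups) + 1L]] <- vs
      positions <- c(positions, cd$position)
    }
  }
  if (length(positions) == 0L) {
    return(structure(
      list(positions = integer(0), vertices = list(), steps = list(),
           new_reads = list()),
      class = "haplotag_graph"
    ))
  }
  read_starts <- structure(as.integer(reads$start), names = reads$read_id)
  haplotag_graph(positions, groups, read_starts)
}

#' Add artificial edges to keep partially connected positions extendable
#'
#' For a position where some vertex has an incoming edge but another has
#' none, the orphan vertex is connected to every vertex of the previous
#' position by artificial edges carrying empty read sets, so the dynamic
#' program can still consider it. If no vertex at a position has an incoming
#' edge, nothing is added: the chain genuinely breaks there and
#' [split_segments()] will start a new segment instead.
#'
#' @param graph A `haplotag_graph`.
#' @return The graph with artificial edges added (idempotent).
#' @export
add_artificial_edges <- function(graph) {
  for (n in seq_along(graph$steps)[-1L]) {
    st <- graph$steps[[n]]
    incoming <- colSums(st$exists)
    if (any(incoming > 0L) && any(incoming == 0L)) {
      for (j in which(incoming == 0L)) {
        st$exists[, j] <- TRUE
        st$artificial[, j] <- TRUE
      }
      graph$steps[[n]] <- st
    }
  }
  graph
}

#' Split a graph into independently phaseable segments
#'
#' Segments are maximal runs of consecutive positions in which every step has
#' at least one edge. Between segments no read connects the two adjacent
#' positions, so scores cannot be extended and each segment is solved (and
#' phase-block labelled) independently.
#'
#' @param graph A `haplotag_graph`, after [add_artificial_edges()].
#' @return List of integer vectors `c(start, end)` of 1-based position
#'   indices, inclusive; empty list for an empty graph.
#' @export
split_segments <- function(graph) {
  P <- length(graph$positions)
  if (P == 0L) return(list())
  breaks <- integer(0)
  for (n in seq_len(P)[-1L]) {
    if (!any(graph$steps[[n]]$exists)) breaks <- c(breaks, n)
  }
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, P)
  mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
}

#' Render a graph as DOT text for inspection
#'
#' @param graph A `haplotag_graph`.
#' @return Character scalar with a `digraph` description (vertex labels show
#'   allele and read support; artificial edges are dashed).
#' @export
graph_to_dot <- function(graph) {
  lines <- c("digraph haplotag {", "  rankdir=LR;")
  for (n in seq_along(graph$positions)) {
    for (i in seq_along(graph$vertices[[n]])) {
      v <- graph$vertices[[n]][[i]]
      lines <- c(lines, sprintf(
        '  "p%d_v%d" [label="%d:%s%s (%d)"];',
        n, i, graph$positions[n], v$allele, if (isTRUE(v$is_ref)) "*" else "",
        length(v$reads)
      ))
    }
  }
  for (n in seq_along(graph$steps)[-1L]) {
    st <- graph$steps[[n]]
    for (k in seq_len(nrow(st$exists))) {
      for (i in seq_len(ncol(st$exists))) {
        if (st$exists[k, i]) {
          lines <- c(lines, sprintf(
            '  "p%d_v%d" -> "p%d_v%d" [label="%d"%s];',
            n - 1L, k, n, i, length(st$reads[[k, i]]),
            if (st$artificial[k, i]) ", style=dashed" else ""
          ))
        }
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.haplotag_graph <- function(x, ...) {
  P <- length(x$positions)
  nv <- sum(lengths(x$vertices))
  ne <- if (P > 1L) {
    sum(vapply(x$steps[-1L], function(st) sum(st$exists), integer(1)))
  } else 0L
  cat(sprintf("<haplotag_graph: %d position(s), %d vertices, %d edge(s)>\n",
              P, nv, ne))
  invisible(x)
}
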
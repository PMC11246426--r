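# Enumeration of vertex pairs at a position. Canonical pairs (i <= j) are
# the backward state of the dynamic program; ordered pairs additionally
# include (j, i). Row order defines all tie-breaking.
pair_grid <- function(K, canonical) {
  if (canonical) {
    i <- rep(seq_len(K), times = K - seq_len(K) + 1L)
    j <- unlist(lapply(seq_len(K), function(a) a:K))
  } else {
    i <- rep(seq_len(K), each = K)
    j <- rep(seq_len(K), times = K)
  }
  data.frame(i = i, j = j)
}

union_size <- function(...) length(unique(c(...)))

# One backward-state row per unordered pair: the better orientation, ties
# favouring the canonical (i <= j) row. Enumeration order follows the
# canonical pair order.
collapse_orientations <- function(tab) {
  key <- paste(pmin(tab$i, tab$j), pmax(tab$i, tab$j))
  canonical_first <- order(tab$i > tab$j)  # canonical rows first, stable
  tab <- tab[canonical_first, , drop = FALSE]
  key <- key[canonical_first]
  best <- tapply(seq_len(nrow(tab)), key, function(rows) {
    rows[which.max(tab$score[rows])]
  })
  out <- tab[sort(unname(best)), , drop = FALSE]
  out[order(pmin(out$i, out$j), pmax(out$i, out$j)), , drop = FALSE]
}

new_score_table <- function(df, position) {
  attr(df, "position") <- position
  class(df) <- c("pair_score_table", "data.frame")
  df
}

#' Initialize pair scores at the first position of a segment
#'
#' At the start of a segment the score of assigning vertex `i` to haplotype 1
#' and vertex `j` to haplotype 2 is the number of distinct reads supporting
#' either vertex: `S(i, j) = |R(i) u R(j)|`. Entries are created for all
#' canonical pairs `i <= j` (`i == j` is allowed and models a
#' homozygous-like position where one vertex carries both labels).
#'
#' @param graph A `haplotag_graph`.
#' @param position 1-based position index within the graph.
#'
#' @return A `pair_score_table`: data frame with columns `i`, `j`, `score`,
#'   `back_i`, `back_j` (both `NA` at initialization).
#' @export
initialize_scores <- function(graph, position = 1L) {
  if (length(graph$positions) == 0L) stop("empty graph")
  vs <- graph$vertices[[position]]
  if (length(vs) == 0L) stop("no vertices at position ", position)
  pg <- pair_grid(length(vs), canonical = TRUE)
  pg$score <- mapply(function(i, j) {
    union_size(vs[[i]]$reads, vs[[j]]$reads)
  }, pg$i, pg$j)
  pg$back_i <- NA_integer_
  pg$back_j <- NA_integer_
  new_score_table(pg, position)
}

#' Extend pair scores to the next position
#'
#' Computes, for every ordered vertex pair `(i, j)` at `position`, the best
#' extension from the previous position:
#' `S(n,i,j) = max over (k,l) { S(n-1,k,l) + |R(k,i) u R(l,j) u R*(i) u R*(j)| }`
#' where the maximum ranges over previous pairs `(k, l)` for which edges
#' `k -> i` and `l -> j` exist (artificial edges count as existing and
#' contribute empty read sets), `R(k,i)` is the read set of edge `k -> i`,
#' and `R*` is the set of reads starting after the previous position. Ties
#' are broken by the first maximizing pair in enumeration order. A pair with
#' no admissible predecessor gets no entry.
#'
#' In `"canonical"` mode (default) the backward state consists of one entry
#' per unordered previous pair: the better-scoring of its two orientations
#' (ties favour `k <= l`), attached role-preservingly (`k` extends the
#' haplotype-1 chain, `l` the haplotype-2 chain). Because a global label flip
#' of any assignment path preserves its score, this halved state is lossless:
#' the best final score equals that of `"symmetric"` mode, which keeps all
#' ordered pairs as predecessors. Individual intermediate entries may differ
#' between modes (they are orientation-dependent in canonical mode).
#'
#' @param graph A `haplotag_graph` (after [add_artificial_edges()]).
#' @param position 1-based index of the position being entered (`>= 2` within
#'   its segment).
#' @param prev_table The `pair_score_table` of the previous position.
#' @param pair_mode `"canonical"` or `"symmetric"`.
#'
#' @return A `pair_score_table` with one row per admissible ordered pair.
#' @export
extend_scores <- function(graph, position, prev_table,
                          pair_mode = c("canonical", "symmetric")) {
  pair_mode <- match.arg(pair_mode)
  st <- graph$steps[[position]]
  if (is.null(st)) stop("no step structure into position ", position)
  vs <- graph$vertices[[position]]
  rstar <- graph$new_reads[[position]]
  preds <- if (pair_mode == "canonical") {
    collapse_orientations(prev_table)
  } else {
    prev_table
  }
  pg <- pair_grid(length(vs), canonical = FALSE)
  rows <- vector("list", nrow(pg))
  for (r in seq_len(nrow(pg))) {
    i <- pg$i[r]; j <- pg$j[r]
    best <- -1L; bk <- NA_integer_; bl <- NA_integer_
    for (p in seq_len(nrow(preds))) {
      k <- preds$i[p]; l <- preds$j[p]
      if (st$exists[k, i] && st$exists[l, j]) {
        sc <- preds$score[p] +
          union_size(st$reads[[k, i]], st$reads[[l, j]], rstar[[i]], rstar[[j]])
        if (sc > best) {
          best <- sc; bk <- k; bl <- l
        }
      }
    }
    if (best >= 0L) {
      rows[[r]] <- data.frame(i = i, j = j, score = best,
                              back_i = bk, back_j = bl)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no pair at position ", position,
         " can be extended; reinitialization required (segment boundary?)")
  }
  new_score_table(out, position)
}

#' Run the pair-score dynamic program over a segment
#'
#' @param graph A `haplotag_graph` after [add_artificial_edges()].
#' @param segment Integer vector `c(start, end)` of 1-based position indices
#'   (as produced by [split_segments()]).
#' @param pair_mode See [extend_scores()].
#'
#' @return List of `pair_score_table`s, one per position of the segment.
#' @export
segment_scores <- function(graph, segment,
                           pair_mode = c("canonical", "symmetric")) {
  pair_mode <- match.arg(pair_mode)
  s <- segment[1L]; e <- segment[2L]
  tables <- vector("list", e - s + 1L)
  tables[[1L]] <- initialize_scores(graph, s)
  if (e > s) {
    for (n in seq.int(s + 1L, e)) {
      tables[[n - s + 1L]] <- extend_scores(graph, n, tables[[n - s]], pair_mode)
    }
  }
  tables
}

#' Backtrack the best-scoring haplotype assignment of alleles
#'
#' Selects the maximum-score pair at the last position of the segment (ties:
#' first in enumeration order) and follows back pointers to the segment
#' start. At every traversed pair `(i, j)`, vertex `i` is assigned haplotype
#' 1 and vertex `j` haplotype 2; when `i == j` the vertex carries both
#' labels.
#'
#' @param tables List of `pair_score_table`s from [segment_scores()].
#'
#' @return Object of class `allele_haplotags`: list with `best_score`, `path`
#'   (data frame `position`, `hap1_vertex`, `hap2_vertex`; `position` is the
#'   1-based index in the graph) and `vertex_tags` (data frame `position`,
#'   `vertex`, `haplotag`).
#' @export
backtrack_haplotags <- function(tables) {
  if (length(tables) == 0L) stop("empty score tables")
  Tn <- length(tables)
  last <- tables[[Tn]]
  best <- which.max(last$score)
  path_i <- integer(Tn); path_j <- integer(Tn)
  cur <- last[best, ]
  for (t in rev(seq_len(Tn))) {
    path_i[t] <- cur$i; path_j[t] <- cur$j
    if (t > 1L) {
      prev <- tables[[t - 1L]]
      hit <- which(prev$i == cur$back_i & prev$j == cur$back_j)
      if (length(hit) == 0L) stop("broken back pointer at step ", t)
      cur <- prev[hit[1L], ]
    }
  }
  positions <- vapply(tables, attr, integer(1), which = "position")
  vertex_tags <- rbind(
    data.frame(position = positions, vertex = path_i, haplotag = 1L),
    data.frame(position = positions, vertex = path_j, haplotag = 2L)
  )
  vertex_tags <- vertex_tags[order(vertex_tags$position, vertex_tags$haplotag), ]
  rownames(vertex_tags) <- NULL
  structure(
    list(
      best_score = last$score[best],
      path = data.frame(position = positions, hap1_vertex = path_i,
                        hap2_vertex = path_j),
      vertex_tags = vertex_tags
    ),
    class = "allele_haplotags"
  )
}

#' Exhaustive oracle for the best segment score
#'
#' Enumerates every admissible sequence of ordered (haplotype-1 vertex,
#' haplotype-2 vertex) pairs along the segment -- edges must exist
#' role-preservingly between consecutive pairs -- scoring each with the same
#' cumulative union formula as the dynamic program, and returns the maximum.
#' Both dynamic-programming pair modes optimize this objective (the halved
#' canonical backward state is lossless because a global label flip preserves
#' any path's score), so this single enumeration serves as the oracle for
#' either. Intended as an independent correctness check on small instances;
#' refuses instances whose path count exceeds `max_paths`.
#'
#' @param graph A `haplotag_graph` after [add_artificial_edges()].
#' @param segment `c(start, end)` position index range.
#' @param max_paths Enumeration guard.
#'
#' @return Integer: the best achievable segment score.
#' @export
brute_force_best_score <- function(graph, segment, max_paths = 2e5) {
  s <- segment[1L]; e <- segment[2L]
  idx <- s:e
  grids <- lapply(idx, function(t) {
    pair_grid(length(graph$vertices[[t]]), canonical = FALSE)
  })
  n_paths <- prod(vapply(grids, nrow, integer(1)))
  if (n_paths > max_paths) {
    stop("instance too large for exhaustive enumeration (", n_paths, " paths)")
  }

  vs1 <- graph$vertices[[s]]
  init <- mapply(function(i, j) union_size(vs1[[i]]$reads, vs1[[j]]$reads),
                 grids[[1L]]$i, grids[[1L]]$j)

  trans <- list()
  if (e > s) {
    for (t in seq.int(s + 1L, e)) {
      g0 <- grids[[t - s]]; g1 <- grids[[t - s + 1L]]
      st <- graph$steps[[t]]
      rstar <- graph$new_reads[[t]]
      m <- matrix(NA_real_, nrow(g0), nrow(g1))
      for (a in seq_len(nrow(g0))) {
        for (b in seq_len(nrow(g1))) {
          k <- g0$i[a]; l <- g0$j[a]; i <- g1$i[b]; j <- g1$j[b]
          if (st$exists[k, i] && st$exists[l, j]) {
            m[a, b] <- union_size(st$reads[[k, i]], st$reads[[l, j]],
                                  rstar[[i]], rstar[[j]])
          }
        }
      }
      trans[[t - s]] <- m
    }
  }

  choices <- lapply(grids, function(g) seq_len(nrow(g)))
  paths <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  total <- init[paths[, 1L]]
  if (length(trans) > 0L) {
    for (t in seq_along(trans)) {
      total <- total + trans[[t]][cbind(paths[, t], paths[, t + 1L])]
    }
  }
  total <- total[!is.na(total)]
  if (length(total) == 0L) stop("no admissible path through segment")
  as.integer(max(total))
}
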
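test_that("the worked-example pileup builds the expected two-position graph", {
  reads <- example_reads()
  ref <- example_reference()
  cfg <- candidate_filter_config()
  het <- select_het_snp_candidates(
    collect_allele_support(reads, ref, config = cfg), cfg
  )
  graph <- build_graph(het, reads, cfg)

  expect_equal(graph$positions, c(100L, 200L))
  expect_equal(lengths(graph$vertices), c(2L, 2L))
  # reference vertex first at each position
  expect_true(graph$vertices[[1]][[1]]$is_ref)
  expect_true(graph$vertices[[2]][[1]]$is_ref)
  sizes <- lapply(graph$vertices, function(g) vapply(g, function(v) length(v$reads), integer(1)))
  expect_equal(sizes[[1]], c(5L, 6L))
  expect_equal(sizes[[2]], c(4L, 7L))

  st <- graph$steps[[2]]
  expect_true(all(st$exists))
  edge_sizes <- matrix(vapply(st$reads, length, integer(1)), 2, 2)
  expect_equal(edge_sizes, matrix(c(3L, 1L, 2L, 5L), 2, 2))
  expect_false(any(st$artificial))
  # every read spans both positions: no new reads enter at position 2
  expect_true(all(lengths(graph$new_reads[[2]]) == 0))
  expect_equal(split_segments(graph), list(c(1L, 2L)))
})

test_that("degenerate graphs segment correctly", {
  rs <- function(...) structure(c(...), names = paste0("r", c(...)))
  one <- haplotag_graph(
    5L, list(list(list(allele = "A", is_ref = FALSE, reads = c("r1", "r2")))),
    structure(c(0L, 0L), names = c("r1", "r2"))
  )
  expect_equal(split_segments(one), list(c(1L, 1L)))

  # two positions, disjoint read sets: no edges, two segments
  two <- haplotag_graph(
    c(5L, 15L),
    list(
      list(list(allele = "A", is_ref = FALSE, reads = c("r1", "r2"))),
      list(list(allele = "C", is_ref = FALSE, reads = c("r3", "r4")))
    ),
    structure(c(0L, 0L, 12L, 12L), names = paste0("r", 1:4))
  )
  expect_false(any(two$steps[[2]]$exists))
  expect_identical(add_artificial_edges(two), two)  # nothing to connect
  expect_equal(split_segments(two), list(c(1L, 1L), c(2L, 2L)))

  empty <- build_graph(list(), make_reads(character(0), integer(0), character(0)))
  expect_equal(split_segments(empty), list())
})

test_that("artificial edges connect orphan vertices of reachable positions", {
  vertices <- list(
    list(
      list(allele = "A", is_ref = FALSE, reads = "r1"),
      list(allele = "C", is_ref = FALSE, reads = "r2")
    ),
    list(
      list(allele = "G", is_ref = FALSE, reads = "r1"),   # real edge from A
      list(allele = "T", is_ref = FALSE, reads = "r9")    # orphan: new read
    )
  )
  starts <- structure(c(0L, 0L, 10L), names = c("r1", "r2", "r9"))
  g <- haplotag_graph(c(5L, 15L), vertices, starts)
  expect_equal(unname(colSums(g$steps[[2]]$exists)), c(1L, 0L))

  g2 <- add_artificial_edges(g)
  st <- g2$steps[[2]]
  # the orphan is now reachable from every previous vertex, support-free
  expect_equal(unname(colSums(st$exists)), c(1L, 2L))
  expect_equal(unname(colSums(st$artificial)), c(0L, 2L))
  expect_true(all(lengths(st$reads[, 2]) == 0))
  # idempotent, and a fully connected graph is untouched
  expect_identical(add_artificial_edges(g2), g2)
  expect_equal(split_segments(g2), list(c(1L, 2L)))
})

test_that("real edge read sets equal endpoint intersections", {
  for (seed in 1:20) {
    inst <- random_phasing_instance(seed)
    g <- instance_graph(inst)
    for (n in seq_along(g$positions)[-1]) {
      st <- g$steps[[n]]
      for (k in seq_along(g$vertices[[n - 1]])) {
        for (i in seq_along(g$vertices[[n]])) {
          shared <- intersect(g$vertices[[n - 1]][[k]]$reads,
                              g$vertices[[n]][[i]]$reads)
          if (st$artificial[k, i]) {
            expect_length(st$reads[[k, i]], 0)
          } else if (st$exists[k, i]) {
            expect_setequal(st$reads[[k, i]], shared)
          } else {
            expect_length(shared, 0)
          }
        }
      }
    }
    # after artificial edges, within a segment every non-initial position of
    # a segment has at least one incoming edge per vertex
    for (seg in split_segments(g)) {
      if (seg[2] > seg[1]) {
        for (n in (seg[1] + 1):seg[2]) {
          expect_true(all(colSums(g$steps[[n]]$exists) > 0))
        }
      }
    }
  }
})

test_that("graph construction is deterministic and validates input", {
  inst <- random_phasing_instance(42)
  g1 <- instance_graph(inst)
  g2 <- instance_graph(inst)
  expect_identical(g1, g2)

  expect_error(
    haplotag_graph(c(10L, 5L), list(list(), list()), integer(0)),
    "increasing|vertices"
  )
  expect_error(
    haplotag_graph(5L, list(list(list(allele = "A", is_ref = FALSE,
                                      reads = character(0)))),
                   integer(0)),
    "empty read set"
  )
})
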
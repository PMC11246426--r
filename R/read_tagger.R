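#' Assign haplotags to reads by majority vote over haplotagged alleles
#'
#' For every read supporting at least one haplotagged allele of the segment,
#' counts how many haplotype-1 and haplotype-2 alleles it supports. The
#' majority wins; equal counts give haplotag 0. A vertex carrying both labels
#' (homozygous-like position on the best path) contributes one vote to each
#' side for its reads, which keeps such positions neutral.
#'
#' @param allele_haplotags An `allele_haplotags` object
#'   ([backtrack_haplotags()]).
#' @param graph The `haplotag_graph` the segment was solved on.
#' @param segment `c(start, end)` position index range of the segment.
#'
#' @return Data frame with `read_id`, `haplotag`, `phase_block` (leftmost
#'   1-based reference position of the segment; `NA` where haplotag is 0),
#'   `votes1`, `votes2`. Only reads with at least one vote appear.
#' @export
assign_read_haplotags <- function(allele_haplotags, graph, segment) {
  vt <- allele_haplotags$vertex_tags
  reads <- character(0); haps <- integer(0)
  for (r in seq_len(nrow(vt))) {
    rs <- graph$vertices[[vt$position[r]]][[vt$vertex[r]]]$reads
    reads <- c(reads, rs)
    haps <- c(haps, rep(vt$haplotag[r], length(rs)))
  }
  if (length(reads) == 0L) {
    return(data.frame(read_id = character(0), haplotag = integer(0),
                      phase_block = integer(0), votes1 = integer(0),
                      votes2 = integer(0), stringsAsFactors = FALSE))
  }
  ids <- sort(unique(reads))
  votes1 <- vapply(ids, function(id) sum(reads == id & haps == 1L), integer(1))
  votes2 <- vapply(ids, function(id) sum(reads == id & haps == 2L), integer(1))
  haplotag <- ifelse(votes1 > votes2, 1L, ifelse(votes2 > votes1, 2L, 0L))
  block <- graph$positions[segment[1L]] + 1L
  data.frame(
    read_id = ids,
    haplotag = haplotag,
    phase_block = ifelse(haplotag == 0L, NA_integer_, block),
    votes1 = votes1,
    votes2 = votes2,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Haplotag all reads of one window
#'
#' Runs the full per-window pipeline: pileup candidates, heterozygous-SNP
#' filtering, allele-graph construction with artificial edges, segmentation,
#' the pair-score dynamic program per segment, and majority-vote read
#' tagging. A read supporting alleles in more than one segment is voted
#' within each and tagged by the segment where it has the most votes (a tie
#' between segments gives haplotag 0). Reads supporting no haplotagged
#' allele, and every read in a window without usable candidates, get
#' haplotag 0.
#'
#' @param reads `aligned_reads` for the window (reads overlapping it).
#' @param reference A `reference_window` covering the window.
#' @param window 0-based half-open `c(start, end)`; defaults to the
#'   reference extent.
#' @param config A [window_config()].
#'
#' @return Data frame with one row per input read: `read_id`, `start`,
#'   `haplotag`, `phase_block`, `votes1`, `votes2`. The window interval is
#'   attached as attribute `"window"`.
#' @export
haplotag_window <- function(reads, reference, window = NULL,
                            config = window_config()) {
  if (is.null(window)) {
    window <- c(reference$start, reference$start + nchar(reference$sequence))
  }
  base <- data.frame(
    read_id = reads$read_id,
    start = reads$start,
    haplotag = 0L,
    phase_block = NA_integer_,
    votes1 = 0L,
    votes2 = 0L,
    stringsAsFactors = FALSE
  )
  candidates <- collect_allele_support(reads, reference, window, config$filter)
  het <- select_het_snp_candidates(candidates, config$filter)
  graph <- build_graph(het, reads, config$filter)
  graph <- add_artificial_edges(graph)
  segments <- split_segments(graph)
  if (length(segments) > 0L) {
    seg_votes <- lapply(segments, function(seg) {
      tables <- segment_scores(graph, seg, config$pair_mode)
      bt <- backtrack_haplotags(tables)
      assign_read_haplotags(bt, graph, seg)
    })
    all_votes <- do.call(rbind, seg_votes)
    if (nrow(all_votes) > 0L) {
      for (id in unique(all_votes$read_id)) {
        rows <- all_votes[all_votes$read_id == id, , drop = FALSE]
        tot <- rows$votes1 + rows$votes2
        best <- which(tot == max(tot))
        tgt <- which(base$read_id == id)
        if (length(tgt) == 0L) next  # vote from a read absent in this fetch
        pick <- rows[best[1L], ]
        if (length(best) > 1L) {
          # read is torn between segments with equal support: leave untagged
          base$haplotag[tgt] <- 0L
          base$phase_block[tgt] <- NA_integer_
        } else {
          base$haplotag[tgt] <- pick$haplotag
          base$phase_block[tgt] <- pick$phase_block
        }
        base$votes1[tgt] <- pick$votes1
        base$votes2[tgt] <- pick$votes2
      }
    }
  }
  attr(base, "window") <- as.integer(window)
  base
}

#' Merge per-window tagging results
#'
#' Each read receives its tag from the single window containing its
#' alignment start; rows for reads that merely overlap a window (fetched
#' because of overlap semantics) are dropped. Haplotype labels remain local
#' to their window/segment: no global phase reconciliation is attempted.
#'
#' @param window_results List of data frames from [haplotag_window()] (each
#'   carrying its `"window"` attribute), for non-overlapping windows.
#'
#' @return Combined data frame, one row per read.
#' @export
merge_windows <- function(window_results) {
  kept <- lapply(window_results, function(res) {
    w <- attr(res, "window")
    if (is.null(w)) stop("window result lacks its window attribute")
    res[res$start >= w[1L] & res$start < w[2L], , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), start = integer(0),
                      haplotag = integer(0), phase_block = integer(0),
                      votes1 = integer(0), votes2 = integer(0),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$read_id)) {
    stop("read_id assigned by more than one window: ",
         paste(utils::head(unique(out$read_id[duplicated(out$read_id)]), 5),
               collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9,]+)-([0-9,]+))?$", region))[[1L]]
  if (length(m) == 0L) stop("cannot parse region: ", region)
  contig <- m[2L]
  if (m[3L] == "") return(list(contig = contig, start = NULL, end = NULL))
  start1 <- as.integer(gsub(",", "", m[4L]))
  end1 <- as.integer(gsub(",", "", m[5L]))
  if (is.na(start1) || is.na(end1) || end1 < start1) {
    stop("cannot parse region: ", region)
  }
  # 1-based inclusive on the command line -> 0-based half-open internally
  list(contig = contig, start = start1 - 1L, end = end1)
}

#' Haplotag an alignment file end to end
#'
#' Chunks each contig (or the requested region) into windows, haplotags each
#' window independently with [haplotag_window()], merges results by
#' alignment-start window, and optionally writes a haplotagged BAM/SAM and a
#' per-read TSV.
#'
#' @param alignments Coordinate-sorted, indexed SAM/BAM file.
#' @param reference Indexed FASTA the reads were aligned to.
#' @param region Optional `"contig"` or `"contig:start-end"` (1-based
#'   inclusive). Default: all contigs in the alignment header.
#' @param config A [window_config()].
#' @param out_bam Optional path for the haplotagged alignment output
#'   ([write_haplotagged()]).
#' @param out_tsv Optional path for the per-read tag TSV
#'   ([write_tags_tsv()]).
#'
#' @return Data frame with `read_id`, `start`, `haplotag`, `phase_block`,
#'   `votes1`, `votes2`.
#' @export
run_haplotag <- function(alignments, reference, region = NULL,
                         config = window_config(), out_bam = NULL,
                         out_tsv = NULL) {
  bam <- ensure_bam(alignments)
  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(targets) == 0L) stop("alignment file has no reference contigs")
  if (!is.null(region)) {
    reg <- parse_region(region)
    if (!reg$contig %in% names(targets)) {
      stop("region contig not in alignment header: ", reg$contig)
    }
    spans <- list(list(
      contig = reg$contig,
      start = if (is.null(reg$start)) 0L else reg$start,
      end = if (is.null(reg$end)) unname(targets[reg$contig]) else reg$end
    ))
  } else {
    spans <- lapply(names(targets), function(ct) {
      list(contig = ct, start = 0L, end = unname(targets[ct]))
    })
  }
  results <- list()
  for (sp in spans) {
    w_starts <- seq.int(sp$start, max(sp$start, sp$end - 1L), by = config$window_size)
    for (w0 in w_starts) {
      w1 <- min(w0 + config$window_size, sp$end)
      reads <- read_alignments(bam, sp$contig, w0, w1)
      if (nrow(reads) == 0L) next
      refwin <- read_reference(reference, sp$contig, w0, w1)
      results[[length(results) + 1L]] <-
        haplotag_window(reads, refwin, c(w0, w1), config)
    }
  }
  merged <- merge_windows(results)
  if (!is.null(out_tsv)) write_tags_tsv(merged, out_tsv)
  if (!is.null(out_bam)) write_haplotagged(bam, out_bam, merged)
  merged
}
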
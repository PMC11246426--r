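#' Collect per-allele read support at positions differing from the reference
#'
#' Scans the pileup of `reads` over `window` and reports every position where
#' at least `min_alt_support` reads, making up at least `min_alt_fraction` of
#' the quality-passing reads at the position, carry the same non-reference
#' base (after base- and mapping-quality filtering). For each such candidate
#' the
#' supporting read set of every allele, including the reference allele, is
#' recorded. A read whose base at the position is filtered, is an `N`, falls
#' in a deletion, or matches neither the reference nor a retained alternate
#' supports no allele there, so support sets are disjoint by construction.
#'
#' @param reads An `aligned_reads` data frame ([read_alignments()]).
#' @param reference A `reference_window` ([read_reference()]) covering
#'   `window`.
#' @param window 0-based half-open interval `c(start, end)`; defaults to the
#'   reference window extent.
#' @param config A [candidate_filter_config()].
#'
#' @return List of `variant_candidate` objects, each a list with `position`
#'   (0-based), `ref`, `alts` (sorted) and `support` (named list of read-id
#'   vectors, one per allele including the reference).
#' @export
collect_allele_support <- function(reads, reference, window = NULL,
                                   config = candidate_filter_config()) {
  stopifnot(inherits(reference, "reference_window"))
  ref_len <- nchar(reference$sequence)
  if (is.null(window)) window <- c(reference$start, reference$start + ref_len)
  w0 <- as.integer(window[1L]); w1 <- as.integer(window[2L])
  if (w1 <= w0) return(list())
  if (w0 < reference$start || w1 > reference$start + ref_len) {
    stop("reference window does not cover the requested interval")
  }
  ref_chars <- strsplit(
    substr(reference$sequence, w0 - reference$start + 1L, w1 - reference$start),
    "", fixed = TRUE
  )[[1L]]

  reads <- reads[reads$mapq >= config$min_mapping_quality &
                   reads$end > w0 & reads$start < w1, , drop = FALSE]
  if (nrow(reads) == 0L) return(list())

  # First pass: per-read base vectors restricted to the window, plus the
  # table of quality-passing mismatches.
  per_read <- vector("list", nrow(reads))
  mm <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    ov0 <- max(reads$start[r], w0)
    ov1 <- min(reads$end[r], w1)
    i0 <- ov0 - reads$start[r] + 1L
    i1 <- ov1 - reads$start[r]
    chars <- strsplit(substr(reads$ref_seq[r], i0, i1), "", fixed = TRUE)[[1L]]
    phred <- utf8ToInt(substr(reads$ref_qual[r], i0, i1)) - 33L
    refc <- ref_chars[(ov0 - w0 + 1L):(ov1 - w0)]
    valid <- chars %in% DNA_BASES & refc %in% DNA_BASES &
      phred >= config$min_base_quality
    per_read[[r]] <- list(offset = ov0, chars = chars, valid = valid)
    hit <- which(valid & chars != refc)
    if (length(hit) > 0L) {
      mm[[r]] <- data.frame(
        pos = ov0 + hit - 1L, base = chars[hit], stringsAsFactors = FALSE
      )
    }
  }
  mm <- do.call(rbind, mm)
  if (is.null(mm) || nrow(mm) == 0L) return(list())

  counts <- table(paste(mm$pos, mm$base))
  kept <- names(counts)[counts >= config$min_alt_support]
  if (length(kept) == 0L) return(list())
  kept_pos <- as.integer(sub(" .*", "", kept))
  kept_base <- sub(".* ", "", kept)
  cand_pos <- sort(unique(kept_pos))

  # Second pass: classify every quality-passing read base at each candidate
  # position into ref / retained-alt support sets.
  rows <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    pr <- per_read[[r]]
    span <- length(pr$chars)
    pp <- cand_pos[cand_pos >= pr$offset & cand_pos < pr$offset + span]
    if (length(pp) == 0L) next
    idx <- pp - pr$offset + 1L
    ok <- pr$valid[idx]
    if (!any(ok)) next
    rows[[r]] <- data.frame(
      read_id = reads$read_id[r], pos = pp[ok], base = pr$chars[idx][ok],
      stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, rows)

  out <- lapply(cand_pos, function(p) {
    refb <- ref_chars[p - w0 + 1L]
    sub <- obs[obs$pos == p, , drop = FALSE]
    n_valid <- nrow(sub)
    counts <- table(sub$base)
    alt_bases <- setdiff(names(counts), refb)
    keep_alt <- counts[alt_bases] >= config$min_alt_support &
      counts[alt_bases] / n_valid >= config$min_alt_fraction
    alts <- sort(alt_bases[keep_alt])
    if (length(alts) == 0L) return(NULL)
    alleles <- c(refb, alts)
    support <- lapply(alleles, function(b) sub$read_id[sub$base == b])
    names(support) <- alleles
    structure(
      list(position = p, ref = refb, alts = alts, support = support),
      class = "variant_candidate"
    )
  })
  Filter(Negate(is.null), out)
}

#' Filter candidates down to putative heterozygous SNPs
#'
#' A candidate is retained iff (a) every alternate allele is a single-base
#' substitution, and (b) it is not the case that it has exactly one alternate
#' allele while its reference allele is supported by fewer than
#' `min_ref_support` reads. Rule (b) removes likely homozygous-alternate
#' sites; a multi-alternate candidate is kept regardless of reference
#' support, since two alternates can themselves be the two haplotypes. Input
#' order is preserved and the filter is idempotent.
#'
#' @param candidates List of `variant_candidate` ([collect_allele_support()]).
#' @param config A [candidate_filter_config()].
#'
#' @return Filtered candidate list.
#' @export
select_het_snp_candidates <- function(candidates,
                                      config = candidate_filter_config()) {
  keep <- vapply(candidates, function(cd) {
    if (!all(nchar(cd$alts) == 1L & cd$alts %in% DNA_BASES)) return(FALSE)
    ref_support <- length(cd$support[[cd$ref]])
    !(length(cd$alts) == 1L && ref_support < config$min_ref_support)
  }, logical(1))
  candidates[keep]
}

#' @export
print.variant_candidate <- function(x, ...) {
  sup <- vapply(x$support, length, integer(1))
  cat(sprintf(
    "<candidate pos=%d ref=%s alts=%s support=[%s]>\n",
    x$position, x$ref, paste(x$alts, collapse = ","),
    paste(sprintf("%s:%d", names(sup), sup), collapse = " ")
  ))
  invisible(x)
}
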
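#' Switch-aware haplotagging accuracy
#'
#' Compares predicted read haplotags against truth haplotypes, allowing the
#' arbitrary label orientation of each phase block: within every block the
#' better of the two label mappings (1->1/2->2 vs 1->2/2->1) is chosen, and
#' overall accuracy is the match-weighted aggregate over blocks. Haplotag-0
#' reads are never counted as errors; they are excluded from the accuracy
#' numerator/denominator but included in the `tagged_fraction` denominator.
#'
#' @param pred Data frame with `read_id`, `haplotag` (0/1/2) and
#'   `phase_block` (non-`NA` for tagged reads).
#' @param truth Data frame with `read_id` and `haplotype` (1/2), e.g. from
#'   [simulate_diploid()].
#'
#' @return Object of class `haplotag_accuracy`: list with `accuracy` (`NA`
#'   when nothing is tagged), `tagged_fraction`, `n_reads`, `n_tagged`, and
#'   `per_block` (block id, size, chosen permutation, matches, accuracy).
#' @export
switch_aware_accuracy <- function(pred, truth) {
  cmp <- truth_compare_tags(pred, truth)
  n_reads <- nrow(cmp)
  tg <- cmp[cmp$tagged, , drop = FALSE]
  n_tagged <- nrow(tg)
  if (n_tagged == 0L) {
    return(structure(
      list(accuracy = NA_real_, tagged_fraction = 0,
           n_reads = n_reads, n_tagged = 0L,
           per_block = data.frame(block = integer(0), n = integer(0),
                                  permutation = character(0),
                                  matches = integer(0), accuracy = numeric(0))),
      class = "haplotag_accuracy"
    ))
  }
  if (anyNA(tg$phase_block)) stop("tagged reads must carry a phase_block")
  per_block <- lapply(split(tg, tg$phase_block), function(b) {
    m_id <- sum(b$haplotag == b$true_hap)
    m_sw <- sum(b$haplotag == 3L - b$true_hap)
    if (m_id >= m_sw) {
      data.frame(block = b$phase_block[1L], n = nrow(b),
                 permutation = "identity", matches = m_id,
                 accuracy = m_id / nrow(b), stringsAsFactors = FALSE)
    } else {
      data.frame(block = b$phase_block[1L], n = nrow(b),
                 permutation = "swap", matches = m_sw,
                 accuracy = m_sw / nrow(b), stringsAsFactors = FALSE)
    }
  })
  per_block <- do.call(rbind, per_block)
  per_block <- per_block[order(per_block$block), , drop = FALSE]
  rownames(per_block) <- NULL
  structure(
    list(
      accuracy = sum(per_block$matches) / n_tagged,
      tagged_fraction = n_tagged / n_reads,
      n_reads = n_reads,
      n_tagged = n_tagged,
      per_block = per_block
    ),
    class = "haplotag_accuracy"
  )
}

#' @export
print.haplotag_accuracy <- function(x, ...) {
  cat("Switch-aware haplotagging accuracy\n")
  cat(sprintf("  reads:           %d\n", x$n_reads))
  cat(sprintf("  tagged:          %d (%.1f%%)\n",
              x$n_tagged, 100 * x$tagged_fraction))
  if (is.na(x$accuracy)) {
    cat("  accuracy:        undefined (no tagged reads)\n")
  } else {
    cat(sprintf("  accuracy:        %.4f over %d phase block(s)\n",
                x$accuracy, nrow(x$per_block)))
  }
  invisible(x)
}

#' Write an accuracy report as TSV
#'
#' Writes the per-block table with a `#`-prefixed summary header line.
#'
#' @param report A `haplotag_accuracy` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# reads=%d tagged=%d tagged_fraction=%.6f accuracy=%s",
    report$n_reads, report$n_tagged, report$tagged_fraction,
    if (is.na(report$accuracy)) "NA" else sprintf("%.6f", report$accuracy)
  ), con)
  write.table(report$per_block, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
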
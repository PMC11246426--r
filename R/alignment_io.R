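#' Read a reference window from an indexed FASTA
#'
#' @param path Path to a FASTA file with a `.fai` index alongside.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval on the contig. Defaults to the
#'   whole contig.
#'
#' @return An object of class `reference_window`: a list with `contig`,
#'   `start` (0-based offset of the first base of `sequence`) and `sequence`
#'   (uppercase character string).
#' @export
read_reference <- function(path, contig, start = NULL, end = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (!file.exists(paste0(path, ".fai"))) {
    stop("FASTA file is not indexed (missing ", path, ".fai)")
  }
  fa <- Rsamtools::FaFile(path)
  idx <- Rsamtools::scanFaIndex(fa)
  hit <- which(as.character(GenomicRanges::seqnames(idx)) == contig)
  if (length(hit) == 0L) stop("contig not found in FASTA: ", contig)
  contig_len <- GenomicRanges::width(idx)[hit[1L]]
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- contig_len
  start <- as.integer(start)
  end <- as.integer(min(end, contig_len))
  if (start < 0L || end <= start) stop("invalid interval [", start, ", ", end, ")")
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  seq <- Rsamtools::scanFa(fa, param = gr)
  structure(
    list(
      contig = contig,
      start = start,
      sequence = toupper(as.character(seq[[1L]]))
    ),
    class = "reference_window"
  )
}

# Return a path to a sorted, indexed BAM for `path` (converting SAM input).
ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- sub("\\.sam$", "", tempfile(fileext = ".sam"))
    return(Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE))
  }
  path
}

#' Read aligned reads overlapping a region
#'
#' Reads a coordinate-sorted SAM or BAM file and returns one row per primary
#' alignment overlapping the requested interval, with the read sequence and
#' base qualities projected into reference space (insertions removed,
#' deletions/skips marked as gaps) so that downstream pileup code can index
#' bases by reference coordinate.
#'
#' @param path SAM or BAM file. BAM input must be indexed when a region is
#'   requested; SAM input is converted (and sorted/indexed) on the fly.
#' @param contig Contig to fetch from; `NULL` fetches the whole file.
#' @param start,end 0-based half-open interval; reads merely overlapping the
#'   interval are included.
#' @param include_filtered If `TRUE`, secondary/supplementary/duplicate
#'   alignments are returned as well (default drops them).
#'
#' @return A data frame of class `aligned_reads` with columns `read_id`,
#'   `contig`, `start` (0-based), `end` (0-based exclusive), `mapq`,
#'   `ref_seq` (read bases along the reference, `-` at deletions) and
#'   `ref_qual` (phred+33 string aligned with `ref_seq`).
#' @export
read_alignments <- function(path, contig = NULL, start = NULL, end = NULL,
                            include_filtered = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- ensure_bam(path)
  flag <- if (include_filtered) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  } else {
    Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE
    )
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  if (!is.null(contig)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      stop("BAM file is not indexed: ", bam)
    }
    header <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    if (!contig %in% names(header)) stop("contig not found in alignments: ", contig)
    if (is.null(start)) start <- 0L
    if (is.null(end)) end <- header[[contig]]
    which <- GenomicRanges::GRanges(
      contig, IRanges::IRanges(as.integer(start) + 1L, as.integer(end))
    )
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = which)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- data.frame(
      read_id = character(0), contig = character(0), start = integer(0),
      end = integer(0), mapq = integer(0), ref_seq = character(0),
      ref_qual = character(0), stringsAsFactors = FALSE
    )
    class(out) <- c("aligned_reads", "data.frame")
    return(out)
  }
  ref_seq <- GenomicAlignments::sequenceLayer(res$seq, res$cigar, N.letter = "-")
  ref_qual <- GenomicAlignments::sequenceLayer(
    res$qual, res$cigar, D.letter = "!", N.letter = "!"
  )
  start0 <- res$pos - 1L
  out <- data.frame(
    read_id = res$qname,
    contig = as.character(res$rname),
    start = start0,
    end = start0 + Biostrings::width(ref_seq),
    mapq = as.integer(res$mapq),
    ref_seq = toupper(as.character(ref_seq)),
    ref_qual = as.character(ref_qual),
    stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", "data.frame")
  out
}

sam_lines <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    system2("samtools", c("view", "-h", shQuote(path)), stdout = TRUE)
  } else {
    readLines(path)
  }
}

#' Write a haplotagged copy of an alignment file
#'
#' Copies `in_path` to `out_path`, attaching `HP:i` (haplotag 1 or 2) and
#' `PS:i` (phase set: the leftmost 1-based reference position of the phase
#' segment) to each primary alignment listed in `tags` with haplotag 1 or 2.
#' Reads with haplotag 0 carry neither tag (pre-existing HP/PS on primary
#' records are removed). Secondary, supplementary and duplicate-flagged
#' records pass through unmodified.
#'
#' @param in_path Input SAM or BAM.
#' @param out_path Output path; a `.bam` suffix produces sorted, indexed BAM,
#'   anything else plain SAM text.
#' @param tags Data frame with columns `read_id`, `haplotag` (0/1/2) and
#'   `phase_block` (required where haplotag is 1 or 2). Each `read_id` at most
#'   once.
#'
#' @return `out_path`, invisibly.
#' @export
write_haplotagged <- function(in_path, out_path, tags) {
  stopifnot(is.data.frame(tags))
  if (nrow(tags) > 0) {
    stopifnot(all(c("read_id", "haplotag", "phase_block") %in% names(tags)))
    if (anyDuplicated(tags$read_id)) stop("duplicate read_id in tags")
    if (!all(tags$haplotag %in% 0:2)) stop("haplotag values must be 0, 1 or 2")
    need_ps <- tags$haplotag %in% 1:2
    if (any(need_ps & is.na(tags$phase_block))) {
      stop("phase_block required for haplotagged reads")
    }
  }
  lines <- sam_lines(in_path)
  is_header <- startsWith(lines, "@")
  rec_idx <- which(!is_header)
  tagged <- tags[tags$haplotag %in% 1:2, , drop = FALSE]
  hp <- structure(as.integer(tagged$haplotag), names = tagged$read_id)
  ps <- structure(as.integer(tagged$phase_block), names = tagged$read_id)
  seen <- character(0)
  if (length(rec_idx) > 0) {
    recs <- strsplit(lines[rec_idx], "\t", fixed = TRUE)
    recs <- lapply(recs, function(f) {
      fl <- suppressWarnings(as.integer(f[2L]))
      if (is.na(fl) || bitwAnd(fl, 0xD00L) != 0L) return(f)  # non-primary/dup
      f <- f[!grepl("^(HP|PS):i:", f)]
      id <- f[1L]
      seen <<- c(seen, id)
      if (!is.na(hp[id])) f <- c(f, paste0("HP:i:", hp[id]), paste0("PS:i:", ps[id]))
      f
    })
    lines[rec_idx] <- vapply(recs, paste, character(1), collapse = "\t")
  }
  missing <- setdiff(names(hp), seen)
  if (length(missing) > 0) {
    warning(length(missing), " tagged read(s) absent from input, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  if (grepl("\\.bam$", out_path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(lines, tmp)
    Rsamtools::asBam(tmp, sub("\\.bam$", "", out_path, ignore.case = TRUE),
                     overwrite = TRUE, indexDestination = TRUE)
  } else {
    writeLines(lines, out_path)
  }
  invisible(out_path)
}

#' Read HP/PS haplotags back from an alignment file
#'
#' @param path SAM or BAM file.
#' @return Data frame with `read_id`, `haplotag` (0 where no HP tag) and
#'   `phase_block` (`NA` where untagged).
#' @export
read_bam_tags <- function(path) {
  bam <- ensure_bam(path)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE
    ),
    what = c("qname"), tag = c("HP", "PS")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  hp <- res$tag$HP
  ps <- res$tag$PS
  n <- length(res$qname)
  if (is.null(hp)) hp <- rep(NA_integer_, n)
  if (is.null(ps)) ps <- rep(NA_integer_, n)
  data.frame(
    read_id = res$qname,
    haplotag = ifelse(is.na(hp), 0L, as.integer(hp)),
    phase_block = as.integer(ps),
    stringsAsFactors = FALSE
  )
}

#' Write / read per-read haplotag tables as TSV
#'
#' The TSV has columns `read_id`, `haplotag`, `phase_block`, `votes1`,
#' `votes2` and is sorted by `read_id` so output is reproducible.
#'
#' @param tags Data frame as returned by [run_haplotag()] or
#'   [haplotag_window()].
#' @param path Output path.
#' @return `path`, invisibly (`write_tags_tsv`); the table (`read_tags_tsv`).
#' @export
write_tags_tsv <- function(tags, path) {
  cols <- c("read_id", "haplotag", "phase_block", "votes1", "votes2")
  for (col in setdiff(cols, names(tags))) tags[[col]] <- NA_integer_
  tags <- tags[order(tags$read_id), cols, drop = FALSE]
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tags_tsv
#' @export
read_tags_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a simulation truth table
#'
#' @param path TSV with columns `read_id` and `haplotype` (1 or 2), as written
#'   by [simulate_diploid()].
#' @return Data frame.
#' @export
read_truth_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
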
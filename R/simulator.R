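#' Simulate a diploid genome and error-injected long reads
#'
#' Generates a uniform-random reference, plants heterozygous SNPs (the
#' alternate allele on one fairly chosen haplotype) and homozygous SNPs (on
#' both haplotypes), and draws reads from the two haplotypes with equal
#' probability. Read lengths are truncated-normal (minimum 500 bases), start
#' positions uniform such that reads lie fully inside the genome, and
#' substitution errors are injected i.i.d. per base. Because only
#' substitutions are simulated, reads are emitted pre-aligned at their true
#' coordinates with a full-match CIGAR, so no aligner is needed. Output is
#' fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param contig Contig name used in all outputs.
#' @param prefix File name prefix.
#'
#' @return List with paths `fasta`, `sam`, `bam`, `truth_path`,
#'   `variants_path` and data frames `truth` (read_id, haplotype, start, end)
#'   and `variants` (position 1-based, ref, alt, genotype, haplotype).
#' @export
simulate_diploid <- function(config = simulation_config(), out_dir = tempfile(),
                             contig = "sim1", prefix = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  L <- config$genome_length

  ref <- sample(DNA_BASES, L, replace = TRUE)

  draw_alt <- function(refbase) {
    pool <- setdiff(DNA_BASES, refbase)
    pool[sample.int(3L, 1L)]
  }
  het_pos <- which(runif(L) < config$het_snp_rate)
  hom_pos <- setdiff(which(runif(L) < config$hom_snp_rate), het_pos)
  het_alt <- vapply(ref[het_pos], draw_alt, character(1), USE.NAMES = FALSE)
  het_hap <- sample(1:2, length(het_pos), replace = TRUE)
  hom_alt <- vapply(ref[hom_pos], draw_alt, character(1), USE.NAMES = FALSE)

  hap1 <- ref; hap2 <- ref
  hap1[het_pos[het_hap == 1L]] <- het_alt[het_hap == 1L]
  hap2[het_pos[het_hap == 2L]] <- het_alt[het_hap == 2L]
  hap1[hom_pos] <- hom_alt
  hap2[hom_pos] <- hom_alt

  variants <- data.frame(
    position = c(het_pos, hom_pos),
    ref = c(ref[het_pos], ref[hom_pos]),
    alt = c(het_alt, hom_alt),
    genotype = c(rep("het", length(het_pos)), rep("hom", length(hom_pos))),
    haplotype = c(het_hap, rep(NA_integer_, length(hom_pos))),
    stringsAsFactors = FALSE
  )
  variants <- variants[order(variants$position), , drop = FALSE]
  rownames(variants) <- NULL
  if (nrow(variants) == 0L) {
    warning("simulation produced zero variants; haplotagging will be trivial")
  }

  n_reads <- max(1L, round(config$depth * L / config$read_length_mean))
  lens <- round(rnorm(n_reads, config$read_length_mean, config$read_length_sd))
  lens <- pmin(pmax(lens, 500L), L)
  starts <- vapply(lens, function(len) {
    sample.int(L - len + 1L, 1L) - 1L  # 0-based
  }, integer(1))
  haps <- sample(1:2, n_reads, replace = TRUE)

  ord <- order(starts, lens)
  lens <- lens[ord]; starts <- starts[ord]; haps <- haps[ord]
  ids <- sprintf("read%04d", seq_len(n_reads))

  seqs <- character(n_reads)
  for (r in seq_len(n_reads)) {
    src <- if (haps[r] == 1L) hap1 else hap2
    bases <- src[(starts[r] + 1L):(starts[r] + lens[r])]
    err <- which(runif(lens[r]) < config$substitution_error_rate)
    for (k in err) bases[k] <- draw_alt(bases[k])
    seqs[r] <- paste(bases, collapse = "")
  }

  fasta <- file.path(out_dir, paste0(prefix, ".fa"))
  dna <- Biostrings::DNAStringSet(paste(ref, collapse = ""))
  names(dna) <- contig
  Biostrings::writeXStringSet(dna, fasta)
  Rsamtools::indexFa(fasta)

  sam <- file.path(out_dir, paste0(prefix, ".sam"))
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", contig, L),
    sprintf("@PG\tID:localtag.sim\tPN:localtag\tVN:%s",
            as.character(utils::packageVersion("localtag")))
  )
  records <- sprintf(
    "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
    ids, contig, starts + 1L, lens, seqs,
    vapply(lens, function(n) strrep("?", n), character(1))  # phred 30
  )
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, prefix),
                          overwrite = TRUE, indexDestination = TRUE)

  truth <- data.frame(
    read_id = ids, haplotype = haps, start = starts,
    end = starts + lens, stringsAsFactors = FALSE
  )
  truth_path <- file.path(out_dir, paste0(prefix, ".truth.tsv"))
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  variants_path <- file.path(out_dir, paste0(prefix, ".variants.tsv"))
  write.table(variants, variants_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(
    config = config, contig = contig, fasta = fasta, sam = sam, bam = bam,
    truth = truth, variants = variants, truth_path = truth_path,
    variants_path = variants_path
  )
}

#' Join predicted haplotags with simulation truth
#'
#' @param tags Data frame with `read_id`, `haplotag`, `phase_block` (e.g.
#'   from [run_haplotag()]).
#' @param truth Truth data frame from [simulate_diploid()] (or
#'   [read_truth_tsv()]).
#'
#' @return Data frame `read_id`, `haplotag`, `phase_block`, `true_hap`,
#'   `tagged`.
#' @export
truth_compare_tags <- function(tags, truth) {
  if (!all(tags$read_id %in% truth$read_id)) {
    stop("tags contain read_id values absent from truth")
  }
  idx <- match(tags$read_id, truth$read_id)
  data.frame(
    read_id = tags$read_id,
    haplotag = tags$haplotag,
    phase_block = tags$phase_block,
    true_hap = truth$haplotype[idx],
    tagged = tags$haplotag %in% 1:2,
    stringsAsFactors = FALSE
  )
}

#' Count heterozygous truth sites covered by each read
#'
#' @param truth Truth data frame with `read_id`, `start`, `end` (0-based
#'   half-open read span).
#' @param variants Variant table from [simulate_diploid()].
#' @return Named integer vector: per read, the number of planted heterozygous
#'   SNPs inside its span.
#' @export
count_het_sites_covered <- function(truth, variants) {
  het0 <- variants$position[variants$genotype == "het"] - 1L  # to 0-based
  counts <- vapply(seq_len(nrow(truth)), function(r) {
    sum(het0 >= truth$start[r] & het0 < truth$end[r])
  }, integer(1))
  names(counts) <- truth$read_id
  counts
}
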
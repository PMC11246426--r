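#' Candidate filter configuration
#'
#' Thresholds applied while turning pileup columns into putative heterozygous
#' SNP candidates.
#'
#' @param min_ref_support Minimum number of reads supporting the reference
#'   allele for a single-alternate candidate to be considered heterozygous,
#'   and for a reference vertex to be created in the allele graph. Default 3:
#'   a site whose reference allele is seen in fewer than three reads is
#'   treated as a likely homozygous alternate and excluded.
#' @param min_alt_support Minimum number of reads that must carry the same
#'   alternate base for it to become a candidate allele. Default 2, which
#'   suppresses singleton sequencing errors.
#' @param min_alt_fraction Minimum fraction of the quality-passing reads at
#'   the position that must carry the alternate base. Default 0.12. The count
#'   threshold alone cannot reject recurrent sequencing errors at high
#'   coverage (two identical errors among thirty reads are common at a 1%
#'   error rate), so candidate callers in this field combine a count floor
#'   with an allele-fraction floor; a true heterozygous allele sits near 0.5.
#' @param min_base_quality Minimum phred base quality for a read base to
#'   contribute to any allele. Default 10.
#' @param min_mapping_quality Minimum read mapping quality. Default 5.
#'
#' @return An object of class `candidate_filter_config`.
#' @export
#' @examples
#' candidate_filter_config(min_ref_support = 3)
candidate_filter_config <- function(min_ref_support = 3L,
                                    min_alt_support = 2L,
                                    min_alt_fraction = 0.12,
                                    min_base_quality = 10L,
                                    min_mapping_quality = 5L) {
  cfg <- list(
    min_ref_support = as.integer(min_ref_support),
    min_alt_support = as.integer(min_alt_support),
    min_alt_fraction = as.numeric(min_alt_fraction),
    min_base_quality = as.integer(min_base_quality),
    min_mapping_quality = as.integer(min_mapping_quality)
  )
  ints <- cfg[c("min_ref_support", "min_alt_support", "min_base_quality",
                "min_mapping_quality")]
  if (any(vapply(ints, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("all candidate filter thresholds must be non-negative integers")
  }
  if (is.na(cfg$min_alt_fraction) || cfg$min_alt_fraction < 0 ||
      cfg$min_alt_fraction > 1) {
    stop("min_alt_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "candidate_filter_config")
}

#' Window processing configuration
#'
#' @param window_size Width in bases of the independent windows the genome is
#'   chunked into. Default 25000. Haplotype labels are local to a window (in
#'   fact to a phase segment within a window); no global phase is produced.
#' @param filter A [candidate_filter_config()].
#' @param pair_mode `"canonical"` (default) enumerates only canonical
#'   (unordered) vertex pairs of the previous position as dynamic-programming
#'   predecessors; `"symmetric"` enumerates all ordered pairs. See
#'   [extend_scores()].
#'
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_size = 25000L,
                          filter = candidate_filter_config(),
                          pair_mode = c("canonical", "symmetric")) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size <= 0L) stop("window_size must be > 0")
  stopifnot(inherits(filter, "candidate_filter_config"))
  structure(
    list(
      window_size = window_size,
      filter = filter,
      pair_mode = match.arg(pair_mode)
    ),
    class = "window_config"
  )
}

#' Diploid simulation configuration
#'
#' Parameters of the synthetic diploid genome and long-read generator used to
#' test the haplotagger end to end. Defaults emulate a 50 kb locus sequenced
#' with accurate long reads: one heterozygous SNP per kilobase, 30x combined
#' coverage, 15 kb mean read length and a 1% substitution error rate.
#'
#' @param genome_length Reference length in bases.
#' @param het_snp_rate Per-base probability of planting a heterozygous SNP.
#' @param hom_snp_rate Per-base probability of planting a homozygous SNP
#'   (present on both haplotypes; such sites must not be used for phasing).
#' @param depth Mean combined coverage over the two haplotypes.
#' @param read_length_mean,read_length_sd Read length distribution
#'   (truncated normal, minimum 500 bases).
#' @param substitution_error_rate Per-base probability of a substitution
#'   sequencing error.
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 50000L,
                              het_snp_rate = 0.001,
                              hom_snp_rate = 0.0005,
                              depth = 30,
                              read_length_mean = 15000,
                              read_length_sd = 3000,
                              substitution_error_rate = 0.01,
                              seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    het_snp_rate = het_snp_rate,
    hom_snp_rate = hom_snp_rate,
    depth = depth,
    read_length_mean = read_length_mean,
    read_length_sd = read_length_sd,
    substitution_error_rate = substitution_error_rate,
    seed = as.integer(seed)
  )
  rates <- c(cfg$het_snp_rate, cfg$hom_snp_rate, cfg$substitution_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$genome_length <= 0L) stop("genome_length must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$read_length_mean <= 0) stop("read_length_mean must be positive")
  structure(cfg, class = "simulation_config")
}
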
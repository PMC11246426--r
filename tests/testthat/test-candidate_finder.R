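test_that("pileups matching the reference yield no candidates", {
  ref <- reference_from_string(strrep("ACGT", 15))
  reads <- make_reads(paste0("r", 1:10), rep(0L, 10),
                      rep(substr(ref$sequence, 1, 60), 10))
  expect_length(collect_allele_support(reads, ref), 0)
})

test_that("a balanced mismatch column becomes one candidate with full support", {
  ref <- reference_from_string(strrep("A", 60))
  with_base <- function(base) {
    s <- strrep("A", 60); substr(s, 31, 31) <- base; s
  }
  reads <- make_reads(paste0("r", 1:10), rep(0L, 10),
                      c(rep(with_base("C"), 5), rep(strrep("A", 60), 5)))
  cands <- collect_allele_support(reads, ref)
  expect_length(cands, 1)
  cd <- cands[[1]]
  expect_equal(cd$position, 30L)
  expect_equal(cd$ref, "A")
  expect_equal(cd$alts, "C")
  expect_setequal(cd$support[["C"]], paste0("r", 1:5))
  expect_setequal(cd$support[["A"]], paste0("r", 6:10))
})

test_that("reads with a deletion over the position support no allele there", {
  # hand-enumerated six-read pileup: r1,r2 carry C at position 20, r3 has a
  # deletion spanning it, r4-r6 match the reference
  ref <- reference_from_string(strrep("A", 40))
  alt_seq <- strrep("A", 40); substr(alt_seq, 21, 21) <- "C"
  del_seq <- strrep("A", 40); substr(del_seq, 21, 21) <- "-"
  reads <- make_reads(paste0("r", 1:6), rep(0L, 6),
                      c(alt_seq, alt_seq, del_seq, rep(strrep("A", 40), 3)))
  cands <- collect_allele_support(reads, ref)
  expect_length(cands, 1)
  cd <- cands[[1]]
  expect_setequal(cd$support[["C"]], c("r1", "r2"))
  expect_setequal(cd$support[["A"]], c("r4", "r5", "r6"))
  expect_false("r3" %in% unlist(cd$support))
})

test_that("base and mapping quality floors suppress support", {
  ref <- reference_from_string(strrep("A", 40))
  alt_seq <- strrep("A", 40); substr(alt_seq, 21, 21) <- "C"
  lowq <- strrep("I", 40); substr(lowq, 21, 21) <- "#"  # phred 2 at the SNP
  reads <- make_reads(
    c("hq1", "hq2", "lowbase", "lowmap"),
    rep(0L, 4),
    rep(alt_seq, 4),
    quals = c(strrep("I", 40), strrep("I", 40), lowq, strrep("I", 40)),
    mapq = c(60L, 60L, 60L, 0L)
  )
  cands <- collect_allele_support(reads, ref)
  expect_length(cands, 1)
  expect_setequal(cands[[1]]$support[["C"]], c("hq1", "hq2"))
})

test_that("het-SNP filter applies the single-alt/ref-support rule", {
  mk <- function(alts, ref_n, position = 5L) {
    support <- c(
      list(structure(list(), names = NULL)),  # placeholder replaced below
      lapply(alts, function(a) paste0(a, "_", seq_len(3)))
    )
    support[[1]] <- if (ref_n > 0) paste0("ref_", seq_len(ref_n)) else character(0)
    names(support) <- c("A", alts)
    structure(list(position = position, ref = "A", alts = alts,
                   support = support), class = "variant_candidate")
  }
  cfg <- candidate_filter_config()

  expect_length(select_het_snp_candidates(list(mk("C", 2)), cfg), 0)
  expect_length(select_het_snp_candidates(list(mk("C", 3)), cfg), 1)
  # insertion allele: removed regardless of support
  expect_length(select_het_snp_candidates(list(mk("ACT", 10)), cfg), 0)
  # multi-allelic site kept even with weak reference support
  expect_length(select_het_snp_candidates(list(mk(c("C", "G"), 0)), cfg), 1)

  cands <- list(mk("C", 2), mk("C", 3), mk(c("C", "G"), 0), mk("ACT", 9))
  once <- select_het_snp_candidates(cands, cfg)
  expect_identical(select_het_snp_candidates(once, cfg), once)
  # order preserved and every survivor is SNP-only
  expect_true(all(vapply(once, function(cd) all(nchar(cd$alts) == 1), logical(1))))
})

test_that("error-free simulation retains exactly the well-covered het SNPs", {
  sim <- small_sim(seed = 5, error = 0)
  reads <- read_alignments(sim$bam, sim$contig, 0, sim$config$genome_length)
  ref <- read_reference(sim$fasta, sim$contig)
  cfg <- candidate_filter_config()
  het <- select_het_snp_candidates(
    collect_allele_support(reads, ref, config = cfg), cfg
  )
  got <- vapply(het, `[[`, integer(1), "position")

  hets <- sim$variants[sim$variants$genotype == "het", ]
  hap_cov <- function(pos0, hap) {
    ids <- sim$truth$read_id[sim$truth$haplotype == hap &
                               sim$truth$start <= pos0 & sim$truth$end > pos0]
    length(ids)
  }
  expected <- vapply(seq_len(nrow(hets)), function(v) {
    pos0 <- hets$position[v] - 1L
    alt_cov <- hap_cov(pos0, hets$haplotype[v])
    ref_cov <- hap_cov(pos0, 3L - hets$haplotype[v])
    alt_cov >= cfg$min_alt_support && ref_cov >= cfg$min_ref_support &&
      alt_cov / (alt_cov + ref_cov) >= cfg$min_alt_fraction
  }, logical(1))

  expect_setequal(got, hets$position[expected] - 1L)
})
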
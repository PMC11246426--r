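# Fixtures are built in code at test time; nothing binary is stored.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference of 300 bases used by the pipeline-level worked example:
# repeating ACGT, with a 'G' planted at 0-based position 200 so the two
# candidate sites are ref=A at 100 and ref=G at 200.
example_reference <- function() {
  chars <- rep(c("A", "C", "G", "T"), length.out = 300)
  chars[201] <- "G"
  structure(
    list(contig = "chr1", start = 0L, sequence = paste(chars, collapse = "")),
    class = "reference_window"
  )
}

# Eleven reads realizing the worked-example incidence through the pileup:
# reads 1-3 carry ref/ref at the two sites, 4-5 ref/T, 6 C/ref, 7-11 C/T.
example_reads <- function() {
  ref <- example_reference()
  span <- substr(ref$sequence, 51, 250)  # reads cover [50, 250)
  base_at <- function(seq, pos0, base) {
    idx <- pos0 - 50 + 1
    substr(seq, idx, idx) <- base
    seq
  }
  incidence <- list(
    read1 = c("A", "G"), read2 = c("A", "G"), read3 = c("A", "G"),
    read4 = c("A", "T"), read5 = c("A", "T"),
    read6 = c("C", "G"),
    read7 = c("C", "T"), read8 = c("C", "T"), read9 = c("C", "T"),
    read10 = c("C", "T"), read11 = c("C", "T")
  )
  seqs <- vapply(incidence, function(al) {
    base_at(base_at(span, 100, al[1]), 200, al[2])
  }, character(1))
  out <- data.frame(
    read_id = names(incidence),
    contig = "chr1",
    start = 50L,
    end = 250L,
    mapq = 60L,
    ref_seq = unname(seqs),
    ref_qual = strrep("I", 200),
    stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", "data.frame")
  out
}

# Minimal aligned_reads constructor for hand-built pileups.
make_reads <- function(ids, starts, seqs, quals = NULL, mapq = 60L,
                       contig = "chr1") {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  out <- data.frame(
    read_id = ids, contig = contig, start = as.integer(starts),
    end = as.integer(starts) + nchar(seqs), mapq = as.integer(mapq),
    ref_seq = seqs, ref_qual = quals, stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", "data.frame")
  out
}

reference_from_string <- function(seq, contig = "chr1", start = 0L) {
  structure(list(contig = contig, start = as.integer(start), sequence = seq),
            class = "reference_window")
}

write_toy_fasta <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "toy.fa")
  dna <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  path
}

# Small SAM file: three primary reads on a 300 bp contig (one with a
# deletion), one secondary alignment that the readers must drop.
write_toy_sam <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "toy.sam")
  ref <- example_reference()$sequence
  sub_ref <- function(start0, len) substr(ref, start0 + 1, start0 + len)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:300",
    sprintf("rA\t0\tchr1\t1\t60\t20M\t*\t0\t0\t%s\t%s", sub_ref(0, 20), strrep("I", 20)),
    # rB: 5M 2D 5M starting at pos 11 (0-based 10): deletion covers [15,17)
    sprintf("rB\t0\tchr1\t11\t60\t5M2D5M\t*\t0\t0\t%s%s\t%s",
            sub_ref(10, 5), sub_ref(17, 5), strrep("I", 10)),
    sprintf("rB\t256\tchr1\t40\t0\t10M\t*\t0\t0\t%s\t%s", sub_ref(39, 10), strrep("I", 10)),
    sprintf("rC\t0\tchr1\t291\t60\t10M\t*\t0\t0\t%s\t%s", sub_ref(290, 10), strrep("I", 10))
  )
  writeLines(lines, path)
  path
}

# Random small phasing instance: reads cover consecutive position runs and
# support exactly one vertex per covered position, as real reads do.
random_phasing_instance <- function(seed) {
  set.seed(seed)
  P <- sample(1:5, 1)
  K <- sample(1:3, P, replace = TRUE)
  positions <- 10L * seq_len(P)
  spans <- list()
  for (t in seq_len(P)) spans[[t]] <- c(t, t)  # coverage guarantee
  for (r in seq_len(sample(1:30, 1))) {
    a <- sample.int(P, 1)
    b <- if (a == P) P else sample(a:P, 1)
    spans[[length(spans) + 1]] <- c(a, b)
  }
  ids <- paste0("r", seq_along(spans))
  vert_reads <- lapply(K, function(k) replicate(k, character(0), simplify = FALSE))
  for (r in seq_along(spans)) {
    for (t in spans[[r]][1]:spans[[r]][2]) {
      k <- sample.int(K[t], 1)
      vert_reads[[t]][[k]] <- c(vert_reads[[t]][[k]], ids[r])
    }
  }
  vertices <- lapply(seq_len(P), function(t) {
    vs <- Filter(function(x) length(x) > 0, vert_reads[[t]])
    lapply(seq_along(vs), function(k) {
      list(allele = paste0("a", k), is_ref = FALSE, reads = vs[[k]])
    })
  })
  read_starts <- structure(
    positions[vapply(spans, `[`, integer(1), 1)], names = ids
  )
  list(positions = positions, vertices = vertices, read_starts = read_starts)
}

instance_graph <- function(inst) {
  add_artificial_edges(
    haplotag_graph(inst$positions, inst$vertices, inst$read_starts)
  )
}

# Add one read whose span lies inside the given segment, supporting one
# existing vertex per covered position.
add_read_in_segment <- function(inst, segment, id = "extra") {
  a <- sample(segment[1]:segment[2], 1)
  b <- if (a == segment[2]) a else sample(a:segment[2], 1)
  for (t in a:b) {
    k <- sample.int(length(inst$vertices[[t]]), 1)
    inst$vertices[[t]][[k]]$reads <- c(inst$vertices[[t]][[k]]$reads, id)
  }
  inst$read_starts <- c(inst$read_starts,
                        structure(inst$positions[a], names = id))
  inst
}

# Fast pipeline-scale simulation shared by integration tests.
small_sim <- function(seed = 11, error = 0.005, length = 20000L,
                      depth = 20, het = 0.001) {
  simulate_diploid(
    simulation_config(
      genome_length = length, het_snp_rate = het, hom_snp_rate = 0.0005,
      depth = depth, read_length_mean = 6000, read_length_sd = 1500,
      substitution_error_rate = error, seed = seed
    )
  )
}
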
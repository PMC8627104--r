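# Small constructors for alignment-pair fixtures.

FWD1 <- 1L + 64L          # paired, first in pair, both forward
FWD2 <- 1L + 128L

pair_row <- function(qname = "q1", rname1 = "A", pos1 = 1, mapq1 = 60,
                     cigar1 = "100M", flag1 = FWD1, rname2 = "B", pos2 = 1,
                     mapq2 = 60, cigar2 = "100M", flag2 = FWD2) {
  data.frame(qname = qname, rname1 = rname1, pos1 = pos1, mapq1 = mapq1,
             cigar1 = cigar1, flag1 = flag1, rname2 = rname2, pos2 = pos2,
             mapq2 = mapq2, cigar2 = cigar2, flag2 = flag2,
             stringsAsFactors = FALSE)
}

# n pairs linking fixed 5' coordinates on two contigs (forward strand)
pair_block <- function(n, rname1, pos1, rname2, pos2, prefix = "p") {
  do.call(rbind, lapply(seq_len(n), function(i)
    pair_row(qname = sprintf("%s%04d", prefix, i), rname1 = rname1,
             pos1 = pos1 + i - 1, rname2 = rname2, pos2 = pos2 + i - 1)))
}

small_sim <- function(seed, n_chrom = 2, chrom_len = 2e5,
                      contigs_per_chrom = 4, n_pairs = 2e4, ...) {
  p <- sim_params(n_chrom = n_chrom, chrom_len = chrom_len,
                  contigs_per_chrom = contigs_per_chrom, n_pairs = n_pairs,
                  seed = seed, ...)
  sim <- simulate_genome(p)
  list(sim = sim, pairs = simulate_hic_pairs(sim),
       lengths = stats::setNames(sim$truth$length, sim$truth$contig))
}
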
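# Seeded synthetic data: multi-chromosome genomes fragmented into contigs of
# known order/orientation, and Hi-C-like read-pair alignments whose
# intra-chromosomal contact frequency decays with genomic distance and
# dominates the inter-chromosomal frequency. Alignments are emitted directly
# (no mapper involved) so every downstream filter can be exercised with
# injected clipped/duplicate/low-MAPQ noise.

#' Simulation parameters
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length(s), bp (recycled).
#' @param contigs_per_chrom contigs each chromosome is cut into.
#' @param n_pairs total Hi-C pairs to draw.
#' @param alpha intra-chromosomal distance-decay exponent: separation s is
#'   drawn with density proportional to (s + s0)^(-alpha), truncated at the
#'   chromosome length.
#' @param s0 decay offset, bp.
#' @param inter_frac fraction of pairs linking two different chromosomes.
#' @param clip_frac,dup_frac,lowq_frac noise fractions: soft-clipped mates,
#'   duplicated pairs (appended copies), MAPQ-0 mates.
#' @param read_len read length, bp.
#' @param min_contig_len smallest allowed contig, bp. Default: half the
#'   equal-split size, `chrom_len / contigs_per_chrom / 2`. The three-part
#'   split assigns contacts to end thirds, so a contig whose end third is far
#'   smaller than its neighbors' cannot win mutual-best ranking and gets
#'   skipped (a relocation); the default keeps the fixture inside the regime
#'   the scaffolding model targets. Lower it deliberately to study that
#'   failure mode.
#' @param seed mandatory RNG seed (integer).
#' @return list of validated parameters.
#' @export
sim_params <- function(n_chrom = 3, chrom_len = 2e6, contigs_per_chrom = 10,
                       n_pairs = 2e5, alpha = 1.0, s0 = 1000,
                       inter_frac = 0.05, clip_frac = 0.02, dup_frac = 0.02,
                       lowq_frac = 0.02, read_len = 100,
                       min_contig_len = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (is.null(min_contig_len))
    min_contig_len <- floor(min(chrom_len) / contigs_per_chrom / 2)
  stopifnot(n_chrom >= 1, contigs_per_chrom >= 1,
            all(c(inter_frac, clip_frac, dup_frac, lowq_frac) >= 0),
            all(c(inter_frac, clip_frac, dup_frac, lowq_frac) <= 1),
            min_contig_len >= 2 * read_len)
  list(n_chrom = n_chrom,
       chrom_len = rep_len(chrom_len, n_chrom),
       contigs_per_chrom = contigs_per_chrom, n_pairs = n_pairs,
       alpha = alpha, s0 = s0, inter_frac = inter_frac,
       clip_frac = clip_frac, dup_frac = dup_frac, lowq_frac = lowq_frac,
       read_len = read_len, min_contig_len = min_contig_len,
       seed = as.integer(seed))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sorted breakpoints keeping every piece >= min_len
cut_points <- function(L, k, min_len) {
  if (k == 1) return(numeric(0))
  repeat {
    bp <- sort(sample.int(L - 1, k - 1))
    if (all(diff(c(0, bp, L)) >= min_len)) return(bp)
  }
}

#' Simulate a genome and its contig set
#'
#' Chromosomes are random nucleotide sequences cut at random breakpoints into
#' contigs; a random half of the contigs is emitted reverse-complemented, with
#' the true order/orientation recorded.
#'
#' @param params from [sim_params()].
#' @return object of class `sim_truth`: list with `truth` (data.frame
#'   `contig`, `chrom`, `start`, `end` 0-based half-open, `strand`, `length`),
#'   `chrom_len` (named), `contigs` (named character vector of emitted contig
#'   sequences) and `params`.
#' @export
simulate_genome <- function(params) {
  set.seed(params$seed)
  chroms <- stats::setNames(as.numeric(params$chrom_len),
                            sprintf("chr%d", seq_len(params$n_chrom)))
  chrom_seq <- vapply(chroms, random_dna, "")
  rows <- list(); contig_seq <- character(0)
  for (ci in seq_along(chroms)) {
    cn <- names(chroms)[ci]
    L <- chroms[[ci]]
    bp <- cut_points(L, params$contigs_per_chrom, params$min_contig_len)
    start <- c(0, bp); end <- c(bp, L)
    for (j in seq_along(start)) {
      id <- sprintf("%s_c%02d", cn, j)
      strand <- sample(c("+", "-"), 1)
      seq <- substr(chrom_seq[ci], start[j] + 1, end[j])
      if (strand == "-")
        seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq)))
      contig_seq[id] <- seq
      rows[[length(rows) + 1]] <- data.frame(
        contig = id, chrom = cn, start = start[j], end = end[j],
        strand = strand, length = end[j] - start[j], stringsAsFactors = FALSE)
    }
  }
  structure(list(truth = do.call(rbind, rows), chrom_len = chroms,
                 contigs = contig_seq, params = params),
            class = "sim_truth")
}

# inverse-CDF sample of separations with density ~ (s + s0)^(-alpha) on
# [0, Lmax]; vectorized over Lmax
sample_decay <- function(n, alpha, s0, Lmax) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    s <- s0 * ((1 + Lmax / s0)^u - 1)
  } else {
    a <- 1 - alpha
    s <- ((s0^a + u * ((Lmax + s0)^a - s0^a))^(1 / a)) - s0
  }
  pmin(pmax(floor(s), 0), Lmax - 1)
}

# genome position -> (contig, 0-based contig position, flipped?)
genome_to_contig <- function(truth, chrom, gpos) {
  out_ctg <- character(length(gpos)); out_pos <- numeric(length(gpos))
  out_flip <- logical(length(gpos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    tt <- truth[truth$chrom == cn, , drop = FALSE]
    tt <- tt[order(tt$start), , drop = FALSE]
    idx <- findInterval(gpos[sel], tt$start)
    out_ctg[sel] <- tt$contig[idx]
    fwd <- tt$strand[idx] == "+"
    out_pos[sel] <- ifelse(fwd, gpos[sel] - tt$start[idx],
                           tt$end[idx] - 1 - gpos[sel])
    out_flip[sel] <- !fwd
  }
  list(contig = out_ctg, pos = out_pos, flip = out_flip)
}

#' Simulate Hi-C read-pair alignments against the contigs
#'
#' Intra-chromosomal pairs (fraction `1 - inter_frac`) take a uniform start
#' and a separation from the distance-decay distribution; inter-chromosomal
#' pairs take uniform positions on two distinct chromosomes. Positions are
#' translated to contig coordinates and strands through the truth, and noise
#' records (soft-clipped, duplicated, MAPQ-0) are injected to exercise every
#' filter. Output is name-collated. Uses seed `params$seed + 1`.
#'
#' @param sim a `sim_truth` from [simulate_genome()].
#' @return pair data.frame in the [read_hic_pairs()] schema.
#' @export
simulate_hic_pairs <- function(sim) {
  params <- sim$params
  set.seed(params$seed + 1L)
  truth <- sim$truth
  rl <- params$read_len
  n_inter <- round(params$n_pairs * params$inter_frac)
  n_intra <- params$n_pairs - n_inter
  cl <- sim$chrom_len
  # intra: chromosome ~ length, separation ~ decay, direction random
  ch <- sample(names(cl), n_intra, replace = TRUE, prob = cl)
  L <- cl[ch]
  g1 <- floor(stats::runif(n_intra) * L)
  s <- sample_decay(n_intra, params$alpha, params$s0, L)
  dir <- sample(c(-1, 1), n_intra, replace = TRUE)
  g2 <- g1 + dir * s
  g2 <- ifelse(g2 < 0, -g2, g2)               # reflect at chromosome ends
  g2 <- ifelse(g2 >= L, 2 * L - 2 - g2, g2)
  chrom1 <- ch; chrom2 <- ch
  # inter: two distinct chromosomes, uniform positions
  if (n_inter > 0) {
    ca <- sample(names(cl), n_inter, replace = TRUE, prob = cl)
    cb <- sample(names(cl), n_inter, replace = TRUE, prob = cl)
    while (any(same <- ca == cb))
      cb[same] <- sample(names(cl), sum(same), replace = TRUE, prob = cl)
    ga <- floor(stats::runif(n_inter) * cl[ca])
    gb <- floor(stats::runif(n_inter) * cl[cb])
    chrom1 <- c(chrom1, ca); chrom2 <- c(chrom2, cb)
    g1 <- c(g1, ga); g2 <- c(g2, gb)
  }
  n <- length(g1)
  m1 <- genome_to_contig(truth, chrom1, g1)
  m2 <- genome_to_contig(truth, chrom2, g2)
  clen <- stats::setNames(truth$length, truth$contig)
  rev1 <- xor(sample(c(TRUE, FALSE), n, replace = TRUE), m1$flip)
  rev2 <- xor(sample(c(TRUE, FALSE), n, replace = TRUE), m2$flip)
  # clamp the 5' coordinate so the full-length alignment fits in the contig
  clamp5 <- function(pos, rev, id) {
    len <- clen[id]
    ifelse(rev, pmin(pmax(pos, rl - 1), len - 1),
           pmin(pmax(pos, 0), len - rl))
  }
  p1 <- clamp5(m1$pos, rev1, m1$contig)
  p2 <- clamp5(m2$pos, rev2, m2$contig)
  pairs <- data.frame(
    qname = sprintf("sim%07d", seq_len(n)),
    rname1 = m1$contig, pos1 = ifelse(rev1, p1 - (rl - 1), p1) + 1,
    mapq1 = 60L, cigar1 = sprintf("%dM", rl),
    flag1 = 1L + 64L + 16L * rev1 + 32L * rev2,
    rname2 = m2$contig, pos2 = ifelse(rev2, p2 - (rl - 1), p2) + 1,
    mapq2 = 60L, cigar2 = sprintf("%dM", rl),
    flag2 = 1L + 128L + 16L * rev2 + 32L * rev1,
    stringsAsFactors = FALSE)
  # noise injection on disjoint subsets of the core pairs
  n_lowq <- round(n * params$lowq_frac)
  n_clip <- round(n * params$clip_frac)
  pick <- sample.int(n, n_lowq + n_clip)
  if (n_lowq) pairs$mapq1[pick[seq_len(n_lowq)]] <- 0L
  if (n_clip) {
    ic <- pick[n_lowq + seq_len(n_clip)]
    pairs$cigar1[ic] <- sprintf("10S%dM", rl - 10)
  }
  n_dup <- round(n * params$dup_frac)
  if (n_dup) {
    src <- sample.int(n, n_dup, replace = TRUE)
    dups <- pairs[src, , drop = FALSE]
    dups$qname <- sprintf("dup%07d", seq_len(n_dup))
    flagged <- seq_len(n_dup) <= n_dup / 2
    dups$flag1[flagged] <- dups$flag1[flagged] + 1024L
    dups$flag2[flagged] <- dups$flag2[flagged] + 1024L
    pairs <- rbind(pairs, dups)
  }
  rownames(pairs) <- NULL
  pairs
}

#' Write a pair data.frame as a name-collated SAM file
#'
#' @param pairs pair data.frame ([read_hic_pairs()] schema).
#' @param lengths named vector of target sequence lengths (for `@SQ` lines).
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), as.integer(lengths)))
  rec <- function(qn, flag, rn, pos, mapq, cig, rnext, pnext) {
    paste(qn, flag, rn, pos, mapq, cig, rnext, pnext, 0, "*", "*", sep = "\t")
  }
  l1 <- rec(pairs$qname, pairs$flag1, pairs$rname1, pairs$pos1, pairs$mapq1,
            pairs$cigar1,
            ifelse(pairs$rname1 == pairs$rname2, "=", pairs$rname2),
            pairs$pos2)
  l2 <- rec(pairs$qname, pairs$flag2, pairs$rname2, pairs$pos2, pairs$mapq2,
            pairs$cigar2,
            ifelse(pairs$rname1 == pairs$rname2, "=", pairs$rname1),
            pairs$pos1)
  body <- character(2 * nrow(pairs))
  body[seq(1, length(body), by = 2)] <- l1
  body[seq(2, length(body), by = 2)] <- l2
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' The true per-chromosome SAT document
#'
#' One path per chromosome, members in genomic order, oriented so that the
#' scaffold reconstructs the chromosome forward strand.
#'
#' @param sim a `sim_truth`.
#' @param gap_len gap size, bp.
#' @return a `sat_document`.
#' @export
true_paths_doc <- function(sim, gap_len = 200) {
  truth <- sim$truth
  doc <- sat_from_lengths(stats::setNames(truth$length, truth$contig),
                          sequences = sim$contigs, gap_len = gap_len)
  paths <- list(); members <- list()
  for (cn in names(sim$chrom_len)) {
    tt <- truth[truth$chrom == cn, , drop = FALSE]
    tt <- tt[order(tt$start), , drop = FALSE]
    paths[[cn]] <- data.frame(id = cn, length = path_length(tt$length, gap_len),
                              tags = "", stringsAsFactors = FALSE)
    members[[cn]] <- data.frame(path = cn, ord = seq_len(nrow(tt)),
                                contig = tt$contig, orient = tt$strand,
                                stringsAsFactors = FALSE)
  }
  doc$paths <- do.call(rbind, c(list(doc$paths), paths))
  doc$members <- do.call(rbind, c(list(doc$members), members))
  doc$sets$chrom <- names(sim$chrom_len)
  doc$current <- "chrom"
  rownames(doc$paths) <- rownames(doc$members) <- NULL
  validate_sat(doc)
  doc
}

#' Build a deliberately chimeric SAT document
#'
#' Chains the true chromosome paths of `chroms` into a single path, creating
#' one false join per chromosome boundary — the scenario the misjoin stage
#' must resolve.
#'
#' @param sim a `sim_truth`.
#' @param chroms chromosome names to chain (default: all).
#' @param gap_len gap size, bp.
#' @return list with `doc` (the chimeric `sat_document`, chained path id
#'   `"chimera"`) and `joins` (data.frame `path`, `join`, `is_false`: truth
#'   labels for every join of the chained path).
#' @export
make_chimeric_doc <- function(sim, chroms = names(sim$chrom_len),
                              gap_len = 200) {
  stopifnot(length(chroms) >= 2)
  tdoc <- true_paths_doc(sim, gap_len)
  mem <- list()
  for (cn in chroms) mem[[cn]] <- path_members(tdoc, cn)
  block_sizes <- vapply(mem, nrow, 0L)
  mem <- do.call(rbind, mem)
  n_j <- nrow(mem) - 1
  false_at <- cumsum(block_sizes)[-length(block_sizes)]
  doc <- sat_from_lengths(
    stats::setNames(sim$truth$length, sim$truth$contig),
    sequences = sim$contigs, gap_len = gap_len)
  clen <- doc$contigs$length[match(mem$contig, doc$contigs$id)]
  doc$paths <- rbind(doc$paths, data.frame(
    id = "chimera", length = path_length(clen, gap_len), tags = "",
    stringsAsFactors = FALSE))
  doc$members <- rbind(doc$members, data.frame(
    path = "chimera", ord = seq_len(nrow(mem)), contig = mem$contig,
    orient = mem$orient, stringsAsFactors = FALSE))
  keep <- setdiff(names(sim$chrom_len), chroms)
  other <- unlist(lapply(keep, function(cn) path_members(tdoc, cn)$contig))
  doc$sets$chimeric <- c("chimera",
                         if (length(other)) other else character(0))
  # contigs of unchained chromosomes stay as singletons
  doc$current <- "chimeric"
  rownames(doc$paths) <- rownames(doc$members) <- NULL
  validate_sat(doc)
  list(doc = doc,
       joins = data.frame(path = "chimera", join = seq_len(n_j),
                          is_false = seq_len(n_j) %in% false_at))
}

#' Score a scaffolding result against the simulated truth
#'
#' A chromosome counts as recovered when some current path contains exactly
#' its contigs in true genomic order and orientation, up to whole-scaffold
#' reversal. Cross-chromosome joins are adjacent members from different true
#' chromosomes.
#'
#' @param doc a `sat_document`.
#' @param sim a `sim_truth`.
#' @return list with `recovered` (named logical per chromosome) and
#'   `cross_joins` (count of adjacent member pairs spanning chromosomes).
#' @export
scaffold_accuracy <- function(doc, sim) {
  truth <- sim$truth
  sig <- function(m) paste(paste0(m$contig, m$orient), collapse = ",")
  flip <- function(m) data.frame(
    contig = rev(m$contig), orient = rev(chartr("+-", "-+", m$orient)),
    stringsAsFactors = FALSE)
  path_sigs <- unlist(lapply(current_paths(doc), function(p) {
    m <- path_members(doc, p)
    c(sig(m), sig(flip(m)))
  }))
  recovered <- vapply(names(sim$chrom_len), function(cn) {
    tt <- truth[truth$chrom == cn, , drop = FALSE]
    tt <- tt[order(tt$start), , drop = FALSE]
    sig(data.frame(contig = tt$contig, orient = tt$strand)) %in% path_sigs
  }, logical(1))
  cross <- 0L
  for (p in current_paths(doc)) {
    m <- path_members(doc, p)
    if (nrow(m) < 2) next
    ch <- truth$chrom[match(m$contig, truth$contig)]
    cross <- cross + sum(ch[-1] != ch[-length(ch)])
  }
  list(recovered = recovered, cross_joins = cross)
}

#' Transcribed worked example of the scaffolding graph
#'
#' An 11-contig neighbor fixture with 9 mutual edges whose pruning and path
#' outcomes are known: 6 edges survive, giving 6 paths — 3 singletons, one
#' cyclic 3-contig path (11F, 13F, 19F) and the acyclic paths
#' (01F, 04F, 06F) and (03F, 07F). Edge weights are fixture data for the
#' structural outcome, not ground truth in themselves.
#'
#' @return list with `neighbors` (an `nbest_neighbors` object), `lengths`,
#'   and `expected` (list: `surviving_edges`, `n_paths`, `n_singletons`,
#'   `cycle`, `paths`).
#' @export
worked_example <- function() {
  ids <- c("01F", "02F", "03F", "04F", "05F", "06F", "07F",
           "11F", "13F", "19F", "21F")
  lengths <- stats::setNames(rep(1e5, length(ids)), ids)
  e <- data.frame(
    id1 = c("01F", "04F", "03F", "11F", "13F", "19F", "01F", "03F", "13F"),
    end1 = c("t", "t", "t", "t", "t", "t", "t", "t", "t"),
    id2 = c("04F", "06F", "07F", "13F", "19F", "11F", "02F", "05F", "21F"),
    end2 = c("h", "h", "h", "h", "h", "h", "h", "h", "h"),
    weight = c(3.0, 2.5, 4.0, 5.0, 4.5, 4.2, 2.0, 1.0, 1.2),
    stringsAsFactors = FALSE)
  nb <- rbind(
    data.frame(id = e$id1, end = e$end1, nb_id = e$id2, nb_end = e$end2,
               count = 100, nc = e$weight, stringsAsFactors = FALSE),
    data.frame(id = e$id2, end = e$end2, nb_id = e$id1, nb_end = e$end1,
               count = 100, nc = e$weight, stringsAsFactors = FALSE))
  o <- order(nb$id, nb$end, -nb$nc)
  nb <- nb[o, , drop = FALSE]
  grp <- paste(nb$id, nb$end, sep = "\x01")
  nb$rank <- stats::ave(seq_len(nrow(nb)), grp, FUN = seq_along)
  rownames(nb) <- NULL
  nb <- structure(nb, class = c("nbest_neighbors", "data.frame"),
                  ids = ids, lengths = lengths, nbest = 3)
  list(neighbors = nb, lengths = lengths,
       expected = list(
         surviving_edges = e[1:6, ],
         n_edges_before = 9L, n_edges_after = 6L,
         n_paths = 6L, n_singletons = 3L,
         cycle = c("11F", "13F", "19F"),
         paths = list(c("01F", "04F", "06F"), c("03F", "07F"))))
}
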
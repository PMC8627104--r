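# Hi-C alignment input. Reads are expected to have been mapped independently
# (e.g. bwa mem -SP with a raised mismatch penalty); we consume whatever
# qualifying SAM/BAM is provided, name-collated (mates adjacent), and apply
# the pair filters ourselves.

FLAG_UNMAPPED <- 4L
FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L
FLAG_DUP <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

#' Read name-collated Hi-C pairs from SAM/BAM
#'
#' Loads primary alignment records and pairs adjacent records of the same
#' read name into one row per pair. Position-sorted input is rejected (mates
#' would require unbounded buffering); a record whose mate never appears
#' adjacent is an orphan and raises an error reporting the orphan count.
#'
#' @param paths one or more SAM or BAM files, or an already-built pair
#'   data.frame (returned unchanged).
#' @return data.frame with one row per pair: `qname`, and per mate `rname`,
#'   `pos` (1-based leftmost), `mapq`, `cigar`, `flag` (suffixes 1/2).
#' @export
read_hic_pairs <- function(paths) {
  if (is.data.frame(paths)) return(paths)
  res <- lapply(paths, read_hic_pairs_one)
  do.call(rbind, res)
}

read_hic_pairs_one <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
  hd <- hdr[names(hdr) == "@HD"]
  if (length(hd) && any(grepl("SO:coordinate", unlist(hd))))
    stop("input is position-sorted; name-collated alignments are required ",
         "(mates must be adjacent)")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- bitwAnd(b$flag, FLAG_SECONDARY + FLAG_SUPPLEMENTARY) == 0L
  d <- data.frame(qname = b$qname[keep], flag = b$flag[keep],
                  rname = as.character(b$rname)[keep], pos = b$pos[keep],
                  mapq = b$mapq[keep], cigar = b$cigar[keep],
                  stringsAsFactors = FALSE)
  r <- rle(d$qname)
  if (any(r$lengths != 2L)) {
    n_orph <- sum(abs(r$lengths - 2L))
    stop(sprintf(
      "input is not name-collated: %d primary record(s) without an adjacent mate",
      n_orph))
  }
  i1 <- seq(1, nrow(d), by = 2); i2 <- i1 + 1L
  data.frame(qname = d$qname[i1],
             rname1 = d$rname[i1], pos1 = d$pos[i1], mapq1 = d$mapq[i1],
             cigar1 = d$cigar[i1], flag1 = d$flag[i1],
             rname2 = d$rname[i2], pos2 = d$pos[i2], mapq2 = d$mapq[i2],
             cigar2 = d$cigar[i2], flag2 = d$flag[i2],
             stringsAsFactors = FALSE)
}

cigar_ref_width <- function(cigar) {
  w <- rep(NA_real_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok))
    w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  w
}

# Per-mate derived columns: strand, 0-based 5' reference coordinate (leftmost
# base for forward strand, rightmost for reverse), clipping and flags.
annotate_pairs <- function(pairs) {
  for (m in c("1", "2")) {
    flag <- pairs[[paste0("flag", m)]]
    cig <- pairs[[paste0("cigar", m)]]
    pos0 <- pairs[[paste0("pos", m)]] - 1
    unmapped <- bitwAnd(flag, FLAG_UNMAPPED) != 0L | is.na(pos0)
    rev <- bitwAnd(flag, FLAG_REVERSE) != 0L
    rw <- cigar_ref_width(cig)
    fivep <- ifelse(rev, pos0 + rw - 1, pos0)
    fivep[unmapped] <- NA_real_
    pairs[[paste0("strand", m)]] <- ifelse(rev, "-", "+")
    pairs[[paste0("fivep", m)]] <- fivep
    pairs[[paste0("unmapped", m)]] <- unmapped
    pairs[[paste0("clipped", m)]] <- !is.na(cig) & grepl("[SH]", cig)
    pairs[[paste0("dupflag", m)]] <- bitwAnd(flag, FLAG_DUP) != 0L
  }
  pairs
}

# Orientation-normalized duplicate key over raw (contig-level) coordinates.
dup_key <- function(pairs) {
  k1 <- paste(pairs$rname1, pairs$fivep1, pairs$strand1, sep = "\x01")
  k2 <- paste(pairs$rname2, pairs$fivep2, pairs$strand2, sep = "\x01")
  ifelse(k1 <= k2, paste(k1, k2, sep = "\x02"), paste(k2, k1, sep = "\x02"))
}

#' Qualify Hi-C read pairs against a scaffolding state
#'
#' Applies the pair filters: both mates primary and mapped, no soft/hard
#' clipping, mapping quality at least `q`, not a duplicate (duplicate flag or
#' an orientation-normalized coordinate tuple seen before). In `"contact"`
#' mode the two mates must additionally land on *different* scaffolds after
#' lifting contig coordinates through `doc`; in `"spanning"` mode they must
#' land on the same contig or on adjacent members of the same scaffold.
#'
#' @param pairs pair data.frame from [read_hic_pairs()].
#' @param doc a `sat_document` describing the current scaffolds.
#' @param q minimum mapping quality (default 10).
#' @param mode `"contact"` or `"spanning"`.
#' @return the pair data.frame with added columns `scaf1`, `lpos1`, `scaf2`,
#'   `lpos2` (lifted coordinates) and `reason` (`"accept"` or the first
#'   failing filter).
#' @export
qualify_pairs <- function(pairs, doc, q = 10, mode = c("contact", "spanning")) {
  mode <- match.arg(mode)
  pairs <- annotate_pairs(pairs)
  n <- nrow(pairs)
  lt <- lift_table(doc)
  li <- function(rn) {
    i <- match(rn, lt$contig)
    if (anyNA(i[!is.na(rn)] ))
      stop("alignment target not present in SAT document: ",
           rn[which(is.na(i) & !is.na(rn))[1]])
    i
  }
  i1 <- li(pairs$rname1); i2 <- li(pairs$rname2)
  fwd1 <- lt$orient[i1] == "+"; fwd2 <- lt$orient[i2] == "+"
  pairs$scaf1 <- lt$path[i1]
  pairs$scaf2 <- lt$path[i2]
  pairs$lpos1 <- ifelse(fwd1, lt$offset[i1] + pairs$fivep1,
                        lt$offset[i1] + lt$clen[i1] - 1 - pairs$fivep1)
  pairs$lpos2 <- ifelse(fwd2, lt$offset[i2] + pairs$fivep2,
                        lt$offset[i2] + lt$clen[i2] - 1 - pairs$fivep2)
  unmapped <- pairs$unmapped1 | pairs$unmapped2
  clipped <- pairs$clipped1 | pairs$clipped2
  lowq <- !unmapped & (pairs$mapq1 < q | pairs$mapq2 < q)
  # duplicate = duplicate flag, or a coordinate tuple already counted among
  # pairs that pass the other per-record filters
  dup <- pairs$dupflag1 | pairs$dupflag2
  elig <- !unmapped & !clipped & !lowq & !dup
  dup[elig] <- duplicated(dup_key(pairs)[elig])
  reason <- rep("accept", n)
  # assign in reverse priority so the first failing filter wins
  if (mode == "spanning") {
    same_ctg <- !unmapped & pairs$rname1 == pairs$rname2
    adjacent <- !unmapped & !same_ctg & pairs$scaf1 == pairs$scaf2 &
      abs(lt$ord[i1] - lt$ord[i2]) == 1
    reason[!(same_ctg | adjacent)] <- "non_adjacent"
    reason[dup] <- "duplicate"
    reason[lowq] <- "low_mapq"
    reason[clipped] <- "clipped"
  } else {
    reason[dup] <- "duplicate"
    reason[lowq] <- "low_mapq"
    reason[clipped] <- "clipped"
    reason[!unmapped & pairs$scaf1 == pairs$scaf2] <- "intra"
  }
  reason[unmapped] <- "unmapped"
  pairs$reason <- reason
  pairs
}
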
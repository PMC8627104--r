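# SAT documents: the in-memory assembly/scaffold model and its on-disk text
# format. SAT is a GFA-derived dialect with five record types:
#   S <id> <length> [<sequence>] [tags...]          a contig
#   L <id1> <+/-> <id2> <+/-> wt:f:<w> [tags...]    a weighted oriented join
#   P <id> <length> <ctg1+,ctg2-,...> [tags...]     a scaffold path
#   A <set> <pid1,pid2,...>                         an assembly set of paths
#   C <set>                                         the current assembly set
# Coordinates are 0-based half-open internally; AGP output is 1-based.

#' Construct a SAT document
#'
#' A SAT document holds the full scaffolding state: contigs (optionally with
#' sequence), weighted oriented links between contigs, scaffold paths, named
#' assembly sets of paths and the pointer to the current set. Scaffold length
#' is the sum of member contig lengths plus `gap_len` for every internal join.
#'
#' @param contigs data.frame with columns `id`, `length` (and optionally `tags`).
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`, `weight` (and optionally `tags`). May have zero rows.
#' @param paths data.frame with columns `id`, `length` (optionally `tags`).
#' @param members data.frame with columns `path`, `ord` (1-based member index),
#'   `contig`, `orient` (`"+"` or `"-"`).
#' @param sets named list of character vectors of path ids.
#' @param current name of the active assembly set.
#' @param sequences named character vector of contig sequences, or `NULL`.
#' @param gap_len gap size in bp inserted between adjacent scaffold members.
#' @return An object of class `sat_document`.
#' @export
sat_document <- function(contigs, links = empty_links(), paths = empty_paths(),
                         members = empty_members(), sets = list(asm1 = character(0)),
                         current = names(sets)[1], sequences = NULL,
                         gap_len = 200) {
  doc <- structure(list(
    contigs = as.data.frame(contigs, stringsAsFactors = FALSE),
    links = as.data.frame(links, stringsAsFactors = FALSE),
    paths = as.data.frame(paths, stringsAsFactors = FALSE),
    members = as.data.frame(members, stringsAsFactors = FALSE),
    sets = sets, current = current, sequences = sequences,
    gap_len = as.numeric(gap_len)
  ), class = "sat_document")
  if (!"tags" %in% names(doc$contigs))
    doc$contigs$tags <- rep("", nrow(doc$contigs))
  if (!"tags" %in% names(doc$links) && nrow(doc$links)) doc$links$tags <- ""
  if (!"tags" %in% names(doc$paths) && nrow(doc$paths)) doc$paths$tags <- ""
  for (f in c("contigs", "links", "paths", "members"))
    rownames(doc[[f]]) <- NULL
  validate_sat(doc)
  doc
}

empty_links <- function() {
  data.frame(from = character(0), from_orient = character(0),
             to = character(0), to_orient = character(0),
             weight = numeric(0), tags = character(0), stringsAsFactors = FALSE)
}

empty_paths <- function() {
  data.frame(id = character(0), length = numeric(0), tags = character(0),
             stringsAsFactors = FALSE)
}

empty_members <- function() {
  data.frame(path = character(0), ord = integer(0), contig = character(0),
             orient = character(0), stringsAsFactors = FALSE)
}

#' Validate a SAT document's invariants
#'
#' Checks id uniqueness, link/member references, sequence lengths, path length
#' arithmetic and the one-path-per-contig rule within the current set.
#'
#' @param doc a `sat_document`.
#' @return `doc`, invisibly. Stops with an informative error on violation.
#' @export
validate_sat <- function(doc) {
  stopifnot(inherits(doc, "sat_document"))
  cid <- doc$contigs$id
  if (anyDuplicated(cid)) stop("duplicate contig ids in SAT document")
  if (any(doc$contigs$length < 0)) stop("negative contig length")
  if (nrow(doc$links)) {
    bad <- setdiff(c(doc$links$from, doc$links$to), cid)
    if (length(bad)) stop("link references unknown contig: ", bad[1])
    if (any(doc$links$weight < 0)) stop("negative link weight")
  }
  if (nrow(doc$members)) {
    bad <- setdiff(doc$members$contig, cid)
    if (length(bad)) stop("path references unknown contig: ", bad[1])
    if (!all(doc$members$orient %in% c("+", "-"))) stop("bad member orientation")
  }
  if (anyDuplicated(doc$paths$id)) stop("duplicate path ids")
  bad <- setdiff(doc$members$path, doc$paths$id)
  if (length(bad)) stop("member references unknown path: ", bad[1])
  if (!is.null(doc$sequences)) {
    with_seq <- intersect(names(doc$sequences), cid)
    lens <- doc$contigs$length[match(with_seq, cid)]
    if (any(nchar(doc$sequences[with_seq]) != lens))
      stop("sequence length disagrees with S record length")
  }
  if (!doc$current %in% names(doc$sets)) stop("current set does not exist")
  bad <- setdiff(unlist(doc$sets), doc$paths$id)
  if (length(bad)) stop("assembly set references unknown path: ", bad[1])
  cur <- current_paths(doc)
  mem <- doc$members[doc$members$path %in% cur, ]
  if (anyDuplicated(mem$contig))
    stop("contig appears in more than one path of the current set: ",
         mem$contig[duplicated(mem$contig)][1])
  # path lengths must match sum(members) + gap * (k - 1)
  if (nrow(doc$paths)) {
    expect <- vapply(doc$paths$id, function(p) {
      m <- doc$members[doc$members$path == p, ]
      path_length(doc$contigs$length[match(m$contig, cid)], doc$gap_len)
    }, numeric(1))
    if (any(expect != doc$paths$length))
      stop("path length inconsistent with members for path: ",
           doc$paths$id[which(expect != doc$paths$length)[1]])
  }
  invisible(doc)
}

path_length <- function(member_lengths, gap_len) {
  k <- length(member_lengths)
  if (k == 0) return(0)
  sum(member_lengths) + gap_len * (k - 1)
}

#' Path ids of the current assembly set
#' @param doc a `sat_document`.
#' @return character vector of path ids.
#' @export
current_paths <- function(doc) doc$sets[[doc$current]]

#' Ordered members of one path
#' @param doc a `sat_document`.
#' @param path_id path id.
#' @return data.frame with columns `contig`, `orient` in path order.
#' @export
path_members <- function(doc, path_id) {
  m <- doc$members[doc$members$path == path_id, , drop = FALSE]
  m <- m[order(m$ord), c("contig", "orient")]
  rownames(m) <- NULL
  m
}

#' Build a SAT document from contig lengths
#'
#' Each contig becomes a singleton path of the same id, gathered in one
#' current assembly set — the starting state of scaffolding.
#'
#' @param lengths named numeric vector of contig lengths (bp).
#' @param sequences optional named character vector of contig sequences.
#' @param gap_len gap size between scaffold members, bp.
#' @return a `sat_document`.
#' @export
sat_from_lengths <- function(lengths, sequences = NULL, gap_len = 200) {
  ids <- names(lengths)
  if (is.null(ids) || any(ids == "")) stop("lengths must be a named vector")
  sat_document(
    contigs = data.frame(id = ids, length = as.numeric(lengths),
                         stringsAsFactors = FALSE),
    paths = data.frame(id = ids, length = as.numeric(lengths),
                       tags = "", stringsAsFactors = FALSE),
    members = data.frame(path = ids, ord = 1L, contig = ids, orient = "+",
                         stringsAsFactors = FALSE),
    sets = stats::setNames(list(ids), "asm1"), current = "asm1",
    sequences = sequences, gap_len = gap_len
  )
}

#' Build a SAT document from a FASTA file of contigs
#' @param fasta path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param gap_len gap size between scaffold members, bp.
#' @return a `sat_document` carrying the contig sequences.
#' @export
sat_from_fasta <- function(fasta, gap_len = 200) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sat_from_lengths(stats::setNames(Biostrings::width(seqs), names(seqs)),
                   sequences = stats::setNames(as.character(seqs), names(seqs)),
                   gap_len = gap_len)
}

num_field <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

#' Serialize a SAT document to text lines
#'
#' Record order is deterministic: all S (input order), then L, then P sorted by
#' path id, then A sets, then C — so outputs are diffable across runs.
#'
#' @param doc a `sat_document`.
#' @return character vector of tab-separated lines.
#' @export
format_sat <- function(doc) {
  out <- character(0)
  tagf <- function(tags) ifelse(is.na(tags) | tags == "", "", paste0("\t", tags))
  if (nrow(doc$contigs)) {
    seqf <- rep("", nrow(doc$contigs))
    if (!is.null(doc$sequences)) {
      has <- doc$contigs$id %in% names(doc$sequences)
      seqf[has] <- paste0("\t", doc$sequences[doc$contigs$id[has]])
    }
    out <- c(out, paste0("S\t", doc$contigs$id, "\t",
                         num_field(doc$contigs$length), seqf,
                         tagf(doc$contigs$tags)))
  }
  if (nrow(doc$links)) {
    out <- c(out, paste0("L\t", doc$links$from, "\t", doc$links$from_orient,
                         "\t", doc$links$to, "\t", doc$links$to_orient,
                         "\twt:f:", num_field(doc$links$weight),
                         tagf(doc$links$tags)))
  }
  if (nrow(doc$paths)) {
    pids <- sort(doc$paths$id)
    for (p in pids) {
      m <- path_members(doc, p)
      len <- doc$paths$length[doc$paths$id == p]
      tg <- doc$paths$tags[doc$paths$id == p]
      out <- c(out, paste0("P\t", p, "\t", num_field(len), "\t",
                           paste0(m$contig, m$orient, collapse = ","),
                           tagf(tg)))
    }
  }
  for (s in names(doc$sets)) {
    if (length(doc$sets[[s]]))
      out <- c(out, paste0("A\t", s, "\t", paste(doc$sets[[s]], collapse = ",")))
  }
  c(out, paste0("C\t", doc$current))
}

#' Write a SAT document to a file
#' @param doc a `sat_document`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sat <- function(doc, path) {
  writeLines(format_sat(doc), path)
  invisible(path)
}

is_tag_field <- function(x) grepl("^[A-Za-z][A-Za-z0-9]:[AifZHB]:", x)

#' Parse SAT text into a document
#'
#' @param x path to a SAT file, or a character vector of lines (as produced by
#'   [format_sat()]).
#' @param gap_len gap size used for path-length bookkeeping, bp.
#' @return a `sat_document`. Malformed records raise errors naming the line.
#' @export
read_sat <- function(x, gap_len = 200) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  contigs <- list(); links <- list(); paths <- list(); mem <- list()
  seqs <- character(0)
  sets <- list(); current <- NULL
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rt <- f[1]
    err <- function(msg) stop(sprintf("SAT parse error at line %d: %s", i, msg))
    if (rt == "S") {
      if (length(f) < 3) err("S record needs id and length")
      len <- suppressWarnings(as.numeric(f[3]))
      if (is.na(len)) err("non-numeric contig length")
      rest <- f[-(1:3)]
      seq <- NULL
      if (length(rest) && !is_tag_field(rest[1])) {
        seq <- rest[1]; rest <- rest[-1]
        if (nchar(seq) != len) err("sequence length != declared length")
      }
      contigs[[length(contigs) + 1]] <-
        data.frame(id = f[2], length = len,
                   tags = paste(rest, collapse = "\t"), stringsAsFactors = FALSE)
      if (!is.null(seq)) seqs[f[2]] <- seq
    } else if (rt == "L") {
      if (length(f) < 5) err("L record needs 4 fields")
      if (!f[3] %in% c("+", "-") || !f[5] %in% c("+", "-"))
        err("L orientations must be + or -")
      rest <- f[-(1:5)]
      wt_i <- grep("^wt:f:", rest)
      wt <- 0
      if (length(wt_i)) {
        wt <- suppressWarnings(as.numeric(sub("^wt:f:", "", rest[wt_i[1]])))
        if (is.na(wt)) err("bad wt tag")
        rest <- rest[-wt_i[1]]
      }
      links[[length(links) + 1]] <-
        data.frame(from = f[2], from_orient = f[3], to = f[4],
                   to_orient = f[5], weight = wt,
                   tags = paste(rest, collapse = "\t"), stringsAsFactors = FALSE)
    } else if (rt == "P") {
      if (length(f) < 4) err("P record needs id, length, members")
      len <- suppressWarnings(as.numeric(f[3]))
      if (is.na(len)) err("non-numeric path length")
      parts <- strsplit(f[4], ",", fixed = TRUE)[[1]]
      if (!length(parts)) err("empty path")
      ori <- substring(parts, nchar(parts))
      ctg <- substring(parts, 1, nchar(parts) - 1)
      if (!all(ori %in% c("+", "-"))) err("member orientation must be + or -")
      rest <- f[-(1:4)]
      paths[[length(paths) + 1]] <-
        data.frame(id = f[2], length = len,
                   tags = paste(rest, collapse = "\t"), stringsAsFactors = FALSE)
      mem[[length(mem) + 1]] <-
        data.frame(path = f[2], ord = seq_along(ctg), contig = ctg,
                   orient = ori, stringsAsFactors = FALSE)
    } else if (rt == "A") {
      if (length(f) < 3) err("A record needs set name and path list")
      sets[[f[2]]] <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    } else if (rt == "C") {
      if (length(f) < 2) err("C record needs a set name")
      current <- f[2]
    } else err(paste0("unknown record type '", rt, "'"))
  }
  contigs <- if (length(contigs)) do.call(rbind, contigs) else
    data.frame(id = character(0), length = numeric(0), tags = character(0),
               stringsAsFactors = FALSE)
  paths <- if (length(paths)) do.call(rbind, paths) else empty_paths()
  if (is.null(current)) {
    if (length(sets)) current <- names(sets)[1]
    else { sets <- list(asm1 = paths$id); current <- "asm1" }
  }
  if (!current %in% names(sets)) sets[[current]] <- character(0)
  if (!length(sets)) { sets <- stats::setNames(list(character(0)), current) }
  doc <- sat_document(
    contigs = contigs,
    links = if (length(links)) do.call(rbind, links) else empty_links(),
    paths = paths,
    members = if (length(mem)) do.call(rbind, mem) else empty_members(),
    sets = sets, current = current,
    sequences = if (length(seqs)) seqs else NULL, gap_len = gap_len
  )
  doc
}

#' @export
print.sat_document <- function(x, ...) {
  cat(sprintf(
    "sat_document: %d contigs, %d links, %d paths, %d sets (current '%s')\n",
    nrow(x$contigs), nrow(x$links), nrow(x$paths), length(x$sets), x$current))
  cur <- current_paths(x)
  if (length(cur)) {
    len <- x$paths$length[match(cur, x$paths$id)]
    cat(sprintf("current set: %d scaffolds, total %s bp, N50 %s bp\n",
                length(cur), format(sum(len), big.mark = ","),
                format(n50(len), big.mark = ",")))
  }
  invisible(x)
}

#' Drop scaffolding history from a SAT document
#'
#' Keeps only the paths of the current assembly set (and the links between
#' their members), discarding superseded paths and sets. Useful when emitting
#' a final result; the full document retains the whole iterative history.
#'
#' @param doc a `sat_document`.
#' @return a `sat_document` with a single assembly set.
#' @export
compact_sat <- function(doc) {
  cur <- current_paths(doc)
  doc$paths <- doc$paths[doc$paths$id %in% cur, , drop = FALSE]
  doc$members <- doc$members[doc$members$path %in% cur, , drop = FALSE]
  doc$sets <- stats::setNames(list(sort(cur)), doc$current)
  for (f in c("paths", "members")) rownames(doc[[f]]) <- NULL
  validate_sat(doc)
  doc
}

#' Coordinate lifting table for the current assembly set
#'
#' One row per contig of the current set, with the scaffold it belongs to,
#' its 0-based start offset on that scaffold, its orientation, member index
#' and the scaffold length. Used to translate contig-level alignment
#' coordinates to scaffold coordinates between scaffolding rounds.
#'
#' @param doc a `sat_document`.
#' @return data.frame with columns `contig`, `path`, `offset`, `orient`,
#'   `ord`, `clen`, `plen`, `n_members`.
#' @export
lift_table <- function(doc) {
  cur <- current_paths(doc)
  mem <- doc$members[doc$members$path %in% cur, , drop = FALSE]
  mem <- mem[order(mem$path, mem$ord), , drop = FALSE]
  clen <- doc$contigs$length[match(mem$contig, doc$contigs$id)]
  # offset of member j: sum of earlier member lengths + gap per earlier join
  off <- numeric(nrow(mem))
  for (ii in split(seq_len(nrow(mem)), mem$path))
    off[ii] <- cumsum(c(0, utils::head(clen[ii] + doc$gap_len, -1)))
  plen <- doc$paths$length[match(mem$path, doc$paths$id)]
  nm <- stats::ave(rep(1, nrow(mem)), mem$path, FUN = sum)
  data.frame(contig = mem$contig, path = mem$path, offset = off,
             orient = mem$orient, ord = mem$ord, clen = clen, plen = plen,
             n_members = nm, stringsAsFactors = FALSE)
}

#' Lift contig positions to scaffold coordinates
#'
#' For a `+`-oriented member at scaffold offset `o`, contig base `pos` maps to
#' `o + pos` on strand `+`; for a `-`-oriented member it maps to
#' `o + (contig_length - 1 - pos)` on strand `-`.
#'
#' @param doc a `sat_document`.
#' @param contig character vector of contig ids.
#' @param pos 0-based positions within each contig.
#' @return data.frame with columns `scaffold`, `position` (0-based), `strand`.
#' @export
lift_position <- function(doc, contig, pos) {
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n)
  pos <- rep_len(pos, n)
  lt <- lift_table(doc)
  i <- match(contig, lt$contig)
  if (anyNA(i))
    stop("contig not in any current path: ", contig[which(is.na(i))[1]])
  if (any(pos < 0 | pos >= lt$clen[i]))
    stop("position outside contig")
  fwd <- lt$orient[i] == "+"
  data.frame(
    scaffold = lt$path[i],
    position = ifelse(fwd, lt$offset[i] + pos,
                      lt$offset[i] + lt$clen[i] - 1 - pos),
    strand = ifelse(fwd, "+", "-"), stringsAsFactors = FALSE)
}

#' Convert a SAT document to AGP v2.1 records
#'
#' Emits one W line per contig and one U gap line (gap_type "scaffold",
#' linkage "yes", evidence "proximity_ligation") per internal join, with
#' 1-based inclusive object coordinates, for the current assembly set.
#'
#' @param doc a `sat_document`.
#' @param gap_len gap length in bp (default: the document's).
#' @return data.frame with the nine AGP columns.
#' @export
sat_to_agp <- function(doc, gap_len = doc$gap_len) {
  rows <- list()
  for (p in sort(current_paths(doc))) {
    m <- path_members(doc, p)
    clen <- doc$contigs$length[match(m$contig, doc$contigs$id)]
    at <- 1; part <- 1
    for (j in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- data.frame(
        object = p, object_beg = at, object_end = at + clen[j] - 1,
        part_number = part, component_type = "W", component_id = m$contig[j],
        component_beg = 1, component_end = clen[j],
        orientation = m$orient[j], stringsAsFactors = FALSE)
      at <- at + clen[j]; part <- part + 1
      if (j < nrow(m)) {
        rows[[length(rows) + 1]] <- data.frame(
          object = p, object_beg = at, object_end = at + gap_len - 1,
          part_number = part, component_type = "U", component_id = gap_len,
          component_beg = "scaffold", component_end = "yes",
          orientation = "proximity_ligation", stringsAsFactors = FALSE)
        at <- at + gap_len; part <- part + 1
      }
    }
  }
  if (!length(rows))
    return(data.frame(object = character(0), object_beg = numeric(0),
                      object_end = numeric(0), part_number = integer(0),
                      component_type = character(0), component_id = character(0),
                      component_beg = character(0), component_end = character(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write AGP records to a file
#' @param agp data.frame from [sat_to_agp()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Emit scaffold sequences for the current assembly set
#'
#' Members are concatenated in path order, `-`-oriented members
#' reverse-complemented, separated by `gap_len` Ns.
#'
#' @param doc a `sat_document`.
#' @param sequences named character vector of contig sequences (default: the
#'   document's own).
#' @param gap_len gap length in bp (default: the document's).
#' @return a named `Biostrings::DNAStringSet`, one entry per scaffold.
#' @export
scaffold_fasta <- function(doc, sequences = doc$sequences,
                           gap_len = doc$gap_len) {
  if (is.null(sequences)) stop("no contig sequences available")
  out <- character(0)
  gap <- strrep("N", gap_len)
  for (p in sort(current_paths(doc))) {
    m <- path_members(doc, p)
    miss <- setdiff(m$contig, names(sequences))
    if (length(miss)) stop("missing sequence for contig: ", miss[1])
    chunk <- sequences[m$contig]
    rev <- m$orient == "-"
    if (any(rev))
      chunk[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(chunk[rev])))
    out[p] <- paste(chunk, collapse = gap)
  }
  Biostrings::DNAStringSet(out)
}

#' Assembly contiguity metrics
#'
#' N50 is the length at which cumulative sorted-descending scaffold lengths
#' reach half the assembly size; NG50 replaces assembly size by `genome_size`.
#'
#' @param x a `sat_document`, a `DNAStringSet`, a FASTA path, or a numeric
#'   vector of lengths.
#' @param genome_size optional true genome size in bp (for NG50).
#' @return list with `count`, `total`, `largest`, `n50` and, when
#'   `genome_size` is given, `ng50`.
#' @export
assembly_metrics <- function(x, genome_size = NULL) {
  len <- if (inherits(x, "sat_document")) {
    x$paths$length[match(current_paths(x), x$paths$id)]
  } else if (inherits(x, "DNAStringSet")) {
    Biostrings::width(x)
  } else if (is.character(x)) {
    Biostrings::width(Biostrings::readDNAStringSet(x))
  } else as.numeric(x)
  if (!length(len)) stop("no sequences")
  res <- list(count = length(len), total = sum(len), largest = max(len),
              n50 = n50(len))
  if (!is.null(genome_size)) res$ng50 <- n50(len, genome_size)
  res
}

n50 <- function(lengths, target_size = sum(lengths)) {
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= target_size / 2)
  if (!length(i)) return(NA_real_)
  s[i[1]]
}
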
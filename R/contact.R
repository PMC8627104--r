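# Contact matrix over contig/scaffold ends. Each sequence is split into
# three equal parts (middle ignored) or two halves; the head and tail parts
# act as graph vertices so that joins carry orientation. Qualified
# inter-sequence pairs are tallied per unordered end pair, normalized by
# sequence length, and reduced to per-end N-best neighbor lists.

#' Head/tail intervals of a split sequence
#'
#' For `parts = 3` the head is the first third `[0, floor(L/3))` and the tail
#' the last third `[L - floor(L/3), L)`; the middle third carries no vertex.
#' For `parts = 2` the two halves meet at `floor(L/2)`.
#'
#' @param length sequence length, bp.
#' @param parts 2 or 3.
#' @return list with `head` and `tail`, each a 0-based half-open `c(start, end)`.
#' @export
split_intervals <- function(length, parts = 3) {
  stopifnot(length >= 1, parts %in% c(2, 3))
  k <- floor(length / parts)
  if (parts == 3) list(head = c(0, k), tail = c(length - k, length))
  else list(head = c(0, k), tail = c(k, length))
}

#' Assign a position to a sequence end
#'
#' Vectorized over positions/lengths. Returns `"h"` for the head interval,
#' `"t"` for the tail, and `NA` for the ignored middle third.
#'
#' @param pos 0-based positions.
#' @param length sequence lengths (recycled).
#' @param parts 2 or 3.
#' @return character vector of `"h"`, `"t"`, `NA`.
#' @export
assign_end <- function(pos, length, parts = 3) {
  stopifnot(parts %in% c(2, 3))
  k <- floor(length / parts)
  if (parts == 3) {
    out <- rep(NA_character_, max(length(pos), length(length)))
    out[pos < k] <- "h"
    out[pos >= length - k] <- "t"
    out
  } else ifelse(pos < k, "h", "t")
}

#' Scaffolding parameters
#'
#' @param q minimum mapping quality (default 10).
#' @param w minimum raw contact count for a pair of ends to be ranked
#'   (default 5); guards against short sequences attaining spuriously large
#'   normalized contacts.
#' @param nbest number of best neighbors kept per end (default 3).
#' @param parts split each sequence into 3 parts (middle ignored) or 2 halves.
#' @param norm `"summation"` (divide by `l_i/parts + l_j/parts`) or
#'   `"multiplication"` (divide by the product).
#' @return list of validated parameters.
#' @export
scaffold_params <- function(q = 10, w = 5, nbest = 3, parts = 3,
                            norm = c("summation", "multiplication")) {
  norm <- match.arg(norm)
  stopifnot(q >= 0, w >= 1, nbest >= 1, parts %in% c(2, 3))
  list(q = q, w = w, nbest = nbest, parts = parts, norm = norm)
}

#' Build the contact matrix
#'
#' Counts qualified inter-scaffold read pairs whose two 5' positions (lifted
#' to scaffold coordinates through `doc`) both fall in head/tail intervals.
#' Entries are stored once per unordered end pair; the matrix is symmetric by
#' construction.
#'
#' @param pairs pair data.frame from [read_hic_pairs()] (or simulator output).
#' @param doc a `sat_document`; in the first round, singleton paths per contig.
#' @param params from [scaffold_params()].
#' @return object of class `contact_matrix`: a list with `counts` (data.frame
#'   `id1`, `end1`, `id2`, `end2`, `count`), `lengths` (named scaffold
#'   lengths), `parts` and `stats` (pair counts by filter reason).
#' @export
build_contact_matrix <- function(pairs, doc, params = scaffold_params()) {
  qp <- qualify_pairs(pairs, doc, q = params$q, mode = "contact")
  stats <- table(factor(qp$reason,
                        levels = c("accept", "unmapped", "intra", "clipped",
                                   "low_mapq", "duplicate")))
  acc <- qp[qp$reason == "accept", , drop = FALSE]
  cur <- current_paths(doc)
  plen <- stats::setNames(doc$paths$length[match(cur, doc$paths$id)], cur)
  e1 <- assign_end(acc$lpos1, plen[acc$scaf1], params$parts)
  e2 <- assign_end(acc$lpos2, plen[acc$scaf2], params$parts)
  keep <- !is.na(e1) & !is.na(e2)
  acc <- acc[keep, , drop = FALSE]
  e1 <- e1[keep]; e2 <- e2[keep]
  # canonical unordered pair: (id, end) lexicographically smaller first
  k1 <- paste(acc$scaf1, e1, sep = "\x01")
  k2 <- paste(acc$scaf2, e2, sep = "\x01")
  swap <- k2 < k1
  a <- ifelse(swap, k2, k1); b <- ifelse(swap, k1, k2)
  key <- paste(a, b, sep = "\x02")
  tab <- table(key)
  counts <- if (length(tab)) {
    halves <- strsplit(names(tab), "\x02", fixed = TRUE)
    p1 <- strsplit(vapply(halves, `[`, "", 1), "\x01", fixed = TRUE)
    p2 <- strsplit(vapply(halves, `[`, "", 2), "\x01", fixed = TRUE)
    data.frame(id1 = vapply(p1, `[`, "", 1), end1 = vapply(p1, `[`, "", 2),
               id2 = vapply(p2, `[`, "", 1), end2 = vapply(p2, `[`, "", 2),
               count = as.numeric(tab), stringsAsFactors = FALSE)
  } else {
    data.frame(id1 = character(0), end1 = character(0), id2 = character(0),
               end2 = character(0), count = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  structure(list(counts = counts, lengths = plen, parts = params$parts,
                 stats = stats, n_counted = nrow(acc)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d sequences, %d end pairs, %d counted pairs\n",
              length(x$lengths), nrow(x$counts), x$n_counted))
  invisible(x)
}

#' Normalize a contact count by sequence lengths
#'
#' Summation mode divides the count by `l_i/parts + l_j/parts`; multiplication
#' mode divides by `(l_i/parts) * (l_j/parts)`. Real division throughout.
#'
#' @param count raw contact count(s).
#' @param l_i,l_j sequence lengths, bp.
#' @param norm `"summation"` or `"multiplication"`.
#' @param parts 2 or 3.
#' @return normalized contact number(s).
#' @export
normalize_contacts <- function(count, l_i, l_j,
                               norm = c("summation", "multiplication"),
                               parts = 3) {
  norm <- match.arg(norm)
  if (norm == "summation") count / (l_i / parts + l_j / parts)
  else count / ((l_i / parts) * (l_j / parts))
}

#' Select N-best neighbors per sequence end
#'
#' End pairs with raw count below `w` are dropped before ranking. Per end, the
#' remaining partners are ranked by normalized contact descending (ties broken
#' by larger raw count, then lexicographic partner id/end) and the top
#' `nbest` kept.
#'
#' @param cm a `contact_matrix`.
#' @param params from [scaffold_params()].
#' @return object of class `nbest_neighbors`: data.frame `id`, `end`, `nb_id`,
#'   `nb_end`, `count`, `nc`, `rank`, with attributes `ids` (all sequence
#'   ids), `lengths` and `nbest`.
#' @export
n_best_neighbors <- function(cm, params = scaffold_params()) {
  stopifnot(inherits(cm, "contact_matrix"))
  ct <- cm$counts[cm$counts$count >= params$w, , drop = FALSE]
  # both directions of every retained unordered pair
  d <- rbind(
    data.frame(id = ct$id1, end = ct$end1, nb_id = ct$id2, nb_end = ct$end2,
               count = ct$count, stringsAsFactors = FALSE),
    data.frame(id = ct$id2, end = ct$end2, nb_id = ct$id1, nb_end = ct$end1,
               count = ct$count, stringsAsFactors = FALSE))
  d$nc <- normalize_contacts(d$count, cm$lengths[d$id], cm$lengths[d$nb_id],
                             params$norm, cm$parts)
  o <- order(d$id, d$end, -d$nc, -d$count, d$nb_id, d$nb_end)
  d <- d[o, , drop = FALSE]
  grp <- paste(d$id, d$end, sep = "\x01")
  d$rank <- stats::ave(seq_len(nrow(d)), grp, FUN = seq_along)
  d <- d[d$rank <= params$nbest, , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("nbest_neighbors", "data.frame"),
            ids = names(cm$lengths), lengths = cm$lengths,
            nbest = params$nbest)
}
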
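# Independent brute-force references. Deliberately naive, loop-based, and
# structured differently from the package implementation so they can serve
# as oracles.

okey <- function(id, end) paste(id, end, sep = ".")

# plain data.frame view of an nbest_neighbors object for comparisons
strip_nb <- function(x) {
  out <- data.frame(unclass(x)[c("id", "end", "nb_id", "nb_end", "count",
                                 "nc", "rank")], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# mutual-membership edge construction by exhaustive pairwise lookup
oracle_mutual_edges <- function(nb) {
  fwd <- paste(okey(nb$id, nb$end), okey(nb$nb_id, nb$nb_end))
  rows <- list()
  for (i in seq_len(nrow(nb))) {
    back <- paste(okey(nb$nb_id[i], nb$nb_end[i]), okey(nb$id[i], nb$end[i]))
    a <- okey(nb$id[i], nb$end[i]); b <- okey(nb$nb_id[i], nb$nb_end[i])
    if (back %in% fwd && a < b)
      rows[[length(rows) + 1]] <- data.frame(
        id1 = nb$id[i], end1 = nb$end[i], id2 = nb$nb_id[i],
        end2 = nb$nb_end[i], weight = nb$nc[i], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id1 = character(0), end1 = character(0),
                      id2 = character(0), end2 = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$id1, out$end1, out$id2, out$end2), , drop = FALSE]
}

# per-vertex unique-maximum candidate intersection, one vertex at a time
oracle_prune <- function(edges) {
  if (!nrow(edges)) return(edges)
  v1 <- okey(edges$id1, edges$end1); v2 <- okey(edges$id2, edges$end2)
  cand <- list()
  for (v in unique(c(v1, v2))) {
    inc <- which(v1 == v | v2 == v)
    w <- edges$weight[inc]
    cand[[v]] <- if (sum(w == max(w)) == 1L) inc[which.max(w)] else NA_integer_
  }
  keep <- vapply(seq_len(nrow(edges)), function(i)
    identical(cand[[v1[i]]], i) && identical(cand[[v2[i]]], i), logical(1))
  edges[keep, , drop = FALSE]
}

# contig partition via igraph connected components over end vertices
oracle_partition <- function(ids, edges) {
  el <- cbind(okey(ids, "h"), okey(ids, "t"))
  if (nrow(edges))
    el <- rbind(el, cbind(okey(edges$id1, edges$end1),
                          okey(edges$id2, edges$end2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(g)$membership
  parts <- split(ids, memb[okey(ids, "h")])
  unname(lapply(parts, function(x) sort(x)))
}

canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, "", 1))]
}

# full-sort N-best ranking, one end at a time
oracle_nbest <- function(cm, params) {
  rows <- list()
  ct <- cm$counts
  ends <- unique(rbind(data.frame(id = ct$id1, end = ct$end1),
                       data.frame(id = ct$id2, end = ct$end2)))
  for (i in seq_len(nrow(ends))) {
    id <- ends$id[i]; end <- ends$end[i]
    sel1 <- ct$id1 == id & ct$end1 == end
    sel2 <- ct$id2 == id & ct$end2 == end
    part <- rbind(
      data.frame(nb_id = ct$id2[sel1], nb_end = ct$end2[sel1],
                 count = ct$count[sel1], stringsAsFactors = FALSE),
      data.frame(nb_id = ct$id1[sel2], nb_end = ct$end1[sel2],
                 count = ct$count[sel2], stringsAsFactors = FALSE))
    part <- part[part$count >= params$w, , drop = FALSE]
    if (!nrow(part)) next
    part$nc <- if (params$norm == "summation")
      part$count / (cm$lengths[id] / cm$parts + cm$lengths[part$nb_id] / cm$parts)
    else part$count / ((cm$lengths[id] / cm$parts) *
                         (cm$lengths[part$nb_id] / cm$parts))
    part <- part[order(-part$nc, -part$count, part$nb_id, part$nb_end), ,
                 drop = FALSE]
    part <- utils::head(part, params$nbest)
    rows[[length(rows) + 1]] <- data.frame(
      id = id, end = end, nb_id = part$nb_id, nb_end = part$nb_end,
      count = part$count, nc = part$nc, rank = seq_len(nrow(part)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$id, out$end, out$rank), , drop = FALSE]
}

# per-base loop accumulation of closed spans
oracle_coverage <- function(lo, hi, L) {
  cov <- numeric(L)
  for (i in seq_along(lo))
    for (b in lo[i]:hi[i]) cov[b + 1] <- cov[b + 1] + 1
  cov
}

# ---- random instance generators (caller controls the seed) ----

random_contact_matrix <- function(n_contigs = 10, density = 0.3,
                                  max_count = 50) {
  ids <- sprintf("c%02d", seq_len(n_contigs))
  lengths <- stats::setNames(sample(5000:500000, n_contigs, replace = TRUE),
                             ids)
  ends <- expand.grid(id = ids, end = c("h", "t"), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(ends) - 1)) {
    for (j in seq(i + 1, nrow(ends))) {
      if (ends$id[i] == ends$id[j]) next
      if (stats::runif(1) > density) next
      rows[[length(rows) + 1]] <- data.frame(
        id1 = ends$id[i], end1 = ends$end[i],
        id2 = ends$id[j], end2 = ends$end[j],
        count = sample.int(max_count, 1), stringsAsFactors = FALSE)
    }
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(0), end1 = character(0), id2 = character(0),
               end2 = character(0), count = numeric(0), stringsAsFactors = FALSE)
  # canonical order: (id, end) pair with smaller key first
  k1 <- paste(counts$id1, counts$end1, sep = "\x01")
  k2 <- paste(counts$id2, counts$end2, sep = "\x01")
  swap <- k2 < k1
  tmp <- counts[swap, c("id1", "end1")]
  counts[swap, c("id1", "end1")] <- counts[swap, c("id2", "end2")]
  counts[swap, c("id2", "end2")] <- tmp
  structure(list(counts = counts, lengths = lengths, parts = 3,
                 stats = NULL, n_counted = sum(counts$count)),
            class = "contact_matrix")
}

random_nbest <- function(n_contigs = 10, ...) {
  cm <- random_contact_matrix(n_contigs, ...)
  n_best_neighbors(cm, scaffold_params(w = 1))
}

# random graph with max degree 1 per vertex (valid pruned graph)
random_pruned_graph <- function(n_contigs = 10, join_prob = 0.6) {
  ids <- sprintf("c%02d", seq_len(n_contigs))
  ends <- sample(paste(rep(ids, each = 2), c("h", "t"), sep = "\x01"))
  rows <- list()
  i <- 1
  while (i < length(ends)) {
    a <- strsplit(ends[i], "\x01", fixed = TRUE)[[1]]
    b <- strsplit(ends[i + 1], "\x01", fixed = TRUE)[[1]]
    if (a[1] != b[1] && stats::runif(1) < join_prob) {
      sw <- paste(a, collapse = "") > paste(b, collapse = "")
      rows[[length(rows) + 1]] <- data.frame(
        id1 = if (sw) b[1] else a[1], end1 = if (sw) b[2] else a[2],
        id2 = if (sw) a[1] else b[1], end2 = if (sw) a[2] else b[2],
        weight = round(stats::runif(1), 3), stringsAsFactors = FALSE)
      i <- i + 2
    } else i <- i + 1
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id1 = character(0), end1 = character(0), id2 = character(0),
               end2 = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(ids = ids, edges = edges), class = "scaffold_graph")
}

# random valid SAT document (no sequences)
random_sat_doc <- function(n_contigs = 8, gap_len = 200) {
  ids <- sprintf("ctg%02d", seq_len(n_contigs))
  lengths <- stats::setNames(sample(100:10000, n_contigs, replace = TRUE), ids)
  doc <- sat_from_lengths(lengths, gap_len = gap_len)
  # random grouping of contigs into multi-member paths
  groups <- split(sample(ids), sample(seq_len(max(1, n_contigs %/% 3)),
                                      n_contigs, replace = TRUE))
  groups <- Filter(function(g) length(g) > 1, groups)
  paths <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    list(members = data.frame(contig = g,
                              orient = sample(c("+", "-"), length(g),
                                              replace = TRUE),
                              stringsAsFactors = FALSE),
         cyclic = FALSE, weights = round(stats::runif(length(g) - 1), 4))
  })
  singles <- setdiff(ids, unlist(groups))
  paths <- c(paths, lapply(singles, function(s) list(
    members = data.frame(contig = s, orient = "+", stringsAsFactors = FALSE),
    cyclic = FALSE, weights = numeric(0))))
  doc <- compose_scaffolds(doc, paths)
  doc$contigs$tags[1] <- "xx:Z:note"
  doc
}
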
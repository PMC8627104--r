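# The scaffolding graph: an undirected graph whose vertices are the head and
# tail ends of each sequence. An edge exists iff the two ends are mutually
# among each other's N-best neighbors; pruning keeps, per vertex, only an
# incident edge of strictly unique maximum weight, and an edge survives iff
# it is the chosen candidate of both endpoints. After adding the implicit
# head-tail edge of every sequence, each component is a simple path or cycle,
# read out as an ordered, oriented scaffold.

vkey <- function(id, end) paste(id, end, sep = "\x01")

#' Build the scaffolding graph from mutual N-best neighbors
#'
#' An edge `(ia, jb)` is present iff `jb` appears in `ia`'s N-best list and
#' vice versa. Edge weight is the (symmetric) normalized contact number.
#'
#' @param nb `nbest_neighbors` from [n_best_neighbors()].
#' @return object of class `scaffold_graph`: list with `ids` (all sequence
#'   ids) and `edges` (data.frame `id1`, `end1`, `id2`, `end2`, `weight`,
#'   canonically ordered, no parallel edges).
#' @export
build_scaffold_graph <- function(nb) {
  stopifnot(inherits(nb, "nbest_neighbors"))
  fwd <- vkey(nb$id, nb$end)
  rev <- vkey(nb$nb_id, nb$nb_end)
  dir_key <- paste(fwd, rev, sep = "\x02")
  rev_key <- paste(rev, fwd, sep = "\x02")
  mutual <- dir_key %in% rev_key
  e <- nb[mutual, , drop = FALSE]
  keep <- vkey(e$id, e$end) < vkey(e$nb_id, e$nb_end)
  e <- e[keep, , drop = FALSE]
  edges <- data.frame(id1 = e$id, end1 = e$end, id2 = e$nb_id, end2 = e$nb_end,
                      weight = e$nc, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(ids = attr(nb, "ids"), edges = edges),
            class = "scaffold_graph")
}

#' Prune the scaffolding graph to max degree one
#'
#' Each vertex independently nominates its incident edge of strictly unique
#' maximum weight; a tie for the maximum nominates nothing and discards all
#' edges at that vertex. An edge survives iff both endpoints nominated it.
#' Weight equality is exact (no epsilon).
#'
#' @param g a `scaffold_graph`.
#' @return the pruned `scaffold_graph`; every vertex has at most one
#'   inter-sequence edge.
#' @export
prune_scaffold_graph <- function(g) {
  stopifnot(inherits(g, "scaffold_graph"))
  e <- g$edges
  if (!nrow(e)) return(g)
  eid <- seq_len(nrow(e))
  inc <- data.frame(v = c(vkey(e$id1, e$end1), vkey(e$id2, e$end2)),
                    eid = c(eid, eid), w = c(e$weight, e$weight),
                    stringsAsFactors = FALSE)
  cand <- tapply(seq_len(nrow(inc)), inc$v, function(ii) {
    w <- inc$w[ii]
    mx <- max(w)
    if (sum(w == mx) > 1L) NA_integer_ else inc$eid[ii[which.max(w)]]
  })
  nominated <- tabulate(unlist(cand[!is.na(cand)]), nbins = nrow(e))
  g$edges <- e[nominated == 2L, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

# partner lookup: named vector vertex-key -> c(id, end) of the linked vertex
partner_map <- function(edges) {
  k1 <- vkey(edges$id1, edges$end1)
  k2 <- vkey(edges$id2, edges$end2)
  if (anyDuplicated(c(k1, k2)))
    stop("internal error: pruned graph has a vertex with degree > 1")
  m <- c(stats::setNames(k2, k1), stats::setNames(k1, k2))
  w <- c(stats::setNames(edges$weight, k1), stats::setNames(edges$weight, k2))
  list(partner = m, weight = w)
}

#' Extract scaffold paths from a pruned graph
#'
#' Adds the implicit head-tail edge of each sequence and walks components.
#' A sequence traversed head-to-tail is `+`, tail-to-head is `-`. Cycles are
#' broken deterministically: the lexicographically smallest member starts the
#' path at its head vertex and the edge into that head (its predecessor) is
#' dropped. Acyclic paths are emitted with the lexicographically smaller
#' terminal first; isolated sequences become singleton `+` paths.
#'
#' @param g a pruned `scaffold_graph`.
#' @return list of paths, each a list with `members` (data.frame `contig`,
#'   `orient`), `cyclic` (logical) and `weights` (numeric vector of the
#'   junction edge weights, length `nrow(members) - 1`). Ordered by first
#'   member id.
#' @export
extract_scaffold_paths <- function(g) {
  stopifnot(inherits(g, "scaffold_graph"))
  pm <- partner_map(g$edges)
  other_end <- c(h = "t", t = "h")
  # walk away from (id, exit_end) until a free end or back to the start
  walk <- function(id, exit_end) {
    chain_id <- character(0); chain_or <- character(0); wts <- numeric(0)
    cur <- id; ex <- exit_end
    repeat {
      nxt <- pm$partner[vkey(cur, ex)]
      if (is.na(nxt)) return(list(ids = chain_id, ors = chain_or,
                                  wts = wts, cyclic = FALSE))
      wts <- c(wts, unname(pm$weight[vkey(cur, ex)]))
      p <- strsplit(nxt, "\x01", fixed = TRUE)[[1]]
      nid <- p[1]; nend <- p[2]
      if (nid == id) return(list(ids = chain_id, ors = chain_or,
                                 wts = wts, cyclic = TRUE))
      chain_id <- c(chain_id, nid)
      chain_or <- c(chain_or, if (nend == "h") "+" else "-")
      cur <- nid; ex <- other_end[nend]
    }
  }
  visited <- character(0)
  paths <- list()
  for (c0 in sort(g$ids)) {
    if (c0 %in% visited) next
    right <- walk(c0, "t")   # c0 taken as '+'
    if (right$cyclic) {
      # cycle: members are c0 + chain; restart at smallest member's head
      cyc_ids <- c(c0, right$ids)
      start <- sort(cyc_ids)[1]
      r2 <- walk(start, "t")
      ids <- c(start, r2$ids); ors <- c("+", r2$ors); wts <- r2$wts
      # the predecessor edge (into start's head) is dropped: wts has one
      # weight per junction plus the closing edge; drop the closing weight
      wts <- wts[-length(wts)]
      paths[[length(paths) + 1]] <- list(
        members = data.frame(contig = ids, orient = ors,
                             stringsAsFactors = FALSE),
        cyclic = TRUE, weights = wts)
      visited <- c(visited, ids)
      next
    }
    left <- walk(c0, "h")
    ids <- c(rev(left$ids), c0, right$ids)
    ors <- c(rev(chartr("+-", "-+", left$ors)), "+", right$ors)
    wts <- c(rev(left$wts), right$wts)
    if (length(ids) > 1 && ids[length(ids)] < ids[1]) {
      ids <- rev(ids); ors <- rev(chartr("+-", "-+", ors)); wts <- rev(wts)
    }
    paths[[length(paths) + 1]] <- list(
      members = data.frame(contig = ids, orient = ors,
                           stringsAsFactors = FALSE),
      cyclic = FALSE, weights = wts)
    visited <- c(visited, ids)
  }
  firsts <- vapply(paths, function(p) p$members$contig[1], "")
  paths[order(firsts)]
}

next_scaffold_id <- function(doc, n = 1) {
  u <- grep("^u[0-9]{9}$", doc$paths$id, value = TRUE)
  base <- if (length(u)) max(as.integer(substring(u, 2))) else 0L
  sprintf("u%09d", base + seq_len(n))
}

#' Compose a new scaffolding round into the SAT document
#'
#' Graph paths are over the *current scaffolds*; each multi-member graph path
#' concatenates the member scaffolds' contig lists (reversing and flipping
#' `-`-oriented members) into a new path named `u<9-digit counter>`.
#' Singleton graph paths keep their existing path. Junction links (weighted by
#' the surviving edge's normalized contact) are appended and a new assembly
#' set becomes current.
#'
#' @param doc a `sat_document`.
#' @param paths output of [extract_scaffold_paths()] (members are path ids of
#'   `doc`'s current set).
#' @return the updated `sat_document`.
#' @export
compose_scaffolds <- function(doc, paths) {
  multi <- Filter(function(p) nrow(p$members) > 1, paths)
  if (!length(multi)) return(doc)
  new_ids <- next_scaffold_id(doc, length(multi))
  keep_single <- unlist(lapply(Filter(function(p) nrow(p$members) == 1, paths),
                               function(p) p$members$contig))
  new_paths <- list(); new_members <- list(); new_links <- list()
  for (k in seq_along(multi)) {
    gp <- multi[[k]]
    mem <- list()
    for (j in seq_len(nrow(gp$members))) {
      old <- path_members(doc, gp$members$contig[j])
      if (gp$members$orient[j] == "-") {
        old <- old[rev(seq_len(nrow(old))), , drop = FALSE]
        old$orient <- chartr("+-", "-+", old$orient)
      }
      mem[[j]] <- old
    }
    # junction links at the contig level, one per joined pair
    for (j in seq_len(nrow(gp$members) - 1)) {
      lseg <- mem[[j]]; rseg <- mem[[j + 1]]
      new_links[[length(new_links) + 1]] <- data.frame(
        from = lseg$contig[nrow(lseg)], from_orient = lseg$orient[nrow(lseg)],
        to = rseg$contig[1], to_orient = rseg$orient[1],
        weight = gp$weights[j], tags = "", stringsAsFactors = FALSE)
    }
    mem <- do.call(rbind, mem)
    clen <- doc$contigs$length[match(mem$contig, doc$contigs$id)]
    new_paths[[k]] <- data.frame(id = new_ids[k],
                                 length = path_length(clen, doc$gap_len),
                                 tags = if (isTRUE(gp$cyclic)) "cy:i:1" else "",
                                 stringsAsFactors = FALSE)
    new_members[[k]] <- data.frame(path = new_ids[k], ord = seq_len(nrow(mem)),
                                   contig = mem$contig, orient = mem$orient,
                                   stringsAsFactors = FALSE)
  }
  doc$paths <- rbind(doc$paths, do.call(rbind, new_paths))
  doc$members <- rbind(doc$members, do.call(rbind, new_members))
  if (length(new_links))
    doc$links <- rbind(doc$links, do.call(rbind, new_links))
  set_name <- paste0("asm", length(doc$sets) + 1)
  doc$sets[[set_name]] <- sort(c(keep_single, new_ids))
  doc$current <- set_name
  for (f in c("links", "paths", "members")) rownames(doc[[f]]) <- NULL
  validate_sat(doc)
  doc
}
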
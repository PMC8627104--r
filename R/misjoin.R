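# Misjoin detection by physical spanning coverage. Pairs mapping to the same
# contig or to adjacent members of one scaffold increment coverage on the
# closed interval between their lifted 5' positions. A join is broken when
# its maximum coverage is below p% of the maximum of *each* neighboring
# contig — a dip against one side only (e.g. a short or missing sequence)
# is kept, which is what makes the rule robust to scaffold length.

#' Physical spanning coverage per scaffold
#'
#' @param pairs pair data.frame from [read_hic_pairs()].
#' @param doc a `sat_document`.
#' @param q minimum mapping quality (default 10).
#' @return object of class `coverage_profile`: named list of numeric vectors,
#'   one per scaffold of the current set (index i = scaffold base i-1,
#'   gap bases included), with attribute `stats` (filter reason counts).
#' @export
spanning_coverage <- function(pairs, doc, q = 10) {
  qp <- qualify_pairs(pairs, doc, q = q, mode = "spanning")
  acc <- qp[qp$reason == "accept", , drop = FALSE]
  cur <- current_paths(doc)
  plen <- stats::setNames(doc$paths$length[match(cur, doc$paths$id)], cur)
  lo <- pmin(acc$lpos1, acc$lpos2)
  hi <- pmax(acc$lpos1, acc$lpos2)
  prof <- lapply(cur, function(p) {
    L <- plen[[p]]
    sel <- acc$scaf1 == p
    # difference array over the closed span [lo, hi]
    delta <- numeric(L + 1)
    if (any(sel)) {
      add <- tabulate(lo[sel] + 1, nbins = L + 1)
      rem <- tabulate(hi[sel] + 2, nbins = L + 1)
      delta <- add - rem
    }
    cumsum(delta)[seq_len(L)]
  })
  structure(stats::setNames(prof, cur), class = "coverage_profile",
            stats = table(factor(qp$reason,
                                 levels = c("accept", "unmapped", "clipped",
                                            "low_mapq", "duplicate",
                                            "non_adjacent"))))
}

#' Maximum spanning coverage per contig and per join
#'
#' The join region between members j and j+1 is the gap interval plus one
#' flanking base on each side (for zero-length gaps, the two boundary bases).
#'
#' @param profile a `coverage_profile`.
#' @param doc the `sat_document` the profile was computed against.
#' @return list with `contig_max` (data.frame `path`, `ord`, `contig`, `max`)
#'   and `join_max` (data.frame `path`, `join`, `join_max`, `left_max`,
#'   `right_max`; join j sits between members j and j+1).
#' @export
collect_maxima <- function(profile, doc) {
  lt <- lift_table(doc)
  cmax <- data.frame(path = lt$path, ord = lt$ord, contig = lt$contig,
                     max = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lt))) {
    cov <- profile[[lt$path[i]]]
    span <- seq.int(lt$offset[i] + 1, lt$offset[i] + lt$clen[i])
    cmax$max[i] <- max(cov[span])
  }
  jrows <- list()
  for (p in names(profile)) {
    sub <- lt[lt$path == p, , drop = FALSE]
    sub <- sub[order(sub$ord), , drop = FALSE]
    if (nrow(sub) < 2) next
    cov <- profile[[p]]
    for (j in seq_len(nrow(sub) - 1)) {
      gap_start <- sub$offset[j] + sub$clen[j]        # 0-based
      gap_end <- sub$offset[j + 1]                    # exclusive
      region <- seq.int(gap_start - 1, gap_end)       # +1 flank each side
      region <- region[region >= 0 & region < length(cov)] + 1
      jrows[[length(jrows) + 1]] <- data.frame(
        path = p, join = j, join_max = max(cov[region]),
        left_max = cmax$max[cmax$path == p & cmax$ord == j],
        right_max = cmax$max[cmax$path == p & cmax$ord == j + 1],
        stringsAsFactors = FALSE)
    }
  }
  jmax <- if (length(jrows)) do.call(rbind, jrows) else
    data.frame(path = character(0), join = integer(0), join_max = numeric(0),
               left_max = numeric(0), right_max = numeric(0),
               stringsAsFactors = FALSE)
  list(contig_max = cmax, join_max = jmax)
}

#' Decide which joins to break
#'
#' A join is broken iff its maximum spanning coverage is strictly less than
#' `p`% of the maximum of the left neighbor AND of the right neighbor.
#'
#' @param maxima output of [collect_maxima()].
#' @param p break threshold in percent (default 30).
#' @return data.frame of break decisions: `path`, `join`, `join_max`,
#'   `left_max`, `right_max`, `broken`.
#' @export
detect_breaks <- function(maxima, p = 30) {
  j <- maxima$join_max
  j$broken <- j$join_max < (p / 100) * j$left_max &
    j$join_max < (p / 100) * j$right_max
  j
}

#' Apply break decisions to a SAT document
#'
#' Each path with m broken joins is split into m+1 sub-paths preserving
#' member order and orientation; sub-paths get fresh `u`-numbered ids (a path
#' with no breaks is untouched). The contig set is unchanged. A new assembly
#' set holding the post-break paths becomes current, and links at broken
#' junctions are removed.
#'
#' @param doc a `sat_document`.
#' @param decisions data.frame from [detect_breaks()].
#' @return the corrected `sat_document`.
#' @export
apply_breaks <- function(doc, decisions) {
  br <- decisions[decisions$broken, , drop = FALSE]
  if (!nrow(br)) return(doc)
  cur <- current_paths(doc)
  new_set <- character(0)
  n_new <- 0L
  pieces_all <- list()
  for (p in cur) {
    joins <- sort(br$join[br$path == p])
    if (!length(joins)) { new_set <- c(new_set, p); next }
    m <- path_members(doc, p)
    piece_id <- cumsum(c(1, seq_len(nrow(m) - 1) %in% joins))
    for (k in unique(piece_id)) {
      pc <- m[piece_id == k, , drop = FALSE]
      n_new <- n_new + 1L
      pieces_all[[n_new]] <- list(path = p, join_left = joins, members = pc)
    }
    # drop links at the broken junctions
    for (j in joins) {
      lft <- m[j, ]; rgt <- m[j + 1, ]
      drop <- (doc$links$from == lft$contig & doc$links$to == rgt$contig &
                 doc$links$from_orient == lft$orient &
                 doc$links$to_orient == rgt$orient) |
        (doc$links$from == rgt$contig & doc$links$to == lft$contig &
           doc$links$from_orient == chartr("+-", "-+", rgt$orient) &
           doc$links$to_orient == chartr("+-", "-+", lft$orient))
      doc$links <- doc$links[!drop, , drop = FALSE]
    }
  }
  if (n_new) {
    ids <- next_scaffold_id(doc, n_new)
    for (k in seq_len(n_new)) {
      pc <- pieces_all[[k]]$members
      clen <- doc$contigs$length[match(pc$contig, doc$contigs$id)]
      doc$paths <- rbind(doc$paths, data.frame(
        id = ids[k], length = path_length(clen, doc$gap_len), tags = "",
        stringsAsFactors = FALSE))
      doc$members <- rbind(doc$members, data.frame(
        path = ids[k], ord = seq_len(nrow(pc)), contig = pc$contig,
        orient = pc$orient, stringsAsFactors = FALSE))
      new_set <- c(new_set, ids[k])
    }
  }
  set_name <- paste0("asm", length(doc$sets) + 1)
  doc$sets[[set_name]] <- sort(new_set)
  doc$current <- set_name
  for (f in c("links", "paths", "members")) rownames(doc[[f]]) <- NULL
  validate_sat(doc)
  doc
}
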
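# Walk enumeration and joint decomposition: reconstructing alleles as
# paths/cycles through a balanced genome graph whose copy-weighted
# element counts sum to kappa.

walk_key <- function(vids, uids) paste(paste(vids, collapse = "."),
                                       paste(uids, collapse = "."), sep = "|")

# canonical orientation: lexicographically smaller serialized key of the
# walk vs its reverse complement (cycles: minimal rotation first)
canonical_path <- function(vids, uids, end_uids) {
  rc_v <- rev(rc_vid(vids))
  rc_u <- rev(uids)
  rc_e <- rev(end_uids)
  k1 <- walk_key(vids, c(end_uids[1], uids, end_uids[2]))
  k2 <- walk_key(rc_v, c(rc_e[1], rc_u, rc_e[2]))
  if (k2 < k1) list(vids = rc_v, uids = rc_u, end_uids = rc_e, key = k2)
  else list(vids = vids, uids = uids, end_uids = end_uids, key = k1)
}

canonical_cycle <- function(vids, uids) {
  m <- length(vids)
  rot <- function(v, u, r) {
    if (r == 0) list(v = v, u = u)
    else list(v = c(v[(r + 1):m], v[1:r]), u = c(u[(r + 1):m], u[1:r]))
  }
  best <- NULL
  for (orient in 1:2) {
    if (orient == 2) {
      # reverse complement of a cycle: reverse vertices, shift edges
      vids <- rev(rc_vid(vids))
      uids <- rev(c(uids[m], uids[-m]))
    }
    for (r in 0:(m - 1)) {
      ru <- rot(vids, uids, r)
      k <- walk_key(ru$v, ru$u)
      if (is.null(best) || k < best$key)
        best <- list(vids = ru$v, uids = ru$u, key = k)
    }
  }
  best
}

#' Enumerate the minimal walks of a balanced genome graph
#'
#' Exhaustively traverses the subgraph of vertices and edges with
#' nonzero copy number, returning every vertex-simple path between end
#' sides (nonzero loose edges or chromosome termini) and every
#' vertex-simple cycle, in canonical orientation and deduplicated.
#' "Vertex-simple" means no oriented vertex is revisited; alleles that
#' revisit a segment in the same orientation (deep BFB stages) are
#' reached by splicing cycles into paths with [combine_walks()].
#'
#' @param g a `genome_graph`.
#' @param kappa a `copy_assignment` satisfying junction balance.
#' @param max_walks abort (with an error suggesting region restriction)
#'   if more walks than this are found.
#' @return a `walk_set`: list with `walks` (each a list with `vids`,
#'   `uids`, `end_uids`, `closed`, `key`) and the generating graph.
#' @export
enumerate_minimal_walks <- function(g, kappa, max_walks = 10000) {
  v_cn <- setNames(kappa$vertex$cn, kappa$vertex$seg_id)
  e_cn <- setNames(kappa$edge$cn, kappa$edge$uid)
  ed <- g$edges
  live_uid <- as.integer(names(e_cn)[e_cn > 0])
  live_seg <- as.integer(names(v_cn)[v_cn > 0])
  # adjacency over signed vertices via live non-loose records
  rec <- ed[!is.na(ed$from_vid) & !is.na(ed$to_vid) & ed$uid %in% live_uid, ]
  rec <- rec[seg_of_vid(rec$from_vid) %in% live_seg &
             seg_of_vid(rec$to_vid) %in% live_seg, ]
  # drop parallel fold-back records (same uid, same endpoints)
  rec <- rec %>% distinct(.data$uid, .data$from_vid, .data$to_vid)
  adj <- split(rec[, c("to_vid", "uid")], rec$from_vid)

  loose <- ed[ed$kind == "loose" & !is.na(ed$from_vid) & ed$uid %in% live_uid, ]
  # vids whose head side carries a live loose end / terminus
  term_head <- c(
    loose$from_vid,
    ifelse(g$termini$side == "R", vid_of(g$termini$seg_id, TRUE),
           vid_of(g$termini$seg_id, FALSE)))
  term_head <- unique(term_head[seg_of_vid(term_head) %in% live_seg])
  head_loose_uid <- setNames(loose$uid, loose$from_vid)  # NA if terminus

  walks <- list()
  keys <- character(0)
  add_walk <- function(w) {
    if (w$key %in% keys) return(invisible(NULL))
    keys <<- c(keys, w$key)
    walks[[length(walks) + 1L]] <<- w
    if (length(walks) > max_walks)
      abort(sprintf(
        "walk enumeration exceeded max_walks = %d; raise the cap or restrict the region",
        max_walks))
  }

  # paths: start at the reverse complement of an end head
  starts <- sort(unique(rc_vid(term_head)))
  for (v0 in starts) {
    stack <- list(list(vids = v0, uids = integer(0)))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- cur$vids[length(cur$vids)]
      if (v %in% term_head) {
        lo1 <- head_loose_uid[as.character(rc_vid(cur$vids[1]))]
        lo2 <- head_loose_uid[as.character(v)]
        cp <- canonical_path(cur$vids, cur$uids,
                             c(ifelse(is.na(lo1), 0L, lo1), ifelse(is.na(lo2), 0L, lo2)))
        cp$closed <- FALSE
        add_walk(cp)
      }
      nxt <- adj[[as.character(v)]]
      if (is.null(nxt)) next
      for (k in seq_len(nrow(nxt))) {
        w <- nxt$to_vid[k]
        if (w %in% cur$vids) next  # vertex-simple
        stack[[length(stack) + 1L]] <-
          list(vids = c(cur$vids, w), uids = c(cur$uids, nxt$uid[k]))
      }
    }
  }

  # cycles: minimal vid is the anchor; never visit a smaller vid
  all_vids <- sort(unique(c(rec$from_vid, rec$to_vid)))
  for (v0 in all_vids) {
    stack <- list(list(vids = v0, uids = integer(0)))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- cur$vids[length(cur$vids)]
      nxt <- adj[[as.character(v)]]
      if (is.null(nxt)) next
      for (k in seq_len(nrow(nxt))) {
        w <- nxt$to_vid[k]
        if (w == v0 && length(cur$vids) >= 1) {
          cc <- canonical_cycle(cur$vids, c(cur$uids, nxt$uid[k]))
          cc$closed <- TRUE
          cc$end_uids <- c(0L, 0L)
          add_walk(cc)
          next
        }
        if (w <= v0 || w %in% cur$vids) next
        stack[[length(stack) + 1L]] <-
          list(vids = c(cur$vids, w), uids = c(cur$uids, nxt$uid[k]))
      }
    }
  }

  structure(list(walks = walks, graph = g), class = "walk_set")
}

#' @export
print.walk_set <- function(x, ...) {
  ncl <- sum(vapply(x$walks, `[[`, TRUE, "closed"))
  cat(sprintf("<walk_set> %d walk(s): %d path(s), %d cycle(s)\n",
              length(x$walks), length(x$walks) - ncl, ncl))
  invisible(x)
}

# multiplicity of unsigned segments and edges in a walk
walk_deltas <- function(w) {
  segs <- table(seg_of_vid(w$vids))
  uids <- table(c(w$uids, w$end_uids[w$end_uids > 0]))
  list(seg = segs, uid = uids)
}

#' Jointly decompose balanced clone graphs into walk copy numbers
#'
#' Solves the joint integer program that assigns a nonnegative copy
#' number to every enumerated walk of every clone such that, for each
#' clone, copy-weighted walk membership sums to the clone's vertex and
#' edge copy numbers, while minimizing the number of unique walks used
#' across the compendium (walks are identified across clones by their
#' projected element sequence on the shared prototype).
#'
#' @param comp a `graph_compendium` (or a single `genome_graph` for the
#'   one-clone case).
#' @param assignments named list of per-clone `copy_assignment`s.
#' @param walk_sets named list of per-clone `walk_set`s (defaults to
#'   enumerating from each assignment).
#' @param node_limit branch-and-bound node budget.
#' @return a `walk_decomposition`: tibble `clone`, `walk_id`, `proto_id`,
#'   `phi`, plus the walk sets and the objective (number of unique walks).
#' @export
decompose_joint <- function(comp, assignments, walk_sets = NULL,
                            node_limit = 200000L) {
  g <- if (inherits(comp, "genome_graph")) comp else comp$prototype
  clones <- names(assignments)
  if (is.null(walk_sets))
    walk_sets <- lapply(assignments, function(k) enumerate_minimal_walks(g, k))

  # prototype walk ids: shared canonical keys
  all_keys <- unique(unlist(lapply(walk_sets, function(ws)
    vapply(ws$walks, `[[`, "", "key"))))
  proto_id <- setNames(seq_along(all_keys), all_keys)

  cols <- list()   # one per (clone, walk)
  for (cl in clones) {
    ws <- walk_sets[[cl]]
    for (j in seq_along(ws$walks)) {
      w <- ws$walks[[j]]
      cols[[length(cols) + 1L]] <- list(clone = cl, walk_id = j,
                                        proto = proto_id[[w$key]],
                                        delta = walk_deltas(w))
    }
  }
  n_phi <- length(cols)
  n_y <- length(all_keys)
  if (n_phi == 0) abort("no walks to decompose")

  # rows: per clone, one per nonzero-kappa segment and edge
  row_defs <- list()
  for (cl in clones) {
    k <- assignments[[cl]]
    for (s in k$vertex$seg_id[k$vertex$cn > 0])
      row_defs[[length(row_defs) + 1L]] <- list(clone = cl, type = "seg",
                                                id = s, rhs = k$vertex$cn[k$vertex$seg_id == s])
    for (u in k$edge$uid[k$edge$cn > 0])
      row_defs[[length(row_defs) + 1L]] <- list(clone = cl, type = "uid",
                                                id = u, rhs = k$edge$cn[k$edge$uid == u])
  }
  m0 <- length(row_defs)
  maxk <- max(vapply(assignments, function(k) max(c(k$vertex$cn, 1)), 0))
  bigM <- maxk * length(clones) + 1

  nvar <- n_phi + n_y + n_y          # phi | y | slack for linking rows
  A <- matrix(0, m0 + n_y, nvar)
  rhs <- numeric(m0 + n_y)
  for (r in seq_len(m0)) {
    rd <- row_defs[[r]]
    rhs[r] <- rd$rhs
    for (j in seq_len(n_phi)) {
      co <- cols[[j]]
      if (co$clone != rd$clone) next
      d <- co$delta[[if (rd$type == "seg") "seg" else "uid"]]
      val <- d[as.character(rd$id)]
      if (!is.na(val)) A[r, j] <- as.numeric(val)
    }
  }
  for (w in seq_len(n_y)) {
    r <- m0 + w
    for (j in seq_len(n_phi)) if (cols[[j]]$proto == w) A[r, j] <- 1
    A[r, n_phi + w] <- -bigM
    A[r, n_phi + n_y + w] <- 1
    rhs[r] <- 0
  }
  obj <- c(rep(0, n_phi), rep(1, n_y), rep(0, n_y))
  lb <- rep(0, nvar)
  ub <- c(rep(maxk, n_phi), rep(1, n_y), rep(bigM, n_y))
  sol <- cg_milp(obj, A, rhs, lb, ub, int_idx = seq_len(n_phi + n_y),
                 node_limit = node_limit)
  if (sol$status != "optimal") {
    uncovered <- purrr::map(clones, function(cl) {
      k <- assignments[[cl]]
      segs <- k$vertex$seg_id[k$vertex$cn > 0]
      covered <- unique(unlist(lapply(walk_sets[[cl]]$walks, function(w)
        seg_of_vid(w$vids))))
      tibble(clone = cl, seg_id = setdiff(segs, covered))
    }) %>% bind_rows()
    return(structure(list(status = sol$status, uncovered = uncovered),
                     class = "walk_decomposition"))
  }
  phi <- purrr::imap(cols, function(co, j)
    tibble(clone = co$clone, walk_id = co$walk_id, proto_id = unname(co$proto),
           phi = round(sol$x[j]))) %>% bind_rows()
  structure(list(
    status = "optimal", phi = phi, walk_sets = walk_sets,
    objective = round(sol$objval),
    n_unique_walks = round(sol$objval)
  ), class = "walk_decomposition")
}

#' @export
print.walk_decomposition <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    cat(sprintf("<walk_decomposition> %s\n", x$status))
    if (!is.null(x$uncovered) && nrow(x$uncovered))
      cat("  segments not covered by any enumerated walk:",
          paste(unique(x$uncovered$seg_id), collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("<walk_decomposition> %d unique walk(s) across %d clone(s)\n",
              x$n_unique_walks, length(unique(x$phi$clone))))
  invisible(x)
}

#' @method tidy walk_decomposition
#' @export
tidy.walk_decomposition <- function(x, ...) x$phi

#' Verify walk-copy conservation against a copy assignment
#'
#' Checks that copy-weighted walk membership reproduces every vertex and
#' edge copy number of a clone exactly.
#'
#' @param ws a `walk_set`.
#' @param phi tibble `walk_id`,`phi` for this clone.
#' @param kappa the clone's `copy_assignment`.
#' @return maximum absolute discrepancy (0 on exact conservation).
#' @export
walk_conservation_gap <- function(ws, phi, kappa) {
  seg_sum <- setNames(rep(0, nrow(kappa$vertex)), kappa$vertex$seg_id)
  uid_sum <- setNames(rep(0, nrow(kappa$edge)), kappa$edge$uid)
  for (i in seq_len(nrow(phi))) {
    w <- ws$walks[[phi$walk_id[i]]]
    d <- walk_deltas(w)
    seg_sum[names(d$seg)] <- seg_sum[names(d$seg)] + phi$phi[i] * as.numeric(d$seg)
    uid_sum[names(d$uid)] <- uid_sum[names(d$uid)] + phi$phi[i] * as.numeric(d$uid)
  }
  max(abs(c(seg_sum - kappa$vertex$cn, uid_sum - kappa$edge$cn)))
}

#' Splice cycles into paths to build linear somatic haplotypes
#'
#' Reproducibly applies the manual walk-combination step: each merge
#' splices one copy of a cycle into a path at a shared anchor vertex
#' (entering the cycle at the anchor, traversing it once, and resuming
#' the path), decrementing the cycle's copy bookkeeping.
#'
#' @param ws a `walk_set`.
#' @param phi tibble `walk_id`,`phi` (copy numbers for this clone).
#' @param merges tibble `cycle`,`path`,`anchor_seg`: walk ids and the
#'   anchoring segment; applied in order, `path` may reference the result
#'   of an earlier merge (its original path id).
#' @return list with `haplotypes` (list of walks) and `phi_left`
#'   (remaining copies).
#' @export
combine_walks <- function(ws, phi, merges = NULL) {
  paths <- list()
  phi_left <- setNames(phi$phi, phi$walk_id)
  for (i in seq_len(nrow(phi))) {
    w <- ws$walks[[phi$walk_id[i]]]
    if (!w$closed && phi$phi[i] > 0) paths[[as.character(phi$walk_id[i])]] <- w
  }
  if (is.null(merges) || nrow(merges) == 0)
    return(list(haplotypes = unname(paths), phi_left = phi_left))
  for (i in seq_len(nrow(merges))) {
    cyc_id <- as.character(merges$cycle[i])
    path_id <- as.character(merges$path[i])
    anchor <- merges$anchor_seg[i]
    cyc <- ws$walks[[as.integer(cyc_id)]]
    if (is.null(cyc) || !cyc$closed) abort(sprintf("merge %d: cycle id %s is not a cycle", i, cyc_id))
    pth <- paths[[path_id]]
    if (is.null(pth)) abort(sprintf("merge %d: unknown path id %s", i, path_id))
    if (phi_left[cyc_id] < 1) abort(sprintf("merge %d: no copies of cycle %s left", i, cyc_id))
    pos <- which(seg_of_vid(pth$vids) == anchor)
    if (length(pos) == 0) abort(sprintf("merge %d: anchor segment %d not on path", i, anchor))
    # orient the cycle to pass through the path's anchor vertex
    hit <- NULL
    for (orient in 1:2) {
      cv <- cyc$vids; cu <- cyc$uids
      if (orient == 2) { cv <- rev(rc_vid(cv)); cu <- rev(c(cu[length(cu)], cu[-length(cu)])) }
      for (p in pos) {
        j <- which(cv == pth$vids[p])
        if (length(j) == 1) { hit <- list(cv = cv, cu = cu, j = j, p = p); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) abort(sprintf("merge %d: anchor vertex not shared between cycle and path", i))
    m <- length(hit$cv)
    rot <- (hit$j - 1 + seq_len(m) - 1) %% m + 1   # anchor, then around the cycle
    ins_v <- hit$cv[rot[-1]]
    ins_u <- hit$cu[rot]
    p <- hit$p
    new_vids <- c(pth$vids[seq_len(p)], ins_v, pth$vids[p],
                  if (p < length(pth$vids)) pth$vids[(p + 1):length(pth$vids)])
    new_uids <- c(pth$uids[seq_len(p - 1)], ins_u, if (p <= length(pth$uids)) pth$uids[p:length(pth$uids)])
    paths[[path_id]] <- list(vids = new_vids, uids = new_uids,
                             end_uids = pth$end_uids, closed = FALSE,
                             key = walk_key(new_vids, new_uids))
    phi_left[cyc_id] <- phi_left[cyc_id] - 1
  }
  list(haplotypes = unname(paths), phi_left = phi_left)
}

#' Convert a walk to oriented genomic intervals
#'
#' Maps a walk's oriented vertices back to `chrom,start,end,strand` rows,
#' merging runs that are reference-contiguous, so walks can be compared
#' to allele interval walks directly.
#'
#' @param g the `genome_graph` the walk lives in.
#' @param w a walk (list with `vids`).
#' @return a walk tibble as used by the simulator.
#' @export
walk_as_intervals <- function(g, w) {
  segs <- g$segments
  rows <- lapply(w$vids, function(v) {
    s <- segs[segs$seg_id == seg_of_vid(v), ]
    tibble(chrom = s$chrom, start = s$start, end = s$end,
           strand = ifelse(is_fwd_vid(v), "+", "-"))
  }) %>% bind_rows()
  # merge reference-adjacent runs
  out <- list()
  cur <- rows[1, ]
  for (i in seq_len(nrow(rows))[-1]) {
    r <- rows[i, ]
    if (r$chrom == cur$chrom && r$strand == cur$strand &&
        ((r$strand == "+" && cur$end == r$start) ||
         (r$strand == "-" && cur$start == r$end))) {
      if (r$strand == "+") cur$end <- r$end else cur$start <- r$start
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- r
    }
  }
  out[[length(out) + 1L]] <- cur
  bind_rows(out)
}
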
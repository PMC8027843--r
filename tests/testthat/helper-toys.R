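suppressMessages({
  library(dplyr)
  library(tibble)
})

# uniform bins with a per-region constant value
mkbins <- function(chrom, lo, hi, w, vals) {
  st <- seq(lo, hi - w, by = w)
  tibble(chrom = chrom, start = st, end = st + w, value = rep_len(vals, length(st)))
}

piecewise_bins <- function(chrom, bounds, values, w) {
  bind_rows(purrr::map2(seq_along(values), values, function(i, v)
    mkbins(chrom, bounds[i], bounds[i + 1], w, v)))
}

# the three-segment deletion toy: A[0,3k) B[3k,7k) C[7k,10k), del A->C
deletion_toy <- function() {
  del <- tibble(chrom1 = "chr1", pos1 = 3000, strand1 = "+",
                chrom2 = "chr1", pos2 = 7000, strand2 = "-")
  g <- genome_graph(tibble(chrom = "chr1", start = 0, end = 10000), del)
  u <- graph_edges(g, signed = FALSE)
  list(graph = g, junction = del,
       ref_uids = u$uid[u$kind == "reference"],
       var_uid = u$uid[u$kind == "variant"],
       loose_uids = u$uid[u$kind == "loose"])
}

# random small genome graph for property tests
random_toy_graph <- function(n_seg = 3, n_var = 1, chrom_len = 10000) {
  bp <- sort(sample(seq(1000, chrom_len - 1000, by = 1000), n_seg - 1))
  segs <- tibble(chrom = "chr1", start = c(0, bp), end = c(bp, chrom_len))
  bnd_pool <- tibble(pos = rep(bp, 2), strand = rep(c("+", "-"), each = length(bp)))
  jn <- NULL
  if (n_var > 0 && nrow(bnd_pool) > 0) {
    pick <- function() bnd_pool[sample(nrow(bnd_pool), 1), ]
    jn <- bind_rows(lapply(seq_len(n_var), function(i) {
      b1 <- pick(); b2 <- pick()
      tibble(chrom1 = "chr1", pos1 = b1$pos, strand1 = b1$strand,
             chrom2 = "chr1", pos2 = b2$pos, strand2 = b2$strand)
    })) %>% distinct()
  }
  g <- genome_graph(segs, jn)
  attr(g, "toy_segments") <- segs
  attr(g, "toy_junctions") <- jn
  g
}

# exhaustive oracle for the balance programs on tiny graphs.
# Enumerates all edge assignments (non-loose) up to `cap`, and for each
# segment all copy numbers consistent with its side sums, letting loose
# edges absorb any per-side deficit. Returns, per clone, the Pareto set
# of (residual, deficit-side pattern); combine across clones outside.
oracle_clone_candidates <- function(g, stats, open_uid, cap = 4) {
  uids <- graph_edges(g, signed = FALSE)
  nonloose <- uids[uids$kind != "loose", ]
  loose <- uids[uids$kind == "loose", ]
  ed <- g$edges[!is.na(g$edges$from_vid), ]
  sides <- crisisgraph:::interstitial_sides(g)
  sides$vid <- ifelse(sides$side == "R",
                      crisisgraph:::vid_of(sides$seg_id, TRUE),
                      crisisgraph:::vid_of(sides$seg_id, FALSE))
  # loose uid attached at each side (if any)
  side_loose <- vapply(sides$vid, function(v) {
    u <- ed$uid[ed$from_vid == v & ed$kind == "loose"]
    if (length(u)) u[1] else NA_integer_
  }, 1L)
  # non-loose contribution multiplicity per (side, uid)
  contrib <- lapply(sides$vid, function(v) {
    tab <- table(ed$uid[ed$from_vid == v & ed$kind != "loose"])
    tab
  })
  w <- stats$n_bins[match(g$segments$seg_id, stats$seg_id)]
  xb <- stats$mean_depth[match(g$segments$seg_id, stats$seg_id)]

  grids <- lapply(nonloose$uid, function(u)
    if (isTRUE(open_uid[as.character(u)])) 0:cap else 0L)
  combos <- do.call(expand.grid, grids)
  cands <- list()
  for (r in seq_len(nrow(combos))) {
    ev <- setNames(as.integer(combos[r, ]), nonloose$uid)
    # per-side non-loose sum
    side_sum <- vapply(seq_len(nrow(sides)), function(i) {
      tb <- contrib[[i]]
      sum(as.integer(tb) * ev[names(tb)])
    }, 0)
    # per segment: kappa >= max of its side sums; deficits = kappa - sum
    per_seg <- vector("list", nrow(g$segments))
    feasible <- TRUE
    for (s in seq_len(nrow(g$segments))) {
      si <- which(sides$seg_id == g$segments$seg_id[s])
      lo_k <- if (length(si)) max(side_sum[si]) else 0
      if (lo_k > cap) { feasible <- FALSE; break }
      opts <- lapply(lo_k:cap, function(k) {
        defic <- si[side_sum[si] < k]
        # a deficit side without a loose edge is infeasible
        if (any(is.na(side_loose[defic]))) return(NULL)
        list(res = w[s] * (xb[s] - k)^2,
             pattern = sort(side_loose[defic]),
             copies = sum(k - side_sum[defic]))
      })
      opts <- purrr::compact(opts)
      if (length(opts) == 0) { feasible <- FALSE; break }
      per_seg[[s]] <- opts
    }
    if (!feasible) next
    # combine segments (patterns are disjoint across segments)
    acc <- list(list(res = 0, pattern = integer(0), copies = 0))
    for (s in seq_along(per_seg)) {
      acc <- purrr::flatten(lapply(acc, function(a)
        lapply(per_seg[[s]], function(o)
          list(res = a$res + o$res, pattern = sort(c(a$pattern, o$pattern)),
               copies = a$copies + o$copies))))
    }
    cands <- c(cands, acc)
  }
  # keep the best residual/copies per pattern
  keys <- vapply(cands, function(a) paste(a$pattern, collapse = ","), "")
  best <- list()
  for (i in seq_along(cands)) {
    k <- keys[i]
    if (is.null(best[[k]]) || cands[[i]]$res < best[[k]]$res - 1e-12 ||
        (abs(cands[[i]]$res - best[[k]]$res) < 1e-12 &&
         cands[[i]]$copies < best[[k]]$copies))
      best[[k]] <- cands[[i]]
  }
  unname(best)
}

# oracle optimum of the joint program: minimize lambda*|union pattern| +
# sum residuals over per-clone candidate choices
oracle_joint_objective <- function(g, stats_list, open_list, lambda, cap = 4) {
  cand <- purrr::map2(stats_list, open_list, function(st, op)
    oracle_clone_candidates(g, st, op, cap))
  best <- Inf
  rec <- function(i, res, pat) {
    if (res + lambda * length(pat) >= best) return(invisible(NULL))
    if (i > length(cand)) { best <<- min(best, res + lambda * length(pat)); return(invisible(NULL)) }
    for (a in cand[[i]]) rec(i + 1, res + a$res, union(pat, a$pattern))
  }
  rec(1, 0, integer(0))
  best
}

# oracle optimum of the single-sample program: residual + slack * copies
oracle_single_objective <- function(g, stats, open_uid, slack, cap = 4) {
  cand <- oracle_clone_candidates(g, stats, open_uid, cap)
  min(vapply(cand, function(a) a$res + slack * a$copies, 0))
}
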
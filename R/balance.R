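#' Balance configuration
#'
#' Parameters of the junction-balance programs. `lambda` weighs the joint
#' complexity penalty (count of unique prototype loose ends with nonzero
#' copy across the compendium); `slack_penalty` is the per-copy loose-end
#' weight used by the single-sample fit; `cn_cap` bounds every copy
#' number (chosen from the data when `NULL`).
#'
#' @param lambda joint loose-end penalty (default 100).
#' @param slack_penalty single-sample per-copy loose penalty (default 500;
#'   100 is the documented alternative for less clonal material).
#' @param cn_cap integer copy-number cap, or `NULL` to derive
#'   `max(ceiling(bin means)) + 2` from the data.
#' @param min_support minimum junction read support for an edge to stay
#'   open (used by [derive_edge_bounds()]).
#' @param node_limit branch-and-bound node budget per inner program.
#' @param outer_node_limit node budget for the joint search over prototype
#'   loose ends. On clean instances the search proves optimality well
#'   within it; when noise makes many near-tied alternatives, the search
#'   stops at the budget and returns the incumbent flagged `"feasible"`.
#'   A node budget (rather than wall time) keeps results deterministic.
#' @param seed integer seed recorded with solutions (the solver itself is
#'   deterministic).
#' @return a `balance_config` list.
#' @export
balance_config <- function(lambda = 100, slack_penalty = 500, cn_cap = NULL,
                           min_support = 1, node_limit = 200000L,
                           outer_node_limit = 200L, seed = 1L) {
  stopifnot(lambda >= 0, slack_penalty >= 0)
  structure(list(lambda = lambda, slack_penalty = slack_penalty,
                 cn_cap = cn_cap, min_support = min_support,
                 node_limit = as.integer(node_limit),
                 outer_node_limit = as.integer(outer_node_limit),
                 seed = as.integer(seed)),
            class = "balance_config")
}

# ---- depth profiles ------------------------------------------------------

#' Map depth bins onto graph segments
#'
#' Assigns each bin to the segment containing its midpoint and summarises
#' per-segment mean depth and bin count (the weights of the read-depth
#' residual).
#'
#' @param g a `genome_graph`.
#' @param bins tibble with `chrom`, `start`, `end`, `value` (depth in
#'   copy-number units).
#' @return tibble with one row per segment: `seg_id`, `n_bins`, `mean_depth`.
#' @export
map_bins_to_segments <- function(g, bins) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(bins)))
  if (any(!is.finite(bins$value)) || any(bins$value < 0))
    abort("bin values must be finite and nonnegative")
  mid <- (bins$start + bins$end) / 2
  gr_bins <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(floor(mid) + 1, floor(mid) + 1))
  gr_seg <- GenomicRanges::GRanges(g$segments$chrom,
                                   IRanges::IRanges(g$segments$start + 1, g$segments$end))
  hit <- GenomicRanges::findOverlaps(gr_bins, gr_seg, select = "first")
  tibble(seg_id = g$segments$seg_id) %>%
    left_join(
      tibble(seg_id = g$segments$seg_id[hit[!is.na(hit)]],
             value = bins$value[!is.na(hit)]) %>%
        group_by(.data$seg_id) %>%
        summarise(n_bins = n(), mean_depth = mean(.data$value), .groups = "drop"),
      by = "seg_id") %>%
    mutate(n_bins = if_else(is.na(.data$n_bins), 0L, .data$n_bins),
           mean_depth = if_else(is.na(.data$mean_depth), 0, .data$mean_depth))
}

#' Read-depth residual of a copy assignment
#'
#' The bin-count-weighted squared error between per-segment mean depth
#' and assigned integer copy number: sum over segments of
#' `n_bins * (mean_depth - cn)^2`. Segments with no mapped bins
#' contribute zero and are reported in the `"unmapped"` attribute.
#'
#' @param g a `genome_graph`.
#' @param kappa a `copy_assignment`.
#' @param bins depth bins (see [map_bins_to_segments()]), or a
#'   precomputed per-segment stats table from that function.
#' @return nonnegative residual, with attribute `unmapped` listing
#'   segments without bins.
#' @export
depth_residual <- function(g, kappa, bins) {
  stats <- if (all(c("seg_id", "n_bins", "mean_depth") %in% names(bins))) bins
           else map_bins_to_segments(g, bins)
  stats <- left_join(stats, kappa$vertex, by = "seg_id")
  res <- sum(stats$n_bins * (stats$mean_depth - stats$cn)^2)
  attr(res, "unmapped") <- stats$seg_id[stats$n_bins == 0L]
  res
}

# ---- edge bounds ---------------------------------------------------------

#' Derive per-clone edge upper bounds from junction read support
#'
#' Variant edges are open (unbounded) in a clone iff their supporting
#' read-pair count reaches `min_support`; reference and loose edges are
#' always open.
#'
#' @param comp a `graph_compendium`.
#' @param support tibble `clone`, `uid`, `support` (defaults to the
#'   compendium's recorded junction support).
#' @param min_support minimum count for an open edge.
#' @return tibble `clone`, `uid`, `open` (logical) covering every variant
#'   edge of every clone.
#' @export
derive_edge_bounds <- function(comp, support = NULL, min_support = 1) {
  if (is.null(support)) support <- comp$junction_support
  stopifnot(all(c("clone", "uid", "support") %in% names(support)))
  if (any(support$support < 0)) abort("support counts must be nonnegative")
  var_uids <- unique(comp$prototype$edges$uid[comp$prototype$edges$kind == "variant"])
  if (nrow(support) > 0 && !all(support$uid %in% var_uids))
    abort("support refers to a junction absent from the compendium")
  tidyr::expand_grid(clone = comp$clone_ids, uid = var_uids) %>%
    left_join(support, by = c("clone", "uid")) %>%
    mutate(support = if_else(is.na(.data$support), 0, .data$support),
           open = .data$support >= min_support) %>%
    select("clone", "uid", "open")
}

# ---- MILP assembly -------------------------------------------------------

# Precompute the structural pieces of one clone's balance program.
clone_program_frame <- function(g, cap) {
  segs <- g$segments
  uids <- graph_edges(g, signed = FALSE)
  n_s <- nrow(segs); n_e <- nrow(uids)
  # incidence: for each interstitial side, counts of each uid leaving it
  sides <- interstitial_sides(g)
  ed <- g$edges[!is.na(g$edges$from_vid), ]
  side_rows <- vector("list", nrow(sides))
  for (i in seq_len(nrow(sides))) {
    v <- if (sides$side[i] == "R") vid_of(sides$seg_id[i], TRUE)
         else vid_of(sides$seg_id[i], FALSE)
    cnt <- table(ed$uid[ed$from_vid == v])
    side_rows[[i]] <- list(seg = sides$seg_id[i],
                           uid = as.integer(names(cnt)), mult = as.integer(cnt))
  }
  # loose uid attached at each side (every interstitial side has one)
  loose_rec <- ed[ed$kind == "loose", ]
  side_loose <- vapply(seq_len(nrow(sides)), function(i) {
    v <- if (sides$side[i] == "R") vid_of(sides$seg_id[i], TRUE)
         else vid_of(sides$seg_id[i], FALSE)
    u <- loose_rec$uid[loose_rec$from_vid == v]
    if (length(u)) u[1] else NA_integer_
  }, 1L)

  # variable layout: kappa_v | kappa_e | y (n_s * cap)
  n_y <- n_s * cap
  nvar <- n_s + n_e + n_y
  m <- length(side_rows) + n_s
  A <- matrix(0, m, nvar)
  rhs <- numeric(m)
  seg_col <- setNames(seq_len(n_s), segs$seg_id)
  uid_col <- setNames(n_s + seq_len(n_e), uids$uid)
  for (i in seq_along(side_rows)) {
    sr <- side_rows[[i]]
    A[i, seg_col[as.character(sr$seg)]] <- -1
    A[i, uid_col[as.character(sr$uid)]] <- sr$mult
  }
  # kappa_v = sum_t y_{v,t}
  for (s in seq_len(n_s)) {
    r <- length(side_rows) + s
    A[r, s] <- 1
    A[r, n_s + n_e + (s - 1L) * cap + seq_len(cap)] <- -1
  }
  list(A = A, rhs = rhs, n_s = n_s, n_e = n_e, cap = cap,
       seg_col = seg_col, uid_col = uid_col, uids = uids, segs = segs,
       sides = sides, side_rows = side_rows, side_loose = side_loose)
}

# Solve one clone's balance program.
#   stats: per-segment n_bins/mean_depth; open: named logical per uid
#   loose_cost: per-copy cost on loose edges (slack mode), usually 0
#   stage2_residual: if non-NULL, minimize total loose copies subject to
#   residual <= stage2_residual instead of minimizing the residual
solve_clone_balance <- function(frame, stats, open_uid, loose_cost = 0,
                                stage2_residual = NULL, node_limit = 200000L) {
  n_s <- frame$n_s; n_e <- frame$n_e; cap <- frame$cap
  nvar <- n_s + n_e + n_s * cap
  stats <- stats[match(frame$segs$seg_id, stats$seg_id), ]
  w <- stats$n_bins; xb <- stats$mean_depth

  # convex unit-step costs for the quadratic residual
  y_cost <- as.vector(vapply(seq_len(n_s), function(s) {
    t <- seq_len(cap)
    w[s] * ((t - xb[s])^2 - (t - 1 - xb[s])^2)
  }, numeric(cap)))
  offset <- sum(w * xb^2)

  kinds <- frame$uids$kind
  loose_sel <- kinds == "loose"
  obj <- c(rep(0, n_s),
           ifelse(loose_sel, loose_cost, 0),
           y_cost)
  lb <- rep(0, nvar)
  ub <- c(rep(cap, n_s),
          ifelse(open_uid[as.character(frame$uids$uid)], cap, 0),
          rep(1, n_s * cap))
  A <- frame$A; rhs <- frame$rhs
  if (!is.null(stage2_residual)) {
    # row: residual(y) + slack = stage2_residual   (residual = offset + y_cost.y)
    row <- c(rep(0, n_s + n_e), y_cost, 1)
    A <- cbind(A, 0)
    A <- rbind(A, row)
    rhs <- c(rhs, stage2_residual - offset)
    obj <- c(rep(0, n_s), as.numeric(loose_sel), rep(0, n_s * cap), 0)
    lb <- c(lb, 0)
    ub <- c(ub, sum(abs(y_cost)) + abs(stage2_residual) + 1)
  }
  int_idx <- seq_len(n_s + n_e)
  sol <- cg_milp(obj, A, rhs, lb, ub, int_idx, node_limit = node_limit)
  if (sol$status != "optimal") return(list(status = sol$status))
  x <- sol$x
  kap <- structure(list(
    vertex = tibble(seg_id = frame$segs$seg_id, cn = round(x[seq_len(n_s)])),
    edge = tibble(uid = frame$uids$uid, cn = round(x[n_s + seq_len(n_e)]))),
    class = "copy_assignment")
  residual <- sum(w * (xb - kap$vertex$cn)^2)
  loose_used <- kap$edge$uid[loose_sel & kap$edge$cn > 0]
  list(status = "optimal", kappa = kap, residual = residual,
       loose_used = loose_used,
       loose_copies = sum(kap$edge$cn[loose_sel]))
}

# Joint-mode clone subproblem: minimum residual subject to balance with
# the loose edges in `closed_uids` forbidden, then minimum loose usage at
# that residual. Exploits the structure that a side with an open loose
# edge constrains nothing: only segments touching closed sides (or
# sharing an edge with one) are coupled; every other segment's optimum is
# independent per-segment rounding.
solve_clone_subproblem <- function(frame, stats, open_uid, node_limit = 200000L) {
  n_s <- frame$n_s; n_e <- frame$n_e; cap <- frame$cap
  stats <- stats[match(frame$segs$seg_id, stats$seg_id), ]
  w <- stats$n_bins; xb <- stats$mean_depth
  kv <- pmin(pmax(round(xb), 0), cap)
  kv[w == 0] <- 0

  closed_side <- !open_uid[as.character(frame$side_loose)]
  if (any(closed_side)) {
    # coupled subnetwork around the closed sides
    ec_uids <- sort(unique(unlist(lapply(which(closed_side), function(i) {
      sr <- frame$side_rows[[i]]
      setdiff(sr$uid, frame$side_loose[i])
    }))))
    c_segs <- sort(unique(c(
      frame$sides$seg_id[closed_side],
      unlist(lapply(seq_along(frame$side_rows), function(i)
        if (any(frame$side_rows[[i]]$uid %in% ec_uids))
          frame$sides$seg_id[i] else integer(0))))))
    c_rows <- which(frame$sides$seg_id %in% c_segs)
    c_loose <- frame$side_loose[c_rows][!closed_side[c_rows]]
    # variables: kappa_v (c_segs) | kappa_e (ec) | loose (open C sides) | y
    n_c <- length(c_segs); n_ec <- length(ec_uids); n_l <- length(c_loose)
    n_y <- n_c * cap
    nvar <- n_c + n_ec + n_l + n_y
    m <- length(c_rows) + n_c
    A <- matrix(0, m, nvar); rhs <- numeric(m)
    seg_col <- setNames(seq_len(n_c), c_segs)
    ec_col <- setNames(n_c + seq_len(n_ec), ec_uids)
    l_col <- setNames(n_c + n_ec + seq_len(n_l), c_loose)
    ri <- 0L
    for (i in c_rows) {
      ri <- ri + 1L
      sr <- frame$side_rows[[i]]
      A[ri, seg_col[as.character(frame$sides$seg_id[i])]] <- -1
      for (k in seq_along(sr$uid)) {
        u <- sr$uid[k]
        if (u %in% ec_uids) A[ri, ec_col[as.character(u)]] <- sr$mult[k]
        else if (!closed_side[i] && u == frame$side_loose[i])
          A[ri, l_col[as.character(u)]] <- 1
        # other (open, uncoupled) edges sit at zero
      }
    }
    for (s in seq_len(n_c)) {
      ri <- ri + 1L
      A[ri, s] <- 1
      A[ri, n_c + n_ec + n_l + (s - 1L) * cap + seq_len(cap)] <- -1
    }
    idx <- match(c_segs, frame$segs$seg_id)
    y_cost <- as.vector(vapply(idx, function(s) {
      t <- seq_len(cap)
      w[s] * ((t - xb[s])^2 - (t - 1 - xb[s])^2)
    }, numeric(cap)))
    obj <- c(rep(0, n_c),
             rep(0, n_ec), rep(0, n_l), y_cost)
    lb <- rep(0, nvar)
    ub <- c(rep(cap, n_c),
            ifelse(open_uid[as.character(ec_uids)], cap, 0),
            rep(cap, n_l), rep(1, n_y))
    sol <- cg_milp(obj, A, rhs, lb, ub, int_idx = seq_len(n_c + n_ec + n_l),
                   node_limit = node_limit)
    if (sol$status != "optimal") return(list(status = sol$status))
    kv[idx] <- round(sol$x[seq_len(n_c)])
  }
  residual <- sum(w * (xb - kv)^2)

  # stage 2: minimum total loose copies at the fixed kappa_v
  side_rows_n <- length(frame$side_rows)
  A2 <- frame$A[seq_len(side_rows_n), n_s + seq_len(n_e), drop = FALSE]
  rhs2 <- as.numeric(-frame$A[seq_len(side_rows_n), seq_len(n_s), drop = FALSE] %*% kv)
  loose_sel <- frame$uids$kind == "loose"
  ub2 <- ifelse(open_uid[as.character(frame$uids$uid)], cap, 0)
  sol2 <- cg_milp(as.numeric(loose_sel), A2, rhs2, rep(0, n_e), ub2,
                  int_idx = seq_len(n_e), node_limit = node_limit)
  if (sol2$status != "optimal") return(list(status = sol2$status))
  kap <- structure(list(
    vertex = tibble(seg_id = frame$segs$seg_id, cn = kv),
    edge = tibble(uid = frame$uids$uid, cn = round(sol2$x))),
    class = "copy_assignment")
  loose_used <- kap$edge$uid[loose_sel & kap$edge$cn > 0]
  list(status = "optimal", kappa = kap, residual = residual,
       loose_used = loose_used,
       loose_copies = sum(kap$edge$cn[loose_sel]))
}

resolve_cap <- function(cfg, stats_list) {
  if (!is.null(cfg$cn_cap)) return(as.integer(cfg$cn_cap))
  mx <- max(vapply(stats_list, function(s) max(c(0, s$mean_depth)), 0))
  max(4L, as.integer(ceiling(mx)) + 2L)
}

open_map <- function(frame, bounds_clone) {
  open <- setNames(rep(TRUE, nrow(frame$uids)), frame$uids$uid)
  if (!is.null(bounds_clone) && nrow(bounds_clone) > 0) {
    closed <- bounds_clone$uid[!bounds_clone$open]
    open[as.character(closed)] <- FALSE
  }
  open
}

# ---- single-sample fit ---------------------------------------------------

#' Fit a junction-balanced copy-number assignment to one clone
#'
#' Minimizes the read-depth residual plus a per-copy penalty on loose
#' (slack) edges, subject to integer junction balance. This is the
#' single-sample special case of the joint program.
#'
#' @param g a `genome_graph`.
#' @param bins depth bins (`chrom,start,end,value`) in copy-number units.
#' @param bounds optional tibble `uid`,`open` closing unsupported variant
#'   edges (defaults to all open).
#' @param cfg a [balance_config()].
#' @return a `crisis_balance` object (see [fit_joint()]).
#' @export
fit_single <- function(g, bins, bounds = NULL, cfg = balance_config()) {
  stats <- map_bins_to_segments(g, bins)
  cap <- resolve_cap(cfg, list(stats))
  frame <- clone_program_frame(g, cap)
  open <- open_map(frame, bounds)
  sol <- solve_clone_balance(frame, stats, open, loose_cost = cfg$slack_penalty,
                             node_limit = cfg$node_limit)
  if (sol$status != "optimal")
    return(structure(list(solver_status = sol$status, mode = "single"),
                     class = "crisis_balance"))
  loose_tbl <- loose_end_table(g, list(clone = sol$kappa))
  structure(list(
    mode = "single", graph = g, config = cfg, cn_cap = cap,
    assignments = list(clone = sol$kappa),
    residual_per_clone = c(clone = sol$residual),
    objective = sol$residual + cfg$slack_penalty * sol$loose_copies,
    loose_copies = sol$loose_copies,
    unique_loose_ends = length(sol$loose_used),
    loose_ends = loose_tbl,
    solver_status = "optimal"
  ), class = "crisis_balance")
}

# summarize nonzero loose ends across assignments
loose_end_table <- function(g, assignments) {
  loose <- g$edges %>% filter(.data$kind == "loose", !is.na(.data$from_vid))
  empty <- tibble(clone = character(), uid = integer(), seg_id = integer(),
                  side = character(), cn = numeric())
  rows <- purrr::imap(assignments, function(kap, clone) {
    e <- kap$edge %>% filter(.data$uid %in% loose$uid, .data$cn > 0)
    if (nrow(e) == 0) return(NULL)
    v <- loose$from_vid[match(e$uid, loose$uid)]
    tibble(clone = clone, uid = e$uid, seg_id = seg_of_vid(v),
           side = head_side(v), cn = e$cn)
  })
  bind_rows(c(list(empty), rows))
}

# ---- joint fit -----------------------------------------------------------

#' Jointly fit junction-balanced copy numbers across a clone compendium
#'
#' Solves the joint mixed-integer program: minimize
#' `lambda * (# unique prototype loose ends with nonzero total copy) +
#' sum of per-clone read-depth residuals`, subject to integer junction
#' balance in every clone and per-clone edge bounds. Solved exactly by
#' branch-and-bound over prototype loose ends with per-clone integer
#' subproblems.
#'
#' @param comp a `graph_compendium`.
#' @param bins_list named list (per clone) of depth-bin tibbles.
#' @param bounds per-clone edge bounds from [derive_edge_bounds()], or
#'   `NULL` for all-open.
#' @param cfg a [balance_config()].
#' @return a `crisis_balance` object with per-clone assignments, per-clone
#'   residuals, the count and table of unique nonzero prototype loose
#'   ends, and the joint objective.
#' @export
fit_joint <- function(comp, bins_list, bounds = NULL, cfg = balance_config()) {
  g <- comp$prototype
  clones <- comp$clone_ids
  stopifnot(all(clones %in% names(bins_list)))
  stats_list <- lapply(bins_list[clones], map_bins_to_segments, g = g)
  cap <- resolve_cap(cfg, stats_list)
  frame <- clone_program_frame(g, cap)
  loose_uids <- frame$uids$uid[frame$uids$kind == "loose"]

  base_open <- lapply(clones, function(cl) {
    b <- if (is.null(bounds)) NULL else filter(bounds, .data$clone == cl)
    open_map(frame, b)
  })
  names(base_open) <- clones

  cache <- new.env(parent = emptyenv())
  solve_clone <- function(cl, closed) {
    key <- paste(cl, paste(closed, collapse = ","), sep = "|")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    # reuse a solution computed under a subset of `closed` that avoids it
    for (k2 in ls(cache)) {
      if (!startsWith(k2, paste0(cl, "|"))) next
      prev <- get(k2, envir = cache)
      if (prev$status == "optimal" &&
          all(prev$closed %in% closed) &&
          !any(prev$loose_used %in% closed)) {
        assign(key, prev, envir = cache)
        return(prev)
      }
    }
    open <- base_open[[cl]]
    open[as.character(closed)] <- FALSE
    s <- solve_clone_subproblem(frame, stats_list[[cl]], open,
                                node_limit = cfg$node_limit)
    out <- if (s$status != "optimal") list(status = s$status, closed = closed)
           else list(status = "optimal", kappa = s$kappa, residual = s$residual,
                     loose_used = s$loose_used, closed = closed)
    assign(key, out, envir = cache)
    out
  }

  lam <- cfg$lambda
  best <- NULL; best_obj <- Inf
  proven <- TRUE
  n_outer <- 0L
  nodes <- list(list(F = integer(0), X = integer(0), bound = -Inf))
  while (length(nodes) > 0) {
    if (n_outer >= cfg$outer_node_limit) { proven <- FALSE; break }
    n_outer <- n_outer + 1L
    bb <- vapply(nodes, `[[`, 0, "bound")
    i <- which.min(bb)
    nd <- nodes[[i]]; nodes[[i]] <- NULL
    if (nd$bound >= best_obj - 1e-9) next
    sols <- lapply(clones, solve_clone, closed = nd$X)
    names(sols) <- clones
    if (any(vapply(sols, function(s) s$status != "optimal", TRUE))) next
    residuals <- vapply(sols, `[[`, 0, "residual")
    lb_node <- lam * length(nd$F) + sum(residuals)
    if (lb_node >= best_obj - 1e-9) next
    used <- sort(unique(unlist(lapply(sols, `[[`, "loose_used"))))
    cand_obj <- lam * length(used) + sum(residuals)
    if (cand_obj < best_obj - 1e-9) {
      best_obj <- cand_obj
      best <- list(sols = sols, used = used, residuals = residuals)
    }
    open_used <- setdiff(used, nd$F)
    if (length(open_used) == 0) next  # node resolved exactly
    usage <- vapply(open_used, function(e)
      sum(vapply(sols, function(s) e %in% s$loose_used, TRUE)), 0)
    e_br <- open_used[which.max(usage)]
    nodes[[length(nodes) + 1]] <- list(F = c(nd$F, e_br), X = nd$X, bound = lb_node)
    nodes[[length(nodes) + 1]] <- list(F = nd$F, X = sort(c(nd$X, e_br)), bound = lb_node)
  }

  if (is.null(best))
    return(structure(list(solver_status = "infeasible", mode = "joint"),
                     class = "crisis_balance"))
  assignments <- lapply(best$sols, `[[`, "kappa")
  structure(list(
    mode = "joint", graph = g, config = cfg, cn_cap = cap,
    assignments = assignments,
    residual_per_clone = best$residuals,
    unique_loose_ends = length(best$used),
    unique_loose_uids = best$used,
    loose_ends = loose_end_table(g, assignments),
    objective = best_obj,
    solver_status = if (proven) "optimal" else "feasible"
  ), class = "crisis_balance")
}

#' Independently fit every clone of a compendium
#'
#' Runs [fit_single()] per clone (slack-penalized), the baseline against
#' which the joint fit's loose-end parsimony is measured.
#'
#' @inheritParams fit_joint
#' @return list of `crisis_balance` objects, one per clone, with an
#'   attribute `total_loose_ends`: the summed per-clone count of nonzero
#'   loose ends.
#' @export
fit_independent <- function(comp, bins_list, bounds = NULL, cfg = balance_config()) {
  g <- comp$prototype
  fits <- lapply(comp$clone_ids, function(cl) {
    b <- if (is.null(bounds)) NULL else filter(bounds, .data$clone == cl)
    fit_single(g, bins_list[[cl]], b, cfg)
  })
  names(fits) <- comp$clone_ids
  attr(fits, "total_loose_ends") <- sum(vapply(fits, `[[`, 0, "unique_loose_ends"))
  fits
}

#' @export
print.crisis_balance <- function(x, ...) {
  if (!x$solver_status %in% c("optimal", "feasible")) {
    cat(sprintf("<crisis_balance> %s (%s)\n", x$mode, x$solver_status))
    return(invisible(x))
  }
  cat(sprintf("<crisis_balance> %s fit of %d clone(s): objective %.4g, %d unique loose end(s)%s\n",
              x$mode, length(x$assignments), x$objective, x$unique_loose_ends,
              if (identical(x$solver_status, "feasible"))
                " (incumbent at node budget)" else ""))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a balance fit into one row per clone and segment
#'
#' @param x a `crisis_balance` object.
#' @param ... unused.
#' @return tibble `clone`, `seg_id`, `chrom`, `start`, `end`, `cn`.
#' @method tidy crisis_balance
#' @export
tidy.crisis_balance <- function(x, ...) {
  purrr::imap(x$assignments, function(kap, cl)
    left_join(x$graph$segments, kap$vertex, by = "seg_id") %>%
      mutate(clone = cl)) %>%
    bind_rows() %>%
    select("clone", "seg_id", "chrom", "start", "end", "cn")
}

#' One-row summary of a balance fit
#'
#' @param x a `crisis_balance` object.
#' @param ... unused.
#' @method glance crisis_balance
#' @export
glance.crisis_balance <- function(x, ...) {
  tibble(mode = x$mode, n_clones = length(x$assignments),
         objective = x$objective,
         total_residual = sum(x$residual_per_clone),
         unique_loose_ends = x$unique_loose_ends,
         solver_status = x$solver_status)
}

#' @method autoplot crisis_balance
#' @export
autoplot.crisis_balance <- function(object, clones = NULL, ...) {
  d <- tidy(object)
  if (!is.null(clones)) d <- filter(d, .data$clone %in% clones)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$cn, yend = .data$cn),
                          linewidth = 1.2, colour = "steelblue") +
    ggplot2::facet_grid(clone ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "integer copy number") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
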
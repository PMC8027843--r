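#' @import tibble
#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n pull rename row_number select summarise ungroup across all_of
#'   first last lead lag if_else
#' @importFrom rlang .data abort
NULL

# ---- signed-vertex encoding ---------------------------------------------
# Segment s yields two oriented vertices: +s (vid 2s-1, traversed left to
# right) and -s (vid 2s, its reverse complement). The head side of +s is
# the segment's right (higher-coordinate) side; the head side of -s its
# left side. Edges are stored as signed records in reverse-complement
# pairs; a fold-back junction contributes two parallel records so that
# per-side stoichiometry counts it twice.

vid_of <- function(seg_id, forward) {
  forward <- rep_len(forward, length(seg_id))
  ifelse(forward, 2L * seg_id - 1L, 2L * seg_id)
}
seg_of_vid <- function(vid) (vid + 1L) %/% 2L
is_fwd_vid <- function(vid) vid %% 2L == 1L
rc_vid <- function(vid) vid + ifelse(vid %% 2L == 1L, 1L, -1L)

# side of a segment that a signed vertex's head faces: "R" for +s, "L" for -s
head_side <- function(vid) ifelse(is_fwd_vid(vid), "R", "L")

new_genome_graph <- function(segments, edges, termini) {
  g <- list(segments = segments, edges = edges, termini = termini)
  class(g) <- "genome_graph"
  g
}

#' @export
print.genome_graph <- function(x, ...) {
  nvar <- length(unique(x$edges$uid[x$edges$kind == "variant"]))
  nloose <- length(unique(x$edges$uid[x$edges$kind == "loose"]))
  cat(sprintf(
    "<genome_graph> %d segments on %d chromosome(s); %d variant junction(s), %d loose slot(s)\n",
    nrow(x$segments), length(unique(x$segments$chrom)), nvar, nloose))
  invisible(x)
}

#' Tidy view of the oriented vertices of a genome graph
#'
#' Each physical segment appears twice: once per orientation, with its
#' reverse-complement partner's id alongside.
#'
#' @param g a `genome_graph`.
#' @return a tibble with one row per oriented vertex.
#' @export
graph_vertices <- function(g) {
  s <- g$segments
  bind_rows(
    tibble(vid = vid_of(s$seg_id, TRUE), seg_id = s$seg_id, chrom = s$chrom,
           start = s$start, end = s$end, orientation = "+"),
    tibble(vid = vid_of(s$seg_id, FALSE), seg_id = s$seg_id, chrom = s$chrom,
           start = s$start, end = s$end, orientation = "-")
  ) %>%
    mutate(rc_vid = rc_vid(.data$vid)) %>%
    arrange(.data$vid)
}

#' Tidy view of the edges of a genome graph
#'
#' @param g a `genome_graph`.
#' @param signed if `TRUE` (default) return one row per signed edge record
#'   (each junction appears with its reverse-complement partner); otherwise
#'   one row per unsigned edge.
#' @return a tibble of edges.
#' @export
graph_edges <- function(g, signed = TRUE) {
  if (signed) return(as_tibble(g$edges))
  if (nrow(g$edges) == 0)
    return(tibble(uid = integer(), kind = character(), eid = integer()))
  g$edges %>%
    group_by(.data$uid) %>%
    summarise(kind = first(.data$kind), eid = min(.data$eid), .groups = "drop") %>%
    arrange(.data$uid)
}

# every (seg, side) that must satisfy junction balance
interstitial_sides <- function(g) {
  sides <- bind_rows(
    tibble(seg_id = g$segments$seg_id, side = "L"),
    tibble(seg_id = g$segments$seg_id, side = "R")
  )
  dplyr::anti_join(sides, g$termini, by = c("seg_id", "side")) %>%
    arrange(.data$seg_id, .data$side)
}

#' Reverse complement of a genome graph
#'
#' Maps every oriented vertex and edge to its reverse-complement partner.
#' Applying it twice returns the original graph elementwise.
#'
#' @param g a `genome_graph`.
#' @return a `genome_graph`.
#' @export
reverse_complement <- function(g) {
  e <- g$edges
  rc <- e[match(e$rc_eid, e$eid), ]
  e2 <- tibble(eid = e$eid, uid = e$uid, kind = e$kind,
               from_vid = rc$from_vid, to_vid = rc$to_vid, rc_eid = e$rc_eid)
  new_genome_graph(g$segments, e2, g$termini)
}

# ---- construction --------------------------------------------------------

normalize_junctions <- function(j) {
  if (is.null(j) || nrow(j) == 0) {
    return(tibble(chrom1 = character(), pos1 = numeric(), strand1 = character(),
                  chrom2 = character(), pos2 = numeric(), strand2 = character()))
  }
  j <- as_tibble(j)
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (!all(need %in% names(j)))
    abort(paste("junction table must have columns:", paste(need, collapse = ", ")))
  ok <- j$strand1 %in% c("+", "-") & j$strand2 %in% c("+", "-")
  if (!all(ok)) abort("junction strands must be '+' or '-'")
  # canonical breakend order for deduplication
  key1 <- paste(j$chrom1, format(j$pos1, scientific = FALSE, trim = TRUE), j$strand1)
  key2 <- paste(j$chrom2, format(j$pos2, scientific = FALSE, trim = TRUE), j$strand2)
  swap <- key2 < key1
  j2 <- j
  j2[swap, c("chrom1", "pos1", "strand1")] <- j[swap, c("chrom2", "pos2", "strand2")]
  j2[swap, c("chrom2", "pos2", "strand2")] <- j[swap, c("chrom1", "pos1", "strand1")]
  j2
}

junction_key <- function(j) {
  paste(j$chrom1, format(j$pos1, scientific = FALSE, trim = TRUE), j$strand1,
        j$chrom2, format(j$pos2, scientific = FALSE, trim = TRUE), j$strand2, sep = "|")
}

# snap positions within merge_window of each other to one representative
snap_positions <- function(pos, window) {
  if (window <= 0 || length(pos) == 0) return(pos)
  u <- sort(unique(pos))
  rep_of <- u
  cur <- u[1]
  for (i in seq_along(u)) {
    if (u[i] - cur <= window) rep_of[i] <- cur else { cur <- u[i]; rep_of[i] <- cur }
  }
  rep_of[match(pos, u)]
}

#' Build a prototype genome graph and clone compendium
#'
#' Takes per-clone segmentations and junction calls, refines all
#' breakpoints into a shared disjoint segmentation, pools junctions
#' (exact-coordinate deduplication, optionally within a merge window),
#' and returns a compendium in which every clone graph is a replica of
#' the shared prototype. Reference edges join genome-adjacent segments;
#' a loose (slack) edge is attached at every interstitial segment side;
#' declared chromosome ends are exempt from balance.
#'
#' @param segment_sets named list (one per clone) of tibbles with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param junction_sets named list (one per clone) of junction tibbles with
#'   columns `chrom1,pos1,strand1,chrom2,pos2,strand2` and optionally
#'   `support`. Strand `+` denotes the segment side facing higher
#'   coordinates.
#' @param merge_window pool junction breakends within this many bp
#'   (default 0: exact match only).
#' @return a `graph_compendium`: list with `prototype` (genome_graph),
#'   `graphs` (per-clone replicas), `clone_ids`, and `junction_support`
#'   (tibble clone/uid/support). The projection `p` from clone elements to
#'   prototype elements is the identity on ids (replicas share ids).
#' @export
build_prototype <- function(segment_sets, junction_sets = NULL, merge_window = 0) {
  stopifnot(is.list(segment_sets), length(segment_sets) > 0)
  clone_ids <- names(segment_sets)
  if (is.null(clone_ids) || any(clone_ids == ""))
    clone_ids <- paste0("clone", seq_along(segment_sets))
  if (is.null(junction_sets)) junction_sets <- setNames(
    rep(list(NULL), length(segment_sets)), clone_ids)

  seg_all <- purrr::imap(segment_sets, function(s, id) {
    s <- as_tibble(s)
    stopifnot(all(c("chrom", "start", "end") %in% names(s)))
    if (any(s$end <= s$start)) abort("segment with end <= start")
    ov <- s %>% group_by(.data$chrom) %>% arrange(.data$start, .by_group = TRUE) %>%
      summarise(bad = any(.data$start < lag(.data$end, default = -Inf)), .groups = "drop")
    if (any(ov$bad)) abort(sprintf("overlapping segments within clone %s", id))
    mutate(s, clone = id)
  }) %>% bind_rows()

  # consistent chromosome extents across clones
  ext <- seg_all %>% group_by(.data$clone, .data$chrom) %>%
    summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop")
  bad <- ext %>% group_by(.data$chrom) %>%
    summarise(n_ext = dplyr::n_distinct(paste(.data$lo, .data$hi)), .groups = "drop") %>%
    filter(.data$n_ext > 1)
  if (nrow(bad) > 0)
    abort(sprintf("mixed genome builds: inconsistent extents for chromosome(s) %s",
                  paste(bad$chrom, collapse = ", ")))
  ext <- ext %>% group_by(.data$chrom) %>%
    summarise(lo = first(.data$lo), hi = first(.data$hi), .groups = "drop")

  jn_all <- purrr::imap(junction_sets, function(j, id) {
    j <- normalize_junctions(j)
    if (nrow(j) == 0) return(mutate(j, clone = character(0)))
    mutate(j, clone = id)
  }) %>% bind_rows()

  if (nrow(jn_all) > 0 && merge_window > 0) {
    for (cc in unique(c(jn_all$chrom1, jn_all$chrom2))) {
      sel1 <- jn_all$chrom1 == cc; sel2 <- jn_all$chrom2 == cc
      pos <- c(jn_all$pos1[sel1], jn_all$pos2[sel2])
      snapped <- snap_positions(pos, merge_window)
      jn_all$pos1[sel1] <- snapped[seq_len(sum(sel1))]
      jn_all$pos2[sel2] <- snapped[sum(sel1) + seq_len(sum(sel2))]
    }
  }

  # validate breakends against extents
  if (nrow(jn_all) > 0) {
    for (k in 1:2) {
      chrom <- jn_all[[paste0("chrom", k)]]
      pos <- jn_all[[paste0("pos", k)]]
      strand <- jn_all[[paste0("strand", k)]]
      m <- match(chrom, ext$chrom)
      bad <- is.na(m) |
        (strand == "+" & (pos <= ext$lo[m] | pos > ext$hi[m])) |
        (strand == "-" & (pos < ext$lo[m] | pos >= ext$hi[m]))
      if (any(bad)) {
        i <- which(bad)[1]
        abort(sprintf("junction breakend %s:%s(%s) does not lie on any segment",
                      chrom[i], format(pos[i], scientific = FALSE), strand[i]))
      }
    }
  }

  # disjoint refinement: all clone boundaries plus junction breakends
  bp <- bind_rows(
    seg_all %>% select(chrom = "chrom", pos = "start"),
    seg_all %>% select(chrom = "chrom", pos = "end"),
    if (nrow(jn_all) > 0) bind_rows(
      tibble(chrom = jn_all$chrom1, pos = jn_all$pos1),
      tibble(chrom = jn_all$chrom2, pos = jn_all$pos2))
  ) %>% distinct()

  segs <- purrr::pmap(ext, function(chrom, lo, hi) {
    b <- sort(unique(c(lo, hi, bp$pos[bp$chrom == chrom & bp$pos > lo & bp$pos < hi])))
    tibble(chrom = chrom, start = b[-length(b)], end = b[-1])
  }) %>% bind_rows() %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(seg_id = row_number()) %>%
    select("seg_id", "chrom", "start", "end")

  # unique junctions with per-clone provenance
  if (nrow(jn_all) > 0) {
    jn_all$key <- junction_key(jn_all)
    jn_uniq <- jn_all %>% distinct(.data$key, .keep_all = TRUE) %>%
      arrange(.data$chrom1, .data$pos1, .data$chrom2, .data$pos2) %>%
      mutate(jid = row_number())
  } else {
    jn_uniq <- mutate(jn_all, key = character(0), jid = integer(0))
  }

  g <- assemble_graph(segs, jn_uniq)

  support <- if (nrow(jn_all) > 0) {
    jn_all %>%
      mutate(uid = g$junction_uid[match(.data$key, jn_uniq$key)],
             support = if ("support" %in% names(jn_all)) .data$support else 1) %>%
      select("clone", "uid", "support")
  } else tibble(clone = character(), uid = integer(), support = numeric())

  proto <- g$graph
  comp <- list(
    prototype = proto,
    clone_ids = clone_ids,
    graphs = setNames(rep(list(proto), length(clone_ids)), clone_ids),
    junction_support = support
  )
  class(comp) <- "graph_compendium"
  comp
}

#' @export
print.graph_compendium <- function(x, ...) {
  cat(sprintf("<graph_compendium> %d clone(s) over a prototype of %d segments\n",
              length(x$clone_ids), nrow(x$prototype$segments)))
  print(x$prototype)
  invisible(x)
}

# resolve a breakend (chrom,pos,strand) to the head vid it attaches to
breakend_vid <- function(chrom, pos, strand, segs) {
  if (strand == "+") {
    i <- which(segs$chrom == chrom & segs$end == pos)
    if (length(i) != 1) abort(sprintf(
      "junction breakend %s:%s(+) is not a segment boundary", chrom, pos))
    vid_of(segs$seg_id[i], TRUE)
  } else {
    i <- which(segs$chrom == chrom & segs$start == pos)
    if (length(i) != 1) abort(sprintf(
      "junction breakend %s:%s(-) is not a segment boundary", chrom, pos))
    vid_of(segs$seg_id[i], FALSE)
  }
}

# build the full edge table (reference + variant + loose) and termini
assemble_graph <- function(segs, junctions) {
  termini <- segs %>% group_by(.data$chrom) %>%
    summarise(first_seg = first(.data$seg_id), last_seg = last(.data$seg_id),
              .groups = "drop")
  term_tbl <- bind_rows(
    tibble(seg_id = termini$first_seg, side = "L"),
    tibble(seg_id = termini$last_seg, side = "R")
  ) %>% arrange(.data$seg_id, .data$side)

  rows <- list()
  uid <- 0L

  # reference edges between genome-adjacent segments
  adj <- segs %>% group_by(.data$chrom) %>%
    mutate(nxt = lead(.data$seg_id)) %>% ungroup() %>%
    filter(!is.na(.data$nxt))
  for (i in seq_len(nrow(adj))) {
    uid <- uid + 1L
    s <- adj$seg_id[i]; t <- adj$nxt[i]
    rows[[length(rows) + 1L]] <- tibble(
      uid = uid, kind = "reference",
      from_vid = c(vid_of(s, TRUE), vid_of(t, FALSE)),
      to_vid = c(vid_of(t, TRUE), vid_of(s, FALSE)))
  }

  junction_uid <- integer(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    uid <- uid + 1L
    junction_uid[i] <- uid
    v1 <- breakend_vid(junctions$chrom1[i], junctions$pos1[i], junctions$strand1[i], segs)
    v2 <- breakend_vid(junctions$chrom2[i], junctions$pos2[i], junctions$strand2[i], segs)
    # traversal: into breakend 1, out of breakend 2 (and the RC partner);
    # a fold-back (v1 == v2) yields two parallel records on purpose
    rows[[length(rows) + 1L]] <- tibble(
      uid = uid, kind = "variant",
      from_vid = c(v1, v2), to_vid = c(rc_vid(v2), rc_vid(v1)))
  }

  # loose slack at every interstitial side
  sides <- bind_rows(
    tibble(seg_id = segs$seg_id, side = "L"),
    tibble(seg_id = segs$seg_id, side = "R")
  ) %>% dplyr::anti_join(term_tbl, by = c("seg_id", "side")) %>%
    arrange(.data$seg_id, .data$side)
  for (i in seq_len(nrow(sides))) {
    uid <- uid + 1L
    v <- if (sides$side[i] == "R") vid_of(sides$seg_id[i], TRUE) else vid_of(sides$seg_id[i], FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      uid = uid, kind = "loose",
      from_vid = c(v, NA_integer_), to_vid = c(NA_integer_, rc_vid(v)))
  }

  if (length(rows) == 0) {
    rows <- list(tibble(uid = integer(), kind = character(),
                        from_vid = integer(), to_vid = integer()))
  }
  edges <- bind_rows(rows) %>%
    mutate(eid = row_number(),
           rc_eid = .data$eid + if_else(.data$eid %% 2L == 1L, 1L, -1L)) %>%
    select("eid", "uid", "kind", "from_vid", "to_vid", "rc_eid")

  list(graph = new_genome_graph(segs, edges, term_tbl), junction_uid = junction_uid)
}

#' Construct a single genome graph
#'
#' Convenience wrapper over [build_prototype()] for one clone.
#'
#' @param segments tibble with `chrom`, `start`, `end`.
#' @param junctions optional junction tibble (see [build_prototype()]).
#' @return a `genome_graph`.
#' @export
genome_graph <- function(segments, junctions = NULL) {
  build_prototype(list(g = segments), list(g = junctions))$prototype
}

# ---- copy assignments ----------------------------------------------------

#' Create a copy assignment for a genome graph
#'
#' @param g a `genome_graph`.
#' @param vertex_cn integer copy number per segment (recycled or named by
#'   seg_id order).
#' @param edge_cn named/ordered integer copy number per unsigned edge uid;
#'   defaults to 0.
#' @return a `copy_assignment`: list of `vertex` and `edge` tibbles.
#' @export
copy_assignment <- function(g, vertex_cn, edge_cn = NULL) {
  uids <- sort(unique(g$edges$uid))
  v <- tibble(seg_id = g$segments$seg_id,
              cn = as.numeric(rep_len(vertex_cn, nrow(g$segments))))
  e <- tibble(uid = uids, cn = 0)
  if (!is.null(edge_cn)) {
    ec <- as_tibble(edge_cn)
    stopifnot(all(c("uid", "cn") %in% names(ec)))
    e$cn[match(ec$uid, e$uid)] <- ec$cn
  }
  structure(list(vertex = v, edge = e), class = "copy_assignment")
}

#' Check junction-balance invariants of a copy assignment
#'
#' Verifies nonnegative integrality and, at every interstitial side, that
#' the segment copy number equals the copy-weighted sum of incident edges
#' (fold-back junctions counting twice).
#'
#' @param g a `genome_graph`.
#' @param kappa a `copy_assignment`.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly, or aborts with the first violated side.
#' @export
check_balance <- function(g, kappa, tol = 1e-6) {
  v_cn <- setNames(kappa$vertex$cn, kappa$vertex$seg_id)
  e_cn <- setNames(kappa$edge$cn, kappa$edge$uid)
  if (any(v_cn < -tol) || any(e_cn < -tol)) abort("negative copy number")
  if (any(abs(v_cn - round(v_cn)) > tol) || any(abs(e_cn - round(e_cn)) > tol))
    abort("non-integer copy number")
  sides <- interstitial_sides(g)
  ed <- g$edges[!is.na(g$edges$from_vid), ]
  for (i in seq_len(nrow(sides))) {
    v <- if (sides$side[i] == "R") vid_of(sides$seg_id[i], TRUE)
         else vid_of(sides$seg_id[i], FALSE)
    inc <- ed$uid[ed$from_vid == v]
    lhs <- v_cn[as.character(sides$seg_id[i])]
    rhs <- sum(e_cn[as.character(inc)])
    if (abs(lhs - rhs) > tol)
      abort(sprintf("balance violated at segment %d side %s: %g != %g",
                    sides$seg_id[i], sides$side[i], lhs, rhs))
  }
  invisible(TRUE)
}

# ---- (de)serialization ---------------------------------------------------

#' Serialize a genome graph (and optional copy assignment) to JSON
#'
#' @param g a `genome_graph`.
#' @param path output file path.
#' @param assignment optional `copy_assignment` stored alongside.
#' @export
write_genome_graph <- function(g, path, assignment = NULL) {
  doc <- list(format = "crisisgraph-graph", version = 1L,
              segments = g$segments, edges = g$edges, termini = g$termini)
  if (!is.null(assignment))
    doc$assignment <- list(vertex = assignment$vertex, edge = assignment$edge)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a genome graph serialized by [write_genome_graph()]
#'
#' @param path input file path.
#' @return a list with `graph` and (possibly `NULL`) `assignment`.
#' @export
read_genome_graph <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort(sprintf("malformed graph document: %s",
                                                    conditionMessage(e))))
  for (f in c("segments", "edges", "termini"))
    if (is.null(doc[[f]])) abort(sprintf("malformed graph document: missing field '%s'", f))
  segs <- as_tibble(doc$segments)
  edges <- as_tibble(doc$edges)
  term <- as_tibble(doc$termini)
  segs$seg_id <- as.integer(segs$seg_id)
  segs$start <- as.numeric(segs$start)
  segs$end <- as.numeric(segs$end)
  for (cl in c("eid", "uid", "from_vid", "to_vid", "rc_eid"))
    edges[[cl]] <- as.integer(edges[[cl]])
  term$seg_id <- as.integer(term$seg_id)
  ref_vids <- c(edges$from_vid, edges$to_vid)
  ref_vids <- ref_vids[!is.na(ref_vids)]
  if (length(ref_vids) && !all(seg_of_vid(ref_vids) %in% segs$seg_id))
    abort("malformed graph document: edge references a missing vertex (field 'edges')")
  if (!all(edges$rc_eid %in% edges$eid))
    abort("malformed graph document: broken reverse-complement pairing (field 'edges')")
  g <- new_genome_graph(segs, edges, term)
  asg <- NULL
  if (!is.null(doc$assignment))
    asg <- structure(list(vertex = as_tibble(doc$assignment$vertex),
                          edge = as_tibble(doc$assignment$edge)),
                     class = "copy_assignment")
  list(graph = g, assignment = asg)
}
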
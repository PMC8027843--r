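#' @importFrom stats rnorm rpois rbinom runif median setNames dist hclust
#'   cutree dbinom
NULL

# ---- allele walks --------------------------------------------------------
# An allele is an ordered walk of oriented genomic intervals:
# tibble(chrom, start, end, strand) with 0-based half-open coordinates.
# Rows are traversed in order; a "+" row runs start -> end, a "-" row
# end -> start (its reverse complement).

walk_tbl <- function(chrom, start, end, strand) {
  tibble(chrom = chrom, start = start, end = end, strand = strand)
}

#' Reverse complement of an allele walk
#' @param w a walk tibble (`chrom`,`start`,`end`,`strand`).
#' @return the walk traversed in the opposite direction.
#' @export
walk_reverse_complement <- function(w) {
  if (nrow(w) == 0) return(w)
  w <- w[rev(seq_len(nrow(w))), ]
  w$strand <- ifelse(w$strand == "+", "-", "+")
  w
}

# truncate the walk within its terminal row at genomic position break_pos,
# dropping everything traversed after the cut
walk_truncate <- function(w, break_pos) {
  if (nrow(w) == 0) abort("cannot truncate an empty walk")
  last <- w[nrow(w), ]
  if (break_pos <= last$start || break_pos >= last$end)
    abort(sprintf("break position %s outside the terminal segment span [%s,%s)",
                  format(break_pos, scientific = FALSE), last$start, last$end))
  if (last$strand == "+") w$end[nrow(w)] <- break_pos else w$start[nrow(w)] <- break_pos
  w
}

#' Apply one breakage-fusion-bridge cycle to an allele walk
#'
#' Models sister-chromatid fusion after a break: the walk is cut inside
#' its terminal segment at `break_pos`, the distal portion is lost, and
#' the retained walk is fused to its own reverse complement, creating a
#' fold-back junction at the cut. Copy number of every retained interval
#' doubles; successive cycles with breaks clustered at a focus build the
#' stepwise staircase characteristic of BFB amplification.
#'
#' @param w allele walk tibble.
#' @param break_pos genomic coordinate of the break, strictly inside the
#'   terminal row's span.
#' @return the post-cycle walk (a palindrome ending where it started).
#' @export
apply_fold_back <- function(w, break_pos) {
  t <- walk_truncate(w, break_pos)
  bind_rows(t, walk_reverse_complement(t))
}

#' Truncate an allele walk at a bridge break
#'
#' The bridge-breakage half of a BFB cycle without re-fusion: cuts the
#' walk inside its terminal segment and discards the distal portion,
#' leaving an unprotected end (a loose end unless a stabilizing fusion
#' follows).
#'
#' @inheritParams apply_fold_back
#' @export
apply_truncate <- function(w, break_pos) walk_truncate(w, break_pos)

#' Fuse a partner arm onto an allele terminus
#'
#' Models stabilization of an unstable derivative chromosome by
#' translocation: the partner walk (typically an intact acrocentric
#' q-arm ending in a telomere) is appended at the current terminus,
#' creating a translocation junction.
#'
#' @param w allele walk tibble.
#' @param partner walk appended after `w`.
#' @export
apply_stabilizing_fusion <- function(w, partner) bind_rows(w, partner)

# subtract [lo,hi) on `chrom` from every row of the walk
#' Delete an interval from an allele walk
#'
#' Removes `[lo,hi)` on `chrom` from every row that covers it, splicing
#' the flanks together (a simple interstitial deletion junction).
#'
#' @param w allele walk tibble.
#' @param chrom,lo,hi the deleted interval.
#' @export
apply_deletion <- function(w, chrom, lo, hi) {
  out <- list()
  for (i in seq_len(nrow(w))) {
    r <- w[i, ]
    if (r$chrom != chrom || hi <= r$start || lo >= r$end) {
      out[[length(out) + 1]] <- r
      next
    }
    a <- r; b <- r
    a$end <- max(r$start, lo)   # left piece
    b$start <- min(r$end, hi)   # right piece
    pieces <- list(a, b)
    if (r$strand == "-") pieces <- rev(pieces)
    for (p in pieces) if (p$end > p$start) out[[length(out) + 1]] <- p
  }
  bind_rows(out)
}

#' Tandem-duplicate an interval within an allele walk
#'
#' Duplicates `[lo,hi)` in place in the first row that fully contains it.
#'
#' @param w allele walk tibble.
#' @param chrom,lo,hi the duplicated interval.
#' @export
apply_tandem_dup <- function(w, chrom, lo, hi) {
  i <- which(w$chrom == chrom & w$start <= lo & w$end >= hi)[1]
  if (is.na(i)) abort("tandem duplication interval not contained in one walk row")
  r <- w[i, ]
  a <- r; a$end <- lo
  b <- r; b$start <- lo; b$end <- hi
  c_ <- r; c_$start <- hi
  pieces <- list(a, b, b, c_)
  if (r$strand == "-") pieces <- rev(pieces)
  keep <- purrr::keep(pieces, ~ .x$end > .x$start)
  bind_rows(w[seq_len(i - 1), ], bind_rows(keep), w[seq_len(nrow(w)) > i, ])
}

#' Shatter and randomly re-ligate a region of an allele walk
#'
#' Chromothripsis model: the region `[lo,hi)` (which must lie within a
#' single walk row) is cut at `n_fragments - 1` positions, each fragment
#' retained independently with probability `retain_prob`, and the kept
#' fragments re-joined in random order and orientation. Copy number over
#' the region oscillates between the row's base copy and loss.
#'
#' @param w allele walk tibble.
#' @param chrom,lo,hi shattered region.
#' @param n_fragments number of fragments (>= 2).
#' @param retain_prob per-fragment retention probability.
#' @param snap if positive, cut positions are drawn on this lattice
#'   (keeps desk-scale depth bins breakpoint-aligned).
#' @export
apply_chromothripsis <- function(w, chrom, lo, hi, n_fragments, retain_prob,
                                 snap = 0) {
  stopifnot(n_fragments >= 2, retain_prob >= 0, retain_prob <= 1)
  i <- which(w$chrom == chrom & w$start <= lo & w$end >= hi)[1]
  if (is.na(i)) abort("chromothripsis region not contained in one walk row")
  r <- w[i, ]
  if (snap > 0) {
    grid <- seq(ceiling(lo / snap) * snap, floor(hi / snap) * snap, by = snap)
    grid <- setdiff(grid, c(lo, hi))
    cuts <- sort(sample(grid, min(n_fragments - 1L, length(grid))))
  } else {
    cuts <- sort(runif(n_fragments - 1L, lo, hi))
  }
  bnd <- c(lo, cuts, hi)
  frags <- walk_tbl(chrom, bnd[-length(bnd)], bnd[-1], "+")
  keep <- frags[runif(nrow(frags)) < retain_prob, ]
  if (nrow(keep) > 0) {
    keep <- keep[sample(nrow(keep)), ]
    flip <- runif(nrow(keep)) < 0.5
    keep$strand[flip] <- "-"
  }
  a <- r; a$end <- lo
  c_ <- r; c_$start <- hi
  mid <- keep
  if (r$strand == "-") {
    mid <- walk_reverse_complement(keep)
    pieces <- bind_rows(c_, mid, a)
  } else {
    pieces <- bind_rows(a, mid, c_)
  }
  pieces <- pieces[pieces$end > pieces$start, ]
  bind_rows(w[seq_len(i - 1), ], pieces, w[seq_len(nrow(w)) > i, ])
}

# ---- walk-derived truth --------------------------------------------------

# breakend of the side a traversal leaves a row from (the row's head)
row_head_breakend <- function(r) {
  if (r$strand == "+") list(chrom = r$chrom, pos = r$end, strand = "+")
  else list(chrom = r$chrom, pos = r$start, strand = "-")
}
# breakend of the side a traversal enters a row through (the row's tail)
row_tail_breakend <- function(r) {
  if (r$strand == "+") list(chrom = r$chrom, pos = r$start, strand = "-")
  else list(chrom = r$chrom, pos = r$end, strand = "+")
}

#' Non-reference junctions implied by an allele walk
#'
#' Scans consecutive walk rows and reports every adjacency that is not a
#' reference adjacency, as breakend pairs in BEDPE-style strand
#' convention (`+` = segment side facing higher coordinates).
#'
#' @param w allele walk tibble.
#' @return junction tibble (`chrom1,pos1,strand1,chrom2,pos2,strand2`).
#' @export
walk_junctions <- function(w) {
  out <- list()
  for (i in seq_len(max(0, nrow(w) - 1))) {
    r1 <- w[i, ]; r2 <- w[i + 1, ]
    is_ref <- r1$chrom == r2$chrom && r1$strand == r2$strand &&
      ((r1$strand == "+" && r1$end == r2$start) ||
       (r1$strand == "-" && r1$start == r2$end))
    if (is_ref) next
    # both breakends in attachment convention: the strand names the side
    # of the segment the junction binds ("+" = facing higher coordinates)
    b1 <- row_head_breakend(r1); b2 <- row_tail_breakend(r2)
    out[[length(out) + 1]] <- tibble(
      chrom1 = b1$chrom, pos1 = b1$pos, strand1 = b1$strand,
      chrom2 = b2$chrom, pos2 = b2$pos, strand2 = b2$strand)
  }
  if (length(out) == 0)
    return(normalize_junctions(NULL))
  normalize_junctions(bind_rows(out))
}

#' Copy-number coverage of a set of allele walks
#'
#' @param walks list of walk tibbles.
#' @param chroms tibble `chrom`,`length`.
#' @return function `cov(chrom, lo, hi)` giving mean copy number over an
#'   interval, plus attribute `steps`: per-chrom breakpoint/level tables.
#' @export
walk_coverage <- function(walks, chroms) {
  rows <- bind_rows(walks)
  steps <- lapply(seq_len(nrow(chroms)), function(i) {
    cc <- chroms$chrom[i]
    r <- rows[rows$chrom == cc, ]
    bp <- sort(unique(c(0, chroms$length[i], r$start, r$end)))
    lo <- bp[-length(bp)]; hi <- bp[-1]
    cn <- vapply(seq_along(lo), function(k)
      sum(r$start <= lo[k] & r$end >= hi[k]), 0L)
    tibble(chrom = cc, start = lo, end = hi, cn = cn)
  })
  steps <- bind_rows(steps)
  f <- function(chrom, lo, hi) {
    s <- steps[steps$chrom == chrom & steps$end > lo & steps$start < hi, ]
    if (nrow(s) == 0) return(0)
    wts <- pmin(s$end, hi) - pmax(s$start, lo)
    sum(wts * s$cn) / (hi - lo)
  }
  attr(f, "steps") <- steps
  f
}

# ---- scenario ------------------------------------------------------------

#' Define a telomere-crisis simulation scenario
#'
#' The default scenario emulates a compendium of 13 post-crisis clones
#' over a 120-Mbp metacentric chromosome ("chrA", the rearranged one,
#' p-arm `[0,35 Mbp)`) and a 45-Mbp acrocentric partner ("chrB"):
#' two unrearranged clones, one independent-lineage arm-loss clone, one
#' chromothripsis clone, one arm-loss clone inside the rearranged clade,
#' and an eight-clone BFB lineage accreting fold-back junctions at an
#' 9-10 Mbp focus, most stabilized by fusion to the chrB q-arm. All
#' rearrangements hit the L parental haplotype of the chrA p-arm.
#'
#' @param n_snv_per_branch somatic SNVs accrued on every tree branch.
#' @param depth_sd Gaussian depth noise, CN units (default 0.15).
#' @param dropout probability that a true junction loses all read support
#'   in a clone (creating loose ends).
#' @param presence_error per clone-by-SNV probability of flipping the
#'   biological presence state before counts are emitted (default 0: the
#'   only error source is the sequencing error rate baked into the
#'   emitted counts).
#' @param bin_width depth bin width in bp.
#' @param snv_depth,snp_depth mean sequencing depth at SNV / SNP sites.
#' @param het_spacing spacing of parental heterozygous SNP sites in bp
#'   (default 2000, the approximate genome-wide density of heterozygous
#'   polymorphism-panel sites in a human individual).
#' @param support_mean mean junction-supporting read-pair count.
#' @param snp_noise "poisson" or "none" (deterministic allele counts).
#' @param seed integer seed; all emitted randomness derives from it.
#' @return a `crisis_scenario` object.
#' @export
crisis_scenario <- function(n_snv_per_branch = 250, depth_sd = 0.15,
                            dropout = 0, presence_error = 0,
                            bin_width = 10000, snv_depth = 40, snp_depth = 40,
                            het_spacing = 2000, support_mean = 10,
                            snp_noise = "poisson", seed = 1L) {
  chroms <- tibble(chrom = c("chrA", "chrB"),
                   length = c(120e6, 45e6),
                   centromere = c(35e6, 5e6))
  # q-side anchor of the L haplotype of chrA: q telomere -> centromere
  q_anchor <- walk_tbl("chrA", 35e6, 120e6, "-")
  arm0 <- walk_tbl("chrA", 0, 35e6, "-")          # centromere -> p telomere
  chrB_q <- walk_tbl("chrB", 5e6, 45e6, "+")      # fusion partner arm

  ev <- function(...) list(...)
  fb <- function(pos) ev(type = "fold_back", pos = pos)
  tr <- function(pos) ev(type = "truncate", pos = pos)
  fuse <- ev(type = "stabilizing_fusion")
  # shared interstitial deletion on the stable (q) side of the L haplotype:
  # a lineage marker junction carried by the whole rearranged clade
  dele <- ev(type = "deletion_q", lo = 60e6, hi = 75e6)
  cmth <- ev(type = "chromothripsis", lo = 12e6, hi = 19.9e6,
             n_fragments = 12, retain_prob = 0.5)
  loss <- ev(type = "arm_loss")

  # lineage tree: id, parent, leaf clone label, events on the incoming branch
  tree <- tribble(
    ~id,      ~parent,  ~label, ~events,
    "root",   NA,       NA,     list(),
    "U",      "root",   NA,     list(),
    "Y1",     "U",      "Y1",   list(),
    "Y4",     "U",      "Y4",   list(),
    "Y11",    "root",   "Y11",  list(loss),
    "M",      "root",   NA,     list(dele),
    "Y8",     "M",      "Y8",   list(cmth),
    "MB",     "M",      NA,     list(),
    "Y15",    "MB",     "Y15",  list(loss),
    "BFB",    "MB",     NA,     list(fb(9.0e6)),
    "P78",    "BFB",    NA,     list(),
    "B07",    "P78",    "B07",  list(tr(10.40e6), fuse),
    "B08",    "P78",    "B08",  list(tr(10.45e6)),
    "B2",     "BFB",    NA,     list(fb(9.5e6)),
    "P56",    "B2",     NA,     list(),
    "B05",    "P56",    "B05",  list(tr(10.30e6), fuse),
    "B06",    "P56",    "B06",  list(tr(12.5e6)),
    "B3",     "B2",     NA,     list(fb(9.7e6)),
    "P34",    "B3",     NA,     list(),
    "B03",    "P34",    "B03",  list(tr(10.20e6), fuse),
    "B04",    "P34",    "B04",  list(tr(10.25e6), fuse),
    "B4",     "B3",     NA,     list(fb(9.8e6)),
    "B01",    "B4",     "B01",  list(tr(10.10e6), fuse),
    "B02",    "B4",     "B02",  list(tr(10.15e6), fuse)
  )

  structure(list(
    chroms = chroms, tree = tree, q_anchor = q_anchor, arm0 = arm0,
    partner_arm = chrB_q,
    kataegis = tibble(pos = c(9.0006e6, 9.0012e6, 9.0021e6), branch = "BFB"),
    n_snv_per_branch = n_snv_per_branch, depth_sd = depth_sd,
    dropout = dropout, presence_error = presence_error,
    bin_width = bin_width, snv_depth = snv_depth, snp_depth = snp_depth,
    het_spacing = het_spacing, support_mean = support_mean,
    snp_noise = snp_noise, seed = as.integer(seed)
  ), class = "crisis_scenario")
}

#' @export
print.crisis_scenario <- function(x, ...) {
  leaves <- x$tree$label[!is.na(x$tree$label)]
  cat(sprintf("<crisis_scenario> %d clones, %d tree nodes, seed %d\n",
              length(leaves), nrow(x$tree), x$seed))
  invisible(x)
}

# walk the lineage tree, applying events cumulatively to the arm allele
derive_clone_alleles <- function(sc) {
  tree <- sc$tree
  state <- list()  # id -> list(q = anchor walk, arm = walk, fused = logical)
  state[["root"]] <- list(q = sc$q_anchor, arm = sc$arm0, fused = FALSE)
  for (i in seq_len(nrow(tree))[-1]) {
    id <- tree$id[i]; par <- tree$parent[i]
    st <- state[[par]]
    for (e in tree$events[[i]]) {
      if (identical(e$type, "deletion_q")) {
        st$q <- apply_deletion(st$q, "chrA", e$lo, e$hi)
        next
      }
      st$arm <- switch(e$type,
        fold_back = apply_fold_back(st$arm, e$pos),
        truncate = apply_truncate(st$arm, e$pos),
        deletion = apply_deletion(st$arm, "chrA", e$lo, e$hi),
        tandem_dup = apply_tandem_dup(st$arm, "chrA", e$lo, e$hi),
        chromothripsis = apply_chromothripsis(st$arm, "chrA", e$lo, e$hi,
                                              e$n_fragments, e$retain_prob,
                                              snap = sc$bin_width),
        arm_loss = st$arm[0, ],
        stabilizing_fusion = { st$fused <- TRUE
                               apply_stabilizing_fusion(st$arm, sc$partner_arm) },
        abort(sprintf("unknown event type %s", e$type)))
    }
    state[[id]] <- st
  }
  leaves <- tree$id[!is.na(tree$label)]
  out <- lapply(leaves, function(id) {
    st <- state[[id]]
    derived <- bind_rows(st$q, st$arm)   # full L-chrA derivative
    # the translocated chrB q-arm on the derivative is a gained copy:
    # both parental chrB homologs stay intact (fused clones show the
    # partner-arm gain signature)
    alleles <- list(
      L_chrA = derived,
      R_chrA = walk_tbl("chrA", 0, 120e6, "+"),
      chrB_h1 = walk_tbl("chrB", 0, 45e6, "+"),
      chrB_h2 = walk_tbl("chrB", 0, 45e6, "+"))
    alleles
  })
  names(out) <- tree$label[!is.na(tree$label)]
  out
}

# leaf sets under each tree node
tree_leafsets <- function(tree) {
  kids <- split(tree$id, tree$parent)
  leaves <- function(id) {
    lab <- tree$label[tree$id == id]
    if (!is.na(lab)) return(lab)
    unlist(lapply(kids[[id]], leaves))
  }
  ids <- tree$id[-1]  # skip root (all leaves; not a branch)
  setNames(lapply(ids, leaves), ids)
}

# planted phylogeny as an ape tree (branch lengths = SNV counts)
planted_tree <- function(tree, n_snv) {
  kids <- split(tree$id, tree$parent)
  nwk <- function(id) {
    lab <- tree$label[tree$id == id]
    inner <- if (!is.na(lab)) lab
             else paste0("(", paste(vapply(kids[[id]], nwk, ""), collapse = ","), ")")
    if (id == "root") paste0(inner, ";") else paste0(inner, ":", n_snv)
  }
  ape::read.tree(text = nwk("root"))
}

# ---- emission ------------------------------------------------------------

#' Emit a full synthetic clone-compendium data set
#'
#' Generates, deterministically under the scenario seed: per-clone binned
#' read depth (Gaussian noise in CN units around true total copy
#' number), per-clone junction calls with Poisson read support and
#' optional dropout, somatic SNV allelic counts accreted along the
#' lineage tree, phased parental heterozygous SNP counts, and a ground-
#' truth manifest (allele walks, per-segment copy number, junctions,
#' planted tree, SNV branch labels, phases).
#'
#' @param sc a [crisis_scenario()].
#' @param drop_spec optional tibble of targeted junction dropouts:
#'   columns `clone` plus the six junction breakend columns; matching
#'   junctions get zero support in that clone.
#' @return a list with `depth`, `junctions`, `segment_sets`, `snv`,
#'   `snp`, and `truth`.
#' @export
emit_clone_data <- function(sc, drop_spec = NULL) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(sc$seed)

  alleles <- derive_clone_alleles(sc)
  clones <- names(alleles)
  covs <- lapply(alleles, function(a) walk_coverage(a, sc$chroms))

  # truth junctions per clone
  true_jn <- lapply(alleles, function(a)
    bind_rows(lapply(a, walk_junctions)) %>% distinct())

  # depth bins
  bw <- sc$bin_width
  grid <- bind_rows(lapply(seq_len(nrow(sc$chroms)), function(i) {
    st <- seq(0, sc$chroms$length[i] - bw, by = bw)
    tibble(chrom = sc$chroms$chrom[i], start = st, end = st + bw)
  }))
  depth <- lapply(clones, function(cl) {
    steps <- attr(covs[[cl]], "steps")
    val <- binned_mean_from_steps(steps, grid)
    if (sc$depth_sd > 0) val <- pmax(0, val + rnorm(length(val), 0, sc$depth_sd))
    mutate(grid, value = val)
  })
  names(depth) <- clones

  # per-clone preliminary segmentation: this clone's true CN change points
  segment_sets <- lapply(clones, function(cl) {
    steps <- attr(covs[[cl]], "steps")
    steps %>% group_by(.data$chrom) %>%
      mutate(new = .data$cn != lag(.data$cn, default = -1L),
             grp = cumsum(.data$new)) %>%
      group_by(.data$chrom, .data$grp) %>%
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
      select("chrom", "start", "end") %>% arrange(.data$chrom, .data$start)
  })
  names(segment_sets) <- clones

  # junction support with dropout
  junctions <- lapply(clones, function(cl) {
    j <- true_jn[[cl]]
    if (nrow(j) == 0) return(mutate(j, support = numeric(0)))
    supp <- pmax(1, rpois(nrow(j), sc$support_mean))
    drop <- runif(nrow(j)) < sc$dropout
    if (!is.null(drop_spec)) {
      ds <- drop_spec[drop_spec$clone == cl, ]
      if (nrow(ds) > 0) {
        tgt <- junction_key(normalize_junctions(ds))
        drop <- drop | junction_key(j) %in% tgt
      }
    }
    supp[drop] <- 0
    mutate(j, support = supp)
  })
  names(junctions) <- clones

  # SNVs along the tree
  leafsets <- tree_leafsets(sc$tree)
  branch_ids <- names(leafsets)
  arm_hi <- sc$chroms$centromere[1]
  genome <- sc$chroms
  snv_sites <- list()
  for (b in branch_ids) {
    n <- sc$n_snv_per_branch
    # uniform over the genome, excluding the rearranged arm so that tree
    # presence is not erased by copy-number loss of the carrier allele
    pos <- numeric(0); chrom <- character(0)
    while (length(pos) < n) {
      p <- runif(2 * n, 0, sum(genome$length))
      cc <- ifelse(p < genome$length[1], "chrA", "chrB")
      pp <- ifelse(p < genome$length[1], p, p - genome$length[1])
      keep <- !(cc == "chrA" & pp < arm_hi)
      pos <- c(pos, round(pp[keep])); chrom <- c(chrom, cc[keep])
    }
    snv_sites[[b]] <- tibble(chrom = chrom[seq_len(n)], pos = pos[seq_len(n)],
                             branch = b)
  }
  # kataegis-like cluster on the BFB stem, inside the amplified focus
  kat <- mutate(sc$kataegis, chrom = "chrA")
  snv_sites[["kataegis"]] <- select(kat, "chrom", "pos", "branch")
  snv <- bind_rows(snv_sites) %>%
    arrange(.data$chrom, .data$pos) %>%
    mutate(snv_id = row_number(),
           ref = sample(c("C", "G"), n(), TRUE),
           alt = sample(c("T", "A"), n(), TRUE))

  presence_true <- vapply(clones, function(cl)
    snv$branch %in% c(cl, names(which(vapply(leafsets, function(s) cl %in% s, TRUE)))),
    logical(nrow(snv)))
  presence_emit <- presence_true
  if (sc$presence_error > 0) {
    flip <- matrix(runif(length(presence_emit)) < sc$presence_error,
                   nrow(presence_emit))
    presence_emit <- xor(presence_emit, flip)
  }
  # counts: depth ~ Poisson, alt ~ Binomial(depth, VAF); VAF is 0.5 off
  # the rearranged arm and copy-adjusted inside it (carrier = L allele)
  counts <- lapply(clones, function(cl) {
    dp <- rpois(nrow(snv), sc$snv_depth)
    on_arm <- snv$chrom == "chrA" & snv$pos < arm_hi
    vaf <- rep(0.5, nrow(snv))
    if (any(on_arm)) {
      tot <- vapply(which(on_arm), function(i)
        covs[[cl]]("chrA", snv$pos[i], snv$pos[i] + 1), 0)
      carrier <- vapply(which(on_arm), function(i)
        walk_coverage(alleles[[cl]]["L_chrA"], sc$chroms)("chrA", snv$pos[i], snv$pos[i] + 1), 0)
      vaf[on_arm] <- ifelse(tot > 0, carrier / pmax(tot, 1), 0)
    }
    p <- ifelse(presence_emit[, cl], pmax(vaf, 0.05), 0.001)
    alt <- rbinom(nrow(snv), dp, p)
    tibble(snv_id = snv$snv_id, clone = cl, ref_count = dp - alt, alt_count = alt)
  }) %>% bind_rows()
  snv_tbl <- list(sites = mutate(snv, mq60 = TRUE, evs = 20, pass = TRUE),
                  counts = counts)

  # parental het SNPs with L/R phase
  snp <- bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    pos <- seq(sc$het_spacing / 2, genome$length[i] - 1, by = sc$het_spacing)
    tibble(chrom = genome$chrom[i], pos = pos)
  })) %>%
    mutate(site_id = row_number(),
           ref = sample(c("A", "C", "G", "T"), n(), TRUE),
           alt = sample(c("A", "C", "G", "T"), n(), TRUE),
           ref_is_L = runif(n()) < 0.5)
  half <- sc$snp_depth / 2
  snp_counts <- lapply(clones, function(cl) {
    stepsL <- attr(walk_coverage(alleles[[cl]][c("L_chrA", "chrB_h2")], sc$chroms), "steps")
    stepsR <- attr(walk_coverage(alleles[[cl]][c("R_chrA", "chrB_h1")], sc$chroms), "steps")
    cl_L <- steps_point(stepsL, snp$chrom, snp$pos)
    cl_R <- steps_point(stepsR, snp$chrom, snp$pos)
    nL <- if (sc$snp_noise == "poisson") rpois(nrow(snp), half * cl_L)
          else round(half * cl_L)
    nR <- if (sc$snp_noise == "poisson") rpois(nrow(snp), half * cl_R)
          else round(half * cl_R)
    tibble(site_id = snp$site_id, clone = cl,
           ref_count = ifelse(snp$ref_is_L, nL, nR),
           alt_count = ifelse(snp$ref_is_L, nR, nL))
  }) %>% bind_rows()
  parental <- tibble(site_id = snp$site_id,
                     ref_count = rpois(nrow(snp), half),
                     alt_count = rpois(nrow(snp), half))

  # truth kappa on the prototype segmentation
  comp <- build_prototype(segment_sets, junctions)
  proto <- comp$prototype
  kappa_true <- lapply(clones, function(cl) {
    cn <- vapply(seq_len(nrow(proto$segments)), function(k)
      covs[[cl]](proto$segments$chrom[k], proto$segments$start[k],
                 proto$segments$end[k]), 0)
    tibble(seg_id = proto$segments$seg_id, cn = round(cn))
  })
  names(kappa_true) <- clones

  list(
    depth = depth, junctions = junctions, segment_sets = segment_sets,
    snv = snv_tbl, snp = list(sites = snp, parental = parental,
                              counts = snp_counts),
    truth = list(
      scenario = sc, alleles = alleles, coverage = covs,
      junctions = true_jn,
      kappa = kappa_true, prototype = proto, compendium = comp,
      tree = planted_tree(sc$tree, sc$n_snv_per_branch),
      leafsets = leafsets,
      snv_presence = presence_true, snv_branch = snv$branch,
      snp_phase = select(snp, "site_id", "chrom", "pos", "ref_is_L"))
  )
}

# mean of a per-chrom step function over uniform bins, vectorized via the
# cumulative integral of the step function
binned_mean_from_steps <- function(steps, grid) {
  out <- numeric(nrow(grid))
  for (cc in unique(grid$chrom)) {
    s <- steps[steps$chrom == cc, ]
    sel <- grid$chrom == cc
    if (nrow(s) == 0) next
    s <- s[order(s$start), ]
    cum <- c(0, cumsum(s$cn * (s$end - s$start)))
    Fint <- function(x) {
      i <- pmin(pmax(findInterval(x, s$start), 1L), nrow(s))
      cum[i] + s$cn[i] * (pmin(pmax(x, s$start[i]), s$end[i]) - s$start[i])
    }
    out[sel] <- (Fint(grid$end[sel]) - Fint(grid$start[sel])) /
      (grid$end[sel] - grid$start[sel])
  }
  out
}

# step-function value at single positions, vectorized
steps_point <- function(steps, chrom, pos) {
  out <- numeric(length(pos))
  for (cc in unique(chrom)) {
    s <- steps[steps$chrom == cc, ]
    sel <- chrom == cc
    if (nrow(s) == 0) next
    s <- s[order(s$start), ]
    i <- pmin(pmax(findInterval(pos[sel], s$start), 1L), nrow(s))
    v <- s$cn[i]
    v[pos[sel] < s$start[i] | pos[sel] >= s$end[i]] <- 0
    out[sel] <- v
  }
  out
}

#' Simulate a low-pass depth cohort over the six post-crisis archetypes
#'
#' Emits a clones-by-bins depth matrix for a large cohort drawn from the
#' six qualitative copy-number archetypes the crisis produces:
#' unrearranged, partner-arm (chrB q) gain, p-arm loss, early BFB (one
#' fold-back), full BFB staircase, and chromothripsis.
#'
#' @param n_clones cohort size (default 118).
#' @param depth_sd Gaussian depth noise in CN units.
#' @param bin_width bin width in bp.
#' @param seed integer seed.
#' @return list with `matrix` (clones x bins), `bins`, `labels`.
#' @export
simulate_depth_cohort <- function(n_clones = 118, depth_sd = 0.15,
                                  bin_width = 10000, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sc <- crisis_scenario(bin_width = bin_width, seed = seed)
  base <- list(
    unrearranged = sc$arm0[0, ],
    gain21q = walk_tbl("chrB", 5e6, 45e6, "+"),   # extra partner q-arm
    arm_loss = NULL,                               # handled below
    early_bfb = apply_fold_back(sc$arm0, 9.0e6),
    bfb = Reduce(function(w, p) apply_fold_back(w, p), c(9.5e6, 9.7e6, 9.8e6),
                 apply_fold_back(sc$arm0, 9.0e6)),
    chromothripsis = apply_chromothripsis(sc$arm0, "chrA", 12e6, 22e6, 12, 0.5,
                                          snap = bin_width)
  )
  diploid <- list(walk_tbl("chrA", 0, 120e6, "+"), walk_tbl("chrA", 0, 120e6, "+"),
                  walk_tbl("chrB", 0, 45e6, "+"), walk_tbl("chrB", 0, 45e6, "+"))
  profiles <- lapply(names(base), function(nm) {
    walks <- switch(nm,
      unrearranged = diploid,
      gain21q = c(diploid, list(base$gain21q)),
      arm_loss = c(list(walk_tbl("chrA", 35e6, 120e6, "+")), diploid[-1]),
      c(list(bind_rows(sc$q_anchor, base[[nm]])), diploid[-1]))
    cov <- walk_coverage(walks, sc$chroms)
    attr(cov, "steps")
  })
  names(profiles) <- names(base)
  grid <- bind_rows(lapply(seq_len(nrow(sc$chroms)), function(i) {
    st <- seq(0, sc$chroms$length[i] - bin_width, by = bin_width)
    tibble(chrom = sc$chroms$chrom[i], start = st, end = st + bin_width)
  }))
  means <- vapply(profiles, binned_mean_from_steps, numeric(nrow(grid)),
                  grid = grid)
  labels <- rep(names(base), length.out = n_clones)
  mat <- t(vapply(seq_len(n_clones), function(i)
    pmax(0, means[, labels[i]] + rnorm(nrow(grid), 0, depth_sd)),
    numeric(nrow(grid))))
  rownames(mat) <- sprintf("C%03d", seq_len(n_clones))
  list(matrix = mat, bins = grid, labels = setNames(labels, rownames(mat)))
}
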
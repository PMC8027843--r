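test_that("fold-back cycles double retained copy and build staircases", {
  arm <- tibble(chrom = "chrA", start = 0, end = 35e6, strand = "-")
  # one cycle retaining [9M,35M): copy 2 there, distal part lost
  w1 <- apply_fold_back(arm, 9e6)
  cov <- walk_coverage(list(w1), tibble(chrom = "chrA", length = 120e6))
  expect_equal(cov("chrA", 9e6, 35e6), 2)
  expect_equal(cov("chrA", 0, 9e6), 0)

  # k cycles retaining a proximal focus: copy 2^k, exactly
  for (k in 1:4) {
    w <- arm
    cuts <- c(20e6, 21e6, 20.5e6, 20.3e6)[seq_len(k)]
    for (b in cuts) w <- apply_fold_back(w, b)
    covk <- walk_coverage(list(w), tibble(chrom = "chrA", length = 120e6))
    # [20,20.3M) survives every cut, so it doubles each cycle
    expect_equal(covk("chrA", 20.05e6, 20.25e6), 2^k)
  }

  # clustered cycles make a staircase that never increases away from the focus
  w <- arm
  for (b in c(9e6, 9.5e6, 9.7e6)) w <- apply_fold_back(w, b)
  st <- attr(walk_coverage(list(w), tibble(chrom = "chrA", length = 120e6)),
             "steps") %>% filter(end <= 35e6, cn > 0) %>% arrange(start)
  expect_equal(st$cn, c(8, 4, 2))   # 2^3 at the focus, halving proximally
  expect_true(all(diff(st$cn) <= 0))
  expect_error(apply_fold_back(arm, 40e6), "outside")
})

test_that("chromothripsis retains fragments at the requested rate", {
  arm <- tibble(chrom = "chrA", start = 0, end = 35e6, strand = "-")
  chroms <- tibble(chrom = "chrA", length = 120e6)
  set.seed(1)
  # retain everything: copy numbers unchanged, junctions may reorder
  w1 <- apply_chromothripsis(arm, "chrA", 12e6, 22e6, 10, 1)
  cov1 <- walk_coverage(list(w1), chroms)
  expect_equal(cov1("chrA", 12e6, 22e6), 1)
  # retain nothing: clean deletion
  w0 <- apply_chromothripsis(arm, "chrA", 12e6, 22e6, 10, 0)
  cov0 <- walk_coverage(list(w0), chroms)
  expect_equal(cov0("chrA", 12e6, 22e6), 0)
  expect_equal(cov0("chrA", 0, 12e6), 1)

  # retention fraction within binomial bounds across seeds
  set.seed(99)
  fr <- replicate(40, {
    w <- apply_chromothripsis(arm, "chrA", 12e6, 22e6, 20, 0.5)
    walk_coverage(list(w), chroms)("chrA", 12e6, 22e6)
  })
  expect_gt(mean(fr), 0.5 - 2 * sqrt(0.25 / 20 / 40))
  expect_lt(mean(fr), 0.5 + 2 * sqrt(0.25 / 20 / 40))
})

test_that("emitted data are deterministic under the seed", {
  sc <- crisis_scenario(seed = 7, n_snv_per_branch = 20)
  e1 <- emit_clone_data(sc)
  e2 <- emit_clone_data(sc)
  expect_identical(e1$depth, e2$depth)
  expect_identical(e1$junctions, e2$junctions)
  expect_identical(e1$snv, e2$snv)
  expect_identical(e1$snp, e2$snp)
  e3 <- emit_clone_data(crisis_scenario(seed = 8, n_snv_per_branch = 20))
  expect_false(identical(e1$depth, e3$depth))
})

test_that("truth manifests are self-consistent", {
  sc <- crisis_scenario(depth_sd = 0, dropout = 0, seed = 13,
                        n_snv_per_branch = 20)
  em <- emit_clone_data(sc)
  g <- em$truth$prototype
  segs <- g$segments
  uids <- graph_edges(g, FALSE)
  ed <- g$edges

  for (cl in c("Y1", "Y11", "Y8", "B01", "B08")) {
    walks <- em$truth$alleles[[cl]]
    # vertex copy from walk coverage equals the manifest
    cov <- walk_coverage(walks, sc$chroms)
    cn <- vapply(seq_len(nrow(segs)), function(i)
      cov(segs$chrom[i], segs$start[i], segs$end[i]), 0)
    expect_equal(round(cn), em$truth$kappa[[cl]]$cn)

    # edge copy derived by counting walk adjacencies balances the graph
    jn_counts <- bind_rows(lapply(walks, walk_junctions)) %>%
      count(chrom1, pos1, strand1, chrom2, pos2, strand2)
    var_eids <- ed %>% filter(kind == "variant") %>% distinct(uid, .keep_all = TRUE)
    edge_cn <- tibble(uid = uids$uid, cn = 0)
    for (i in seq_len(nrow(var_eids))) {
      # identify the junction by its two breakend sides
      v1 <- var_eids$from_vid[i]; v2 <- crisisgraph:::rc_vid(var_eids$to_vid[i])
      be <- function(v) {
        s <- segs[segs$seg_id == crisisgraph:::seg_of_vid(v), ]
        if (crisisgraph:::is_fwd_vid(v)) c(s$chrom, s$end, "+") else c(s$chrom, s$start, "-")
      }
      b1 <- be(v1); b2 <- be(v2)
      jk <- crisisgraph:::junction_key(crisisgraph:::normalize_junctions(
        tibble(chrom1 = b1[1], pos1 = as.numeric(b1[2]), strand1 = b1[3],
               chrom2 = b2[1], pos2 = as.numeric(b2[2]), strand2 = b2[3])))
      hit <- jn_counts[crisisgraph:::junction_key(jn_counts) == jk, ]
      if (nrow(hit)) edge_cn$cn[edge_cn$uid == var_eids$uid[i]] <- hit$n
    }
    # reference edges: traversals crossing each internal boundary, plus
    # reference adjacencies between consecutive walk rows at the boundary
    ref_eids <- ed %>% filter(kind == "reference") %>% distinct(uid, .keep_all = TRUE)
    rows <- bind_rows(walks)
    ref_adj <- bind_rows(lapply(walks, function(w) {
      if (nrow(w) < 2) return(NULL)
      bind_rows(lapply(seq_len(nrow(w) - 1), function(i) {
        r1 <- w[i, ]; r2 <- w[i + 1, ]
        ok <- r1$chrom == r2$chrom && r1$strand == r2$strand &&
          ((r1$strand == "+" && r1$end == r2$start) ||
           (r1$strand == "-" && r1$start == r2$end))
        if (!ok) return(NULL)
        tibble(chrom = r1$chrom,
               pos = if (r1$strand == "+") r1$end else r1$start)
      }))
    }))
    for (i in seq_len(nrow(ref_eids))) {
      s <- segs[segs$seg_id == crisisgraph:::seg_of_vid(ref_eids$from_vid[i]), ]
      b <- s$end
      n_cross <- sum(rows$chrom == s$chrom & rows$start < b & rows$end > b)
      n_adj <- if (nrow(ref_adj)) sum(ref_adj$chrom == s$chrom & ref_adj$pos == b)
               else 0L
      edge_cn$cn[edge_cn$uid == ref_eids$uid[i]] <- n_cross + n_adj
    }
    # loose edges: non-telomeric walk termini at each side
    loose <- ed %>% filter(kind == "loose", !is.na(from_vid))
    term <- bind_rows(lapply(walks, function(w) {
      if (nrow(w) == 0) return(NULL)
      bind_rows(as_tibble(crisisgraph:::row_head_breakend(w[nrow(w), ])),
                as_tibble(crisisgraph:::row_tail_breakend(w[1, ])))
    }))
    chr_len <- setNames(sc$chroms$length, sc$chroms$chrom)
    term <- term[!(term$pos == 0 | term$pos == chr_len[term$chrom]), ]
    for (i in seq_len(nrow(loose))) {
      v <- loose$from_vid[i]
      s <- segs[segs$seg_id == crisisgraph:::seg_of_vid(v), ]
      pos <- if (crisisgraph:::is_fwd_vid(v)) s$end else s$start
      strand <- if (crisisgraph:::is_fwd_vid(v)) "+" else "-"
      n <- sum(term$chrom == s$chrom & term$pos == pos & term$strand == strand)
      if (n > 0) edge_cn$cn[edge_cn$uid == loose$uid[i]] <- n
    }
    kap <- copy_assignment(g, em$truth$kappa[[cl]]$cn, edge_cn)
    expect_true(check_balance(g, kap))
  }
})

test_that("SNV presence is hereditary along the planted tree", {
  sc <- crisis_scenario(seed = 5, n_snv_per_branch = 30, presence_error = 0)
  em <- emit_clone_data(sc)
  pres <- em$truth$snv_presence
  leafsets <- em$truth$leafsets
  branches <- em$truth$snv_branch
  for (b in unique(branches)) {
    carriers <- colnames(pres)[colSums(pres[branches == b, , drop = FALSE]) > 0]
    expect_true(all(carriers %in% leafsets[[b]]))
    # presence equals the full clade (no back-mutation)
    expect_true(all(apply(pres[branches == b, leafsets[[b]], drop = FALSE], 1, all)))
  }
})

test_that("the cohort generator emits separable archetypes", {
  coh <- simulate_depth_cohort(n_clones = 12, depth_sd = 0, seed = 3)
  expect_equal(dim(coh$matrix), c(12, nrow(coh$bins)))
  expect_length(coh$labels, 12)
  expect_equal(length(unique(coh$labels)), 6)
  # noiseless profiles of the same archetype are identical, others distinct
  same <- which(coh$labels == coh$labels[1])
  expect_true(all(coh$matrix[same[1], ] == coh$matrix[same[2], ]))
  other <- which(coh$labels != coh$labels[1])[1]
  expect_false(all(coh$matrix[1, ] == coh$matrix[other, ]))
})
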
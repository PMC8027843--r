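test_that("minimal walk enumeration matches hand enumeration on toys", {
  # linear chromosome, kappa 1: the chromosome itself, no cycles
  g <- genome_graph(tibble(chrom = "chr1", start = c(0, 3000, 7000),
                           end = c(3000, 7000, 10000)))
  u <- graph_edges(g, FALSE)
  k1 <- copy_assignment(g, 1, tibble(uid = u$uid[u$kind == "reference"], cn = 1))
  ws <- enumerate_minimal_walks(g, k1)
  expect_length(ws$walks, 1)
  expect_false(ws$walks[[1]]$closed)

  # deletion toy: exactly the paths A.B.C and A.C
  toy <- deletion_toy()
  kd <- copy_assignment(toy$graph, c(2, 1, 2),
                        tibble(uid = c(toy$ref_uids, toy$var_uid), cn = c(1, 1, 1)))
  wsd <- enumerate_minimal_walks(toy$graph, kd)
  expect_length(wsd$walks, 2)
  expect_true(all(!vapply(wsd$walks, `[[`, TRUE, "closed")))
  lens <- sort(vapply(wsd$walks, function(w) length(w$vids), 0))
  expect_equal(lens, c(2, 3))

  # tandem duplication on B: one path and one cycle
  td <- tibble(chrom1 = "chr1", pos1 = 7000, strand1 = "+",
               chrom2 = "chr1", pos2 = 3000, strand2 = "-")
  gt <- genome_graph(tibble(chrom = "chr1", start = 0, end = 10000), td)
  ut <- graph_edges(gt, FALSE)
  kt <- copy_assignment(gt, c(1, 2, 1),
                        tibble(uid = ut$uid[ut$kind != "loose"], cn = 1))
  wst <- enumerate_minimal_walks(gt, kt)
  closed <- vapply(wst$walks, `[[`, TRUE, "closed")
  expect_equal(sum(closed), 1)
  expect_equal(sum(!closed), 1)
})

test_that("enumeration is canonical under reverse complement", {
  set.seed(11)
  for (i in 1:6) {
    g <- random_toy_graph(n_seg = sample(2:4, 1), n_var = sample(0:2, 1))
    # a balanced assignment via a cheap fit on integer depth
    cn <- sample(1:2, 1)
    fs <- fit_single(g, mkbins("chr1", 0, 10000, 250, cn),
                     cfg = balance_config(slack_penalty = 1, cn_cap = 4))
    kap <- fs$assignments$clone
    ws1 <- enumerate_minimal_walks(g, kap)
    ws2 <- enumerate_minimal_walks(reverse_complement(g), kap)
    keys1 <- sort(vapply(ws1$walks, `[[`, "", "key"))
    keys2 <- sort(vapply(ws2$walks, `[[`, "", "key"))
    expect_identical(keys1, keys2)
  }
})

test_that("joint decomposition is conserved and matches brute force on toys", {
  toy <- deletion_toy()
  kd <- copy_assignment(toy$graph, c(2, 1, 2),
                        tibble(uid = c(toy$ref_uids, toy$var_uid), cn = c(1, 1, 1)))
  wsd <- enumerate_minimal_walks(toy$graph, kd)
  dec <- decompose_joint(toy$graph, list(c1 = kd), list(c1 = wsd))
  expect_identical(dec$status, "optimal")
  expect_equal(dec$objective, 2)
  expect_equal(walk_conservation_gap(wsd, dplyr::filter(dec$phi, clone == "c1"), kd), 0)

  # brute force over all phi <= 4 confirms the optimum
  brute <- function(ws, kap, max_phi = 4) {
    nw <- length(ws$walks)
    grid <- do.call(expand.grid, rep(list(0:max_phi), nw))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      phi <- tibble(walk_id = seq_len(nw), phi = as.integer(grid[r, ]))
      if (walk_conservation_gap(ws, phi, kap) == 0)
        best <- min(best, sum(phi$phi > 0))
    }
    best
  }
  expect_equal(dec$objective, brute(wsd, kd))

  # two clones sharing the allele: unique walks counted once
  dec2 <- decompose_joint(toy$graph, list(a = kd, b = kd), list(a = wsd, b = wsd))
  expect_equal(dec2$objective, 2)
  for (cl in c("a", "b"))
    expect_equal(walk_conservation_gap(wsd, dplyr::filter(dec2$phi, clone == cl), kd), 0)

  # a single linear graph: one walk, phi = 1
  g <- genome_graph(tibble(chrom = "chr1", start = 0, end = 5000))
  k <- copy_assignment(g, 1)
  ws <- enumerate_minimal_walks(g, k)
  d1 <- decompose_joint(g, list(x = k), list(x = ws))
  expect_equal(d1$objective, 1)
})

test_that("brute force agrees on randomized balanced toys", {
  set.seed(5)
  done <- 0
  for (i in 1:12) {
    g <- random_toy_graph(n_seg = sample(2:4, 1), n_var = sample(1:2, 1))
    fs <- fit_single(g, mkbins("chr1", 0, 10000, 250, 2),
                     cfg = balance_config(slack_penalty = 1, cn_cap = 3))
    if (fs$solver_status != "optimal") next
    kap <- fs$assignments$clone
    ws <- tryCatch(enumerate_minimal_walks(g, kap, max_walks = 8),
                   error = function(e) NULL)
    if (is.null(ws) || length(ws$walks) == 0 || length(ws$walks) > 8) next
    dec <- decompose_joint(g, list(c1 = kap), list(c1 = ws))
    if (dec$status != "optimal") next   # kappa not expressible by minimal walks
    expect_equal(walk_conservation_gap(ws, dplyr::filter(dec$phi, clone == "c1"), kap), 0)
    nw <- length(ws$walks)
    grid <- do.call(expand.grid, rep(list(0:3), nw))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      phi <- tibble(walk_id = seq_len(nw), phi = as.integer(grid[r, ]))
      if (walk_conservation_gap(ws, phi, kap) == 0)
        best <- min(best, sum(phi$phi > 0))
    }
    expect_equal(dec$objective, best)
    done <- done + 1
  }
  expect_gte(done, 3)
})

test_that("splicing a duplication cycle rebuilds the tandem allele", {
  td <- tibble(chrom1 = "chr1", pos1 = 7000, strand1 = "+",
               chrom2 = "chr1", pos2 = 3000, strand2 = "-")
  gt <- genome_graph(tibble(chrom = "chr1", start = 0, end = 10000), td)
  ut <- graph_edges(gt, FALSE)
  kt <- copy_assignment(gt, c(1, 2, 1),
                        tibble(uid = ut$uid[ut$kind != "loose"], cn = 1))
  wst <- enumerate_minimal_walks(gt, kt)
  dec <- decompose_joint(gt, list(c = kt), list(c = wst))
  cyc <- which(vapply(wst$walks, `[[`, TRUE, "closed"))
  pth <- which(!vapply(wst$walks, `[[`, TRUE, "closed"))
  comb <- combine_walks(wst, dplyr::filter(dec$phi, clone == "c")[, c("walk_id", "phi")],
                        merges = tibble(cycle = cyc, path = pth, anchor_seg = 2))
  iv <- walk_as_intervals(gt, comb$haplotypes[[1]])
  # A.B.B.C merges to [0,7000)+ then [3000,10000)+
  expect_equal(iv$start, c(0, 3000))
  expect_equal(iv$end, c(7000, 10000))
  expect_equal(iv$strand, c("+", "+"))
  expect_equal(unname(comb$phi_left[as.character(cyc)]), 0)

  # no merges: paths pass through unchanged
  comb0 <- combine_walks(wst, dplyr::filter(dec$phi, clone == "c")[, c("walk_id", "phi")])
  expect_length(comb0$haplotypes, 1)
  expect_identical(comb0$haplotypes[[1]]$vids, wst$walks[[pth]]$vids)

  # errors: anchor not shared; exhausted copies
  expect_error(combine_walks(wst, dplyr::filter(dec$phi, clone == "c")[, c("walk_id", "phi")],
                             merges = tibble(cycle = cyc, path = pth, anchor_seg = 1)),
               "anchor")
  two <- tibble(cycle = c(cyc, cyc), path = c(pth, pth), anchor_seg = c(2, 2))
  expect_error(combine_walks(wst, dplyr::filter(dec$phi, clone == "c")[, c("walk_id", "phi")],
                             merges = two), "no copies")
})
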
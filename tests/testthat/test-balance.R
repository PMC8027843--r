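test_that("depth residual is the bin-weighted squared error", {
  g1 <- genome_graph(tibble(chrom = "chr1", start = 0, end = 2000))
  # 4 bins at 1.5 against integer copy 2 -> 4 * 0.25
  expect_equal(as.numeric(depth_residual(g1, copy_assignment(g1, 2),
                                         mkbins("chr1", 0, 2000, 500, 1.5))), 1)
  # exact integer depth -> zero residual
  expect_equal(as.numeric(depth_residual(g1, copy_assignment(g1, 2),
                                         mkbins("chr1", 0, 2000, 500, 2))), 0)
  # unchanged by the reverse complement of the graph
  toy <- deletion_toy()
  bins <- piecewise_bins("chr1", c(0, 3000, 7000, 10000), c(2, 1, 2), 500)
  k <- copy_assignment(toy$graph, c(2, 1, 2))
  expect_equal(as.numeric(depth_residual(toy$graph, k, bins)),
               as.numeric(depth_residual(reverse_complement(toy$graph), k, bins)))
})

test_that("single-sample fit solves the deletion toy", {
  toy <- deletion_toy()
  bins <- piecewise_bins("chr1", c(0, 3000, 7000, 10000), c(2, 1, 2), 10)
  cfg <- balance_config(slack_penalty = 100, cn_cap = 4)
  fs <- fit_single(toy$graph, bins, cfg = cfg)
  expect_identical(fs$solver_status, "optimal")
  expect_equal(fs$assignments$clone$vertex$cn, c(2, 1, 2))
  del_cn <- fs$assignments$clone$edge$cn[
    match(toy$var_uid, fs$assignments$clone$edge$uid)]
  expect_equal(del_cn, 1)
  expect_equal(fs$unique_loose_ends, 0)
  expect_equal(fs$objective, 0)
  check_balance(toy$graph, fs$assignments$clone)

  # unsupported deletion: the optimum buys one loose end per flank
  fs2 <- fit_single(toy$graph, bins, bounds = tibble(uid = toy$var_uid, open = FALSE),
                    cfg = cfg)
  expect_equal(fs2$unique_loose_ends, 2)
  expect_equal(fs2$objective, 2 * 100)
  expect_equal(fs2$assignments$clone$vertex$cn, c(2, 1, 2))

  # flat diploid genome, no variants
  gf <- genome_graph(tibble(chrom = "chr1", start = 0, end = 10000))
  ff <- fit_single(gf, mkbins("chr1", 0, 10000, 100, 2), cfg = cfg)
  expect_equal(ff$assignments$clone$vertex$cn, 2)
  expect_equal(ff$objective, 0)
})

test_that("single-sample fit matches the exhaustive oracle", {
  toy <- deletion_toy()
  set.seed(123)
  for (rep in 1:6) {
    vals <- round(runif(3, 0, 3.4), 2)
    bins <- piecewise_bins("chr1", c(0, 3000, 7000, 10000), vals, 250)
    open_var <- runif(1) < 0.6
    slack <- sample(c(1, 5, 50), 1)
    cfg <- balance_config(slack_penalty = slack, cn_cap = 4)
    bounds <- tibble(uid = toy$var_uid, open = open_var)
    fs <- fit_single(toy$graph, bins, bounds, cfg)
    stats <- map_bins_to_segments(toy$graph, bins)
    uids <- graph_edges(toy$graph, FALSE)
    open <- setNames(rep(TRUE, nrow(uids)), uids$uid)
    open[as.character(toy$var_uid)] <- open_var
    expect_equal(fs$objective,
                 oracle_single_objective(toy$graph, stats, open, slack, cap = 4),
                 tolerance = 1e-8)
    check_balance(toy$graph, fs$assignments$clone)
  }
})

test_that("edge bounds derive from junction support", {
  del <- deletion_toy()$junction
  segs <- tibble(chrom = "chr1", start = 0, end = 10000)
  comp <- build_prototype(list(A = segs, B = segs), list(A = del, B = del))
  uid <- unique(comp$junction_support$uid)
  b <- derive_edge_bounds(comp, tibble(clone = c("A", "B"), uid = uid,
                                       support = c(0, 3)), min_support = 1)
  expect_false(b$open[b$clone == "A"])
  expect_true(b$open[b$clone == "B"])
  expect_error(derive_edge_bounds(comp, tibble(clone = "A", uid = 999L,
                                               support = 1)), "absent")
  expect_error(derive_edge_bounds(comp, tibble(clone = "A", uid = uid,
                                               support = -1)), "nonnegative")
})

test_that("joint fit pools identical unsupported breakpoints across clones", {
  del <- deletion_toy()$junction
  segs <- tibble(chrom = "chr1", start = 0, end = 10000)
  comp <- build_prototype(list(A = segs, B = segs), list(A = del, B = del))
  bins <- piecewise_bins("chr1", c(0, 3000, 7000, 10000), c(2, 1, 2), 10)
  bl <- list(A = bins, B = bins)
  uid <- unique(comp$junction_support$uid)
  closed <- tibble(clone = c("A", "B"), uid = uid, open = FALSE)

  fj <- fit_joint(comp, bl, closed, balance_config(lambda = 100, cn_cap = 4))
  expect_identical(fj$solver_status, "optimal")
  # two unique prototype loose ends (one per flank), however many clones
  expect_equal(fj$unique_loose_ends, 2)
  expect_equal(fj$objective, 200)
  expect_equal(fj$assignments$A$vertex$cn, c(2, 1, 2))
  expect_equal(fj$assignments$B$vertex$cn, c(2, 1, 2))
  for (kap in fj$assignments) check_balance(comp$prototype, kap)

  # independent fits pay the loose ends once per clone
  fi <- fit_independent(comp, bl, closed, balance_config(slack_penalty = 100, cn_cap = 4))
  expect_equal(attr(fi, "total_loose_ends"), 4)

  # fully supported junctions: clean recovery, no loose ends
  fj2 <- fit_joint(comp, bl, NULL, balance_config(lambda = 100, cn_cap = 4))
  expect_equal(fj2$unique_loose_ends, 0)
  expect_equal(fj2$objective, 0)

  # n = 1 degenerates to a per-loose-end penalized single fit
  comp1 <- build_prototype(list(A = segs), list(A = del))
  f1 <- fit_joint(comp1, list(A = bins), tibble(clone = "A", uid = uid, open = FALSE),
                  balance_config(lambda = 100, cn_cap = 4))
  expect_equal(f1$unique_loose_ends, 2)
  expect_equal(f1$objective, 200)
})

test_that("increasing lambda never increases the unique loose-end count", {
  del <- deletion_toy()$junction
  segs <- tibble(chrom = "chr1", start = 0, end = 10000)
  comp <- build_prototype(list(A = segs, B = segs), list(A = del, B = del))
  bins <- piecewise_bins("chr1", c(0, 3000, 7000, 10000), c(2, 1, 2), 25)
  bl <- list(A = bins, B = bins)
  uid <- unique(comp$junction_support$uid)
  closed <- tibble(clone = c("A", "B"), uid = uid, open = FALSE)
  counts <- vapply(c(1, 100, 1e5), function(lam)
    fit_joint(comp, bl, closed, balance_config(lambda = lam, cn_cap = 4))$unique_loose_ends,
    0)
  expect_true(all(diff(counts) <= 0))
  # at extreme lambda the fit flattens instead of buying loose ends
  expect_equal(counts[3], 0)
})

test_that("tidy/glance/autoplot expose the fit", {
  toy <- deletion_toy()
  bins <- piecewise_bins("chr1", c(0, 3000, 7000, 10000), c(2, 1, 2), 100)
  fs <- fit_single(toy$graph, bins, cfg = balance_config(cn_cap = 4))
  td <- tidy(fs)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("clone", "seg_id", "chrom", "start", "end", "cn"))
  gl <- glance(fs)
  expect_equal(gl$solver_status, "optimal")
  expect_s3_class(autoplot(fs), "ggplot")
})
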
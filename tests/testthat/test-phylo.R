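# direct Bayes evaluation, independent of the package implementation
direct_posterior <- function(alt, dp, prior, p1, p0) {
  a <- prior * dbinom(alt, dp, p1)
  b <- (1 - prior) * dbinom(alt, dp, p0)
  a / (a + b)
}

test_that("presence posterior matches direct Bayes evaluation", {
  sites <- tibble(snv_id = 1:3, chrom = "chr1", pos = c(100, 200, 300),
                  ref = "C", alt = "T")
  counts <- bind_rows(
    tibble(snv_id = 1:3, clone = "a", ref_count = c(100, 50, 60), alt_count = c(0, 50, 0)),
    tibble(snv_id = 1:3, clone = "b", ref_count = c(60, 98, 30), alt_count = c(40, 2, 30)))
  m <- snv_matrix(sites, counts)
  pm <- presence_posterior(m, p_present = 0.5, p_absent = 0.001)
  # zero alt of depth 100 -> absent
  expect_lt(pm$posterior[1, "a"], 0.5)
  expect_false(pm$presence[1, "a"])
  # alt = depth/2 -> present even under a weak prior
  expect_gt(pm$posterior[2, "a"], 0.5)
  # agreement with the closed form at the aggregated prior
  prior <- (0 + 40) / (100 + 100)
  expect_equal(unname(pm$posterior[1, "a"]),
               direct_posterior(0, 100, prior, 0.5, 0.001), tolerance = 1e-12)
  prior2 <- (50 + 2) / (100 + 100)
  expect_equal(unname(pm$posterior[2, "b"]),
               direct_posterior(2, 100, prior2, 0.5, 0.001), tolerance = 1e-12)
})

test_that("posterior is monotone in alt count and handles zero depth", {
  sites <- tibble(snv_id = 1, chrom = "chr1", pos = 1, ref = "C", alt = "T")
  post <- vapply(0:30, function(a) {
    counts <- bind_rows(
      tibble(snv_id = 1, clone = "a", ref_count = 30 - a, alt_count = a),
      tibble(snv_id = 1, clone = "b", ref_count = 20, alt_count = 10))
    presence_posterior(snv_matrix(sites, counts))$posterior[1, "a"]
  }, 0)
  expect_true(all(diff(post) >= -1e-12))
  # zero depth falls back to the prior
  counts0 <- bind_rows(
    tibble(snv_id = 1, clone = "a", ref_count = 0, alt_count = 0),
    tibble(snv_id = 1, clone = "b", ref_count = 10, alt_count = 10))
  pm0 <- presence_posterior(snv_matrix(sites, counts0))
  expect_equal(unname(pm0$posterior[1, "a"]), unname(pm0$prior[1]))
})

test_that("hard site filters drop failing sites", {
  sites <- tibble(snv_id = 1:4, chrom = "chr1", pos = 1:4, ref = "C", alt = "T",
                  mq60 = c(TRUE, FALSE, TRUE, TRUE),
                  evs = c(20, 20, 5, 20), pass = TRUE)
  counts <- tidyr::expand_grid(snv_id = 1:4, clone = c("a", "b")) %>%
    mutate(ref_count = 20, alt_count = c(10, 10, 10, 10, 10, 10, 2, 2))
  f <- apply_site_filters(snv_matrix(sites, counts))
  expect_equal(f$sites$snv_id, 1L)  # 2 fails MQ, 3 fails score, 4 fails alt total
})

test_that("neighbor joining is exact on additive distances", {
  # 3 clones: closed-form branch lengths from pairwise sums
  m3 <- rbind(a = c(1, 1, 0, 0, 0), b = c(1, 0, 1, 1, 0), c = c(0, 0, 0, 1, 1))
  tr3 <- neighbor_joining(m3)
  expect_s3_class(tr3, "phylo")
  d <- as.matrix(dist(m3, method = "manhattan"))
  dt <- ape::cophenetic.phylo(tr3)[rownames(d), colnames(d)]
  expect_equal(unname(dt), unname(d), tolerance = 1e-9)

  # 4 clones from a planted tree: topology and lengths recovered exactly
  planted <- ape::read.tree(text = "((a:3,b:2):4,(c:5,d:1):2);")
  dd <- ape::cophenetic.phylo(planted)
  tr4 <- ape::nj(as.dist(dd))
  expect_equal(phangorn::RF.dist(ape::unroot(planted), tr4), 0)
  # and via a binary matrix realizing those distances: accrete SNVs per branch
  set.seed(2)
  leaf_sets <- list(a = "a", b = "b", ab = c("a", "b"), c = "c", d = "d",
                    cd = c("c", "d"))
  nmut <- c(a = 3, b = 2, ab = 4, c = 5, d = 1, cd = 2)
  cols <- unlist(lapply(names(leaf_sets), function(b)
    replicate(nmut[b], leaf_sets[[b]], simplify = FALSE)), recursive = FALSE)
  mat <- vapply(cols, function(s) c(a = "a", b = "b", c = "c", d = "d") %in% s,
                logical(4))
  rownames(mat) <- c("a", "b", "c", "d")
  trb <- neighbor_joining(mat)
  expect_equal(phangorn::RF.dist(ape::unroot(planted), trb), 0)
  expect_error(neighbor_joining(m3[1:2, ]), "at least 3")
})

test_that("branch assignment finds exact clades and respects the threshold", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  sites <- tibble(snv_id = 1:3, chrom = "chr1", pos = 1:3, ref = "C", alt = "T")
  pres <- rbind(c(TRUE, TRUE, FALSE, FALSE),    # the ab clade exactly
                c(TRUE, FALSE, FALSE, FALSE),   # leaf a
                c(TRUE, FALSE, TRUE, FALSE))    # no clade within 0.1
  colnames(pres) <- c("a", "b", "c", "d")
  pm <- structure(list(presence = pres, posterior = pres * 1, sites = sites),
                  class = "presence_matrix")
  asg <- assign_snvs_to_branches(tree, pm, max_jaccard = 0.1)
  inc <- branch_incidence(tree)
  tips <- tree$tip.label
  set1 <- tips[inc[[asg$branch[1]]]]
  expect_true(setequal(set1, c("a", "b")) || setequal(set1, c("c", "d")))
  expect_equal(asg$jaccard[1], 0)
  set2 <- tips[inc[[asg$branch[2]]]]
  expect_true(setequal(set2, "a") || setequal(set2, c("b", "c", "d")))
  expect_true(is.na(asg$branch[3]))
  # at threshold infinity everything nonzero is assigned; tightening only removes
  asg_inf <- assign_snvs_to_branches(tree, pm, max_jaccard = Inf)
  expect_true(all(!is.na(asg_inf$branch)))
  expect_true(all(which(!is.na(asg$branch)) %in% which(!is.na(asg_inf$branch))))
})

test_that("rainfall clusters match the worked example and partition the input", {
  snvs <- tibble(chrom = "chr1", pos = c(100, 1500, 10000, 11000, 11900))
  cl <- rainfall_clusters(snvs, max_gap_bp = 2000, min_run = 2)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n, c(2, 3))
  expect_equal(cl$start, c(100, 10000))
  expect_equal(cl$end, c(1500, 11900))
  # single SNV: none
  expect_equal(nrow(rainfall_clusters(tibble(chrom = "chr1", pos = 5))), 0)
  expect_equal(nrow(rainfall_clusters(tibble(chrom = character(), pos = numeric()))), 0)

  # property vs brute force on random sets; clusters partition the SNVs
  brute <- function(pos, gap, min_run) {
    pos <- sort(pos)
    runs <- split(pos, cumsum(c(TRUE, diff(pos) >= gap)))
    runs[vapply(runs, length, 0) >= min_run]
  }
  set.seed(9)
  for (i in 1:50) {
    pos <- sort(sample(1:50000, sample(2:30, 1)))
    cl <- rainfall_clusters(tibble(chrom = "chrX", pos = pos), 2000, 2)
    bf <- brute(pos, 2000, 2)
    expect_equal(nrow(cl), length(bf))
    if (nrow(cl) > 0) {
      expect_equal(unname(cl$n), unname(vapply(bf, length, 0)))
      member <- unlist(cl$positions)
      expect_equal(length(member), length(unique(member)))  # no SNV in two clusters
      expect_true(all(member %in% pos))
    }
  }
})
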
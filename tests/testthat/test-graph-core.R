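test_that("prototype construction refines breakpoints across clones", {
  # identity case: one segment, no junctions
  g1 <- genome_graph(tibble(chrom = "chr1", start = 0, end = 10000))
  expect_equal(nrow(g1$segments), 1)
  expect_equal(sum(g1$edges$kind == "variant"), 0)
  expect_equal(nrow(g1$termini), 2)

  # disjoint refinement of two clones' breakpoints
  comp <- build_prototype(list(
    A = tibble(chrom = "chr1", start = c(0, 3000), end = c(3000, 10000)),
    B = tibble(chrom = "chr1", start = c(0, 7000), end = c(7000, 10000))))
  expect_equal(comp$prototype$segments$start, c(0, 3000, 7000))
  expect_equal(comp$prototype$segments$end, c(3000, 7000, 10000))

  # identical junctions from two clones collapse to one prototype edge
  del <- tibble(chrom1 = "chr1", pos1 = 3000, strand1 = "+",
                chrom2 = "chr1", pos2 = 7000, strand2 = "-")
  comp2 <- build_prototype(
    list(A = tibble(chrom = "chr1", start = 0, end = 10000),
         B = tibble(chrom = "chr1", start = 0, end = 10000)),
    list(A = del, B = del))
  nvar <- comp2$prototype$edges %>% filter(kind == "variant") %>%
    distinct(uid) %>% nrow()
  expect_equal(nvar, 1)
  # p maps both clones' copies to the same prototype junction
  expect_equal(nrow(comp2$junction_support), 2)
  expect_equal(length(unique(comp2$junction_support$uid)), 1)
})

test_that("prototype construction rejects malformed input", {
  expect_error(build_prototype(list(
    A = tibble(chrom = "chr1", start = 0, end = 10000),
    B = tibble(chrom = "chr1", start = 0, end = 9000))), "mixed genome builds")
  expect_error(build_prototype(
    list(A = tibble(chrom = "chr1", start = 0, end = 10000)),
    list(A = tibble(chrom1 = "chr1", pos1 = 20000, strand1 = "+",
                    chrom2 = "chr1", pos2 = 3000, strand2 = "-"))),
    "does not lie on any segment")
  expect_error(build_prototype(list(
    A = tibble(chrom = "chr1", start = c(0, 2000), end = c(3000, 5000)))),
    "overlapping")
})

test_that("junction merge window pools nearby breakends", {
  j1 <- tibble(chrom1 = "chr1", pos1 = 3000, strand1 = "+",
               chrom2 = "chr1", pos2 = 7000, strand2 = "-")
  j2 <- mutate(j1, pos1 = 3004)
  segs <- tibble(chrom = "chr1", start = 0, end = 10000)
  # default: exact match only -> two junctions
  c0 <- build_prototype(list(A = segs, B = segs), list(A = j1, B = j2))
  expect_equal(length(unique(c0$junction_support$uid)), 2)
  # +-10 bp window -> one junction
  c1 <- build_prototype(list(A = segs, B = segs), list(A = j1, B = j2),
                        merge_window = 10)
  expect_equal(length(unique(c1$junction_support$uid)), 1)
})

test_that("reverse complement is an involution and pairs elements", {
  toy <- deletion_toy()
  g <- toy$graph
  rc <- reverse_complement(g)
  # the variant junction's endpoints are swapped to the partner record
  v1 <- g$edges %>% filter(kind == "variant") %>% arrange(eid)
  v2 <- rc$edges %>% filter(kind == "variant") %>% arrange(eid)
  expect_equal(v2$from_vid, v1$from_vid[c(2, 1)])
  expect_equal(v2$to_vid, v1$to_vid[c(2, 1)])
  expect_identical(reverse_complement(rc), g)

  # property: involution on random graphs; rc-closure of edge sets
  set.seed(42)
  for (i in 1:10) {
    gr <- random_toy_graph(n_seg = sample(2:5, 1), n_var = sample(0:3, 1))
    attr(gr, "toy_segments") <- attr(gr, "toy_junctions") <- NULL
    expect_identical(reverse_complement(reverse_complement(gr)), gr)
    e <- gr$edges
    expect_true(all(e$rc_eid %in% e$eid))
    expect_equal(e$rc_eid[match(e$rc_eid, e$eid)], e$eid)  # partner of partner
    # vertex set closed under rc
    v <- graph_vertices(gr)
    expect_setequal(v$rc_vid, v$vid)
  }
})

test_that("serialization round-trips graphs and assignments", {
  # empty-ish graph
  g0 <- genome_graph(tibble(chrom = "chr1", start = 0, end = 1000))
  p0 <- withr::local_tempfile(fileext = ".json")
  write_genome_graph(g0, p0)
  expect_identical(read_genome_graph(p0)$graph$segments, g0$segments)

  set.seed(7)
  for (i in 1:8) {
    g <- random_toy_graph(n_seg = sample(2:5, 1), n_var = sample(0:3, 1))
    k <- copy_assignment(g, sample(0:4, nrow(g$segments), TRUE))
    p <- withr::local_tempfile(fileext = ".json")
    write_genome_graph(g, p, k)
    rt <- read_genome_graph(p)
    expect_equal(as.data.frame(rt$graph$segments), as.data.frame(g$segments))
    expect_equal(as.data.frame(rt$graph$edges), as.data.frame(g$edges))
    expect_equal(as.data.frame(rt$graph$termini), as.data.frame(g$termini))
    expect_equal(rt$assignment$vertex$cn, k$vertex$cn)
    expect_equal(rt$assignment$edge$cn, k$edge$cn)
  }
})

test_that("reader rejects documents with broken references", {
  g <- deletion_toy()$graph
  p <- withr::local_tempfile(fileext = ".json")
  write_genome_graph(g, p)
  doc <- jsonlite::fromJSON(p)
  doc$edges$from_vid[1] <- 999L
  jsonlite::write_json(doc, p, auto_unbox = TRUE, na = "null")
  expect_error(read_genome_graph(p), "missing vertex")
  expect_error(read_genome_graph(tempfile()), "malformed")
})

test_that("balance checker enforces the stoichiometric invariants", {
  toy <- deletion_toy()
  g <- toy$graph
  k_ok <- copy_assignment(g, c(2, 1, 2),
                          tibble(uid = c(toy$ref_uids, toy$var_uid), cn = c(1, 1, 1)))
  expect_true(check_balance(g, k_ok))
  k_bad <- copy_assignment(g, c(2, 2, 2),
                           tibble(uid = c(toy$ref_uids, toy$var_uid), cn = c(1, 1, 1)))
  expect_error(check_balance(g, k_bad), "balance violated")
  k_neg <- copy_assignment(g, c(2, 1, 2), tibble(uid = toy$var_uid, cn = -1))
  expect_error(check_balance(g, k_neg), "negative")
})
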
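# SNV presence calling, clone phylogeny, branch assignment, and
# kataegis-like cluster detection.

#' Bundle SNV sites and per-clone allelic counts
#'
#' @param sites tibble `snv_id`,`chrom`,`pos`,`ref`,`alt` and optional
#'   filter flags `mq60` (logical), `evs` (caller score), `pass`.
#' @param counts long tibble `snv_id`,`clone`,`ref_count`,`alt_count`.
#' @return a `snv_matrix` object.
#' @export
snv_matrix <- function(sites, counts) {
  stopifnot(all(c("snv_id", "chrom", "pos") %in% names(sites)),
            all(c("snv_id", "clone", "ref_count", "alt_count") %in% names(counts)))
  if (any(counts$ref_count < 0) || any(counts$alt_count < 0))
    abort("negative read counts")
  structure(list(sites = as_tibble(sites), counts = as_tibble(counts)),
            class = "snv_matrix")
}

#' Apply hard site filters to an SNV matrix
#'
#' Retains sites passing the caller flag, a mapping-quality flag, a
#' caller-score threshold, and a minimum total ALT count across clones.
#'
#' @param m a [snv_matrix()].
#' @param min_evs minimum caller score (default 12, exclusive).
#' @param min_alt_total minimum summed ALT count (default 4, exclusive).
#' @return the filtered `snv_matrix`.
#' @export
apply_site_filters <- function(m, min_evs = 12, min_alt_total = 4) {
  tot <- m$counts %>% group_by(.data$snv_id) %>%
    summarise(alt_total = sum(.data$alt_count), .groups = "drop")
  s <- left_join(m$sites, tot, by = "snv_id") %>%
    mutate(alt_total = if_else(is.na(.data$alt_total), 0, as.numeric(.data$alt_total)))
  ok <- s$alt_total > min_alt_total
  if ("mq60" %in% names(s)) ok <- ok & s$mq60
  if ("evs" %in% names(s)) ok <- ok & s$evs > min_evs
  if ("pass" %in% names(s)) ok <- ok & s$pass
  keep <- s$snv_id[ok]
  snv_matrix(m$sites[m$sites$snv_id %in% keep, ],
             m$counts[m$counts$snv_id %in% keep, ])
}

#' Posterior probability that each SNV is present in each clone
#'
#' Two-component binomial mixture per site and clone: the ALT count is
#' binomial with success probability `p_present` (clonal heterozygous
#' VAF in a pure, near-diploid clone) if the variant is present and
#' `p_absent` (sequencing error) if not. The prior is the site's
#' aggregated allele frequency across all clones. Zero-depth entries
#' fall back to the prior. Entries are called present when the
#' posterior exceeds 0.5.
#'
#' @param m a [snv_matrix()].
#' @param p_present VAF under presence (default 0.5).
#' @param p_absent error rate under absence (default 0.001).
#' @return a `presence_matrix`: list with `posterior` and binary
#'   `presence` matrices (sites x clones) and the per-site `prior`.
#' @export
presence_posterior <- function(m, p_present = 0.5, p_absent = 0.001) {
  stopifnot(p_absent > 0, p_absent < p_present, p_present <= 1)
  eps <- 1e-6
  wide_alt <- tidyr::pivot_wider(m$counts, id_cols = "snv_id",
                                 names_from = "clone", values_from = "alt_count")
  wide_ref <- tidyr::pivot_wider(m$counts, id_cols = "snv_id",
                                 names_from = "clone", values_from = "ref_count")
  ord <- match(m$sites$snv_id, wide_alt$snv_id)
  alt <- as.matrix(wide_alt[ord, -1]); ref <- as.matrix(wide_ref[ord, -1])
  alt[is.na(alt)] <- 0; ref[is.na(ref)] <- 0
  dp <- alt + ref
  prior <- rowSums(alt) / pmax(rowSums(dp), 1)
  clamped <- prior <= 0 | prior >= 1
  if (any(clamped))
    message(sprintf("%d site prior(s) clamped away from {0,1}", sum(clamped)))
  prior <- pmin(pmax(prior, eps), 1 - eps)
  l1 <- dbinom(alt, dp, p_present) * prior
  l0 <- dbinom(alt, dp, p_absent) * (1 - prior)
  post <- l1 / (l1 + l0)
  post[dp == 0] <- prior[row(post)[dp == 0]]
  rownames(post) <- m$sites$snv_id
  structure(list(posterior = post, presence = post > 0.5, prior = prior,
                 sites = m$sites),
            class = "presence_matrix")
}

#' Neighbor-joining clone phylogeny from a binary presence matrix
#'
#' Pairwise clone distances are symmetric-difference SNV counts
#' (Hamming), the natural additive distance under a no-recurrence
#' accretion model; the unrooted tree is built with classical
#' neighbor joining. Negative branch-length estimates are clamped to
#' zero (reported via a message).
#'
#' @param pm a `presence_matrix` (or a clones-in-rows binary matrix).
#' @return an `ape` `phylo` tree with tip labels = clone names.
#' @export
neighbor_joining <- function(pm) {
  mat <- if (inherits(pm, "presence_matrix")) t(pm$presence) else pm
  if (nrow(mat) < 3) abort("neighbor joining requires at least 3 clones")
  d <- dist(mat * 1, method = "manhattan")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    message(sprintf("%d negative branch length(s) clamped to 0",
                    sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Clone-incidence vectors of every tree branch
#'
#' For each edge of the tree, the logical vector marking the tips in the
#' clade below it (in `tree$tip.label` order). Used to compare SNV
#' presence patterns against branches.
#'
#' @param tree an `ape` `phylo` object.
#' @return list of logical vectors, one per row of `tree$edge`.
#' @export
branch_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- lapply(seq_len(ntip + tree$Nnode), function(i) integer(0))
  # postorder accumulation of tip sets
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    par <- po[r, 1]; ch <- po[r, 2]
    desc[[par]] <- union(desc[[par]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(r) {
    tips <- desc[[tree$edge[r, 2]]]
    v <- logical(ntip)
    v[tips] <- TRUE
    v
  })
}

#' Assign SNVs to phylogeny branches by Jaccard distance
#'
#' Each branch of the unrooted tree defines a binary clone-incidence
#' vector (the clade below it; both orientations of each edge are
#' considered and the closer one used). Every SNV is assigned to its
#' closest branch iff the Jaccard distance is below `max_jaccard`;
#' ties break deterministically to the smallest branch id and are
#' flagged.
#'
#' @param tree an `ape` tree over the clones.
#' @param pm a `presence_matrix`.
#' @param max_jaccard assignment threshold (default 0.1, exclusive).
#' @return tibble `snv_id`, `branch` (edge index or `NA`), `jaccard`,
#'   `tie` (logical).
#' @export
assign_snvs_to_branches <- function(tree, pm, max_jaccard = 0.1) {
  stopifnot(setequal(tree$tip.label, colnames(pm$presence)))
  pres <- pm$presence[, tree$tip.label, drop = FALSE]
  inc <- branch_incidence(tree)
  ntip <- length(tree$tip.label)
  inc_mat <- do.call(cbind, inc) * 1           # clones x branches
  both <- cbind(inc_mat, 1 - inc_mat)          # both orientations
  p <- pres * 1                                # sites x clones
  inter <- p %*% both
  sz_b <- colSums(both)
  sz_s <- rowSums(p)
  uni <- outer(sz_s, sz_b, `+`) - inter
  jac <- 1 - inter / pmax(uni, 1)
  jac[, sz_b == 0] <- 1                        # empty orientation never matches
  nb <- length(inc)
  # fold orientations: per branch take the better one
  jfold <- pmin(jac[, seq_len(nb), drop = FALSE],
                jac[, nb + seq_len(nb), drop = FALSE])
  best <- apply(jfold, 1, which.min)
  bestd <- jfold[cbind(seq_len(nrow(jfold)), best)]
  tie <- rowSums(abs(jfold - bestd) < 1e-12) > 1
  zero <- sz_s == 0
  tibble(snv_id = pm$sites$snv_id,
         branch = ifelse(!zero & bestd < max_jaccard, best, NA_integer_),
         jaccard = ifelse(zero, NA_real_, bestd),
         tie = tie & !zero)
}

#' Detect kataegis-like SNV clusters
#'
#' Maximal runs of `min_run` or more SNVs in which every successive
#' inter-SNV distance is below `max_gap_bp`, per chromosome.
#'
#' @param snvs tibble `chrom`,`pos` (one clone's SNVs).
#' @param max_gap_bp inter-SNV distance threshold (default 2000,
#'   exclusive).
#' @param min_run minimum run length (default 2).
#' @return tibble `cluster_id`,`chrom`,`start`,`end`,`n`, plus the
#'   member positions as a list column.
#' @export
rainfall_clusters <- function(snvs, max_gap_bp = 2000, min_run = 2) {
  if (nrow(snvs) == 0)
    return(tibble(cluster_id = integer(), chrom = character(),
                  start = numeric(), end = numeric(), n = integer(),
                  positions = list()))
  out <- snvs %>%
    group_by(.data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(newrun = c(TRUE, diff(.data$pos) >= max_gap_bp),
           run = cumsum(.data$newrun)) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$pos), end = max(.data$pos), n = n(),
              positions = list(.data$pos), .groups = "drop") %>%
    filter(.data$n >= min_run) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(cluster_id = row_number()) %>%
    select("cluster_id", "chrom", "start", "end", "n", "positions")
  out
}

#' Rainfall plot of inter-SNV distances
#'
#' @param snvs tibble `chrom`,`pos`.
#' @param max_gap_bp reference line for the clustering threshold.
#' @return a ggplot.
#' @export
plot_rainfall <- function(snvs, max_gap_bp = 2000) {
  d <- snvs %>% group_by(.data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(iedist = c(NA, diff(.data$pos))) %>% ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$iedist)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = max_gap_bp, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "inter-SNV distance (bp)") +
    ggplot2::theme_minimal()
}
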
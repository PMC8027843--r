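# Parental heterozygous-SNP phasing through a single-allele-loss clone
# and absolute allelic copy number.

#' Call heterozygous parental SNP sites
#'
#' Retains candidate loci whose parental variant allele fraction lies
#' strictly inside `(vaf_lo, vaf_hi)` at sufficient depth. Zero-depth
#' sites are dropped and counted in a message.
#'
#' @param parental tibble `site_id`,`chrom`,`pos`,`ref_count`,`alt_count`.
#' @param vaf_lo,vaf_hi strict VAF bounds (defaults 0.3 and 0.7).
#' @param min_depth minimum parental depth (default 10).
#' @return the retained sites with a `vaf` column.
#' @export
call_het_sites <- function(parental, vaf_lo = 0.3, vaf_hi = 0.7,
                           min_depth = 10) {
  stopifnot(all(parental$ref_count >= 0), all(parental$alt_count >= 0))
  dp <- parental$ref_count + parental$alt_count
  if (any(dp == 0))
    message(sprintf("%d zero-depth site(s) dropped", sum(dp == 0)))
  keep <- dp >= min_depth
  vaf <- ifelse(dp > 0, parental$alt_count / dp, NA_real_)
  out <- parental[keep & vaf > vaf_lo & vaf < vaf_hi, ]
  out$vaf <- vaf[keep & vaf > vaf_lo & vaf < vaf_hi]
  out
}

#' Phase heterozygous SNPs into lost/retained haplotypes
#'
#' Uses a clone carrying a single-allele loss over `region`: at each
#' site, the allele (reference or alternate) with a zero read count in
#' the loss clone is assigned to the lost (L) haplotype and the other to
#' the retained (R) haplotype. Sites where neither or both alleles are
#' zero are left unphased and flagged.
#'
#' @param het sites from [call_het_sites()].
#' @param counts long tibble `site_id`,`clone`,`ref_count`,`alt_count`.
#' @param loss_clone clone id with the single-allele loss.
#' @param region tibble `chrom`,`start`,`end` (the lost segment).
#' @return the sites in the region with columns `phase` (`"ref_L"`,
#'   `"alt_L"`, or `NA` for unphased) and `phased` (logical).
#' @export
phase_by_loss_clone <- function(het, counts, loss_clone, region) {
  inr <- rep(FALSE, nrow(het))
  for (j in seq_len(nrow(region)))
    inr <- inr | (het$chrom == region$chrom[j] & het$pos >= region$start[j] &
                    het$pos < region$end[j])
  sites <- het[inr, ]
  if (nrow(sites) == 0) return(mutate(sites, phase = character(0), phased = logical(0)))
  lc <- counts[counts$clone == loss_clone, ]
  m <- match(sites$site_id, lc$site_id)
  r0 <- lc$ref_count[m] == 0
  a0 <- lc$alt_count[m] == 0
  phase <- dplyr::case_when(r0 & !a0 ~ "ref_L", a0 & !r0 ~ "alt_L",
                            TRUE ~ NA_character_)
  if (any(is.na(phase)))
    message(sprintf("%d site(s) left unphased (no single zero-count allele)",
                    sum(is.na(phase))))
  mutate(sites, phase = phase, phased = !is.na(phase))
}

#' Absolute allelic copy number at phased sites
#'
#' Divides per-clone L- and R-allele read counts by a per-clone
#' normalizer (the genome-wide mean single-allele count at heterozygous
#' sites in these pure, near-diploid clones) to express counts in
#' absolute copy-number units.
#'
#' @param phased output of [phase_by_loss_clone()] (phased sites only
#'   are used).
#' @param counts long tibble `site_id`,`clone`,`ref_count`,`alt_count`.
#' @param normalizer named per-clone normalizer, or `NULL` to compute it
#'   as the mean het-site allele count over `norm_sites` (e.g., all
#'   het sites outside the event region).
#' @param norm_sites sites used for the normalizer when computed
#'   (tibble with `site_id`); defaults to the phased sites themselves.
#' @return tibble `site_id`,`chrom`,`pos`,`clone`,`L_count`,`R_count`,
#'   `L_cn`,`R_cn`.
#' @export
allelic_copy_number <- function(phased, counts, normalizer = NULL,
                                norm_sites = NULL) {
  ph <- phased[phased$phased, ]
  cc <- counts[counts$site_id %in% ph$site_id, ]
  m <- match(cc$site_id, ph$site_id)
  L <- ifelse(ph$phase[m] == "ref_L", cc$ref_count, cc$alt_count)
  R <- ifelse(ph$phase[m] == "ref_L", cc$alt_count, cc$ref_count)
  if (is.null(normalizer)) {
    ns <- if (is.null(norm_sites)) counts[counts$site_id %in% ph$site_id, ]
          else counts[counts$site_id %in% norm_sites$site_id, ]
    normalizer <- ns %>% group_by(.data$clone) %>%
      summarise(nrm = mean(c(.data$ref_count, .data$alt_count)), .groups = "drop") %>%
      { setNames(.$nrm, .$clone) }
  }
  if (any(normalizer <= 0)) abort("normalizer must be positive")
  nrm <- unname(normalizer[cc$clone])
  tibble(site_id = cc$site_id, chrom = ph$chrom[m], pos = ph$pos[m],
         clone = cc$clone, L_count = L, R_count = R,
         L_cn = L / nrm, R_cn = R / nrm)
}

#' Segment-level allelic copy-number summary
#'
#' Mean L/R copy number over the phased sites falling in each segment.
#'
#' @param acn site-level table from [allelic_copy_number()].
#' @param segments tibble `chrom`,`start`,`end`.
#' @return tibble `clone`,`chrom`,`start`,`end`,`n_sites`,`L_cn`,`R_cn`.
#' @export
allelic_segment_means <- function(acn, segments) {
  purrr::pmap(segments, function(chrom, start, end, ...) {
    s <- acn[acn$chrom == chrom & acn$pos >= start & acn$pos < end, ]
    if (nrow(s) == 0) return(NULL)
    s %>% group_by(.data$clone) %>%
      summarise(n_sites = n(), L_cn = mean(.data$L_cn), R_cn = mean(.data$R_cn),
                .groups = "drop") %>%
      mutate(chrom = chrom, start = start, end = end)
  }) %>% bind_rows() %>%
    select("clone", "chrom", "start", "end", "n_sites", "L_cn", "R_cn")
}

#' Allele-specific copy-number plot along a region
#'
#' @param acn site-level table from [allelic_copy_number()].
#' @param clones optional subset of clones.
#' @return a ggplot of L and R copy number along the genome.
#' @export
plot_allelic_cn <- function(acn, clones = NULL) {
  d <- acn
  if (!is.null(clones)) d <- d[d$clone %in% clones, ]
  d <- tidyr::pivot_longer(d, c("L_cn", "R_cn"), names_to = "haplotype",
                           values_to = "cn")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$cn,
                                  colour = .data$haplotype)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::facet_grid(clone ~ chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(L_cn = "firebrick", R_cn = "grey40")) +
    ggplot2::labs(x = "position (bp)", y = "allelic copy number") +
    ggplot2::theme_minimal()
}
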
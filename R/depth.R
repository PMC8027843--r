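# Read-depth aggregation, noisy-region masking, and clone clustering by
# copy-number profile (the low-pass screening analysis).

#' Collapse uniform depth bins by a factor, taking the median
#'
#' Aggregates consecutive bins (e.g., 1-kbp to 10-kbp) with the median,
#' which is robust to single-bin outliers. A trailing partial bin uses
#' the bins available.
#'
#' @param bins tibble `chrom`,`start`,`end`,`value` with uniform width.
#' @param factor integer >= 1.
#' @return collapsed bin tibble tiling the same span.
#' @export
collapse_bins <- function(bins, factor) {
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  if (nrow(bins) == 0) return(bins)
  if (factor == 1L) return(bins)
  bins %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(grp = (row_number() - 1L) %/% factor) %>%
    group_by(.data$chrom, .data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              value = median(.data$value), .groups = "drop") %>%
    select("chrom", "start", "end", "value") %>%
    arrange(.data$chrom, .data$start)
}

#' Bundle a clones-by-bins depth matrix
#'
#' @param matrix clones x bins numeric matrix (rownames = clone ids).
#' @param bins tibble `chrom`,`start`,`end` describing the columns.
#' @param mask optional logical per bin (`TRUE` = excluded).
#' @return a `depth_matrix` object.
#' @export
depth_matrix <- function(matrix, bins, mask = NULL) {
  stopifnot(ncol(matrix) == nrow(bins))
  if (is.null(mask)) mask <- rep(FALSE, nrow(bins))
  structure(list(matrix = matrix, bins = as_tibble(bins), mask = mask),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(sprintf("<depth_matrix> %d clone(s) x %d bin(s); %d masked\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$mask)))
  invisible(x)
}

#' Mask recurrently noisy depth regions
#'
#' Flags a window in a clone when the population standard deviation of
#' bin value over the window mean exceeds `sd_cut`; bins in windows
#' flagged in more than `recurrence` of the cohort (or overlapping a
#' user-supplied low-quality region list) are masked. Zero-mean windows
#' are flagged as degenerate and reported via a message.
#'
#' @param dm a [depth_matrix()].
#' @param window_bp window size (multiple of the bin width).
#' @param sd_cut threshold on sd(value / window mean) (default 0.3).
#' @param recurrence cohort fraction above which a window is masked
#'   (default 0.1).
#' @param low_quality optional tibble `chrom`,`start`,`end` of regions to
#'   mask outright.
#' @param reference optional second [depth_matrix()] cohort from which
#'   the variance mask is derived instead (e.g., a high-pass dataset).
#' @return the `depth_matrix` with an updated mask.
#' @export
mask_noisy_regions <- function(dm, window_bp = 100000, sd_cut = 0.3,
                               recurrence = 0.1, low_quality = NULL,
                               reference = NULL) {
  src <- if (is.null(reference)) dm else reference
  bw <- src$bins$end[1] - src$bins$start[1]
  if (window_bp %% bw != 0) abort("window_bp must be a multiple of the bin width")
  win <- paste(src$bins$chrom, src$bins$start %/% window_bp)
  wid <- match(win, unique(win))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  n_win <- max(wid)
  flagged <- matrix(FALSE, nrow(src$matrix), n_win)
  degenerate <- FALSE
  for (i in seq_len(nrow(src$matrix))) {
    v <- src$matrix[i, ]
    mu <- tapply(v, wid, mean)
    sdv <- tapply(v, wid, pop_sd)
    zero <- mu <= 0
    degenerate <- degenerate || any(zero)
    flagged[i, ] <- ifelse(zero, TRUE, sdv / mu > sd_cut)
  }
  if (degenerate) message("zero-mean window(s) flagged as degenerate")
  frac <- colMeans(flagged)
  bad_win <- which(frac > recurrence)
  mask <- wid %in% bad_win
  # map the source-window mask onto this matrix's bin frame
  if (!is.null(reference)) {
    key_src <- unique(win)[bad_win]
    key <- paste(dm$bins$chrom, dm$bins$start %/% window_bp)
    mask <- key %in% key_src
  }
  if (!is.null(low_quality)) {
    for (j in seq_len(nrow(low_quality)))
      mask <- mask | (dm$bins$chrom == low_quality$chrom[j] &
                        dm$bins$start < low_quality$end[j] &
                        dm$bins$end > low_quality$start[j])
  }
  dm$mask <- dm$mask | mask
  dm
}

#' Cluster clones by copy-number profile
#'
#' Agglomerative clustering of clones on genome-wide Euclidean bin
#' distance with Ward linkage in its squared-update form (`ward.D2`),
#' cut at `k` clusters. Masked bins are excluded; `region` optionally
#' restricts the bins considered.
#'
#' @param dm a [depth_matrix()].
#' @param k number of clusters (a parameter: the analysis that motivated
#'   this chose it by dendrogram inspection).
#' @param region optional tibble `chrom`,`start`,`end` restricting bins.
#' @return list with `labels` (named integer vector), `hclust`, and
#'   `newick` (the dendrogram as a Newick string).
#' @export
cluster_clones <- function(dm, k, region = NULL) {
  if (k > nrow(dm$matrix)) abort("k exceeds the number of clones")
  keep <- !dm$mask
  if (!is.null(region)) {
    inr <- rep(FALSE, nrow(dm$bins))
    for (j in seq_len(nrow(region)))
      inr <- inr | (dm$bins$chrom == region$chrom[j] &
                      dm$bins$start < region$end[j] &
                      dm$bins$end > region$start[j])
    keep <- keep & inr
  }
  if (!any(keep)) abort("no unmasked bins to cluster on")
  d <- dist(dm$matrix[, keep, drop = FALSE], method = "euclidean")
  hc <- hclust(d, method = "ward.D2")
  labels <- cutree(hc, k = k)
  phy <- ape::as.phylo(hc)
  list(labels = labels, hclust = hc,
       newick = ape::write.tree(phy))
}
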
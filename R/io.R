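# Readers/writers for the standard interchange formats: bedGraph depth,
# BEDPE junctions, BED copy number, TSV tables.

#' Read a bedGraph file of binned depth
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based
#'   half-open).
#' @return tibble `chrom`,`start`,`end`,`value`.
#' @export
read_bedgraph <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  as_tibble(d)
}

#' @rdname read_bedgraph
#' @param bins tibble to write.
#' @export
write_bedgraph <- function(bins, path) {
  utils::write.table(bins[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read junctions from a BEDPE file
#'
#' Columns chrom1,start1,end1,chrom2,start2,end2,name,score,strand1,
#' strand2. Breakend positions are taken as `end1`/`end2` for `+`
#' strands (segment side facing higher coordinates) and `start1`/
#' `start2` for `-` strands; the `score` column is read as junction
#' support when numeric.
#'
#' @param path BEDPE file.
#' @return junction tibble (`chrom1,pos1,strand1,chrom2,pos2,strand2`,
#'   `name`, `support`).
#' @export
read_bedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#")
  if (ncol(d) < 10) abort("BEDPE needs 10 columns (chrom1..strand2)")
  names(d)[1:10] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score", "strand1", "strand2")
  tibble(
    chrom1 = as.character(d$chrom1),
    pos1 = ifelse(d$strand1 == "+", d$end1, d$start1),
    strand1 = as.character(d$strand1),
    chrom2 = as.character(d$chrom2),
    pos2 = ifelse(d$strand2 == "+", d$end2, d$start2),
    strand2 = as.character(d$strand2),
    name = as.character(d$name),
    support = suppressWarnings(as.numeric(d$score)))
}

#' @rdname read_bedpe
#' @param junctions junction tibble; a `support` column becomes the
#'   BEDPE score.
#' @export
write_bedpe <- function(junctions, path) {
  j <- normalize_junctions(junctions)
  score <- if ("support" %in% names(junctions)) junctions$support else "."
  d <- data.frame(
    chrom1 = j$chrom1,
    start1 = ifelse(j$strand1 == "+", j$pos1 - 1, j$pos1),
    end1 = ifelse(j$strand1 == "+", j$pos1, j$pos1 + 1),
    chrom2 = j$chrom2,
    start2 = ifelse(j$strand2 == "+", j$pos2 - 1, j$pos2),
    end2 = ifelse(j$strand2 == "+", j$pos2, j$pos2 + 1),
    name = if ("name" %in% names(junctions)) junctions$name
           else sprintf("junction_%d", seq_len(nrow(j))),
    score = score, strand1 = j$strand1, strand2 = j$strand2)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-segment copy number as BED
#'
#' @param fit a `crisis_balance` object.
#' @param dir output directory (one BED per clone).
#' @export
write_cn_bed <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- tidy(fit)
  for (cl in unique(d$clone)) {
    dd <- d[d$clone == cl, c("chrom", "start", "end", "cn")]
    utils::write.table(dd, file.path(dir, paste0(cl, ".cn.bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
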
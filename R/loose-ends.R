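# Telomere-motif screening of loose-end mate sequences: nominating or
# rejecting neo-telomere formation at unresolved copy-number ends.

#' Telomere repeat motif set
#'
#' All distinct cyclic rotations of a telomere repeat (default the
#' 12-bp double repeat `TTAGGGTTAGGG`, which has period 6 and hence 6
#' distinct rotations), optionally with their reverse complements.
#'
#' @param motif base motif string.
#' @param both_strands include reverse complements (default TRUE).
#' @return character vector of distinct motif strings.
#' @export
telomere_motifs <- function(motif = "TTAGGGTTAGGG", both_strands = TRUE) {
  n <- nchar(motif)
  rots <- unique(vapply(seq_len(n) - 1L, function(k)
    paste0(substr(motif, k + 1, n), substr(motif, 1, k)), ""))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(rots)))
    rots <- unique(c(rots, rc))
  }
  rots
}

#' Count telomere-motif occurrences in sequences
#'
#' Counts (overlapping) occurrences of every motif in the set in each
#' sequence; `N` never matches.
#'
#' @param seqs character vector of DNA sequences.
#' @param motifs motif set (default [telomere_motifs()]).
#' @return integer vector of per-sequence total motif counts.
#' @export
count_telomere_motif <- function(seqs, motifs = telomere_motifs()) {
  if (length(seqs) == 0) return(integer(0))
  ss <- Biostrings::DNAStringSet(seqs)
  counts <- rep(0L, length(seqs))
  for (m in motifs)
    counts <- counts + Biostrings::vcountPattern(m, ss)
  counts
}

#' Classify a loose end from its mate-sequence evidence
#'
#' A loose end is nominated as a neo-telomere candidate iff at least
#' `min_reads` mate sequences each carry at least `min_count` telomere-
#' motif hits; otherwise it is reported as repetitive/unresolved (the
#' outcome observed for all loose ends in the system this models).
#'
#' @param seqs mate sequences (character vector; may be empty).
#' @param min_count motif hits required per supporting read.
#' @param min_reads supporting reads required.
#' @param motifs motif set.
#' @return list with `classification` ("neo_telomere_candidate" or
#'   "repetitive_unresolved"), `n_reads`, `n_telomeric`, `counts`.
#' @export
classify_loose_end <- function(seqs, min_count = 1, min_reads = 3,
                               motifs = telomere_motifs()) {
  counts <- count_telomere_motif(seqs, motifs)
  n_tel <- sum(counts >= min_count)
  cls <- if (length(seqs) > 0 && n_tel >= min_reads) "neo_telomere_candidate"
         else "repetitive_unresolved"
  list(classification = cls, n_reads = length(seqs), n_telomeric = n_tel,
       counts = counts)
}

#' Screen a table of loose-end mate sequences
#'
#' @param evidence tibble `loose_id`,`seq` (one row per mate sequence).
#' @param min_count,min_reads see [classify_loose_end()].
#' @param motifs motif set.
#' @return tibble `loose_id`,`n_reads`,`n_telomeric`,`classification`.
#' @export
screen_loose_ends <- function(evidence, min_count = 1, min_reads = 3,
                              motifs = telomere_motifs()) {
  evidence %>%
    group_by(.data$loose_id) %>%
    summarise(res = list(classify_loose_end(.data$seq, min_count, min_reads,
                                            motifs)), .groups = "drop") %>%
    mutate(n_reads = vapply(.data$res, `[[`, 0L, "n_reads"),
           n_telomeric = vapply(.data$res, `[[`, 0L, "n_telomeric"),
           classification = vapply(.data$res, `[[`, "", "classification")) %>%
    select("loose_id", "n_reads", "n_telomeric", "classification")
}
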
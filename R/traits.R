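# Community-level genomic trait indices. Unmatched taxa (no reference genome)
# are excluded from both numerator and denominator; a coverage column reports
# the abundance fraction the matched taxa represent so users can judge
# representativeness.

.matched_support <- function(abundances, ref) {
  if (is.null(names(abundances)))
    abort_fmt("sample abundances must be named by taxon id")
  idx <- match(names(abundances), ref$taxon_id)
  matched <- !is.na(idx) & ref$matched[idx]
  keep <- matched & abundances > 0
  if (!any(keep))
    abort_fmt("no matched taxa with positive abundance in sample")
  list(a = abundances[keep], ref_rows = idx[keep])
}

#' Community-level rrn copy number
#'
#' The ratio of the summed abundance of matched taxa to the summed
#' copy-number-adjusted abundance (abundance divided by per-taxon rrn copies):
#' sum(a_i) / sum(a_i / c_i). This is the abundance-weighted harmonic mean of
#' rrn copy numbers, which is how a community's 16S-amplicon pool relates to
#' its genome pool. Higher values indicate communities of faster-growing
#' taxa.
#'
#' @param abundances named numeric vector, taxon id -> abundance (counts or
#'   relative; the index is scale-invariant).
#' @param ref a [trait_reference()].
#' @return scalar rrn copy number, bounded by the min and max c_i among taxa
#'   present.
#' @export
community_rrn_copy_number <- function(abundances, ref) {
  s <- .matched_support(abundances, ref)
  c_i <- ref$rrn_copies[s$ref_rows]
  sum(s$a) / sum(s$a / c_i)
}

#' Abundance-weighted community trait
#'
#' sum(a_i * x_i) / sum(a_i) over matched taxa with positive abundance.
#'
#' @param abundances named numeric vector, taxon id -> abundance.
#' @param ref a [trait_reference()].
#' @param trait `"genome_size"` (Mbp) or `"gc"` (percent).
#' @return scalar weighted trait value.
#' @export
abundance_weighted_trait <- function(abundances, ref,
                                     trait = c("genome_size", "gc")) {
  trait <- match.arg(trait)
  s <- .matched_support(abundances, ref)
  x <- switch(trait,
              genome_size = ref$genome_size_mbp[s$ref_rows],
              gc = ref$gc_percent[s$ref_rows])
  sum(s$a * x) / sum(s$a)
}

#' Per-sample community genomic trait indices
#'
#' @param table a [community_table()].
#' @param ref a [trait_reference()].
#' @return data.frame with one row per sample: `sample_id`, `community_rrn`,
#'   `weighted_genome_size`, `weighted_gc` and `coverage` (fraction of total
#'   abundance carried by matched taxa).
#' @export
community_traits <- function(table, ref) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  res <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts[i, ]
    idx <- match(names(a), ref$taxon_id)
    matched <- !is.na(idx) & ref$matched[idx]
    cov <- if (sum(a) > 0) sum(a[matched]) / sum(a) else NA_real_
    data.frame(sample_id = rownames(counts)[i],
               community_rrn = community_rrn_copy_number(a, ref),
               weighted_genome_size = abundance_weighted_trait(a, ref,
                                                               "genome_size"),
               weighted_gc = abundance_weighted_trait(a, ref, "gc"),
               coverage = cov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  merge(out, table$samples, by = "sample_id", sort = FALSE)
}
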
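#' Community abundance table
#'
#' Samples-by-taxa abundance matrix together with sample metadata (habitat,
#' treatment, year, block). This is the central container consumed by the
#' trait, dissimilarity, stochasticity and network modules.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns; rownames
#'   are sample ids, colnames are taxon ids. Non-negative, no missing values.
#' @param samples data.frame with one row per sample; must contain a
#'   `sample_id` column matching `rownames(counts)`, and normally `habitat`
#'   (`"litterbag"`/`"soil"`), `treatment` (`"warm"`/`"control"`), `group`
#'   (e.g. `"WL"`), `year` and `block`.
#' @return an object of class `community_table`: a list with elements
#'   `counts` and `samples`.
#' @export
community_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) abort_fmt("counts must be numeric")
  if (anyNA(counts)) abort_fmt("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    abort_fmt("negative abundance at sample '%s', taxon '%s'",
              rownames(counts)[bad[1L]] %||% bad[1L],
              colnames(counts)[bad[2L]] %||% bad[2L])
  }
  if (is.null(rownames(counts))) abort_fmt("counts must have sample rownames")
  if (is.null(colnames(counts))) abort_fmt("counts must have taxon colnames")
  if (anyDuplicated(rownames(counts)))
    abort_fmt("duplicated sample ids: %s",
              paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                    collapse = ", "))
  if (anyDuplicated(colnames(counts))) abort_fmt("duplicated taxon ids")
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples))
    abort_fmt("samples must contain a sample_id column")
  if (!setequal(samples$sample_id, rownames(counts)))
    abort_fmt("samples$sample_id does not match rownames(counts)")
  samples <- samples[match(rownames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  if ("group" %in% names(x$samples))
    print(table(x$samples$group))
  invisible(x)
}

#' Relative abundances of a community table
#'
#' @param x a `community_table` or a numeric abundance matrix (samples x taxa).
#' @return matrix of per-sample relative abundances; each row sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "community_table")) x$counts else as.matrix(x)
  rs <- rowSums(m)
  if (any(rs <= 0)) abort_fmt("sample '%s' has zero total abundance",
                              rownames(m)[which(rs <= 0)[1L]])
  sweep(m, 1, rs, "/")
}

#' Per-taxon genomic trait reference
#'
#' @param taxon_id character vector of taxon ids.
#' @param rrn_copies mean 16S rRNA operon copies per genome (>= 1; fractional
#'   values arise from averaging several equally good genome matches). NA for
#'   unmatched taxa.
#' @param genome_size_mbp genome size in Mbp (> 0, NA if unmatched).
#' @param gc_percent genome GC content in percent (0-100 exclusive, NA if
#'   unmatched).
#' @return data.frame of class `trait_reference` with a logical `matched`
#'   column.
#' @export
trait_reference <- function(taxon_id, rrn_copies, genome_size_mbp, gc_percent) {
  if (length(taxon_id) == 0L) abort_fmt("empty taxon list")
  matched <- !is.na(rrn_copies)
  ok <- matched
  if (any(rrn_copies[ok] < 1)) abort_fmt("rrn_copies must be >= 1")
  if (any(genome_size_mbp[!is.na(genome_size_mbp)] <= 0))
    abort_fmt("genome_size_mbp must be positive")
  gc <- gc_percent[!is.na(gc_percent)]
  if (any(gc <= 0 | gc >= 100)) abort_fmt("gc_percent must lie in (0, 100)")
  out <- data.frame(taxon_id = as.character(taxon_id),
                    rrn_copies = as.numeric(rrn_copies),
                    genome_size_mbp = as.numeric(genome_size_mbp),
                    gc_percent = as.numeric(gc_percent),
                    matched = matched,
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_reference", "data.frame")
  out
}

#' Functional-gene probe intensity table
#'
#' Probes-by-samples intensity matrix in the style of a functional-gene
#' microarray, with per-probe gene and carbon-substrate-category annotations.
#' Zero intensity encodes non-detection.
#'
#' @param intensity numeric matrix, probes in rows, samples in columns;
#'   non-negative.
#' @param annotation data.frame with columns `probe_id`, `gene`, `category`,
#'   one row per probe, matching `rownames(intensity)`.
#' @param groups character vector of group labels, one per sample (named by
#'   sample id or in column order).
#' @return object of class `probe_table`.
#' @export
probe_table <- function(intensity, annotation, groups) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) > 0 && (!is.numeric(intensity) || anyNA(intensity)))
    abort_fmt("intensities must be numeric and complete")
  if (any(intensity < 0)) abort_fmt("negative probe intensity")
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "category")
  if (!all(need %in% names(annotation)))
    abort_fmt("annotation must contain columns %s", paste(need, collapse = ", "))
  if (nrow(annotation) != nrow(intensity))
    abort_fmt("annotation rows (%d) != intensity rows (%d)",
              nrow(annotation), nrow(intensity))
  if (anyNA(annotation$gene) || any(annotation$gene == ""))
    abort_fmt("every probe needs a gene annotation")
  if (nrow(intensity) > 0 && is.null(rownames(intensity)))
    rownames(intensity) <- annotation$probe_id
  groups <- as.character(groups)
  if (length(groups) != ncol(intensity))
    abort_fmt("groups length (%d) != number of samples (%d)",
              length(groups), ncol(intensity))
  if (!is.null(names(groups)) && ncol(intensity) > 0)
    groups <- groups[colnames(intensity)]
  structure(list(intensity = intensity, annotation = annotation,
                 groups = unname(groups)),
            class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes x %d samples, %d genes\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$annotation$gene))))
  invisible(x)
}

#' Daily environmental forcing series
#'
#' @param day integer day index (1-based, consecutive).
#' @param temperature_C daily mean soil temperature.
#' @param moisture_vv volumetric soil moisture in (0, 1].
#' @param litter_input litter-fall carbon input, mg C g^-1 soil d^-1 (>= 0).
#' @param start_date origin for the ISO-8601 date column (default
#'   `"2016-01-01"`).
#' @return data.frame of class `mend_forcing` with columns `date`, `day`,
#'   `temperature_C`, `moisture_vv`, `litter_input`.
#' @export
mend_forcing <- function(day, temperature_C, moisture_vv, litter_input,
                         start_date = "2016-01-01") {
  n <- length(day)
  if (n < 1L) abort_fmt("forcing must contain at least one day")
  if (!identical(as.integer(day), seq_len(n)))
    abort_fmt("forcing days must be consecutive 1..n (gap-filled series required)")
  lens <- c(length(temperature_C), length(moisture_vv), length(litter_input))
  if (any(lens != n)) abort_fmt("forcing series have unequal lengths")
  if (anyNA(c(temperature_C, moisture_vv, litter_input)))
    abort_fmt("forcing contains missing values; supply a cleaned, gap-filled series")
  if (any(moisture_vv <= 0 | moisture_vv > 1))
    abort_fmt("moisture must lie in (0, 1]; offending day %d",
              which(moisture_vv <= 0 | moisture_vv > 1)[1L])
  if (any(litter_input < 0))
    abort_fmt("litter input must be >= 0; offending day %d",
              which(litter_input < 0)[1L])
  out <- data.frame(
    date = as.Date(start_date) + (seq_len(n) - 1L),
    day = as.integer(day),
    temperature_C = as.numeric(temperature_C),
    moisture_vv = as.numeric(moisture_vv),
    litter_input = as.numeric(litter_input)
  )
  class(out) <- c("mend_forcing", "data.frame")
  out
}
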
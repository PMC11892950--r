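# Readers and writers for the plain-text interchange formats used by the
# pipeline: abundance/probe tables as TSV (taxa or probes as rows, samples as
# columns, annotation columns prefixed '#'), forcing and observation series as
# CSV with an ISO-8601 date column.

#' Write / read a community table
#'
#' The on-disk layout is TSV with taxa as rows and samples as columns; sample
#' metadata columns are carried in a header block of lines starting with
#' `#meta`.
#'
#' @param x a [community_table()].
#' @param path file path.
#' @return `write_community_table` returns `path` invisibly;
#'   `read_community_table` returns a `community_table`.
#' @export
write_community_table <- function(x, path) {
  stopifnot(inherits(x, "community_table"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- x$samples
  for (col in setdiff(names(meta), "sample_id")) {
    writeLines(paste(c(paste0("#meta\t", col),
                       as.character(meta[[col]])), collapse = "\t"), con)
  }
  tab <- t(x$counts)  # taxa rows, sample columns
  writeLines(paste(c("#taxon_id", colnames(tab)), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' @rdname write_community_table
#' @export
read_community_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#meta\t", lines, value = TRUE)
  header_i <- grep("^#taxon_id\t", lines)[1L]
  if (is.na(header_i)) abort_fmt("%s: missing '#taxon_id' header line", path)
  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  body <- utils::read.table(text = lines[(header_i + 1L):length(lines)],
                            sep = "\t", row.names = 1L,
                            colClasses = c("character", rep("numeric",
                                                            length(sample_ids))))
  colnames(body) <- sample_ids
  samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (ml in meta_lines) {
    parts <- strsplit(ml, "\t", fixed = TRUE)[[1L]]
    col <- sub("^#meta$", "", parts[1L])
    col <- parts[2L]
    vals <- parts[-(1:2)]
    if (length(vals) != length(sample_ids))
      abort_fmt("%s: metadata column '%s' has %d values for %d samples",
                path, col, length(vals), length(sample_ids))
    suppressWarnings(num <- as.numeric(vals))
    samples[[col]] <- if (!anyNA(num)) num else vals
  }
  counts <- t(as.matrix(body))
  if (anyNA(counts)) abort_fmt("%s: non-numeric or missing abundances", path)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    abort_fmt("%s: negative abundance at sample '%s', taxon '%s'",
              path, rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  community_table(counts, samples)
}

#' Write / read a trait reference table (TSV)
#'
#' @param x a [trait_reference()].
#' @param path file path.
#' @export
write_trait_reference <- function(x, path) {
  stopifnot(inherits(x, "trait_reference"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_reference
#' @export
read_trait_reference <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  trait_reference(df$taxon_id, df$rrn_copies, df$genome_size_mbp,
                  df$gc_percent)
}

#' Write / read a probe table (TSV; annotation columns prefixed '#')
#'
#' @param x a [probe_table()].
#' @param path file path.
#' @export
write_probe_table <- function(x, path) {
  stopifnot(inherits(x, "probe_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#group", x$groups), collapse = "\t"), con)
  header <- c("#probe_id", "#gene", "#category", colnames(x$intensity))
  writeLines(paste(header, collapse = "\t"), con)
  df <- cbind(x$annotation[c("probe_id", "gene", "category")],
              as.data.frame(x$intensity))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  lines <- readLines(path)
  grp <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (grp[1L] != "#group") abort_fmt("%s: missing '#group' line", path)
  header <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-(1:3)]
  if (length(lines) > 2L) {
    body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                              stringsAsFactors = FALSE)
    names(body) <- c("probe_id", "gene", "category", sample_ids)
    intensity <- as.matrix(body[sample_ids])
    rownames(intensity) <- body$probe_id
    ann <- body[c("probe_id", "gene", "category")]
  } else {
    intensity <- matrix(numeric(0), 0, length(sample_ids),
                        dimnames = list(NULL, sample_ids))
    ann <- data.frame(probe_id = character(0), gene = character(0),
                      category = character(0))
  }
  probe_table(intensity, ann, grp[-1L])
}

#' Write / read a forcing series (CSV with ISO-8601 date column)
#'
#' @param x a [mend_forcing()] data.frame.
#' @param path file path.
#' @export
write_forcing <- function(x, path) {
  stopifnot(inherits(x, "mend_forcing"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "day", "temperature_C", "moisture_vv", "litter_input")
  if (!all(need %in% names(df)))
    abort_fmt("%s: forcing needs columns %s", path, paste(need, collapse = ", "))
  if (!identical(as.integer(df$day), seq_len(nrow(df))))
    abort_fmt("%s: forcing has missing or unordered days; gap-fill upstream",
              path)
  mend_forcing(df$day, df$temperature_C, df$moisture_vv, df$litter_input,
               start_date = df$date[1L])
}

#' Write / read an observation set (CSV, long format)
#'
#' @param x a `mend_observations` object (see [gen_observations()]).
#' @param path file path.
#' @export
write_observations <- function(x, path) {
  stopifnot(inherits(x, "mend_observations"))
  long <- do.call(rbind, lapply(names(x$series), function(nm) {
    cbind(series = nm, x$series[[nm]])
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  series <- lapply(split(df[c("date", "day", "value")], df$series),
                   function(d) {
                     d$date <- as.Date(d$date)
                     rownames(d) <- NULL
                     d
                   })
  structure(list(series = series), class = "mend_observations")
}
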
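## Readers and writers for every interchange format used by the pipeline.
## All readers fail fast with the offending row named; every writer's
## output round-trips through its reader.

.viability_cols <- c("compound", "drug_class", "cell_line", "dose_M", "day",
                     "replicate", "viability")

#' Read a long-format viability table
#'
#' Expects exactly the header
#' `compound,drug_class,cell_line,dose_M,day,replicate,viability` with one
#' observation per row (dose in molar, day in days, viability as a fraction
#' of vehicle control).
#'
#' @param path CSV file path.
#' @return Data frame of typed records.
#' @export
read_viability_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(raw), .viability_cols))
    stop_named("read_viability_csv: header must be exactly '%s', got '%s'",
               paste(.viability_cols, collapse = ","),
               paste(names(raw), collapse = ","))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop_named("read_viability_csv: non-numeric %s '%s' at row %d", col,
                 raw[[col]][bad[1]], bad[1])
    v
  }
  out <- data.frame(compound = raw$compound, drug_class = raw$drug_class,
                    cell_line = raw$cell_line, dose_M = num("dose_M"),
                    day = num("day"),
                    replicate = as.integer(num("replicate")),
                    viability = num("viability"), stringsAsFactors = FALSE)
  if (any(out$dose_M <= 0))
    stop_named("read_viability_csv: nonpositive dose at row %d",
               which(out$dose_M <= 0)[1])
  if (any(out$viability < 0))
    stop_named("read_viability_csv: negative viability at row %d",
               which(out$viability < 0)[1])
  key <- paste(out$compound, out$cell_line, out$dose_M, out$day,
               out$replicate)
  if (anyDuplicated(key))
    stop_named("read_viability_csv: duplicate observation at row %d",
               which(duplicated(key))[1])
  out
}

#' Write a viability table
#' @param table Viability data frame.
#' @param path Output CSV path.
#' @export
write_viability_csv <- function(table, path) {
  stopifnot(all(.viability_cols %in% names(table)))
  write.csv(table[.viability_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genes x samples count matrix
#'
#' Tab-separated, first column gene ids, remaining columns one sample each.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop_named("read_counts_tsv: duplicate gene id '%s'",
               genes[duplicated(genes)][1])
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop_named("read_counts_tsv: non-numeric counts")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a genes x samples count matrix
#' @param counts Matrix with gene rownames.
#' @param path Output TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the sample-metadata table
#'
#' Columns: `sample, cell_line, compound, dose_nM` (compound `"control"`
#' marks untreated samples).
#' @param path TSV path.
#' @export
read_samples_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "compound", "dose_nM")
  if (!all(need %in% names(df)))
    stop_named("read_samples_tsv: missing column(s) %s",
               paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}

#' @rdname read_samples_tsv
#' @param samples Sample table.
#' @export
write_samples_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes. Order is
#' preserved; duplicate set names are an error; duplicate members within a
#' set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with the description lines
#'   attached as `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm))
    stop_named("read_gmt: duplicate set name '%s'", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) {
    members <- if (length(p) > 2) p[-(1:2)] else character()
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("read_gmt: duplicate members deduplicated in set '%s'",
                      p[1]), call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else "", ""), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets)))
    stop_named("write_gmt: duplicate set names")
  lines <- vapply(names(sets), function(nm) {
    desc <- descriptions[[nm]] %||% ""
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write scored peak intervals (BED 3+1)
#'
#' Four tab-separated columns without header: chrom, start, end, score
#' (0-based half-open intervals, as in BED). The fourth column holds the
#' peak height score rather than a BED name field, hence the dedicated
#' reader.
#'
#' @param path BED-like file path.
#' @return A peak set (`GRanges`), see [peak_set()].
#' @export
read_peak_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4)
    stop_named("read_peak_bed: expected 4 columns (chrom, start, end, score)")
  names(df)[1:4] <- c("chrom", "start", "end", "score")
  if (!is.numeric(df$start) || !is.numeric(df$end) || !is.numeric(df$score))
    stop_named("read_peak_bed: non-numeric coordinates or scores")
  peak_set(df[1:4])
}

#' @rdname read_peak_bed
#' @param peaks A peak set.
#' @export
write_peak_bed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   score = peaks$score)
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read / write TSS coordinates as BED6
#'
#' Standard six-column BED (`chrom, pos, pos+1, gene, 0, strand`); reading
#' goes through `rtracklayer`.
#'
#' @param path BED file path.
#' @return Data frame `gene, chrom, pos, strand` (pos 0-based).
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr) - 1L,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_tss_bed
#' @param tss Data frame `gene, chrom, pos, strand`.
#' @export
write_tss_bed <- function(tss, path) {
  df <- data.frame(tss$chrom, tss$pos, tss$pos + 1L, tss$gene, 0L,
                   if ("strand" %in% names(tss)) tss$strand else "+")
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
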
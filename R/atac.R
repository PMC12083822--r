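## Control-vs-treated comparison of scored ATAC peak sets.

#' Build a validated peak set
#'
#' Peaks use BED conventions: 0-based half-open `[start, end)` intervals
#' with a positive height score. The returned `GRanges` (1-based closed,
#' as usual for Bioconductor) is sorted by (chrom, start) with names
#' `"chrom:start-end"` in BED coordinates.
#'
#' @param x Data frame with columns `chrom, start, end, score`, or a
#'   `GRanges` with a `score` column.
#' @return A sorted, named `GRanges` with metadata column `score`.
#' @export
peak_set <- function(x) {
  if (methods::is(x, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                     start = GenomicRanges::start(x) - 1L,
                     end = GenomicRanges::end(x),
                     score = x$score, stringsAsFactors = FALSE)
    return(peak_set(df))
  }
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(x)))
  if (nrow(x) > 0 && any(x$start >= x$end))
    stop_named("peak_set: intervals need start < end (row %d)",
               which(x$start >= x$end)[1])
  if (nrow(x) > 0 && any(x$score <= 0))
    stop_named("peak_set: scores must be positive")
  key <- peak_key(x$chrom, as.integer(x$start), as.integer(x$end))
  if (anyDuplicated(key))
    stop_named("peak_set: duplicate interval %s", key[duplicated(key)][1])
  ord <- order(x$chrom, x$start, x$end)
  x <- x[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    score = x$score)
  names(gr) <- peak_key(x$chrom, as.integer(x$start), as.integer(x$end))
  gr
}

#' Match peaks between control and treated conditions
#'
#' Candidate pairs are overlapping (control, treated) peaks whose
#' reciprocal overlap — the shared span divided by each interval's own
#' length — is at least `min_reciprocal_overlap` on *both* sides. Pairs are
#' accepted greedily, best first (largest minimum reciprocal overlap, ties
#' by smaller control then treated start), each peak matching at most once.
#' Unmatched control peaks are "lost", unmatched treated peaks "gained".
#'
#' @param control,treated Peak sets (see [peak_set()]).
#' @param min_reciprocal_overlap Fraction in (0, 1].
#' @return Object of class `peak_delta`: `matched` (data frame
#'   `control_key, treated_key, control_score, treated_score, log2_ratio`),
#'   `lost` and `gained` (`GRanges`), `n_control`, `n_treated`.
#' @export
match_peaks <- function(control, treated, min_reciprocal_overlap = 0.5) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  ## disjoint chromosome sets are legitimate (everything lost/gained), so
  ## silence the no-common-seqlevels warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(control, treated))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(control)[qi], GenomicRanges::ranges(treated)[si]))
  fc <- ow / GenomicRanges::width(control)[qi]
  ft <- ow / GenomicRanges::width(treated)[si]
  pass <- fc >= min_reciprocal_overlap & ft >= min_reciprocal_overlap
  qi <- qi[pass]; si <- si[pass]
  quality <- pmin(fc, ft)[pass]
  ord <- order(-quality, GenomicRanges::start(control)[qi],
               GenomicRanges::start(treated)[si])
  qi <- qi[ord]; si <- si[ord]
  c_free <- rep(TRUE, length(control))
  t_free <- rep(TRUE, length(treated))
  keep <- logical(length(qi))
  for (p in seq_along(qi)) {
    if (c_free[qi[p]] && t_free[si[p]]) {
      keep[p] <- TRUE
      c_free[qi[p]] <- FALSE
      t_free[si[p]] <- FALSE
    }
  }
  qi <- qi[keep]; si <- si[keep]
  matched <- data.frame(
    control_key = names(control)[qi],
    treated_key = names(treated)[si],
    control_score = control$score[qi],
    treated_score = treated$score[si],
    log2_ratio = log2(treated$score[si] / control$score[qi]),
    stringsAsFactors = FALSE)
  out <- list(matched = matched,
              lost = control[c_free],
              gained = treated[t_free],
              n_control = length(control),
              n_treated = length(treated))
  class(out) <- "peak_delta"
  out
}

#' @export
print.peak_delta <- function(x, ...) {
  cat(sprintf("peak_delta: %d control / %d treated peaks; %d matched, %d lost, %d gained\n",
              x$n_control, x$n_treated, nrow(x$matched), length(x$lost),
              length(x$gained)))
  invisible(x)
}

#' Link peaks to genes by TSS window
#'
#' A peak links to a gene when its interval overlaps
#' `[tss - window, tss + window)` (BED coordinates). Chromosome names are
#' normalized ("chr1" and "1" compare equal); when the two inputs use
#' different styles this is noted with a message. A peak may link to any
#' number of genes.
#'
#' @param peaks A peak set (see [peak_set()]).
#' @param tss Data frame `gene, chrom, pos` (0-based TSS position),
#'   optionally `strand`.
#' @param window Half-width of the linking window in bp.
#' @return Named list: gene -> character vector of linked peak keys.
#' @export
link_peaks_to_genes <- function(peaks, tss, window = 5e4) {
  stopifnot(all(c("gene", "chrom", "pos") %in% names(tss)), window >= 0)
  pk_chr <- as.character(GenomicRanges::seqnames(peaks))
  pref <- grepl("^chr", c(pk_chr, tss$chrom))
  mixed <- any(pref) && !all(pref)
  if (mixed)
    message("link_peaks_to_genes: normalizing mixed chromosome-name styles")
  win <- GenomicRanges::GRanges(
    seqnames = norm_chrom(tss$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, as.integer(tss$pos - window + 1L)),
                              end = as.integer(tss$pos + window)))
  pk <- GenomicRanges::GRanges(
    seqnames = norm_chrom(pk_chr),
    ranges = GenomicRanges::ranges(peaks))
  hits <- GenomicRanges::findOverlaps(win, pk)
  out <- setNames(vector("list", nrow(tss)), tss$gene)
  for (g in tss$gene) out[[g]] <- character()
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    sp <- split(names(peaks)[sh], tss$gene[qh])
    for (g in names(sp)) out[[g]] <- unname(sp[[g]])
  }
  out
}

#' Peak losses, gains and significant height changes for a gene set
#'
#' For each gene, counts the linked peaks that were lost or gained between
#' conditions and collects the matched-peak log2 score ratios whose
#' magnitude is at least `min_abs_log2` (boundary inclusive). Links should
#' be computed on the union of the control and treated peak sets. A pooled
#' summary over the gene set is attached.
#'
#' @param delta A `peak_delta` from [match_peaks()].
#' @param links Output of [link_peaks_to_genes()].
#' @param genes Gene ids to report.
#' @param min_abs_log2 Threshold on `|log2(treated/control)|`.
#' @return Data frame `gene, n_linked, n_lost, n_gained, n_sig_down,
#'   n_sig_up, flagged` (flagged = gene absent from links); attribute
#'   `pooled` holds totals and the significant log2 ratios.
#' @export
gene_set_peak_changes <- function(delta, links, genes, min_abs_log2 = 1) {
  stopifnot(inherits(delta, "peak_delta"))
  lost_keys <- names(delta$lost)
  gained_keys <- names(delta$gained)
  sig <- delta$matched[abs(delta$matched$log2_ratio) >= min_abs_log2, ,
                       drop = FALSE]
  rows <- lapply(genes, function(g) {
    lk <- links[[g]]
    flagged <- is.null(lk)
    lk <- lk %||% character()
    in_sig <- sig$control_key %in% lk | sig$treated_key %in% lk
    data.frame(gene = g,
               n_linked = length(lk),
               n_lost = sum(lost_keys %in% lk),
               n_gained = sum(gained_keys %in% lk),
               n_sig_down = sum(in_sig & sig$log2_ratio < 0),
               n_sig_up = sum(in_sig & sig$log2_ratio > 0),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pooled") <- list(
    total_lost = sum(out$n_lost), total_gained = sum(out$n_gained),
    total_sig_down = sum(out$n_sig_down), total_sig_up = sum(out$n_sig_up))
  out
}
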
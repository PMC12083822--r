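## Count normalization, fold changes, fold-change gene sets, baseline
## clustering and cluster-level differential expression / drug sensitivity.

#' Library-size normalization to log2 scale
#'
#' `cpm_log2` computes `log2(1e6 * count / libsize + pseudocount)`.
#' `median_of_ratios_log2` estimates per-sample size factors as the median,
#' over genes with a nonzero geometric mean, of the count-to-geometric-mean
#' ratio, and returns `log2(count / sf + pseudocount)`. All-zero gene rows
#' are retained, never dropped.
#'
#' @param counts Gene x sample matrix of nonnegative counts.
#' @param method `"median_of_ratios_log2"` (default) or `"cpm_log2"`.
#' @param pseudocount Added before taking log2.
#' @return Matrix of the same shape, log2 scale. For the median-of-ratios
#'   method the size factors are attached as `attr(, "size_factors")`.
#' @export
normalize_counts <- function(counts,
                             method = c("median_of_ratios_log2", "cpm_log2"),
                             pseudocount = 1) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts) || is.data.frame(counts))
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_named("normalize_counts: negative counts")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop_named("normalize_counts: all-zero sample")
  if (method == "cpm_log2")
    return(log2(sweep(counts, 2, libsize / 1e6, "/") + pseudocount))
  sf <- size_factors_mor(counts)
  out <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  attr(out, "size_factors") <- sf
  out
}

#' Median-of-ratios size factors
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors_mor <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))          # -Inf for genes with any zero
  use <- is.finite(log_geo)
  if (!any(use))
    stop_named("size_factors_mor: no gene has all-nonzero counts")
  apply(counts[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - log_geo[use])))
}

#' Per-gene log2 fold change of every treated sample against its control
#'
#' On the default normalized scale, `log2fc = norm(treated) - norm(control)`
#' for the same gene within the same cell line; `mode = "raw_ratio"` instead
#' uses `log2((treated + pc) / (control + pc))` on library-size-corrected
#' raw counts.
#'
#' @param bundle An `expression_bundle`.
#' @param pseudocount Pseudocount for the raw-ratio mode.
#' @param mode `"normalized"` (default) or `"raw_ratio"`.
#' @return Data frame of class `fold_change_table`:
#'   `gene, cell_line, compound, log2fc`, one row per gene per treated
#'   sample.
#' @export
fold_changes <- function(bundle, pseudocount = 1,
                         mode = c("normalized", "raw_ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "expression_bundle"))
  s <- bundle$samples
  treated <- s[s$compound != "control", , drop = FALSE]
  ctrl_of <- setNames(s$sample[s$compound == "control"],
                      s$cell_line[s$compound == "control"])
  missing <- setdiff(unique(treated$cell_line), names(ctrl_of))
  if (length(missing))
    stop_named("fold_changes: no control sample for line %s", missing[1])
  mat <- if (mode == "normalized") {
    bundle$norm
  } else {
    sf <- colSums(bundle$counts)
    sf <- sf / exp(mean(log(sf)))
    log2(sweep(bundle$counts, 2, sf, "/") + pseudocount)
  }
  genes <- rownames(mat)
  blocks <- lapply(seq_len(nrow(treated)), function(i) {
    tr <- treated$sample[i]
    ct <- ctrl_of[[treated$cell_line[i]]]
    data.frame(gene = genes, cell_line = treated$cell_line[i],
               compound = treated$compound[i],
               log2fc = mat[, tr] - mat[, ct], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Derive up/down fold-change gene sets per (line, compound)
#'
#' A gene is up-regulated in a cell when `log2fc >= log2(threshold)` and
#' down-regulated when `log2fc <= -log2(threshold)` (boundaries inclusive).
#'
#' @param fc A `fold_change_table`.
#' @param threshold Fold-change cutoff (> 1); default 2-fold.
#' @return Object of class `gene_set_grid`: list with `up` and `down`
#'   (lists keyed `"line|compound"`), `lines`, `compounds`, and the count
#'   matrices `counts_up` / `counts_down` (lines x compounds).
#' @export
derive_gene_sets <- function(fc, threshold = 2) {
  stopifnot(threshold > 1)
  cut <- log2(threshold)
  lines <- unique(fc$cell_line)
  compounds <- unique(fc$compound)
  key <- cell_key(fc$cell_line, fc$compound)
  up <- split(fc$gene[fc$log2fc >= cut], key[fc$log2fc >= cut])
  down <- split(fc$gene[fc$log2fc <= -cut], key[fc$log2fc <= -cut])
  all_keys <- as.vector(outer(lines, compounds, cell_key))
  fill <- function(sets) {
    out <- setNames(vector("list", length(all_keys)), all_keys)
    for (k in all_keys) out[[k]] <- sets[[k]] %||% character()
    out
  }
  up <- fill(up)
  down <- fill(down)
  cnt <- function(sets) {
    m <- matrix(0L, length(lines), length(compounds),
                dimnames = list(lines, compounds))
    for (l in lines) for (cm in compounds)
      m[l, cm] <- length(sets[[cell_key(l, cm)]])
    m
  }
  out <- list(up = up, down = down, lines = lines, compounds = compounds,
              counts_up = cnt(up), counts_down = cnt(down))
  class(out) <- "gene_set_grid"
  out
}

#' Correlation between transcriptomic effect size and potency
#'
#' Per compound, averages the total number of >= threshold-fold genes
#' (`|up| + |down|`) across lines and the corresponding `-log10(IC-50)`
#' across lines, then reports the Pearson correlation (and two-sided
#' p-value) between the two per-compound summaries.
#'
#' @param grid A `gene_set_grid`.
#' @param ic50s Data frame `compound, cell_line, ic50` (molar).
#' @return List: `r`, `p`, `n` (compounds used) and the per-compound
#'   summary `table`. `r` is `NA` with `flag = "zero_variance"` when either
#'   summary is constant.
#' @export
target_count_vs_ic50 <- function(grid, ic50s) {
  stopifnot(inherits(grid, "gene_set_grid"),
            all(c("compound", "cell_line", "ic50") %in% names(ic50s)))
  compounds <- intersect(grid$compounds, unique(ic50s$compound))
  if (length(compounds) < 3L)
    stop_named("target_count_vs_ic50: need >= 3 compounds, got %d",
               length(compounds))
  tab <- data.frame(
    compound = compounds,
    mean_targets = vapply(compounds, function(cm)
      mean(grid$counts_up[, cm] + grid$counts_down[, cm]), 0),
    mean_neglog10_ic50 = vapply(compounds, function(cm)
      mean(-log10(ic50s$ic50[ic50s$compound == cm])), 0),
    stringsAsFactors = FALSE)
  if (sd(tab$mean_targets) == 0 || sd(tab$mean_neglog10_ic50) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(tab), table = tab,
                flag = "zero_variance"))
  ct <- cor.test(tab$mean_targets, tab$mean_neglog10_ic50)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(tab), table = tab)
}

#' Two-cluster partition of lines from baseline (control) expression
#'
#' PCA of the line x gene matrix of control-sample normalized expression
#' (restricted to the `n_top_genes` most variable genes, gene-centered),
#' followed by k-means with k = 2 on the first `n_pcs` principal-component
#' scores (10 restarts under a fixed seed). Cluster 1 is the cluster with
#' more lines; on a tie, the one containing the lexicographically first
#' line.
#'
#' @param bundle An `expression_bundle`.
#' @param n_pcs Number of PC scores fed to k-means.
#' @param n_top_genes Variable-gene count for PCA.
#' @param seed RNG seed for k-means restarts.
#' @return Object of class `cluster_result`: `cluster_of_line` (named
#'   integer), `pc_scores` (line x n_pcs), `var_genes`.
#' @export
baseline_clusters <- function(bundle, n_pcs = 2, n_top_genes = 2000, seed = 1) {
  stopifnot(inherits(bundle, "expression_bundle"))
  s <- bundle$samples
  ctrl <- s[s$compound == "control", ]
  if (nrow(ctrl) < 4L)
    stop_named("baseline_clusters: need >= 4 control samples, got %d", nrow(ctrl))
  mat <- t(bundle$norm[, ctrl$sample, drop = FALSE])   # lines x genes
  rownames(mat) <- ctrl$cell_line
  v <- apply(mat, 2, var)
  if (sum(v > 0) < 2L)
    stop_named("baseline_clusters: fewer than 2 distinct expression profiles")
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, sum(v > 0)))]
  mat <- scale(mat[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  ## order-invariant PCA/k-means: process lines in sorted order
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  pc <- prcomp(mat, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  km <- with_seed(seed, kmeans(scores, centers = 2, nstart = 10))
  assign <- setNames(km$cluster, rownames(scores))
  n1 <- sum(assign == 1L)
  n2 <- sum(assign == 2L)
  flip <- n2 > n1 || (n1 == n2 && assign[[min(names(assign))]] == 2L)
  if (flip) assign <- setNames(3L - assign, names(assign))
  out <- list(cluster_of_line = assign, pc_scores = scores,
              var_genes = colnames(mat))
  class(out) <- "cluster_result"
  out
}

#' Per-drug IC-50 comparison between baseline clusters
#'
#' Welch t-test on log10 IC-50 between cluster-1 and cluster-2 lines, per
#' compound. Means are reported as geometric means on the molar scale.
#'
#' @param clusters A `cluster_result` (or named cluster vector).
#' @param ic50s Data frame `compound, cell_line, ic50`.
#' @param alpha Significance cutoff used in the attached summary counts.
#' @return Data frame `compound, mean_ic50_c1, mean_ic50_c2, p,
#'   cluster2_higher`; attribute `summary` counts compounds with `p < alpha`
#'   and cluster 2 higher.
#' @export
cluster_drug_resistance <- function(clusters, ic50s, alpha = 0.05) {
  cl <- if (inherits(clusters, "cluster_result")) clusters$cluster_of_line
        else clusters
  rows <- lapply(unique(ic50s$compound), function(cm) {
    sub <- ic50s[ic50s$compound == cm, ]
    x <- log10(sub$ic50[cl[sub$cell_line] == 1L])
    y <- log10(sub$ic50[cl[sub$cell_line] == 2L])
    p <- if (length(x) >= 2L && length(y) >= 2L)
      tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(compound = cm,
               mean_ic50_c1 = 10^mean(x), mean_ic50_c2 = 10^mean(y),
               p = p, cluster2_higher = mean(y) > mean(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_significant = sum(out$p < alpha, na.rm = TRUE),
    n_significant_c2_higher = sum(out$p < alpha & out$cluster2_higher,
                                  na.rm = TRUE))
  out
}

#' Differential expression between baseline clusters
#'
#' Per gene, on control samples only: mean difference (cluster 1 minus
#' cluster 2, log2 units), Welch t-test p-value, Benjamini–Hochberg q, and
#' a ranking score `|mean_diff| * -log10(p)`. Genes with zero variance in
#' both clusters get a variance floor (the smallest nonzero per-group gene
#' variance) and are flagged.
#'
#' @param clusters A `cluster_result` (or named cluster vector).
#' @param bundle An `expression_bundle`.
#' @return Data frame sorted by descending `rank_score`: `gene, mean_diff,
#'   p, q, rank_score, floored`.
#' @export
cluster_de <- function(clusters, bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  cl <- if (inherits(clusters, "cluster_result")) clusters$cluster_of_line
        else clusters
  s <- bundle$samples
  ctrl <- s[s$compound == "control", ]
  m <- bundle$norm[, ctrl$sample, drop = FALSE]
  g1 <- m[, cl[ctrl$cell_line] == 1L, drop = FALSE]
  g2 <- m[, cl[ctrl$cell_line] == 2L, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 2L || n2 < 2L)
    stop_named("cluster_de: each cluster needs >= 2 lines")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
  floored <- v1 == 0 & v2 == 0
  nonzero <- c(v1[v1 > 0], v2[v2 > 0])
  if (any(floored)) {
    if (!length(nonzero))
      stop_named("cluster_de: all gene variances are zero")
    floor_v <- min(nonzero)
    v1[floored] <- floor_v
    v2[floored] <- floor_v
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[is.na(p)] <- 1
  q <- p.adjust(p, method = "BH")
  rank_score <- abs(m1 - m2) * -log10(pmax(p, .Machine$double.xmin))
  out <- data.frame(gene = rownames(m), mean_diff = m1 - m2, p = p, q = q,
                    rank_score = rank_score, floored = floored,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_score, out$gene), ]
  rownames(out) <- NULL
  out
}
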
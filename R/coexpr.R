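## Weighted co-expression analysis: soft-threshold selection by approximate
## scale-free topology, unsigned adjacency, topological overlap, module
## detection by average-linkage clustering, hub neighborhoods and
## module-drug effect scoring.

## drop zero-variance gene rows, recording how many were removed
.drop_constant_genes <- function(norm) {
  v <- apply(norm, 1, var)
  removed <- sum(v == 0)
  if (removed > 0)
    message(sprintf("coexpr: removed %d constant gene(s) before correlation",
                    removed))
  structure(norm[v > 0, , drop = FALSE], n_removed = removed)
}

#' Pick the soft-thresholding power by approximate scale-free topology
#'
#' For each candidate power, the weighted connectivity of gene *i* is
#' `k_i = sum_j |cor(i, j)|^beta` over `j != i`. Connectivities are binned
#' into 10 equal-width bins and the scale-free fit is the R-squared of the
#' regression of `log10(frequency)` on `log10(mean k)` over nonempty bins.
#' The selected power is the smallest one with fit >= `fit_cut`; when no
#' power reaches the cut, the power maximizing the fit is returned with
#' `converged = FALSE`.
#'
#' @param norm Gene x sample matrix of log2 expression (>= 10 genes,
#'   >= 3 samples); constant genes are removed with a message.
#' @param powers Ascending integer candidate powers.
#' @param fit_cut R-squared criterion for approximate scale-free topology.
#' @return List: `beta`, `fit_table` (power, r_squared, slope, mean_k),
#'   `converged`, `n_removed`.
#' @export
pick_soft_threshold <- function(norm, powers = 1:12, fit_cut = 0.8) {
  stopifnot(is.matrix(norm), ncol(norm) >= 3, !is.unsorted(powers))
  norm <- .drop_constant_genes(norm)
  if (nrow(norm) < 10L)
    stop_named("pick_soft_threshold: need >= 10 non-constant genes for binning, got %d",
               nrow(norm))
  ac <- abs(cor(t(norm)))
  fit_one <- function(beta) {
    k <- colSums(ac^beta) - 1       # remove the diagonal contribution
    brk <- seq(min(k), max(k), length.out = 11L)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- as.vector(table(bin)) / length(k)
    mk <- tapply(k, bin, mean)
    use <- freq > 0 & !is.na(mk) & mk > 0
    if (sum(use) < 3L)
      return(c(r_squared = NA_real_, slope = NA_real_, mean_k = mean(k)))
    f <- lm(log10(freq[use]) ~ log10(mk[use]))
    c(r_squared = summary(f)$r.squared, slope = unname(coef(f)[2]),
      mean_k = mean(k))
  }
  fits <- t(vapply(powers, fit_one, c(r_squared = 0, slope = 0, mean_k = 0)))
  fit_table <- data.frame(power = powers, fits, row.names = NULL)
  ok <- which(!is.na(fit_table$r_squared) & fit_table$r_squared >= fit_cut)
  if (length(ok)) {
    beta <- powers[ok[1]]
    converged <- TRUE
  } else {
    beta <- powers[which.max(fit_table$r_squared)]
    converged <- FALSE
  }
  list(beta = beta, fit_table = fit_table, converged = converged,
       n_removed = attr(norm, "n_removed"))
}

#' Unsigned (or signed) co-expression adjacency
#'
#' `a_ij = |cor(i, j)|^beta` (unsigned, default) or
#' `((1 + cor) / 2)^beta` (signed), with a zero diagonal.
#'
#' @param norm Gene x sample matrix; constant genes removed with a message.
#' @param beta Soft-thresholding power.
#' @param signed Use the signed transformation.
#' @return Symmetric gene x gene matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency_matrix <- function(norm, beta, signed = FALSE) {
  stopifnot(beta >= 1)
  norm <- .drop_constant_genes(norm)
  cc <- cor(t(norm))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' For a symmetric adjacency with zero diagonal and entries in \[0, 1\],
#' with connectivity `k_i = sum_u a_iu`:
#' `tom_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, and `tom_ii = 1`. The numerator counts shared neighbors plus
#' the direct edge, so genes sharing many strong neighbors score high even
#' when weakly connected directly.
#'
#' @param adjacency Symmetric matrix, zero diagonal, entries in \[0, 1\].
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-8)
    stop_named("tom_matrix: adjacency must be symmetric")
  if (any(diag(a) != 0))
    stop_named("tom_matrix: adjacency must have a zero diagonal")
  if (any(a < 0 | a > 1)) stop_named("tom_matrix: entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`.
#' The tree is cut at the height, scanned over the fixed grid 0.05 to 0.99
#' in steps of 0.01, that yields the largest number of clusters of size >=
#' `min_module_size`; ties are resolved toward the height assigning the
#' most genes to admissible clusters (avoiding fragmented cuts), then
#' toward the lower height. Clusters
#' below the size threshold are assigned module 0 (unassigned); surviving
#' modules are labelled 1..m by decreasing size.
#'
#' @param tom Topological overlap matrix (unit diagonal).
#' @param min_module_size Minimum genes per module.
#' @return Named integer vector gene -> module id (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30) {
  n <- nrow(tom)
  genes <- rownames(tom) %||% as.character(seq_len(n))
  if (n < min_module_size)
    return(setNames(rep(0L, n), genes))
  hc <- hclust(as.dist(1 - tom), method = "average")
  ## exact ties can leave microscopically non-monotone merge heights, which
  ## cutree() rejects; clamp to the monotone envelope
  hc$height <- cummax(round(hc$height, 12))
  heights <- seq(0.05, 0.99, by = 0.01)
  stats <- vapply(heights, function(h) {
    sz <- table(cutree(hc, h = h))
    big <- sz[sz >= min_module_size]
    c(n_big = length(big), assigned = sum(big))
  }, c(n_big = 0L, assigned = 0L))
  if (max(stats["n_big", ]) == 0L)
    return(setNames(rep(0L, n), genes))
  ## most clusters of admissible size; ties resolved toward the height that
  ## assigns the most genes, then toward the lower height
  cand <- which(stats["n_big", ] == max(stats["n_big", ]))
  cand <- cand[stats["assigned", cand] == max(stats["assigned", cand])]
  h_best <- heights[cand[1]]
  cl <- cutree(hc, h = h_best)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  ## label by decreasing size; ties by first appearance in gene order
  first_idx <- vapply(big, function(b) min(which(cl == b)), 0L)
  big <- big[order(-sizes[big], first_idx)]
  out <- rep(0L, n)
  for (m in seq_along(big)) out[cl == big[m]] <- m
  setNames(out, genes)
}

#' Build a full co-expression network
#'
#' Convenience wrapper chaining [pick_soft_threshold()],
#' [adjacency_matrix()], [tom_matrix()] and [detect_modules()].
#'
#' @inheritParams pick_soft_threshold
#' @inheritParams detect_modules
#' @param signed Signed adjacency.
#' @param beta Fixed power; when `NULL` it is selected by scale-free fit.
#' @return Object of class `coexpr_network`: `genes, beta, adjacency, tom,
#'   module_of, fit_table, converged, min_module_size`.
#' @export
build_coexpr_network <- function(norm, powers = 1:12, fit_cut = 0.8,
                                 min_module_size = 30, signed = FALSE,
                                 beta = NULL) {
  fit_table <- NULL
  converged <- NA
  if (is.null(beta)) {
    st <- pick_soft_threshold(norm, powers = powers, fit_cut = fit_cut)
    beta <- st$beta
    fit_table <- st$fit_table
    converged <- st$converged
  }
  adj <- suppressMessages(adjacency_matrix(norm, beta, signed = signed))
  tom <- tom_matrix(adj)
  module_of <- detect_modules(tom, min_module_size = min_module_size)
  out <- list(genes = rownames(adj), beta = beta, adjacency = adj, tom = tom,
              module_of = module_of, fit_table = fit_table,
              converged = converged, min_module_size = min_module_size)
  class(out) <- "coexpr_network"
  out
}

#' @export
print.coexpr_network <- function(x, ...) {
  sizes <- table(x$module_of[x$module_of > 0])
  cat(sprintf("coexpr_network: %d genes, beta = %d, %d module(s)\n",
              length(x$genes), x$beta, length(sizes)))
  if (length(sizes))
    cat("  module sizes:", paste(sprintf("%s:%d", names(sizes), sizes),
                                 collapse = ", "), "\n")
  cat(sprintf("  unassigned: %d\n", sum(x$module_of == 0)))
  invisible(x)
}

#' Hub-gene correlation neighborhood
#'
#' Pearson correlation of every other gene with the hub across all samples
#' (all lines, all treatments); the `k` genes with the largest `|r|` form
#' the neighborhood, with spoke length `1 - |r|` (shorter = more strongly
#' correlated). Ties are broken by gene id.
#'
#' @param norm Gene x sample matrix including the hub row.
#' @param hub Hub gene id.
#' @param k Neighborhood size.
#' @return Data frame of class `hub_neighborhood` (`gene, r,
#'   spoke_length`), sorted by `|r|` descending, with attribute `hub`.
#' @export
hub_neighborhood <- function(norm, hub, k = 20) {
  if (!hub %in% rownames(norm))
    stop_named("hub_neighborhood: hub gene '%s' not in matrix", hub)
  others <- setdiff(rownames(norm), hub)
  if (length(others) < k)
    stop_named("hub_neighborhood: need >= %d other genes, got %d", k,
               length(others))
  if (sd(norm[hub, ]) == 0)
    stop_named("hub_neighborhood: hub gene is constant")
  r <- suppressWarnings(as.vector(cor(norm[hub, ], t(norm[others, , drop = FALSE]))))
  names(r) <- others
  r[is.na(r)] <- 0    # constant partners carry no correlation signal
  ord <- order(-abs(r), names(r))[seq_len(k)]
  out <- data.frame(gene = names(r)[ord], r = unname(r[ord]),
                    spoke_length = 1 - abs(unname(r[ord])),
                    stringsAsFactors = FALSE)
  class(out) <- c("hub_neighborhood", "data.frame")
  attr(out, "hub") <- hub
  out
}

#' Average module fold change per drug
#'
#' For each compound, the mean log2 fold change over all module genes and
#' all lines — the module-level drug effect. With `expanded = TRUE` a
#' gene x compound matrix of per-gene line-averaged fold changes is
#' returned instead.
#'
#' @param module_genes Character vector of module gene ids (e.g. a hub
#'   neighborhood plus the hub).
#' @param fc A `fold_change_table`.
#' @param expanded Return the per-gene matrix.
#' @return Data frame `compound, mean_log2fc` (or gene x compound matrix).
#' @export
module_drug_effect <- function(module_genes, fc, expanded = FALSE) {
  stopifnot(length(module_genes) > 0)
  sub <- fc[fc$gene %in% module_genes, , drop = FALSE]
  if (!nrow(sub))
    stop_named("module_drug_effect: none of the module genes are in the fold-change table")
  if (expanded) {
    agg <- aggregate(log2fc ~ gene + compound, data = sub, FUN = mean)
    genes <- sort(unique(agg$gene))
    compounds <- unique(fc$compound)
    m <- matrix(NA_real_, length(genes), length(compounds),
                dimnames = list(genes, compounds))
    m[cbind(agg$gene, agg$compound)] <- agg$log2fc
    return(m)
  }
  agg <- aggregate(log2fc ~ compound, data = sub, FUN = mean)
  out <- data.frame(compound = agg$compound, mean_log2fc = agg$log2fc,
                    stringsAsFactors = FALSE)
  out[match(unique(fc$compound), out$compound), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}
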
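## Synthetic-data generators: viability screens, RNA-seq counts, ATAC peaks.

#' Generate a replicate-level viability table from a screen truth
#'
#' Mean viability at dose d and timepoint t follows the stored
#' four-parameter logistic with a time-scaled IC-50:
#' `ic50(t) = ic50 * (t/ref_day)^(-s)` for delayed compounds (more potent
#' with prolonged exposure) and `ic50 * (t/ref_day)^(+s)` for acute ones
#' (effect washes out). Inert compounds have mean viability 1 at every dose.
#' Gaussian noise with sd `truth$noise_sd` is added and truncated at 0.
#'
#' @param truth A [screen_truth()] object.
#' @param doses Either a numeric vector of molar doses used at every
#'   timepoint, or a named list mapping timepoint (days, as character) to its
#'   own dose vector — the primary screen uses 1 and 10 uM at day 3 but only
#'   500 nM at day 28.
#' @param timepoints Numeric vector of assay days.
#' @param replicates Number of replicate wells per condition.
#' @param seed RNG seed.
#' @param noise_sd Overrides `truth$noise_sd` when not `NULL`.
#' @return Long-format data frame (one row per observation) with columns
#'   `compound, drug_class, cell_line, dose_M, day, replicate, viability`.
#' @export
generate_screen <- function(truth, doses = list(`3` = c(1e-6, 1e-5), `28` = 5e-7),
                            timepoints = c(3, 28), replicates = 2, seed = 1,
                            noise_sd = NULL) {
  stopifnot(inherits(truth, "screen_truth"), replicates >= 1)
  noise_sd <- noise_sd %||% truth$noise_sd
  if (!is.list(doses))
    doses <- setNames(rep(list(sort(doses)), length(timepoints)),
                      as.character(timepoints))
  for (tp in as.character(timepoints)) {
    if (is.null(doses[[tp]]))
      stop_named("generate_screen: no doses given for timepoint %s", tp)
    if (is.unsorted(doses[[tp]], strictly = TRUE))
      stop_named("generate_screen: doses must be sorted ascending")
  }
  fp <- truth$fourpl
  blocks <- lapply(as.character(timepoints), function(tp) {
    t <- as.numeric(tp)
    d <- doses[[tp]]
    g <- fp[rep(seq_len(nrow(fp)), each = length(d)), ]
    g$dose_M <- rep(d, times = nrow(fp))
    g$day <- t
    kin <- truth$kinetics[g$compound]
    if (anyNA(kin))
      stop_named("generate_screen: compound without kinetics in truth: %s",
                 g$compound[which(is.na(kin))[1]])
    s <- truth$kinetics_strength[g$compound]
    scale <- (t / truth$ref_day)^(ifelse(kin == "delayed", -s, s))
    mu <- fourpl(g$dose_M, g$top, g$bottom, g$ic50 * scale, g$hill)
    mu[kin == "inert"] <- 1
    g$mu <- mu
    g
  })
  tab <- do.call(rbind, blocks)
  tab <- tab[rep(seq_len(nrow(tab)), each = replicates), ]
  tab$replicate <- rep(seq_len(replicates), length.out = nrow(tab))
  cls <- setNames(truth$compounds$drug_class, truth$compounds$compound)
  tab$drug_class <- cls[tab$compound]
  out <- with_seed(seed, {
    v <- tab$mu + if (noise_sd > 0) rnorm(nrow(tab), 0, noise_sd) else 0
    data.frame(compound = tab$compound, drug_class = tab$drug_class,
               cell_line = tab$cell_line, dose_M = tab$dose_M, day = tab$day,
               replicate = tab$replicate, viability = pmax(0, v),
               stringsAsFactors = FALSE)
  })
  out <- out[order(out$compound, out$cell_line, out$day, out$dose_M,
                   out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Generate negative-binomial RNA-seq counts with planted structure
#'
#' One control and one treated sample per (line, compound). Per-gene means
#' on the log2 scale are the baseline abundance, plus the per-line module
#' latent factor times the gene loading, plus the cluster-marker elevation
#' in cluster-1 lines, plus the planted treatment effects (consistent
#' down-set, per-line stress up-sets, line/compound-specific sets, module
#' down-shift). Means are rescaled per sample to a drawn library size and
#' counts are sampled as NB with variance `mu + dispersion * mu^2`.
#'
#' @param truth An [expression_truth()] object.
#' @param lines,compounds Subsets to generate (defaults: all in truth).
#' @param libsize_range Length-2 numeric, uniform library-size range.
#' @param dispersion NB dispersion (mean–dispersion parameterization); must
#'   be > 0.
#' @param seed RNG seed.
#' @param normalization Method handed to [normalize_counts()] for the
#'   bundled `norm` matrix.
#' @return An `expression_bundle`: list with integer `counts` (gene x
#'   sample), `norm` (log2 normalized), and `samples` data frame
#'   (`sample, cell_line, compound, dose_nM`).
#' @export
generate_expression <- function(truth, lines = truth$lines,
                                compounds = truth$compounds,
                                libsize_range = c(5e5, 1e6),
                                dispersion = 0.1, seed = 1,
                                normalization = "median_of_ratios_log2") {
  stopifnot(inherits(truth, "expression_truth"))
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop_named("generate_expression: dispersion must be > 0")
  bad <- setdiff(lines, truth$lines)
  if (length(bad)) stop_named("generate_expression: unknown line %s", bad[1])
  bad <- setdiff(compounds, truth$compounds)
  if (length(bad)) stop_named("generate_expression: unknown compound %s", bad[1])

  genes <- truth$genes
  samples <- data.frame(
    sample = as.vector(t(outer(lines, c("control", compounds), paste, sep = "_"))),
    cell_line = rep(lines, each = length(compounds) + 1L),
    compound = rep(c("control", compounds), times = length(lines)),
    stringsAsFactors = FALSE)
  samples$dose_nM <- ifelse(samples$compound == "control", 0, 500)

  with_seed(seed, {
    ## per-line module latent factors
    z <- matrix(rnorm(length(truth$modules) * length(lines), 0, truth$factor_sd),
                nrow = length(truth$modules),
                dimnames = list(NULL, lines))
    log2mu <- matrix(truth$base_log2[genes], nrow = length(genes),
                     ncol = nrow(samples),
                     dimnames = list(genes, samples$sample))
    c1_lines <- names(truth$cluster_of_line)[truth$cluster_of_line == 1L]
    for (j in seq_len(nrow(samples))) {
      l <- samples$cell_line[j]
      cm <- samples$compound[j]
      for (m in seq_along(truth$modules)) {
        g <- truth$modules[[m]]$genes
        log2mu[g, j] <- log2mu[g, j] + truth$module_loadings[g] * z[m, l]
      }
      if (l %in% c1_lines)
        log2mu[truth$cluster_marker_genes, j] <-
          log2mu[truth$cluster_marker_genes, j] + truth$marker_log2fc
      if (cm != "control") {
        if (cm == truth$consistent_down_compound)
          log2mu[truth$consistent_down, j] <-
            log2mu[truth$consistent_down, j] - truth$effect_log2fc
        log2mu[truth$line_stress_up[[l]], j] <-
          log2mu[truth$line_stress_up[[l]], j] + truth$stress_log2fc
        sp <- truth$line_specific[[cell_key(l, cm)]]
        log2mu[sp$up, j] <- log2mu[sp$up, j] + truth$effect_log2fc
        log2mu[sp$down, j] <- log2mu[sp$down, j] - truth$effect_log2fc
        if (cm == truth$module_down_compound) {
          g <- truth$modules[[1]]$genes
          log2mu[g, j] <- log2mu[g, j] - truth$module_down_log2fc
        }
      }
    }
    ## absolute abundances scaled by a per-sample sequencing-depth factor;
    ## the realized library size is approximately the drawn target (planted
    ## effects perturb it only marginally), and depth variation is exactly
    ## what median-of-ratios size factors correct
    libsize <- runif(nrow(samples), libsize_range[1], libsize_range[2])
    w <- 2^log2mu
    mu <- sweep(w, 2, libsize / sum(2^truth$base_log2), "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    expression_bundle(counts, samples, normalization = normalization)
  })
}

#' Assemble an expression bundle from counts and sample metadata
#'
#' @param counts Gene x sample matrix of nonnegative integers.
#' @param samples Data frame with columns `sample, cell_line, compound`
#'   (and optionally `dose_nM`); `compound == "control"` marks controls.
#' @param normalization Method for [normalize_counts()].
#' @param pseudocount Pseudocount used on the log2 scale.
#' @return List of class `expression_bundle` (`counts`, `norm`, `samples`).
#' @export
expression_bundle <- function(counts, samples,
                              normalization = "median_of_ratios_log2",
                              pseudocount = 1) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (!setequal(colnames(counts), samples$sample))
    stop_named("expression_bundle: counts columns and samples table disagree")
  counts <- counts[, samples$sample, drop = FALSE]
  ctrl <- table(samples$cell_line[samples$compound == "control"])
  lines <- unique(samples$cell_line)
  if (!all(lines %in% names(ctrl)) || any(ctrl != 1L))
    stop_named("expression_bundle: need exactly one control sample per line")
  out <- list(counts = counts,
              norm = normalize_counts(counts, method = normalization,
                                      pseudocount = pseudocount),
              samples = samples)
  class(out) <- "expression_bundle"
  out
}

#' Generate a control or treated ATAC peak set
#'
#' The control condition returns the truth's peak list verbatim. The treated
#' condition removes each peak with probability `lost_fraction_global`,
#' boosted to `lost_near_module_tss` for peaks within `window` bp of a
#' target-module TSS; retained peaks get log-normal score jitter, and
#' module-proximal retained peaks additionally suffer a score drop of
#' `score_drop_log2` log2 units with probability `score_drop_prob`.
#'
#' @param truth A [peak_truth()] object.
#' @param condition `"control"` or `"treated"`.
#' @param seed RNG seed.
#' @return A peak set (`GRanges` with a `score` column), see [peak_set()].
#' @export
generate_peaks <- function(truth, condition = c("control", "treated"),
                           seed = 1) {
  stopifnot(inherits(truth, "peak_truth"))
  condition <- match.arg(condition)
  pk <- truth$peaks
  if (condition == "control") return(peak_set(pk))
  tss_m <- truth$tss[truth$tss$gene %in% truth$module_genes, ]
  prox <- vapply(seq_len(nrow(pk)), function(i) {
    same <- tss_m$chrom == pk$chrom[i]
    any(same & pk$start[i] < tss_m$pos + truth$window &
          pk$end[i] > tss_m$pos - truth$window)
  }, logical(1))
  p_lose <- ifelse(prox,
                   pmax(truth$lost_near_module_tss, truth$lost_fraction_global),
                   truth$lost_fraction_global)
  with_seed(seed, {
    keep <- runif(nrow(pk)) >= p_lose
    kept <- pk[keep, , drop = FALSE]
    if (nrow(kept)) {
      kept$score <- kept$score * 2^rnorm(nrow(kept), 0, truth$score_jitter_sd)
      drop <- prox[keep] & runif(nrow(kept)) < truth$score_drop_prob
      kept$score[drop] <- kept$score[drop] * 2^(-truth$score_drop_log2)
      kept$score <- round(kept$score, 3)
    }
    peak_set(kept)
  })
}
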
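## Ground-truth constructors for the synthetic study.
##
## The generators in generate.R consume these truth objects; every planted
## feature (delayed-action compound class, consistent down-set, per-line
## stress sets, baseline clusters, co-expression modules, TSS-proximal peak
## losses) is recorded here so downstream stages can be tested by recovery.

## default drug-class (gene-target) vocabulary for the primary screen
.default_classes <- function(n) {
  named <- c("BET", "HDAC", "DNMT", "EZH2", "BRPF", "KDM1A", "KDM5A", "PRMT5",
             "SIRT1", "KAT6A", "EP300", "KMT2A", "DOT1L", "SETD7", "SMARCA4",
             "CHD1", "AURKB", "PARP1", "WEE1", "EHMT2")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("TGT%02d", seq_len(n - length(named)) + length(named)))
}

#' Ground truth for the multi-timepoint primary drug screen
#'
#' Defines a screen of `n_compounds` compounds grouped into `n_classes`
#' gene-target classes against a panel of sphere lines, each (line, compound)
#' pair carrying four-parameter logistic dose-response parameters and a
#' kinetic label. Compounds in `delayed_class` act slowly (their IC-50
#' shrinks at later timepoints), `acute` compounds lose potency over time,
#' and `inert` compounds never affect viability. All members of
#' `inert_class` are inert, mirroring a least-effective reference class.
#'
#' @param lines Character vector of cell-line identifiers.
#' @param n_compounds,n_classes Screen dimensions (defaults: 106 compounds in
#'   36 target classes).
#' @param delayed_class Class whose members are all delayed-action.
#' @param inert_class Class whose members are all inert.
#' @param delayed_strength Exponent of the time scaling of IC-50 for the
#'   planted delayed class (IC-50 is multiplied by `(t/ref_day)^-strength`).
#' @param n_mild_delayed Number of additional weakly delayed compounds
#'   scattered in other classes.
#' @param noise_sd Gaussian viability noise (fraction of control).
#' @param ref_day Reference timepoint (days) at which the stored IC-50 holds.
#' @param seed Integer seed for drawing per-compound/per-line parameters.
#' @return An object of class `screen_truth`: list with `lines`, `compounds`
#'   (data frame compound/drug_class), `fourpl` (data frame with per
#'   (cell_line, compound) top/bottom/ic50/hill), `kinetics` and
#'   `kinetics_strength` (named by compound), `noise_sd`, `ref_day`.
#' @export
screen_truth <- function(lines = c("GS357", "GS372", "GS385", "GS408", "GS412"),
                         n_compounds = 106, n_classes = 36,
                         delayed_class = "BET", inert_class = "BRPF",
                         delayed_strength = 1.2, n_mild_delayed = 2,
                         noise_sd = 0.05, ref_day = 3, seed = 1) {
  stopifnot(n_classes >= 2, n_compounds >= n_classes)
  classes <- .default_classes(n_classes)
  if (!delayed_class %in% classes) classes[1] <- delayed_class
  if (!inert_class %in% classes) classes[2] <- inert_class
  with_seed(seed, {
    ## distribute compounds over classes: at least 2 per class where possible
    sizes <- rep(n_compounds %/% n_classes, n_classes)
    extra <- n_compounds - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    drug_class <- rep(classes, times = sizes)
    compound <- unlist(lapply(classes, function(cl)
      sprintf("%s_%02d", cl, seq_len(sizes[match(cl, classes)]))))
    compounds <- data.frame(compound = compound, drug_class = drug_class,
                            stringsAsFactors = FALSE)

    kinetics <- setNames(rep("inert", n_compounds), compound)
    strength <- setNames(rep(0, n_compounds), compound)
    kinetics[drug_class == delayed_class] <- "delayed"
    strength[drug_class == delayed_class] <- delayed_strength
    pool <- compound[!drug_class %in% c(delayed_class, inert_class)]
    acute <- sample(pool, size = round(0.45 * length(pool)))
    kinetics[acute] <- "acute"
    strength[acute] <- runif(length(acute), 0.5, 1.0)
    mild <- sample(setdiff(pool, acute), n_mild_delayed)
    kinetics[mild] <- "delayed"
    strength[mild] <- 0.35

    ## 4PL parameters: per-compound base IC-50 in the low-micromolar range,
    ## jittered per line (lines differ in sensitivity)
    base_ic50 <- 10^runif(n_compounds, -6.5, -5.3)
    top <- runif(n_compounds, 0.95, 1.08)
    bottom <- runif(n_compounds, 0.00, 0.10)
    hill <- runif(n_compounds, 0.9, 1.8)
    grid <- expand.grid(cell_line = lines, compound = compound,
                        stringsAsFactors = FALSE)
    i <- match(grid$compound, compound)
    fourpl <- data.frame(
      grid,
      top = top[i], bottom = bottom[i],
      ic50 = base_ic50[i] * 10^rnorm(nrow(grid), 0, 0.15),
      hill = hill[i], stringsAsFactors = FALSE)

    out <- list(lines = lines, compounds = compounds, fourpl = fourpl,
                kinetics = kinetics, kinetics_strength = strength,
                delayed_class = delayed_class, inert_class = inert_class,
                noise_sd = noise_sd, ref_day = ref_day)
    class(out) <- "screen_truth"
    validate_screen_truth(out)
  })
}

validate_screen_truth <- function(x) {
  stopifnot(inherits(x, "screen_truth"))
  fp <- x$fourpl
  if (!all(fp$bottom >= 0 & fp$bottom <= fp$top & fp$top <= 1.2))
    stop_named("screen_truth: need 0 <= bottom <= top <= 1.2")
  if (!all(fp$ic50 > 0) || !all(fp$hill > 0))
    stop_named("screen_truth: ic50 and hill must be positive")
  need <- nrow(x$compounds) * length(x$lines)
  if (nrow(unique(fp[c("cell_line", "compound")])) != need)
    stop_named("screen_truth: every (line, compound) pair needs parameters")
  x
}

#' Ground truth for the focused single-timepoint dose-response panel
#'
#' A 12-line x 12-compound panel with a planted two-cluster resistance
#' structure: for `resistant_compounds`, lines in cluster 2 have their IC-50
#' multiplied by `resistance_fold`. Per-line sensitivity is shared across all
#' compounds (log10 IC-50 = compound base + line effect + cluster shift +
#' pair noise), emulating globally resistant/sensitive lines.
#'
#' @param lines Cell-line identifiers.
#' @param compounds Compound identifiers.
#' @param cluster_of_line Named integer (1 or 2) per line.
#' @param base_log10_ic50 Named numeric per compound (molar, log10); drawn
#'   log-uniform over `base_ic50_range` when `NULL`.
#' @param base_ic50_range Log10 molar range of the per-compound base
#'   potencies. The default (about 30 nM to 0.6 uM) reflects that a focused
#'   follow-up panel consists of best-in-class actives selected from a
#'   primary screen, and keeps both the unshifted and the 10x-shifted IC-50
#'   measurable inside a 10 nM - 10 uM dose range.
#' @param resistant_compounds Compounds with a cluster-2 resistance shift;
#'   defaults to a sample of 6.
#' @param resistance_fold IC-50 fold-shift in cluster-2 lines.
#' @param line_effect_sd,pair_sd Standard deviations (log10 units) of the
#'   shared per-line sensitivity effect and the residual per-pair noise.
#' @param noise_sd,day,seed Viability noise, assay day, RNG seed.
#' @return A `screen_truth` object (single timepoint) with extra fields
#'   `cluster_of_line` and `resistant_compounds`.
#' @export
panel_screen_truth <- function(lines, compounds, cluster_of_line,
                               base_log10_ic50 = NULL,
                               base_ic50_range = c(-7.5, -6.2),
                               resistant_compounds = NULL,
                               resistance_fold = 10,
                               line_effect_sd = 0.15, pair_sd = 0.03,
                               noise_sd = 0.05, day = 7, seed = 1) {
  stopifnot(all(names(cluster_of_line) %in% lines),
            all(cluster_of_line %in% 1:2))
  with_seed(seed, {
    n <- length(compounds)
    if (is.null(base_log10_ic50))
      base_log10_ic50 <- setNames(
        runif(n, base_ic50_range[1], base_ic50_range[2]), compounds)
    if (is.null(resistant_compounds)) {
      ## the resistance shift must remain measurable under the 10 nM - 10 uM
      ## assay: both the unshifted IC-50 and the shifted one need to sit
      ## inside the dose range with some margin, i.e. base log10 IC-50 in
      ## [-8 + 0.3, -5 - log10(fold) - 0.3]; compounds closest to that
      ## window are planted as resistant
      lo <- -8 + 0.3
      hi <- -5 - log10(resistance_fold) - 0.3
      b <- base_log10_ic50[compounds]
      dist <- pmax(lo - b, b - hi, 0)
      if (sum(dist == 0) >= 6L) {
        resistant_compounds <- sort(sample(compounds[dist == 0], 6L))
      } else {
        resistant_compounds <- sort(compounds[order(dist, b)][seq_len(min(6L, n))])
      }
    }
    line_eff <- setNames(rnorm(length(lines), 0, line_effect_sd), lines)
    top <- setNames(runif(n, 0.97, 1.05), compounds)
    bottom <- setNames(runif(n, 0.00, 0.08), compounds)
    hill <- setNames(runif(n, 0.9, 1.6), compounds)

    grid <- expand.grid(cell_line = lines, compound = compounds,
                        stringsAsFactors = FALSE)
    shift <- ifelse(grid$compound %in% resistant_compounds &
                      cluster_of_line[grid$cell_line] == 2L,
                    log10(resistance_fold), 0)
    l10 <- base_log10_ic50[grid$compound] + line_eff[grid$cell_line] +
      shift + rnorm(nrow(grid), 0, pair_sd)
    fourpl <- data.frame(grid,
                         top = top[grid$compound],
                         bottom = bottom[grid$compound],
                         ic50 = 10^l10, hill = hill[grid$compound],
                         stringsAsFactors = FALSE)
    out <- list(lines = lines,
                compounds = data.frame(compound = compounds,
                                       drug_class = compounds,
                                       stringsAsFactors = FALSE),
                fourpl = fourpl,
                kinetics = setNames(rep("acute", n), compounds),
                kinetics_strength = setNames(rep(0, n), compounds),
                cluster_of_line = cluster_of_line,
                resistant_compounds = resistant_compounds,
                base_log10_ic50 = base_log10_ic50,
                noise_sd = noise_sd, ref_day = day)
    class(out) <- "screen_truth"
    validate_screen_truth(out)
  })
}

#' Ground truth for synthetic RNA-seq expression data
#'
#' Plants, in a universe of `n_genes` genes: baseline cluster-marker genes
#' (elevated in cluster-1 lines), one compound with a consistent cross-line
#' down-regulated set, per-line "stress response" up-sets induced by every
#' compound, line-and-compound-specific up/down sets (sizes optionally
#' coupled to compound potency), and co-expression modules driven by
#' line-level latent factors with one hub gene each. All planted sets are
#' pairwise disjoint except the line/compound-specific noise sets, which are
#' drawn from the leftover background pool.
#'
#' @param n_genes Size of the gene universe.
#' @param lines,compounds Identifiers; defaults: 12 lines, 12 compounds.
#' @param cluster_of_line Named integer (1/2) per line; default assigns 7
#'   lines to cluster 1 and 5 to cluster 2 at random.
#' @param n_markers Number of baseline cluster-1 marker genes. The default
#'   (120) makes the cluster program the dominant axis of baseline
#'   variance, so that an unsupervised PCA view separates the two clusters
#'   the way the emulated study design assumes; smaller marker programs can
#'   be drowned out by module latent variation.
#' @param consistent_down_compound Compound with the consistent down-set
#'   (defaults to the first compound).
#' @param n_consistent_down Size of that set.
#' @param n_stress_per_line Per-line stress-response set size.
#' @param module_sizes Planted co-expression module sizes.
#' @param module_down_compound Compound that down-shifts the genes of the
#'   largest module (defaults to `consistent_down_compound`).
#' @param specific_set_sizes Named integer per compound: size of each
#'   (line, compound)-specific set; default couples size to `potency`
#'   (more potent compounds perturb more genes) or uses 120 when no potency
#'   is given.
#' @param potency Optional named numeric per compound, log10 molar IC-50.
#' @param effect_log2fc Magnitude (log2) of treatment effects on consistent
#'   and line/compound-specific sets.
#' @param stress_log2fc Magnitude of stress-response induction.
#' @param marker_log2fc Baseline elevation of cluster markers.
#' @param module_down_log2fc Down-shift of the target module under
#'   `module_down_compound`.
#' @param factor_sd Standard deviation (log2) of the per-line module latent
#'   factor; the default 0.85, with loadings in 0.8-1 and NB noise at
#'   dispersion 0.1, realizes a within-module Pearson correlation near 0.7.
#' @param seed RNG seed.
#' @return Object of class `expression_truth`.
#' @export
expression_truth <- function(n_genes = 2000,
                             lines = sprintf("GS%02d", 1:12),
                             compounds = sprintf("cmpd%02d", 1:12),
                             cluster_of_line = NULL,
                             n_markers = 120,
                             consistent_down_compound = compounds[1],
                             n_consistent_down = 100,
                             n_stress_per_line = 40,
                             module_sizes = c(120, 60, 30),
                             module_down_compound = consistent_down_compound,
                             specific_set_sizes = NULL,
                             potency = NULL,
                             effect_log2fc = 1.5,
                             stress_log2fc = 3,
                             marker_log2fc = 2,
                             module_down_log2fc = 1,
                             factor_sd = 0.85,
                             seed = 1) {
  stopifnot(effect_log2fc >= 1)
  core <- n_markers + n_consistent_down +
    length(lines) * n_stress_per_line + sum(module_sizes)
  if (n_genes < core + 50)
    stop_named(paste("expression_truth: n_genes = %d cannot hold the planted",
                     "core sets (%d genes) plus background"), n_genes, core)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    if (is.null(cluster_of_line)) {
      c1 <- sample(lines, size = ceiling(length(lines) * 7 / 12))
      cluster_of_line <- setNames(ifelse(lines %in% c1, 1L, 2L), lines)
    }
    pool <- genes
    take <- function(n) {
      picked <- sample(pool, n)
      pool <<- setdiff(pool, picked)
      picked
    }
    markers <- take(n_markers)
    consistent_down <- take(n_consistent_down)
    stress <- lapply(lines, function(l) take(n_stress_per_line))
    names(stress) <- lines
    modules <- lapply(seq_along(module_sizes), function(m) {
      g <- take(module_sizes[m])
      list(id = m, genes = g, hub = g[1])
    })
    background <- pool

    if (is.null(specific_set_sizes)) {
      if (is.null(potency)) {
        specific_set_sizes <- setNames(rep(120L, length(compounds)), compounds)
      } else {
        ## potency coupling: 10 uM -> ~40 genes, 10 nM -> ~180 genes
        specific_set_sizes <- setNames(
          as.integer(round(40 + 140 * pmin(pmax((-5 - potency[compounds]) / 3, 0), 1))),
          compounds)
      }
    }
    ## direction bias: a handful of up-regulators, one strong down-regulator
    n_up_biased <- min(5L, length(compounds) - 1L)
    up_biased <- setdiff(compounds, consistent_down_compound)[seq_len(n_up_biased)]
    up_frac <- setNames(rep(0.5, length(compounds)), compounds)
    up_frac[up_biased] <- 0.85
    up_frac[consistent_down_compound] <- 0    # pure down-regulator

    specific <- list()
    for (l in lines) {
      for (cm in compounds) {
        n_spec <- specific_set_sizes[[cm]]
        g <- sample(background, min(n_spec, length(background)))
        n_up <- round(up_frac[[cm]] * length(g))
        specific[[cell_key(l, cm)]] <-
          list(up = g[seq_len(n_up)],
               down = if (n_up < length(g)) g[(n_up + 1):length(g)] else character())
      }
    }

    ## baseline abundance: planted sets moderately-to-highly expressed so the
    ## Poisson sampling floor does not mask planted effects
    base_log2 <- setNames(runif(n_genes, 3, 8), genes)
    planted <- c(markers, consistent_down, unlist(stress),
                 unlist(lapply(modules, `[[`, "genes")))
    base_log2[planted] <- runif(length(planted), 5, 9)

    ## module loadings: hub loads 1, members 0.8-1
    loadings <- setNames(numeric(0), character(0))
    for (m in modules) {
      lo <- runif(length(m$genes), 0.8, 1.0)
      lo[1] <- 1.0
      loadings[m$genes] <- lo
    }

    out <- list(genes = genes, lines = lines, compounds = compounds,
                cluster_of_line = cluster_of_line,
                cluster_marker_genes = markers,
                consistent_down_compound = consistent_down_compound,
                consistent_down = consistent_down,
                line_stress_up = stress,
                line_specific = specific,
                modules = modules,
                module_loadings = loadings,
                module_down_compound = module_down_compound,
                background = background,
                base_log2 = base_log2,
                effect_log2fc = effect_log2fc,
                stress_log2fc = stress_log2fc,
                marker_log2fc = marker_log2fc,
                module_down_log2fc = module_down_log2fc,
                factor_sd = factor_sd)
    class(out) <- "expression_truth"
    validate_expression_truth(out)
  })
}

validate_expression_truth <- function(x) {
  stopifnot(inherits(x, "expression_truth"))
  core <- list(x$cluster_marker_genes, x$consistent_down,
               unlist(x$line_stress_up, use.names = FALSE),
               unlist(lapply(x$modules, `[[`, "genes"), use.names = FALSE))
  if (length(unlist(core)) != length(unique(unlist(core))))
    stop_named("expression_truth: planted core sets must be disjoint")
  for (m in x$modules) {
    if (length(m$genes) < 30)
      stop_named("expression_truth: module %d has < 30 genes", m$id)
    if (!m$hub %in% m$genes)
      stop_named("expression_truth: hub of module %d not in module", m$id)
  }
  if (x$effect_log2fc < 1)
    stop_named("expression_truth: effect_log2fc must be >= 1")
  x
}

#' Ground truth for synthetic ATAC peak sets
#'
#' Lays out TSS coordinates for every gene of an [expression_truth()] object
#' on a small synthetic genome, places one accessibility peak near each
#' module-gene TSS plus uniform background peaks, and records the
#' treatment-loss model: background peaks are lost at `lost_fraction_global`,
#' peaks within `window` of a target-module TSS at `lost_near_module_tss`.
#'
#' @param expr_truth An `expression_truth` object.
#' @param n_peaks Total number of control peaks.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param lost_fraction_global,lost_near_module_tss Loss probabilities.
#' @param window Gene-link window (bp) around the TSS.
#' @param score_jitter_sd Log2 sd of the score jitter on retained peaks.
#' @param score_drop_log2,score_drop_prob Magnitude and probability of a
#'   treatment-induced score drop on retained module-proximal peaks.
#' @param seed RNG seed.
#' @return Object of class `peak_truth` with fields `peaks` (data frame
#'   chrom/start/end/score, BED half-open), `tss` (gene/chrom/pos/strand),
#'   `module_genes`, and the loss-model parameters.
#' @export
peak_truth <- function(expr_truth, n_peaks = 800,
                       chrom_lengths = c(chr1 = 6e7, chr2 = 6e7),
                       lost_fraction_global = 0.15,
                       lost_near_module_tss = 0.6,
                       window = 5e4,
                       score_jitter_sd = 0.1,
                       score_drop_log2 = 1.5, score_drop_prob = 0.5,
                       seed = 1) {
  stopifnot(inherits(expr_truth, "expression_truth"),
            lost_fraction_global >= 0, lost_fraction_global <= 1,
            lost_near_module_tss >= 0, lost_near_module_tss <= 1)
  genes <- expr_truth$genes
  module_genes <- expr_truth$modules[[1]]$genes
  with_seed(seed, {
    chrom <- sample(names(chrom_lengths), length(genes), replace = TRUE)
    pos <- vapply(chrom, function(ch)
      round(runif(1, 2 * window, chrom_lengths[[ch]] - 2 * window)), 0)
    tss <- data.frame(gene = genes, chrom = chrom, pos = as.integer(pos),
                      strand = sample(c("+", "-"), length(genes), TRUE),
                      stringsAsFactors = FALSE)
    ## one peak near each target-module TSS, remainder background
    i <- match(module_genes, tss$gene)
    prox_start <- pmax(0L, tss$pos[i] + as.integer(round(runif(length(i), -2e4, 2e4))))
    n_bg <- n_peaks - length(i)
    bg_chrom <- sample(names(chrom_lengths), n_bg, replace = TRUE)
    bg_start <- vapply(bg_chrom, function(ch)
      round(runif(1, 0, chrom_lengths[[ch]] - 2000)), 0)
    peaks <- data.frame(
      chrom = c(tss$chrom[i], bg_chrom),
      start = as.integer(c(prox_start, bg_start)),
      stringsAsFactors = FALSE)
    peaks$end <- peaks$start + as.integer(round(runif(n_peaks, 300, 1500)))
    peaks$score <- round(2^runif(n_peaks, 4, 9), 3)
    peaks <- peaks[!duplicated(peaks[c("chrom", "start", "end")]), ]
    peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), ]
    rownames(peaks) <- NULL
    out <- list(chrom_lengths = chrom_lengths, peaks = peaks, tss = tss,
                module_genes = module_genes,
                lost_fraction_global = lost_fraction_global,
                lost_near_module_tss = lost_near_module_tss,
                window = window, score_jitter_sd = score_jitter_sd,
                score_drop_log2 = score_drop_log2,
                score_drop_prob = score_drop_prob)
    class(out) <- "peak_truth"
    out
  })
}

#' Full synthetic-study ground truth
#'
#' Bundles the four truth objects of the emulated study design: the
#' 106-compound x 5-line two-timepoint primary screen, the 12 x 12
#' single-timepoint dose-response panel with planted cluster resistance, the
#' expression truth (with compound potency coupled to planted effect-set
#' sizes), and the ATAC peak truth.
#'
#' @param seed Integer seed; all component truths derive their seeds from it.
#' @param n_genes Gene-universe size for the expression component.
#' @param n_peaks Number of control ATAC peaks.
#' @param dispersion Stored as the default count dispersion for generators.
#' @param ... Passed on to [expression_truth()].
#' @return List of class `study_truth` with elements `screen`, `panel`,
#'   `expression`, `peaks`.
#' @export
study_truth <- function(seed = 1, n_genes = 2000, n_peaks = 800,
                        dispersion = 0.1, ...) {
  lines <- sprintf("GS%02d", 1:12)
  compounds <- sprintf("cmpd%02d", 1:12)
  base_pot <- with_seed(seed + 11L,
                        setNames(runif(12, -7.5, -6.2), compounds))
  expr <- expression_truth(n_genes = n_genes, lines = lines,
                           compounds = compounds, potency = base_pot,
                           seed = seed + 13L, ...)
  panel <- panel_screen_truth(lines, compounds,
                              cluster_of_line = expr$cluster_of_line,
                              base_log10_ic50 = base_pot,
                              seed = seed + 17L)
  out <- list(screen = screen_truth(seed = seed + 7L),
              panel = panel,
              expression = expr,
              peaks = peak_truth(expr, n_peaks = n_peaks, seed = seed + 19L),
              dispersion = dispersion,
              seed = seed)
  class(out) <- "study_truth"
  out
}
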
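## Run configuration and the end-to-end driver chaining all stages:
## simulate -> screen -> rank -> ic50 -> express -> overlap -> coexpr -> atac.

.config_defaults <- function() list(
  outdir = "epidrugscreen_run",
  seed = 1,
  stages = c("screen", "rank", "ic50", "express", "overlap", "coexpr", "atac"),
  simulate = TRUE,
  ## user-data inputs (used when simulate = FALSE)
  viability = NULL, panel_viability = NULL, counts = NULL, samples = NULL,
  control_bed = NULL, treated_bed = NULL, tss_bed = NULL,
  ## simulation scale
  n_genes = 2000, n_peaks = 800, dispersion = 0.1,
  ## stage parameters (module defaults)
  early_day = 3, late_day = 28, panel_day = 7,
  reference = "auto", top_k = 12,
  normalization = "median_of_ratios_log2",
  fold_threshold = 2, min_fraction = 0.75, universal_min_fraction = 1.0,
  regulator_ratio = 2,
  powers = 1:12, fit_cut = 0.8, min_module_size = 30,
  coexpr_n_genes = 2000, hub = NULL, hub_k = 20,
  window = 5e4, min_reciprocal_overlap = 0.5, min_abs_log2 = 1)

#' Build a validated run configuration
#'
#' Every parameter defaults to the documented module default; unknown keys
#' are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_named("run_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  bad <- setdiff(cfg$stages, .config_defaults()$stages)
  if (length(bad))
    stop_named("run_config: unknown stage(s): %s", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals %||% list())
}

## write helper used by stages: write to <path>.partial, caller renames on
## stage success
.finalize_stage <- function(files, failed) {
  for (f in files) {
    part <- paste0(f, ".partial")
    if (failed) {
      if (file.exists(f)) file.rename(f, part)
    }
  }
}

#' Run the full pipeline
#'
#' Executes, in order: simulate (when `simulate = TRUE`), screen (delta
#' AUC + volcano), rank (compound/class ranking, top-class selection),
#' ic50 (panel 4PL fits), express (normalization, fold changes, gene-set
#' counts, baseline clusters, cluster DE, potency correlation, cluster
#' IC-50 association), overlap (consistent/universal/exclusive sets,
#' regulator classification), coexpr (soft threshold, TOM, modules, hub
#' neighborhood, module–drug effects), atac (peak matching and gene-linked
#' changes). Writes `manifest.json` listing every artifact with its md5
#' hash; identical config and seed give identical manifests. A failing
#' stage aborts with the stage named; its partial outputs are kept with a
#' `.partial` suffix.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a data frame (`stage, file, bytes,
#'   md5`).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  manifest <- list()

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    before <- list.files(outdir)
    files <- tryCatch(fun(), error = function(e) {
      .finalize_stage(file.path(outdir, setdiff(list.files(outdir), before)),
                      failed = TRUE)
      stop_named("run_all: stage '%s' failed: %s", name, conditionMessage(e))
    })
    message(sprintf("stage %-8s %5.1fs  (%d artifact%s)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    length(files), if (length(files) == 1) "" else "s"))
    manifest[[name]] <<- files
  }

  p <- function(f) file.path(outdir, f)

  ## ---- simulate ----------------------------------------------------------
  if (isTRUE(config$simulate)) {
    run_stage("simulate", function() {
      truth <- study_truth(seed = config$seed, n_genes = config$n_genes,
                           n_peaks = config$n_peaks,
                           dispersion = config$dispersion)
      env$truth <- truth
      env$viability <- generate_screen(truth$screen, seed = config$seed + 101L)
      env$panel_viability <- generate_screen(
        truth$panel, doses = c(1e-8, 1e-7, 1e-6, 1e-5),
        timepoints = config$panel_day, replicates = 3,
        seed = config$seed + 103L)
      env$bundle <- generate_expression(truth$expression,
                                        dispersion = config$dispersion,
                                        seed = config$seed + 107L,
                                        normalization = config$normalization)
      env$control_peaks <- generate_peaks(truth$peaks, "control")
      env$treated_peaks <- generate_peaks(truth$peaks, "treated",
                                          seed = config$seed + 109L)
      env$tss <- truth$peaks$tss
      write_viability_csv(env$viability, p("viability.csv"))
      write_viability_csv(env$panel_viability, p("panel_viability.csv"))
      write_counts_tsv(env$bundle$counts, p("counts.tsv"))
      write_samples_tsv(env$bundle$samples, p("samples.tsv"))
      write_peak_bed(env$control_peaks, p("control.bed"))
      write_peak_bed(env$treated_peaks, p("treated.bed"))
      write_tss_bed(env$tss, p("tss.bed"))
      tr <- truth$expression
      jsonlite::write_json(list(
        seed = config$seed,
        lines = tr$lines, compounds = tr$compounds,
        cluster_of_line = as.list(tr$cluster_of_line),
        consistent_down_compound = tr$consistent_down_compound,
        consistent_down = tr$consistent_down,
        cluster_marker_genes = tr$cluster_marker_genes,
        module_sizes = vapply(tr$modules, function(m) length(m$genes), 0L),
        module_hubs = vapply(tr$modules, `[[`, "", "hub"),
        module_down_compound = tr$module_down_compound,
        resistant_compounds = truth$panel$resistant_compounds),
        p("truth.json"), auto_unbox = TRUE, digits = NA)
      basename(c(p("viability.csv"), p("panel_viability.csv"), p("counts.tsv"),
                 p("samples.tsv"), p("control.bed"), p("treated.bed"),
                 p("tss.bed"), p("truth.json")))
    })
  }
  ## user-data inputs are read lazily inside the stage that consumes them,
  ## so a malformed file fails with that stage named
  need_viability <- function() {
    if (is.null(env$viability))
      env$viability <- read_viability_csv(config$viability)
  }
  need_bundle <- function() {
    if (is.null(env$bundle))
      env$bundle <- expression_bundle(read_counts_tsv(config$counts),
                                      read_samples_tsv(config$samples),
                                      normalization = config$normalization)
  }
  need_peaks <- function() {
    if (is.null(env$control_peaks) && !is.null(config$control_bed)) {
      env$control_peaks <- read_peak_bed(config$control_bed)
      env$treated_peaks <- read_peak_bed(config$treated_bed)
      env$tss <- read_tss_bed(config$tss_bed)
    }
  }

  ## ---- screen ------------------------------------------------------------
  if ("screen" %in% config$stages) run_stage("screen", function() {
    need_viability()
    env$delta <- delta_auc_table(env$viability, config$early_day,
                                 config$late_day)
    write.csv(env$delta, p("delta_auc.csv"), row.names = FALSE)
    vol <- volcano_stats(env$viability, config$early_day, config$late_day)
    write.csv(vol, p("volcano.csv"), row.names = FALSE)
    c("delta_auc.csv", "volcano.csv")
  })

  ## ---- rank --------------------------------------------------------------
  if ("rank" %in% config$stages) run_stage("rank", function() {
    env$ranks <- rank_compounds(env$delta)
    env$classes <- class_average_ranks(env$ranks, reference = config$reference)
    write.csv(env$classes, p("class_ranks.csv"), row.names = FALSE)
    top <- select_top(env$classes, env$ranks,
                      k = min(config$top_k, nrow(env$classes)))
    write.csv(top, p("top_classes.csv"), row.names = FALSE)
    c("class_ranks.csv", "top_classes.csv")
  })

  ## ---- ic50 --------------------------------------------------------------
  if ("ic50" %in% config$stages) run_stage("ic50", function() {
    if (is.null(env$panel_viability))
      env$panel_viability <- read_viability_csv(config$panel_viability)
    env$ic50 <- fit_ic50_table(env$panel_viability, day = config$panel_day)
    write.csv(env$ic50, p("ic50.csv"), row.names = FALSE)
    "ic50.csv"
  })

  ## ---- express -----------------------------------------------------------
  if ("express" %in% config$stages) run_stage("express", function() {
    need_bundle()
    env$fc <- fold_changes(env$bundle)
    write.csv(env$fc, p("fc_long.csv"), row.names = FALSE)
    env$grid <- derive_gene_sets(env$fc, threshold = config$fold_threshold)
    write.csv(data.frame(cell_line = rownames(env$grid$counts_up),
                         env$grid$counts_up, check.names = FALSE),
              p("set_counts_up.csv"), row.names = FALSE)
    write.csv(data.frame(cell_line = rownames(env$grid$counts_down),
                         env$grid$counts_down, check.names = FALSE),
              p("set_counts_down.csv"), row.names = FALSE)
    sets <- c(env$grid$up, env$grid$down)
    names(sets) <- c(paste0(names(env$grid$up), "|up"),
                     paste0(names(env$grid$down), "|down"))
    write_gmt(sets, p("gene_sets.gmt"))
    env$clusters <- baseline_clusters(env$bundle, seed = config$seed)
    write.csv(data.frame(cell_line = names(env$clusters$cluster_of_line),
                         cluster = unname(env$clusters$cluster_of_line)),
              p("clusters.csv"), row.names = FALSE)
    de <- cluster_de(env$clusters, env$bundle)
    write.csv(de, p("cluster_de.csv"), row.names = FALSE)
    files <- c("fc_long.csv", "set_counts_up.csv", "set_counts_down.csv",
               "gene_sets.gmt", "clusters.csv", "cluster_de.csv")
    if (!is.null(env$ic50)) {
      corr <- target_count_vs_ic50(env$grid, env$ic50)
      res <- cluster_drug_resistance(env$clusters, env$ic50)
      write.csv(res, p("cluster_ic50.csv"), row.names = FALSE)
      jsonlite::write_json(list(
        target_ic50_r = corr$r, target_ic50_p = corr$p, n_compounds = corr$n,
        n_resistance_significant = attr(res, "summary")$n_significant,
        n_resistance_c2_higher = attr(res, "summary")$n_significant_c2_higher),
        p("express_summary.json"), auto_unbox = TRUE, digits = NA)
      files <- c(files, "cluster_ic50.csv", "express_summary.json")
    }
    files
  })

  ## ---- overlap -----------------------------------------------------------
  if ("overlap" %in% config$stages) run_stage("overlap", function() {
    cons_dn <- consistent_sets(env$grid, "down", config$min_fraction)
    cons_up <- consistent_sets(env$grid, "up", config$min_fraction)
    univ_up <- universal_sets(env$grid, "up", config$universal_min_fraction)
    excl_dn <- exclusive_sets(env$grid, "down")
    reg <- classify_regulators(env$grid, ratio = config$regulator_ratio)
    jsonlite::write_json(list(
      consistent_down = lapply(cons_dn, `[[`, "genes"),
      consistent_up = lapply(cons_up, `[[`, "genes"),
      universal_up = univ_up,
      n_exclusive_down = vapply(excl_dn, length, 0L)),
      p("consistency_report.json"), auto_unbox = FALSE, digits = NA)
    write.csv(reg, p("regulators.csv"), row.names = FALSE)
    c("consistency_report.json", "regulators.csv")
  })

  ## ---- coexpr ------------------------------------------------------------
  if ("coexpr" %in% config$stages) run_stage("coexpr", function() {
    norm <- env$bundle$norm
    v <- apply(norm, 1, var)
    keep <- order(v, decreasing = TRUE)[seq_len(min(config$coexpr_n_genes,
                                                    sum(v > 0)))]
    norm <- norm[sort(keep), , drop = FALSE]
    net <- build_coexpr_network(norm, powers = config$powers,
                                fit_cut = config$fit_cut,
                                min_module_size = config$min_module_size)
    env$net <- net
    write.csv(data.frame(gene = names(net$module_of),
                         module = unname(net$module_of)),
              p("modules.csv"), row.names = FALSE)
    write.csv(net$fit_table, p("soft_threshold.csv"), row.names = FALSE)
    hub <- config$hub %||% names(which.max(rowSums(net$tom) - 1))
    env$hub <- hub
    nb <- hub_neighborhood(norm, hub, k = config$hub_k)
    write.csv(nb, p("hub_neighborhood.csv"), row.names = FALSE)
    env$hub_module_genes <- c(hub, nb$gene)
    eff <- module_drug_effect(env$hub_module_genes, env$fc)
    write.csv(eff, p("module_effects.csv"), row.names = FALSE)
    c("modules.csv", "soft_threshold.csv", "hub_neighborhood.csv",
      "module_effects.csv")
  })

  ## ---- atac --------------------------------------------------------------
  if ("atac" %in% config$stages &&
        (!is.null(env$control_peaks) || !is.null(config$control_bed)))
    run_stage("atac", function() {
      need_peaks()
      delta <- match_peaks(env$control_peaks, env$treated_peaks,
                           config$min_reciprocal_overlap)
      u <- rbind(as.data.frame_peaks(env$control_peaks),
                 as.data.frame_peaks(env$treated_peaks))
      union_pk <- peak_set(u[!duplicated(u[c("chrom", "start", "end")]), ])
      links <- link_peaks_to_genes(union_pk, env$tss, window = config$window)
      genes <- env$hub_module_genes %||% env$tss$gene
      changes <- gene_set_peak_changes(delta, links, genes,
                                       min_abs_log2 = config$min_abs_log2)
      write.csv(changes, p("gene_peak_changes.csv"), row.names = FALSE)
      jsonlite::write_json(list(
        n_control = delta$n_control, n_treated = delta$n_treated,
        n_matched = nrow(delta$matched), n_lost = length(delta$lost),
        n_gained = length(delta$gained),
        pooled = attr(changes, "pooled")),
        p("peaks_delta_summary.json"), auto_unbox = TRUE, digits = NA)
      c("gene_peak_changes.csv", "peaks_delta_summary.json")
    })

  ## ---- manifest ----------------------------------------------------------
  rows <- do.call(rbind, lapply(names(manifest), function(st)
    data.frame(stage = st, file = manifest[[st]], stringsAsFactors = FALSE)))
  rows <- rows[order(rows$file), ]
  rows$bytes <- file.size(file.path(outdir, rows$file))
  rows$md5 <- unname(tools::md5sum(file.path(outdir, rows$file)))
  jsonlite::write_json(rows, file.path(outdir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(rows)
}

## GRanges peak set -> BED-coordinate data frame
as.data.frame_peaks <- function(peaks) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
             start = GenomicRanges::start(peaks) - 1L,
             end = GenomicRanges::end(peaks),
             score = peaks$score, stringsAsFactors = FALSE)
}
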
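toy_bundle <- function(counts, lines, compounds) {
  samples <- data.frame(sample = colnames(counts),
                        cell_line = lines, compound = compounds,
                        dose_nM = ifelse(compounds == "control", 0, 500),
                        stringsAsFactors = FALSE)
  expression_bundle(counts, samples)
}

test_that("normalization is library-size invariant and arithmetically exact", {
  set.seed(1)
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  # sample 2 is sample 1 at doubled depth: normalized columns coincide
  m2 <- cbind(s1 = m[, 1], s2 = m[, 1] * 2L)
  for (meth in c("cpm_log2", "median_of_ratios_log2")) {
    n <- normalize_counts(m2, meth)
    expect_equal(unname(n[, 1]), unname(n[, 2]), tolerance = 1e-12,
                 info = meth)
  }
  one <- matrix(999L, 1, 1, dimnames = list("g", "s"))
  expect_equal(as.vector(normalize_counts(one, "cpm_log2")), log2(1e6 + 1))
  expect_error(normalize_counts(m * -1), "negative")
  # all-zero gene rows are retained, not dropped
  mz <- rbind(m, zero = 0L)
  expect_equal(nrow(normalize_counts(mz, "cpm_log2")), nrow(m) + 1L)
})

test_that("median-of-ratios size factors match a brute-force oracle and DESeq2", {
  # printed 5-gene x 3-sample toy matrix
  m <- matrix(c(10, 20, 5, 100, 80,
                20, 40, 10, 200, 160,
                15, 25, 8, 120, 100), 5, 3,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:3)))
  sf <- size_factors_mor(m)
  # brute force: per-gene geometric means, then per-sample median ratio
  geo <- apply(m, 1, function(r) prod(r)^(1 / 3))
  oracle <- apply(m, 2, function(col) median(col / geo))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("fold changes are zero for duplicated controls and exact for known ratios", {
  genes <- sprintf("g%d", 1:5)
  ctrl <- c(10L, 50L, 100L, 200L, 640L)
  counts <- cbind(L1_control = ctrl, L1_drugA = ctrl)
  rownames(counts) <- genes
  b <- toy_bundle(counts, lines = "L1", compounds = c("control", "drugA"))
  fc <- fold_changes(b)
  expect_equal(fc$log2fc, rep(0, 5))
  # raw-ratio mode, pseudocount -> 0 limit: 40 vs 10 at equal libsizes gives 2
  counts2 <- cbind(L1_control = c(10L, 90L), L1_drugA = c(40L, 60L))
  rownames(counts2) <- c("g1", "g2")
  b2 <- toy_bundle(counts2, "L1", c("control", "drugA"))
  fc2 <- fold_changes(b2, pseudocount = 1e-9, mode = "raw_ratio")
  expect_equal(fc2$log2fc[fc2$gene == "g1"], 2, tolerance = 1e-6)
  # missing control names the line
  s3 <- data.frame(sample = "L9_drugA", cell_line = "L9", compound = "drugA",
                   dose_nM = 500)
  expect_error(expression_bundle(matrix(1L, 1, 1,
                                        dimnames = list("g", "L9_drugA")), s3),
               "control")
})

test_that("gene-set derivation respects the inclusive 2-fold boundary", {
  fc <- data.frame(gene = c("a", "b", "c", "d"),
                   cell_line = "L1", compound = "X",
                   log2fc = c(1.0, 0.999, -1.0, -0.5))
  class(fc) <- c("fold_change_table", "data.frame")
  g <- derive_gene_sets(fc, threshold = 2)
  expect_equal(g$up[["L1|X"]], "a")
  expect_equal(g$down[["L1|X"]], "c")
  expect_equal(unname(g$counts_up["L1", "X"]), 1L)
  # everything inside (-1, 1) yields empty sets
  fc$log2fc <- c(0.9, -0.9, 0.2, 0)
  g2 <- derive_gene_sets(fc, threshold = 2)
  expect_length(g2$up[["L1|X"]], 0)
  expect_length(g2$down[["L1|X"]], 0)
  expect_error(derive_gene_sets(fc, threshold = 1), "threshold")
})

test_that("up and down sets are disjoint per cell on random fold changes", {
  set.seed(3)
  fc <- data.frame(gene = rep(sprintf("g%03d", 1:200), 4),
                   cell_line = rep(c("L1", "L2"), each = 400),
                   compound = rep(rep(c("X", "Y"), each = 200), 2),
                   log2fc = rnorm(800, 0, 1.2))
  class(fc) <- c("fold_change_table", "data.frame")
  g <- derive_gene_sets(fc)
  for (k in names(g$up))
    expect_length(intersect(g$up[[k]], g$down[[k]]), 0)
})

test_that("planted gene-set sizes are recovered in the low-dispersion limit", {
  cmpds <- sprintf("cmpd%02d", 1:12)
  truth <- expression_truth(n_genes = 700, n_markers = 10,
                            n_consistent_down = 40, n_stress_per_line = 5,
                            module_sizes = c(30, 30),
                            specific_set_sizes = setNames(rep(0L, 12), cmpds),
                            module_down_compound = cmpds[2],
                            seed = 4)
  b <- generate_expression(truth, dispersion = 1e-4, seed = 5)
  grid <- derive_gene_sets(fold_changes(b))
  dcm <- truth$consistent_down_compound
  expect_equal(unname(grid$counts_down[, dcm]),
               rep(40L, 12))
  cons <- consistent_sets(grid, "down")[[dcm]]
  expect_setequal(cons$genes, truth$consistent_down)
})

test_that("target-count vs potency correlation handles exact and degenerate cases", {
  g <- make_grid(lines = c("L1", "L2"), compounds = c("X", "Y", "Z"),
                 up = list(`L1|X` = sprintf("g%d", 1:10),
                           `L2|X` = sprintf("g%d", 1:10),
                           `L1|Y` = sprintf("g%d", 1:5),
                           `L2|Y` = sprintf("g%d", 1:5)))
  ic50 <- expand.grid(compound = c("X", "Y", "Z"), cell_line = c("L1", "L2"),
                      stringsAsFactors = FALSE)
  # counts are 10, 5, 0; make -log10(ic50) proportional: 10, 5, 0
  ic50$ic50 <- 10^(-c(10, 5, 0))[match(ic50$compound, c("X", "Y", "Z"))]
  res <- target_count_vs_ic50(g, ic50)
  expect_equal(res$r, 1, tolerance = 1e-12)
  flat <- make_grid(c("L1", "L2"), c("X", "Y", "Z"))
  expect_true(is.na(target_count_vs_ic50(flat, ic50)$r))
  expect_error(target_count_vs_ic50(g, ic50[ic50$compound != "Z", ]),
               ">= 3 compounds")
})

test_that("baseline clustering recovers planted clusters and is order invariant", {
  truth <- expression_truth(n_genes = 900, n_markers = 40,
                            n_consistent_down = 40, n_stress_per_line = 5,
                            module_sizes = c(30, 30), seed = 6)
  b <- generate_expression(truth, dispersion = 0.05, seed = 7)
  cl <- baseline_clusters(b, seed = 1)
  expect_equal(unname(cl$cluster_of_line[truth$lines]),
               unname(truth$cluster_of_line[truth$lines]))
  # permuting sample order does not change the partition
  perm <- sample(ncol(b$counts))
  b2 <- expression_bundle(b$counts[, perm], b$samples[perm, ])
  cl2 <- baseline_clusters(b2, seed = 1)
  expect_equal(cl2$cluster_of_line[names(cl$cluster_of_line)],
               cl$cluster_of_line)
})

test_that("duplicated line profiles always co-cluster", {
  genes <- sprintf("g%03d", 1:100)
  set.seed(8)
  base <- matrix(rpois(100 * 4, 60), 100, 4)
  counts <- cbind(base, base[, 4] + 0L, base[, 4] + 0L)
  # two well-separated groups: lines 1-3 low, lines 4-6 high on markers
  counts[1:20, 4:6] <- counts[1:20, 4:6] + 300L
  colnames(counts) <- paste0("L", 1:6, "_control")
  rownames(counts) <- genes
  b <- toy_bundle(counts, lines = paste0("L", 1:6), compounds = rep("control", 6))
  cl <- baseline_clusters(b, seed = 2)
  expect_equal(cl$cluster_of_line[["L5"]], cl$cluster_of_line[["L6"]])
  expect_equal(cl$cluster_of_line[["L4"]], cl$cluster_of_line[["L5"]])
})

test_that("cluster drug-resistance testing flags planted shifts and survives size-1 clusters", {
  set.seed(9)
  lines <- sprintf("GS%02d", 1:12)
  cl <- setNames(rep(1:2, c(7, 5)), lines)
  mk_ic50 <- function(shifted) {
    do.call(rbind, lapply(sprintf("d%02d", 1:12), function(d) {
      shift <- if (d %in% shifted) 1 else 0
      data.frame(compound = d, cell_line = lines,
                 ic50 = 10^(-6 + rnorm(12, 0, 0.05) + shift * (cl == 2)))
    }))
  }
  planted <- sprintf("d%02d", 1:6)
  res <- cluster_drug_resistance(cl, mk_ic50(planted))
  sig <- res$compound[res$p < 0.05 & res$cluster2_higher]
  expect_setequal(sig, planted)
  expect_equal(attr(res, "summary")$n_significant_c2_higher, 6)
  # one line per cluster: p missing, means still reported
  cl1 <- setNames(c(1L, 2L), c("GS01", "GS02"))
  small <- data.frame(compound = "d01", cell_line = c("GS01", "GS02"),
                      ic50 = c(1e-7, 1e-6))
  r1 <- cluster_drug_resistance(cl1, small)
  expect_true(is.na(r1$p))
  expect_equal(r1$mean_ic50_c2, 1e-6)
})

test_that("cluster DE ranks planted markers on top and behaves at the null", {
  truth <- expression_truth(n_genes = 900, n_markers = 40,
                            n_consistent_down = 40, n_stress_per_line = 5,
                            module_sizes = c(30, 30), seed = 10)
  b <- generate_expression(truth, dispersion = 0.01, seed = 11)
  cl <- baseline_clusters(b, seed = 1)
  de <- cluster_de(cl, b)
  expect_gte(mean(truth$cluster_marker_genes %in% de$gene[1:40]), 0.9)
  # BH q monotone in p-rank order
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
  # label permutation null: ~5% of genes significant
  set.seed(12)
  rates <- replicate(20, {
    perm <- setNames(sample(cl$cluster_of_line), names(cl$cluster_of_line))
    if (min(table(perm)) < 2) return(NA_real_)
    mean(cluster_de(perm, b)$p < 0.05)
  })
  expect_lt(abs(mean(rates, na.rm = TRUE) - 0.05), 0.04)
})

test_that("a gene identical across lines gets zero rank score", {
  marker <- c(10L, 12L, 11L, 80L, 85L, 90L)
  counts <- rbind(flat = rep(50L, 6), marker = marker,
                  filler = 200L - marker)   # equal library sizes
  colnames(counts) <- paste0("L", 1:6, "_control")
  b <- toy_bundle(counts, paste0("L", 1:6), rep("control", 6))
  cl <- setNames(rep(1:2, each = 3), paste0("L", 1:6))
  de <- cluster_de(cl, b)
  expect_equal(de$rank_score[de$gene == "flat"], 0)
  expect_true(de$floored[de$gene == "flat"])
})
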
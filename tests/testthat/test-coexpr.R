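test_that("tom_matrix matches hand-evaluated cases", {
  z <- matrix(0, 5, 5)
  expect_equal(tom_matrix(z), diag(5))
  # complete graph, n = 4: tom_ij = (2 + 1) / (3 + 1 - 1) = 1
  a <- matrix(1, 4, 4); diag(a) <- 0
  expect_equal(tom_matrix(a), matrix(1, 4, 4))
  expect_error(tom_matrix(matrix(c(0, 0.5, 0.2, 0), 2, 2)), "symmetric")
  d <- diag(4) * 0.5
  expect_error(tom_matrix(d), "zero diagonal")
})

test_that("tom_matrix equals the triple-loop brute-force oracle", {
  set.seed(1)
  for (rep in 1:5) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_matrix(a)
    k <- rowSums(a)
    oracle <- diag(20)
    for (i in 1:20) for (j in 1:20) {
      if (i == j) next
      num <- sum(a[i, ] * a[, j]) + a[i, j]
      oracle[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
    expect_lt(max(abs(tom - oracle)), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("soft-threshold selection finds scale-free structure and falls back", {
  # single-factor data with power-law loadings gives a power-law-ish
  # connectivity distribution once the correlations are soft-thresholded
  set.seed(2)
  n <- 300; s <- 60
  lo <- (seq_len(n) / n)^1.5
  z <- rnorm(s)
  x <- outer(lo, z) + matrix(rnorm(n * s, 0, 0.6), n, s)
  rownames(x) <- sprintf("g%03d", 1:n)
  st <- pick_soft_threshold(x, powers = 1:10, fit_cut = 0.8)
  expect_true(st$converged)
  expect_gte(max(st$fit_table$r_squared, na.rm = TRUE), 0.8)
  expect_equal(st$beta,
               with(st$fit_table, power[which(r_squared >= 0.8)[1]]))
  # degenerate input: too few genes for binning
  two <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(pick_soft_threshold(two), "genes")
  # no power reaches the cut: argmax with converged = FALSE
  set.seed(3)
  noise <- matrix(rnorm(50 * 30), 50, 30,
                  dimnames = list(sprintf("n%02d", 1:50), NULL))
  stn <- pick_soft_threshold(noise, powers = 1:3, fit_cut = 0.999)
  expect_false(stn$converged)
  expect_equal(stn$beta,
               stn$fit_table$power[which.max(stn$fit_table$r_squared)])
})

test_that("constant genes are removed with a message before correlation", {
  set.seed(4)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(sprintf("g%02d", 1:20), NULL))
  x[3, ] <- 5
  expect_message(a <- adjacency_matrix(x, 6), "constant")
  expect_equal(nrow(a), 19)
  expect_false("g03" %in% rownames(a))
})

test_that("module detection separates planted blocks and honors the size rule", {
  block_tom <- function(sizes, within = 0.8, between = 0.05) {
    n <- sum(sizes)
    tom <- matrix(between, n, n)
    off <- 0
    for (s in sizes) {
      tom[(off + 1):(off + s), (off + 1):(off + s)] <- within
      off <- off + s
    }
    diag(tom) <- 1
    dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
    tom
  }
  m <- detect_modules(block_tom(c(50, 50)), min_module_size = 30)
  expect_equal(unname(table(m)), c(50L, 50L), ignore_attr = TRUE)
  expect_equal(length(unique(m[1:50])), 1)
  expect_equal(length(unique(m[51:100])), 1)
  expect_false(m[[1]] == m[[100]])
  # all-identity tom: everything unassigned
  expect_true(all(detect_modules(diag(40)) == 0))
  # 29 perfectly correlated genes stay below the size threshold
  small <- block_tom(29, within = 0.95)
  expect_true(all(detect_modules(small, min_module_size = 30) == 0))
  # modules labelled by decreasing size
  m2 <- detect_modules(block_tom(c(30, 80)), min_module_size = 30)
  expect_equal(unname(m2[31]), 1L)   # bigger block gets label 1
  expect_equal(unname(m2[1]), 2L)
})

test_that("module detection is invariant to gene order permutation", {
  set.seed(5)
  truth <- network_truth(seed = 5)
  b <- generate_expression(truth, dispersion = 0.1, seed = 6)
  sel <- c(unlist(lapply(truth$modules, `[[`, "genes")), truth$background[1:40])
  tom <- tom_matrix(suppressMessages(adjacency_matrix(b$norm[sel, ], 6)))
  m1 <- detect_modules(tom)
  perm <- sample(nrow(tom))
  m2 <- detect_modules(tom[perm, perm])
  m2 <- m2[names(m1)]
  # same partition up to label permutation
  expect_equal(mclust::adjustedRandIndex(m1, m2), 1)
})

test_that("hub neighborhoods rank by |r| with deterministic ties", {
  set.seed(6)
  x <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(sprintf("g%02d", 1:40), NULL))
  x["g02", ] <- x["g01", ]          # duplicate of the hub
  nb <- hub_neighborhood(x, "g01", k = 20)
  expect_equal(nrow(nb), 20)
  expect_equal(nb$gene[1], "g02")
  expect_equal(nb$r[1], 1)
  expect_equal(nb$spoke_length[1], 0)
  expect_true(all(diff(abs(nb$r)) <= 1e-12))
  expect_error(hub_neighborhood(x, "nope", 5), "not in matrix")
  xc <- x; xc["g01", ] <- 1
  expect_error(hub_neighborhood(xc, "g01", 5), "constant")
})

test_that("planted module partners dominate the hub neighborhood", {
  truth <- network_truth(seed = 7)
  b <- generate_expression(truth, dispersion = 0.01, seed = 8)
  hub <- truth$modules[[1]]$hub
  nb <- hub_neighborhood(b$norm, hub, k = 20)
  expect_gte(sum(nb$gene %in% truth$modules[[1]]$genes), 19)
})

test_that("module-drug effects average fold changes and scale linearly", {
  fc <- data.frame(gene = rep(c("a", "b"), each = 4),
                   cell_line = rep(c("L1", "L2"), 4),
                   compound = rep(rep(c("X", "Y"), each = 2), 2),
                   log2fc = c(-1, -1.2, 0.1, 0, -0.8, -1, 0.2, -0.1))
  class(fc) <- c("fold_change_table", "data.frame")
  eff <- module_drug_effect(c("a", "b"), fc)
  expect_equal(eff$mean_log2fc[eff$compound == "X"], -1)
  expect_equal(eff$mean_log2fc[eff$compound == "Y"], 0.05)
  fc2 <- fc; fc2$log2fc <- fc$log2fc * 2
  eff2 <- module_drug_effect(c("a", "b"), fc2)
  expect_equal(eff2$mean_log2fc, eff$mean_log2fc * 2)
  zero <- fc; zero$log2fc <- 0
  expect_equal(module_drug_effect(c("a", "b"), zero)$mean_log2fc, c(0, 0))
  expect_error(module_drug_effect(character(), fc), "length")
  expect_error(module_drug_effect("zz", fc), "module genes")
})
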
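df_of <- function(ps) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(ps)),
             start = GenomicRanges::start(ps) - 1L,
             end = GenomicRanges::end(ps), score = ps$score,
             stringsAsFactors = FALSE)
}

test_that("peak_set validates, sorts and names intervals", {
  df <- data.frame(chrom = c("chr2", "chr1"), start = c(100L, 50L),
                   end = c(400L, 500L), score = c(5, 7))
  ps <- peak_set(df)
  expect_equal(names(ps), c("chr1:50-500", "chr2:100-400"))
  expect_equal(GenomicRanges::start(ps), c(51L, 101L))   # 1-based internally
  expect_error(peak_set(data.frame(chrom = "chr1", start = 10L, end = 10L,
                                   score = 1)), "start < end")
  expect_error(peak_set(df[c(1, 1), ]), "duplicate")
  expect_error(peak_set(transform(df, score = c(0, 1))), "positive")
})

test_that("identical and disjoint sets give trivial deltas", {
  set.seed(1)
  a <- peak_set(random_peaks(50))
  d <- match_peaks(a, a)
  expect_equal(nrow(d$matched), 50)
  expect_length(d$lost, 0)
  expect_length(d$gained, 0)
  expect_equal(d$matched$log2_ratio, rep(0, 50))
  b <- peak_set(data.frame(chrom = "chr9", start = c(10L, 1000L),
                           end = c(200L, 1500L), score = c(1, 2)))
  d2 <- match_peaks(a, b)
  expect_equal(nrow(d2$matched), 0)
  expect_length(d2$lost, 50)
  expect_length(d2$gained, 2)
})

test_that("matching counts equal the O(n*m) brute-force oracle and partition peaks", {
  set.seed(2)
  for (rep in 1:5) {
    cdf <- random_peaks(200)
    tdf <- random_peaks(200)
    ctrl <- peak_set(cdf)
    trt <- peak_set(tdf)
    d <- match_peaks(ctrl, trt)
    bf <- brute_force_match(df_of(ctrl), df_of(trt))
    expect_equal(nrow(d$matched), bf$matched)
    expect_equal(length(d$lost), bf$lost)
    expect_equal(length(d$gained), bf$gained)
    # lost + matched = |control|; gained + matched = |treated|
    expect_equal(nrow(d$matched) + length(d$lost), length(ctrl))
    expect_equal(nrow(d$matched) + length(d$gained), length(trt))
    # swapping conditions swaps lost and gained
    sw <- match_peaks(trt, ctrl)
    expect_equal(length(sw$lost), length(d$gained))
    expect_equal(length(sw$gained), length(d$lost))
  }
})

test_that("gene linking honors the TSS window and chromosome-name styles", {
  tss <- data.frame(gene = c("gA", "gB"), chrom = c("chr1", "1"),
                    pos = c(100000L, 500000L), strand = "+")
  pk <- peak_set(data.frame(
    chrom = "chr1",
    start = c(99000L, 160000L, 460000L),
    end = c(101000L, 161000L, 461000L), score = 1:3))
  expect_message(links <- link_peaks_to_genes(pk, tss, window = 5e4),
                 "chromosome-name")
  expect_equal(links$gA, "chr1:99000-101000")     # contains the TSS
  expect_equal(links$gB, "chr1:460000-461000")    # inside the window
  # peak entirely beyond the window links nowhere
  expect_false("chr1:160000-161000" %in% unlist(links))
})

test_that("gene links match a brute-force interval scan", {
  set.seed(3)
  tss <- data.frame(gene = sprintf("g%02d", 1:30),
                    chrom = sample(c("chr1", "chr2"), 30, TRUE),
                    pos = sample.int(9e5, 30), strand = "+")
  pdf <- random_peaks(150)
  pk <- peak_set(pdf)
  links <- link_peaks_to_genes(pk, tss, window = 3e4)
  pdf2 <- df_of(pk)
  for (i in seq_len(nrow(tss))) {
    lo <- tss$pos[i] - 3e4
    hi <- tss$pos[i] + 3e4
    hit <- pdf2$chrom == tss$chrom[i] & pdf2$start < hi & pdf2$end > lo
    expect_setequal(links[[tss$gene[i]]],
                    with(pdf2[hit, ], sprintf("%s:%d-%d", chrom, start, end)))
  }
})

test_that("gene-set peak changes count losses and boundary-inclusive score shifts", {
  ctrl <- peak_set(data.frame(chrom = "chr1",
                              start = c(1000L, 5000L, 9000L),
                              end = c(2000L, 6000L, 10000L),
                              score = c(10, 8, 6)))
  # first peak lost; second halved (log2 = -1, boundary); third unchanged
  trt <- peak_set(data.frame(chrom = "chr1",
                             start = c(5000L, 9000L),
                             end = c(6000L, 10000L), score = c(4, 6)))
  d <- match_peaks(ctrl, trt)
  links <- list(gA = names(ctrl), gB = character())
  ch <- gene_set_peak_changes(d, links, c("gA", "gB", "gC"), min_abs_log2 = 1)
  expect_equal(ch$n_lost[ch$gene == "gA"], 1)
  expect_equal(ch$n_sig_down[ch$gene == "gA"], 1)   # -1 is included (>=)
  expect_equal(ch$n_sig_up[ch$gene == "gA"], 0)
  expect_equal(ch$n_linked[ch$gene == "gB"], 0)
  expect_true(ch$flagged[ch$gene == "gC"])          # absent from links
  expect_equal(attr(ch, "pooled")$total_lost, 1)
  # no treatment effect: all zeros
  d0 <- match_peaks(ctrl, ctrl)
  ch0 <- gene_set_peak_changes(d0, links, "gA")
  expect_equal(ch0$n_lost + ch0$n_gained + ch0$n_sig_down + ch0$n_sig_up, 0)
})

test_that("planted TSS-proximal losses concentrate on module genes", {
  truth <- network_truth(seed = 9)
  pt <- peak_truth(truth, n_peaks = 500, seed = 10)
  ctrl <- generate_peaks(pt, "control")
  trt <- generate_peaks(pt, "treated", seed = 11)
  u <- rbind(df_of(ctrl), df_of(trt))
  links <- link_peaks_to_genes(
    peak_set(u[!duplicated(u[c("chrom", "start", "end")]), ]),
    pt$tss, window = pt$window)
  d <- match_peaks(ctrl, trt)
  mg <- pt$module_genes
  bg <- setdiff(truth$background, mg)[seq_along(mg)]
  pooled <- function(genes) {
    p <- attr(gene_set_peak_changes(d, links, genes), "pooled")
    p$total_lost + p$total_sig_down
  }
  expect_gt(pooled(mg), pooled(bg))
})
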
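## Compound ranking, class-level rank aggregation and top-class selection.

#' Rank compounds by delta AUC
#'
#' Default mode averages each compound's delta AUC across lines and ranks
#' the averages (rank 1 = highest mean delta AUC = most anti-tumor
#' efficacy); `"rank_per_line"` first ranks compounds within each line and
#' ranks compounds by their average per-line rank. Ties receive average
#' ranks in either mode.
#'
#' @param delta Data frame of per-(compound, line) delta AUCs as produced by
#'   [delta_auc_table()] (`compound, cell_line, delta_auc`, optionally
#'   `drug_class`).
#' @param mode `"mean_then_rank"` (default) or `"rank_per_line"`.
#' @return Data frame `compound, drug_class, mean_delta_auc, global_rank`,
#'   sorted by rank.
#' @export
rank_compounds <- function(delta, mode = c("mean_then_rank", "rank_per_line")) {
  mode <- match.arg(mode)
  stopifnot(all(c("compound", "delta_auc") %in% names(delta)))
  means <- aggregate(delta_auc ~ compound, data = delta, FUN = mean)
  names(means)[2] <- "mean_delta_auc"
  if (mode == "mean_then_rank") {
    means$global_rank <- rank(-means$mean_delta_auc, ties.method = "average")
  } else {
    per_line <- do.call(rbind, lapply(split(delta, delta$cell_line), function(s) {
      s$line_rank <- rank(-s$delta_auc, ties.method = "average")
      s
    }))
    avg <- aggregate(line_rank ~ compound, data = per_line, FUN = mean)
    means$global_rank <- rank(avg$line_rank[match(means$compound, avg$compound)],
                              ties.method = "average")
  }
  if ("drug_class" %in% names(delta)) {
    cls <- unique(delta[c("compound", "drug_class")])
    means$drug_class <- cls$drug_class[match(means$compound, cls$compound)]
    means <- means[c("compound", "drug_class", "mean_delta_auc", "global_rank")]
  }
  means <- means[order(means$global_rank, means$compound), ]
  rownames(means) <- NULL
  means
}

#' Aggregate compound ranks to drug-class average ranks
#'
#' Each class's average rank is the arithmetic mean of its members' global
#' ranks. Classes are compared to a reference class — by default the class
#' with the worst (largest) average rank, mirroring the use of the least
#' effective class as baseline — with a Welch two-sample t-test on member
#' ranks (or on member mean delta AUCs with `test_on = "delta"`). The
#' reference class gets p = 1; classes with a single member get `NA` with a
#' flag since the test variance is undefined.
#'
#' @param ranks Output of [rank_compounds()]; must carry `drug_class`.
#' @param reference Class id, or `"auto"` to pick the worst class.
#' @param test_on `"ranks"` (default) or `"delta"`.
#' @return Data frame sorted by ascending average rank: `drug_class,
#'   n_compounds, average_rank, p_vs_reference, class_rank, is_reference,
#'   single_member`.
#' @export
class_average_ranks <- function(ranks, reference = "auto",
                                test_on = c("ranks", "delta")) {
  test_on <- match.arg(test_on)
  stopifnot("drug_class" %in% names(ranks))
  val <- if (test_on == "ranks") ranks$global_rank else ranks$mean_delta_auc
  by_class <- split(seq_len(nrow(ranks)), ranks$drug_class)
  avg <- vapply(by_class, function(i) mean(ranks$global_rank[i]), 0)
  if (identical(reference, "auto")) {
    reference <- names(avg)[which.max(avg)]
  } else if (!reference %in% names(avg)) {
    stop_named("class_average_ranks: unknown reference class '%s'", reference)
  }
  ref_val <- val[by_class[[reference]]]
  out <- data.frame(
    drug_class = names(avg),
    n_compounds = vapply(by_class, length, 0L),
    average_rank = unname(avg),
    stringsAsFactors = FALSE)
  out$is_reference <- out$drug_class == reference
  out$single_member <- out$n_compounds < 2L | length(ref_val) < 2L
  out$p_vs_reference <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$is_reference[i]) {
      out$p_vs_reference[i] <- 1
    } else if (!out$single_member[i]) {
      out$p_vs_reference[i] <- tryCatch(
        t.test(val[by_class[[out$drug_class[i]]]], ref_val)$p.value,
        error = function(e) NA_real_)
    }
  }
  out <- out[order(out$average_rank, out$drug_class), ]
  out$class_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top drug classes and the best compound within each
#'
#' Takes the `k` classes with the best (smallest) average rank and, within
#' each, the member compound with the highest mean delta AUC (ties broken
#' lexicographically by compound id).
#'
#' @param classes Output of [class_average_ranks()].
#' @param ranks Output of [rank_compounds()].
#' @param k Number of classes to keep.
#' @return Data frame `drug_class, class_rank, best_compound,
#'   mean_delta_auc`.
#' @export
select_top <- function(classes, ranks, k = 12) {
  stopifnot(k <= nrow(classes))
  top <- classes[order(classes$class_rank), ][seq_len(k), ]
  rows <- lapply(top$drug_class, function(cl) {
    m <- ranks[ranks$drug_class == cl, ]
    m <- m[order(-m$mean_delta_auc, m$compound), ]
    data.frame(drug_class = cl,
               class_rank = top$class_rank[top$drug_class == cl],
               best_compound = m$compound[1],
               mean_delta_auc = m$mean_delta_auc[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
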
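## Cross-line / cross-drug gene-set intersection analysis.

.grid_sets <- function(grid, direction = c("up", "down")) {
  stopifnot(inherits(grid, "gene_set_grid"))
  direction <- match.arg(direction)
  grid[[direction]]
}

#' Per-compound consistent gene sets across lines
#'
#' A gene is consistent for a compound when it appears in that compound's
#' direction-set in at least `ceiling(min_fraction * n_lines)` lines.
#' Support counts (number of lines) are reported for every gene seen in at
#' least 2 lines.
#'
#' @param grid A `gene_set_grid`.
#' @param direction `"up"` or `"down"`.
#' @param min_fraction Fraction of lines required, in (0.5, 1].
#' @return Named list per compound: `genes` (consistent set) and `support`
#'   (named integer, genes with support >= 2).
#' @export
consistent_sets <- function(grid, direction = c("up", "down"),
                            min_fraction = 0.75) {
  direction <- match.arg(direction)
  stopifnot(min_fraction > 0.5, min_fraction <= 1)
  sets <- .grid_sets(grid, direction)
  need <- ceiling(min_fraction * length(grid$lines))
  out <- lapply(grid$compounds, function(cm) {
    tab <- table(unlist(lapply(grid$lines, function(l)
      sets[[cell_key(l, cm)]]), use.names = FALSE))
    support <- tab[tab >= 2L]
    list(genes = sort(names(tab)[tab >= need]),
         support = setNames(as.integer(support), names(support)))
  })
  names(out) <- grid$compounds
  out
}

#' Per-line universal ("stress response") gene sets across compounds
#'
#' A gene is universal for a line when it appears in that line's
#' direction-set for at least `ceiling(min_fraction * n_compounds)`
#' compounds.
#'
#' @inheritParams consistent_sets
#' @param min_fraction Fraction of compounds required; default 1 (every
#'   compound).
#' @return Named list per line of sorted gene vectors.
#' @export
universal_sets <- function(grid, direction = c("up", "down"),
                           min_fraction = 1.0) {
  direction <- match.arg(direction)
  stopifnot(min_fraction > 0.5, min_fraction <= 1)
  sets <- .grid_sets(grid, direction)
  need <- ceiling(min_fraction * length(grid$compounds))
  out <- lapply(grid$lines, function(l) {
    tab <- table(unlist(lapply(grid$compounds, function(cm)
      sets[[cell_key(l, cm)]]), use.names = FALSE))
    sort(names(tab)[tab >= need])
  })
  names(out) <- grid$lines
  out
}

#' Genes exclusive to a single (line, compound) cell
#'
#' @inheritParams consistent_sets
#' @return Named list keyed `"line|compound"` of genes occurring in exactly
#'   one grid cell for that direction.
#' @export
exclusive_sets <- function(grid, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sets <- .grid_sets(grid, direction)
  tab <- table(unlist(sets, use.names = FALSE))
  singles <- names(tab)[tab == 1L]
  lapply(sets, function(g) sort(intersect(g, singles)))
}

#' Classify compounds as up-regulators, down-regulators or mixed
#'
#' Per compound, the medians across lines of the up- and down-set sizes are
#' compared: up-regulator when `med_up >= ratio * med_down`, down-regulator
#' when `med_down >= ratio * med_up`, otherwise mixed. Compounds whose
#' medians are both zero are labelled mixed and flagged inert.
#'
#' @param grid A `gene_set_grid`.
#' @param ratio Fold-difference of medians required for a directional call.
#' @return Data frame `compound, median_up, median_down, class, inert`.
#' @export
classify_regulators <- function(grid, ratio = 2) {
  stopifnot(inherits(grid, "gene_set_grid"))
  med_up <- apply(grid$counts_up, 2, median)
  med_down <- apply(grid$counts_down, 2, median)
  cls <- ifelse(med_up == 0 & med_down == 0, "mixed",
         ifelse(med_up >= ratio * med_down, "up-regulator",
         ifelse(med_down >= ratio * med_up, "down-regulator", "mixed")))
  data.frame(compound = grid$compounds,
             median_up = med_up[grid$compounds],
             median_down = med_down[grid$compounds],
             class = cls[grid$compounds],
             inert = (med_up == 0 & med_down == 0)[grid$compounds],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Membership matrix and exclusive intersection regions of named sets
#'
#' Enumerates the intersection regions of up to 20 sets with exclusive
#' (UpSet-style) semantics: each element of the union belongs to exactly
#' one region, identified by its membership pattern. With more than 20 sets
#' the exhaustive mode is refused and a pairwise intersection-size matrix is
#' returned instead.
#'
#' @param sets Named list of character vectors.
#' @return List with `mode = "exhaustive"`: `membership` (element x set
#'   logical matrix) and `regions` (data frame `pattern, sets, size` for
#'   every nonempty region); with `mode = "pairwise"`: `pairwise` (set x
#'   set intersection sizes).
#' @export
intersection_matrix <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets)))
    stop_named("intersection_matrix: duplicate set names")
  if (length(sets) > 20L) {
    k <- length(sets)
    pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
    for (i in seq_len(k)) for (j in seq_len(k))
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    return(list(mode = "pairwise", pairwise = pw))
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(universe, names(sets)))
  rownames(membership) <- universe
  pattern <- apply(membership, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pattern)
  regions <- data.frame(
    pattern = names(tab),
    sets = vapply(names(tab), function(p) {
      on <- strsplit(p, "")[[1]] == "1"
      paste(names(sets)[on], collapse = "&")
    }, ""),
    size = as.integer(tab), row.names = NULL, stringsAsFactors = FALSE)
  regions <- regions[order(-regions$size, regions$pattern), ]
  rownames(regions) <- NULL
  list(mode = "exhaustive", membership = membership, regions = regions)
}
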
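# Shared fixtures, built in code.

# small screen truth: 4 classes x 2 compounds, 2 lines, exact 4PL parameters
tiny_screen_truth <- function(kinetics = c(A_1 = "delayed", A_2 = "delayed",
                                           B_1 = "acute", B_2 = "acute",
                                           C_1 = "inert", C_2 = "inert",
                                           D_1 = "inert", D_2 = "inert"),
                              strength = 1.2, noise_sd = 0) {
  compounds <- data.frame(compound = names(kinetics),
                          drug_class = sub("_.*", "", names(kinetics)),
                          stringsAsFactors = FALSE)
  lines <- c("L1", "L2")
  grid <- expand.grid(cell_line = lines, compound = compounds$compound,
                      stringsAsFactors = FALSE)
  fourpl <- data.frame(grid, top = 1, bottom = 0, ic50 = 2e-6, hill = 1,
                       stringsAsFactors = FALSE)
  out <- list(lines = lines, compounds = compounds, fourpl = fourpl,
              kinetics = setNames(unname(kinetics), names(kinetics)),
              kinetics_strength = setNames(rep(strength, length(kinetics)),
                                           names(kinetics)),
              noise_sd = noise_sd, ref_day = 3)
  class(out) <- "screen_truth"
  out
}

# build a gene_set_grid directly from named lists of up/down sets
make_grid <- function(lines, compounds, up = list(), down = list()) {
  all_keys <- as.vector(outer(lines, compounds,
                              function(l, cm) paste(l, cm, sep = "|")))
  fill <- function(sets) {
    out <- setNames(vector("list", length(all_keys)), all_keys)
    for (k in all_keys) out[[k]] <- sets[[k]] %||% character()
    out
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  up <- fill(up); down <- fill(down)
  cnt <- function(sets) {
    m <- matrix(0L, length(lines), length(compounds),
                dimnames = list(lines, compounds))
    for (l in lines) for (cm in compounds)
      m[l, cm] <- length(sets[[paste(l, cm, sep = "|")]])
    m
  }
  structure(list(up = up, down = down, lines = lines, compounds = compounds,
                 counts_up = cnt(up), counts_down = cnt(down)),
            class = "gene_set_grid")
}

# expression truth for network tests: modules planted in a realistic-size
# transcriptome; the network itself is built on a gene subset
network_truth <- function(seed = 1) {
  expression_truth(n_genes = 1200, seed = seed,
                   n_markers = 30, n_consistent_down = 50,
                   n_stress_per_line = 10, module_sizes = c(120, 60, 30))
}

# random scored peaks as a data frame in BED coordinates
random_peaks <- function(n, chroms = c("chr1", "chr2"), genome = 1e6,
                         width_range = c(200, 1200)) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(genome - max(width_range) - 1L, n)
  end <- start + sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   score = round(runif(n, 1, 100), 2),
                   stringsAsFactors = FALSE)
  df[!duplicated(df[c("chrom", "start", "end")]), ]
}

# O(n*m) reference implementation of the greedy reciprocal-overlap matching
brute_force_match <- function(control_df, treated_df, min_frac = 0.5) {
  pairs <- NULL
  for (i in seq_len(nrow(control_df))) for (j in seq_len(nrow(treated_df))) {
    if (control_df$chrom[i] != treated_df$chrom[j]) next
    ov <- min(control_df$end[i], treated_df$end[j]) -
      max(control_df$start[i], treated_df$start[j])
    if (ov <= 0) next
    fc <- ov / (control_df$end[i] - control_df$start[i])
    ft <- ov / (treated_df$end[j] - treated_df$start[j])
    if (fc >= min_frac && ft >= min_frac)
      pairs <- rbind(pairs, data.frame(i = i, j = j, q = min(fc, ft)))
  }
  c_taken <- rep(FALSE, nrow(control_df))
  t_taken <- rep(FALSE, nrow(treated_df))
  matched <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$q, control_df$start[pairs$i],
                         treated_df$start[pairs$j]), ]
    for (r in seq_len(nrow(pairs))) {
      if (!c_taken[pairs$i[r]] && !t_taken[pairs$j[r]]) {
        c_taken[pairs$i[r]] <- TRUE
        t_taken[pairs$j[r]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(matched = matched, lost = sum(!c_taken), gained = sum(!t_taken))
}
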
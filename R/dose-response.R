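## Viability AUC, the delta-AUC screening statistic, 4PL IC-50 fitting and
## early-vs-late volcano statistics.

#' Normalized area under a viability–dose curve
#'
#' Trapezoidal mean of viability over log10(dose): the trapezoid integral
#' divided by the log10-dose span. This keeps AUCs on the viability scale
#' (0–1 for full curves) so that timepoints probed with different numbers of
#' doses remain comparable; a single-dose "curve" returns that viability
#' unchanged.
#'
#' @param doses Strictly increasing positive molar doses.
#' @param viabilities Per-dose viabilities (replicates pre-averaged).
#' @return Scalar mean viability over the log-dose span.
#' @export
viability_auc <- function(doses, viabilities) {
  if (length(doses) != length(viabilities))
    stop_named("viability_auc: doses and viabilities differ in length")
  if (length(doses) < 1L) stop_named("viability_auc: need at least one dose")
  if (any(doses <= 0)) stop_named("viability_auc: doses must be positive")
  if (is.unsorted(doses, strictly = TRUE))
    stop_named("viability_auc: doses must be strictly increasing")
  if (length(doses) == 1L) return(viabilities)
  x <- log10(doses)
  trap <- sum(diff(x) * (head(viabilities, -1) + tail(viabilities, -1)) / 2)
  trap / (x[length(x)] - x[1])
}

## replicate-averaged viability per dose for one (compound, line, day)
.dose_means <- function(table, compound, cell_line, day) {
  sub <- table[table$compound == compound & table$cell_line == cell_line &
                 table$day == day, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  agg <- aggregate(viability ~ dose_M, data = sub, FUN = mean)
  agg[order(agg$dose_M), ]
}

#' Delta AUC between an early and a late timepoint
#'
#' `delta_auc = AUC(early) - AUC(late)`, each AUC computed by
#' [viability_auc()] over that timepoint's own dose set. Higher delta AUC
#' means efficacy that grows with prolonged exposure (the late-timepoint
#' viability falls relative to the early one); acutely cytotoxic compounds
#' whose effect washes out give negative values.
#'
#' @param table Long-format viability table (see [generate_screen()]).
#' @param compound,cell_line Identifiers selecting the pair.
#' @param early_day,late_day Timepoints (days).
#' @return One-row data frame: `compound, cell_line, auc_early, auc_late,
#'   delta_auc`.
#' @export
delta_auc <- function(table, compound, cell_line, early_day = 3, late_day = 28) {
  e <- .dose_means(table, compound, cell_line, early_day)
  l <- .dose_means(table, compound, cell_line, late_day)
  if (is.null(e))
    stop_named("delta_auc: no day-%s data for %s / %s", early_day, compound,
               cell_line)
  if (is.null(l))
    stop_named("delta_auc: no day-%s data for %s / %s", late_day, compound,
               cell_line)
  ae <- viability_auc(e$dose_M, e$viability)
  al <- viability_auc(l$dose_M, l$viability)
  data.frame(compound = compound, cell_line = cell_line,
             auc_early = ae, auc_late = al, delta_auc = ae - al,
             stringsAsFactors = FALSE)
}

#' Delta AUC for every (compound, cell line) pair in a viability table
#'
#' @inheritParams delta_auc
#' @return Data frame with one row per pair, carrying `drug_class` when the
#'   input table has it.
#' @export
delta_auc_table <- function(table, early_day = 3, late_day = 28) {
  pairs <- unique(table[c("compound", "cell_line")])
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    delta_auc(table, pairs$compound[i], pairs$cell_line[i], early_day, late_day)))
  if ("drug_class" %in% names(table)) {
    cls <- unique(table[c("compound", "drug_class")])
    out$drug_class <- cls$drug_class[match(out$compound, cls$compound)]
  }
  rownames(out) <- NULL
  out
}

#' Fit a four-parameter logistic dose–response curve
#'
#' Least-squares fit of
#' `V(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)` on the log10
#' dose scale, by Levenberg–Marquardt with a multi-start over initial IC-50
#' values placed at each observed dose level crossed with Hill-slope starts
#' 0.5 / 1 / 2; the fit with the best residual sum of squares is kept. The
#' curve is parameterized as `top` times a unit-scaled logistic so the box
#' bounds enforce `0 <= bottom <= top` exactly. Because viability is
#' normalized to vehicle control, the top plateau is constrained to
#' `top_range` (default 0.8-1.2); without this, curves lacking an upper
#' plateau are unidentifiable from a 4-dose design. The Hill slope is
#' bounded in `[0.2, 4]` and weakly shrunk toward 1 by a ridge penalty on
#' `log10(hill)` (strength 0.05) that resolves the flat top/hill/IC-50
#' trade-off when only one limb of the curve is sampled. When no start
#' converges
#' the IC-50 is clamped to the nearest tested-dose boundary and
#' `converged = FALSE`; all-equal viabilities are flagged as a flat curve.
#'
#' @param doses Molar doses (replicates may repeat a dose); at least 4
#'   distinct dose levels are required.
#' @param viabilities Observed viabilities, same length.
#' @param top_range Allowed range for the top plateau (fraction of control).
#' @return Object of class `dose_response_fit`: list with `top, bottom,
#'   ic50, hill, rss, converged, ic50_in_range, flat`.
#' @export
fit_ic50 <- function(doses, viabilities, top_range = c(0.8, 1.2)) {
  if (length(doses) != length(viabilities))
    stop_named("fit_ic50: doses and viabilities differ in length")
  if (any(doses <= 0)) stop_named("fit_ic50: doses must be positive")
  lev <- sort(unique(doses))
  if (length(lev) < 4L)
    stop_named("fit_ic50: need >= 4 distinct dose levels, got %d", length(lev))
  lx <- log10(doses)
  rng <- range(lev)

  mk <- function(top, bottom, ic50, hill, rss, converged, flat = FALSE) {
    out <- list(top = top, bottom = bottom, ic50 = ic50, hill = hill,
                rss = rss, converged = converged,
                ic50_in_range = ic50 >= rng[1] & ic50 <= rng[2], flat = flat)
    class(out) <- "dose_response_fit"
    out
  }

  if (sd(viabilities) < 1e-9) {
    m <- mean(viabilities)
    return(mk(top = m, bottom = m, ic50 = rng[2], hill = 1,
              rss = sum((viabilities - m)^2), converged = FALSE, flat = TRUE))
  }

  ## parameterization: top t, bottom = t * f with f in [0, 1], so the box
  ## bounds enforce 0 <= bottom <= top exactly; viability is normalized to
  ## vehicle control, so the top plateau is constrained near 1 by default
  ## (curves lacking an upper plateau are otherwise unidentifiable from a
  ## 4-dose design). A weak ridge penalty on log10(hill) breaks the flat
  ## top/hill/ic50 trade-off valley; it vanishes at hill = 1 and is
  ## negligible wherever the data actually pin the slope.
  t0 <- min(top_range[2], max(top_range[1], max(viabilities)))
  f0 <- max(0, min(viabilities)) / max(t0, 0.05)
  v <- viabilities
  pen <- sqrt(0.05)
  fn <- function(p) {
    c(v - p[1] * (p[2] + (1 - p[2]) / (1 + 10^(p[4] * (lx - p[3])))),
      pen * log10(p[4]))
  }
  lowerb <- c(top_range[1], 0, log10(rng[1]) - 3, 0.2)
  upperb <- c(top_range[2], 1, log10(rng[2]) + 3, 4)
  best <- NULL
  for (start_l in log10(lev)) for (start_h in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(t0, min(f0, 0.95), start_l, start_h),
        lower = lowerb, upper = upperb, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- fit$deviance
    if (is.null(best) || obj < best$obj - 1e-12) {
      p <- fit$par
      best <- list(t = p[1], f = p[2], li = p[3], h = p[4], obj = obj,
                   rss = sum((v - p[1] * (p[2] + (1 - p[2]) /
                                            (1 + 10^(p[4] * (lx - p[3])))))^2))
    }
  }
  if (is.null(best)) {
    ## no start converged: clamp to the boundary suggested by the response
    at_max <- mean(viabilities[doses == rng[2]])
    ic <- if (at_max > 0.5) rng[2] else rng[1]
    return(mk(top = max(viabilities), bottom = min(viabilities), ic50 = ic,
              hill = 1, rss = NA_real_, converged = FALSE))
  }
  mk(top = best$t, bottom = best$t * best$f, ic50 = 10^best$li,
     hill = best$h, rss = best$rss, converged = TRUE)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: ic50 = %.3g M (in range: %s), hill = %.2f, top = %.2f, bottom = %.2f\n",
    x$ic50, x$ic50_in_range, x$hill, x$top, x$bottom))
  cat(sprintf("  rss = %.4g, converged = %s%s\n", x$rss, x$converged,
              if (isTRUE(x$flat)) ", flat response" else ""))
  invisible(x)
}

#' Fit IC-50s for every (compound, cell line) pair at one timepoint
#'
#' @param table Long-format viability table.
#' @param day Timepoint (days) whose dose–response is fitted.
#' @return Data frame: `compound, cell_line, ic50, top, bottom, hill, rss,
#'   converged, ic50_in_range` (plus `drug_class` when present).
#' @export
fit_ic50_table <- function(table, day = 7) {
  sub <- table[table$day == day, , drop = FALSE]
  if (!nrow(sub)) stop_named("fit_ic50_table: no data at day %s", day)
  pairs <- unique(sub[c("compound", "cell_line")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- sub[sub$compound == pairs$compound[i] &
               sub$cell_line == pairs$cell_line[i], ]
    f <- fit_ic50(s$dose_M, s$viability)
    data.frame(compound = pairs$compound[i], cell_line = pairs$cell_line[i],
               ic50 = f$ic50, top = f$top, bottom = f$bottom, hill = f$hill,
               rss = f$rss, converged = f$converged,
               ic50_in_range = f$ic50_in_range, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("drug_class" %in% names(table)) {
    cls <- unique(table[c("compound", "drug_class")])
    out$drug_class <- cls$drug_class[match(out$compound, cls$compound)]
  }
  rownames(out) <- NULL
  out
}

#' Dose at which a fitted curve crosses a target viability
#'
#' Inverts the 4PL at viability `v`; useful for picking a sub-cytotoxic
#' treatment dose (e.g. the dose giving ~65% viability).
#'
#' @param fit A `dose_response_fit`.
#' @param viability Target viability fraction.
#' @return Molar dose, or `NA` when the target lies outside (bottom, top).
#' @export
dose_for_viability <- function(fit, viability = 0.65) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (viability <= fit$bottom || viability >= fit$top) return(NA_real_)
  fit$ic50 * ((fit$top - viability) / (viability - fit$bottom))^(1 / fit$hill)
}

#' Per-compound volcano statistics: mean delta AUC vs early/late t-test
#'
#' For each compound, the effect axis is the mean across lines of the
#' per-line delta AUC, and the p-value is a Welch two-sample t-test between
#' all early-timepoint viabilities and all late-timepoint viabilities
#' (pooled over lines, doses and replicates). When both groups have zero
#' variance the comparison is degenerate and reported as p = 1 with a flag.
#'
#' @inheritParams delta_auc
#' @return Data frame: `compound, delta_auc_mean, p_value, n_early, n_late,
#'   degenerate`.
#' @export
volcano_stats <- function(table, early_day = 3, late_day = 28) {
  deltas <- delta_auc_table(table, early_day, late_day)
  out <- lapply(unique(table$compound), function(cm) {
    e <- table$viability[table$compound == cm & table$day == early_day]
    l <- table$viability[table$compound == cm & table$day == late_day]
    if (length(e) < 2L || length(l) < 2L)
      stop_named("volcano_stats: need >= 2 observations per timepoint for %s", cm)
    degenerate <- var(e) == 0 && var(l) == 0
    p <- if (degenerate) 1 else
      tryCatch(t.test(e, l)$p.value, error = function(err) 1)
    data.frame(compound = cm,
               delta_auc_mean = mean(deltas$delta_auc[deltas$compound == cm]),
               p_value = p, n_early = length(e), n_late = length(l),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
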
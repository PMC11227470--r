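# Inferential layer: normality screening, two-sample tests, and the
# Table-style population summary.

#' Compare two samples with normality screening
#'
#' Shapiro-Wilk is run on each sample; if both pass at `alpha`, a two-tailed
#' Welch t-test (unequal variances) compares locations, otherwise the
#' Mann-Whitney (Wilcoxon rank-sum) test is used. A degenerate sample (all
#' values identical, where Shapiro-Wilk is undefined) falls through to
#' Mann-Whitney with a note. `force_test` bypasses the screen to reproduce a
#' fixed per-variable choice.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha significance level (default 0.05).
#' @param variable label recorded in the report.
#' @param groups length-2 character vector of group labels.
#' @param force_test `NULL` (screen), `"t"` or `"mw"`.
#' @return object of class `test_report`.
#' @export
compare_groups <- function(x, y, alpha = 0.05, variable = "value",
                           groups = c("x", "y"), force_test = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("each sample needs at least 3 finite values")
  }
  shapiro_p <- function(v) {
    if (length(unique(v)) < 3L || length(v) > 5000L) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  px <- shapiro_p(x); py <- shapiro_p(y)
  note <- NULL
  if (is.null(force_test)) {
    normal <- !is.na(px) && !is.na(py) && px > alpha && py > alpha
    if (is.na(px) || is.na(py)) {
      note <- "degenerate sample for Shapiro-Wilk; using Mann-Whitney"
    }
    test <- if (normal) "welch_t" else "mann_whitney"
  } else {
    test <- switch(match.arg(force_test, c("t", "mw")),
                   t = "welch_t", mw = "mann_whitney")
  }
  if (test == "welch_t") {
    ht <- stats::t.test(x, y, var.equal = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  }
  p <- as.numeric(ht$p.value)
  if (is.nan(p)) p <- 1  # identical constant samples
  structure(list(variable = variable, groups = groups, test = test,
                 statistic = as.numeric(ht$statistic), p_value = p,
                 alpha = alpha, significant = is.finite(p) && p < alpha,
                 normality_p = c(px, py), note = note),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s [%s vs %s]: %s, stat=%.4g, p=%.4g (%s at alpha=%g)\n",
              x$variable, x$groups[1], x$groups[2], x$test, x$statistic,
              x$p_value, if (x$significant) "significant" else "n.s.", x$alpha))
  invisible(x)
}

test_report_row <- function(r) {
  data.frame(variable = r$variable, group1 = r$groups[1], group2 = r$groups[2],
             test = r$test, statistic = r$statistic, p_value = r$p_value,
             significant = r$significant,
             shapiro_p1 = r$normality_p[1], shapiro_p2 = r$normality_p[2],
             stringsAsFactors = FALSE)
}

#' Population summary of a measured study
#'
#' Builds the reference-style summary: per (node x treatment) means +/- SD of
#' area and both symmetry errors, per (node x pair-category) means of the
#' pairwise metrics, the five population ratio statistics, and the hypothesis
#' test battery (area control vs touched per node; e_d and epsilon_a pooled
#' and per node; d_avg, d_max and D^2 for control-control vs control-touched
#' pairs).
#'
#' @param measurements per-leaf table with `node`, `treatment`, `area_cm2`,
#'   `e_d`, `epsilon_a`.
#' @param pairs pair table with `node`, `category` (cc/ct), `delta_area`,
#'   `d_avg`, `d_max`, `D2`.
#' @param alpha significance level.
#' @param force_test optional `"t"`/`"mw"` override for every test.
#' @return object of class `population_summary`: list with `leaf_stats`,
#'   `pair_stats`, `ratios`, `tests` (list of `test_report`), `tests_table`,
#'   `alpha`.
#' @export
build_summary <- function(measurements, pairs, alpha = 0.05, force_test = NULL) {
  nodes <- unique(measurements$node)
  cells <- expand.grid(node = nodes, treatment = c("control", "touched"),
                       stringsAsFactors = FALSE)
  present <- interaction(measurements$node, measurements$treatment)
  missing <- cells[!interaction(cells$node, cells$treatment) %in% present, ]
  if (nrow(missing)) {
    stop("incomplete design: missing cells ",
         paste(sprintf("%s/%s", missing$node, missing$treatment), collapse = ", "))
  }
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  leaf_stats <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- measurements$node == cells$node[i] &
      measurements$treatment == cells$treatment[i]
    m <- measurements[sel, ]
    data.frame(node = cells$node[i], treatment = cells$treatment[i], n = nrow(m),
               area_mean = mean(m$area_cm2), area_sd = stats::sd(m$area_cm2),
               e_d_mean = mean(m$e_d), e_d_sd = stats::sd(m$e_d),
               epsilon_a_mean = mean(m$epsilon_a), epsilon_a_sd = stats::sd(m$epsilon_a),
               area_se = stats::sd(m$area_cm2) / sqrt(nrow(m)),
               stringsAsFactors = FALSE)
  }))
  pair_cells <- expand.grid(node = nodes, category = c("cc", "ct"),
                            stringsAsFactors = FALSE)
  pair_stats <- do.call(rbind, lapply(seq_len(nrow(pair_cells)), function(i) {
    sel <- pairs$node == pair_cells$node[i] & pairs$category == pair_cells$category[i]
    p <- pairs[sel, ]
    if (!nrow(p)) return(NULL)
    data.frame(node = pair_cells$node[i], category = pair_cells$category[i],
               n = nrow(p), delta_area_pct = 100 * mean(p$delta_area),
               d_avg = mean(p$d_avg), d_max = mean(p$d_max), D2 = mean(p$D2),
               stringsAsFactors = FALSE)
  }))
  cc <- pairs[pairs$category == "cc", ]
  ct <- pairs[pairs$category == "ct", ]
  ctrl <- measurements[measurements$treatment == "control", ]
  tch <- measurements[measurements$treatment == "touched", ]
  ratios <- population_ratios(cc, ct, ctrl, tch)
  tests <- list()
  for (nd in nodes) {
    tests[[paste0("area_", nd)]] <- compare_groups(
      ctrl$area_cm2[ctrl$node == nd], tch$area_cm2[tch$node == nd],
      alpha = alpha, variable = paste0("area_", nd),
      groups = c("control", "touched"), force_test = force_test)
  }
  for (v in c("e_d", "epsilon_a")) {
    tests[[v]] <- compare_groups(ctrl[[v]], tch[[v]], alpha = alpha,
                                 variable = v, groups = c("control", "touched"),
                                 force_test = force_test)
    for (nd in nodes) {
      tests[[paste(v, nd, sep = "_")]] <- compare_groups(
        ctrl[[v]][ctrl$node == nd], tch[[v]][tch$node == nd], alpha = alpha,
        variable = paste(v, nd, sep = "_"), groups = c("control", "touched"),
        force_test = force_test)
    }
  }
  for (v in c("d_avg", "d_max", "D2")) {
    tests[[v]] <- compare_groups(cc[[v]], ct[[v]], alpha = alpha, variable = v,
                                 groups = c("cc", "ct"), force_test = force_test)
  }
  structure(list(leaf_stats = leaf_stats, pair_stats = pair_stats,
                 ratios = ratios, tests = tests,
                 tests_table = do.call(rbind, lapply(tests, test_report_row)),
                 alpha = alpha),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("Per-leaf summary (mean ± SD):\n")
  df <- x$leaf_stats
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  node %s %-8s n=%2d  area %6.2f ± %5.2f cm2  e_d %6.2f ± %5.2f  eps_a %5.1f%% ± %4.1f\n",
                df$node[i], df$treatment[i], df$n[i], df$area_mean[i], df$area_sd[i],
                df$e_d_mean[i], df$e_d_sd[i],
                100 * df$epsilon_a_mean[i], 100 * df$epsilon_a_sd[i]))
  }
  cat("Pairwise summary:\n")
  dp <- x$pair_stats
  for (i in seq_len(nrow(dp))) {
    cat(sprintf("  node %s %-3s n=%2d  delta_area %5.1f%%  d_avg %6.1f  d_max %6.1f  D2 %.4f\n",
                dp$node[i], dp$category[i], dp$n[i], dp$delta_area_pct[i],
                dp$d_avg[i], dp$d_max[i], dp$D2[i]))
  }
  r <- x$ratios
  cat(sprintf("Ratios: delta_avg=%.3f delta_max=%.3f delta_EFD=%.3f delta_d=%.3f delta_a=%.3f\n",
              r$delta_avg, r$delta_max, r$delta_EFD, r$delta_d, r$delta_a))
  nsig <- sum(vapply(x$tests, function(t) t$significant, logical(1)))
  cat(sprintf("Tests: %d of %d significant at alpha=%g\n",
              nsig, length(x$tests), x$alpha))
  invisible(x)
}
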
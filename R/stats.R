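#' Paired statistical workflow
#'
#' Within-subject differences are tested for normality (Shapiro-Wilk),
#' compared with two-sided paired t-tests, and Bonferroni-corrected
#' across the comparison family (four in-lab exotendon-vs-natural
#' comparisons; three track metrics). Corrected p-values are
#' `min(1, p * m)`; significance is declared at alpha = 0.05 on the
#' corrected values. Incomplete pairs are dropped listwise.
#'
#' @name paired_stats
NULL

#' Paired comparison of two per-subject vectors
#'
#' @param values_a,values_b per-subject scalars (same subjects, same
#'   order); `NA` pairs are dropped listwise.
#' @param m number of comparisons in the Bonferroni family.
#' @param alpha significance level applied to corrected p-values.
#' @param label optional comparison label.
#' @return a `paired_stats_result` list: `n`, `mean_diff`, `sd_diff`
#'   (a - b), `shapiro_p`, `t_stat`, `p_raw`, `p_corrected`
#'   (`min(1, p_raw * m)`), `significant`, `degenerate` (zero-variance
#'   differences: t undefined, p reported as 1 with a warning), `label`.
#' @export
paired_comparison <- function(values_a, values_b, m = 1, alpha = 0.05,
                              label = NULL) {
  if (length(values_a) != length(values_b)) {
    stopf("paired vectors must have equal length")
  }
  keep <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[keep]; b <- values_b[keep]
  n <- length(a)
  if (n < 3) stopf("fewer than 3 complete pairs")
  d <- a - b
  degenerate <- stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))
  if (degenerate) {
    warning("zero-variance paired differences: t-test degenerate, p set to 1",
            call. = FALSE)
    sw <- NA_real_; tstat <- NA_real_; p_raw <- 1
  } else {
    sw <- stats::shapiro.test(d)$p.value
    tt <- stats::t.test(a, b, paired = TRUE)
    tstat <- unname(tt$statistic); p_raw <- tt$p.value
  }
  p_corr <- min(1, p_raw * m)
  structure(list(n = n, mean_diff = mean(d), sd_diff = stats::sd(d),
                 shapiro_p = sw, t_stat = tstat, p_raw = p_raw,
                 p_corrected = p_corr, significant = p_corr < alpha,
                 degenerate = degenerate, label = label),
            class = "paired_stats_result")
}

#' @export
print.paired_stats_result <- function(x, ...) {
  cat(sprintf(
    "%s: n=%d, mean diff %.3g (SD %.3g), t=%.3g, p=%.3g (corrected %.3g)%s\n",
    x$label %||% "paired comparison", x$n, x$mean_diff, x$sd_diff,
    x$t_stat, x$p_raw, x$p_corrected, if (x$significant) " *" else ""))
  invisible(x)
}

#' In-lab family: each exotendon condition vs natural
#'
#' Applies [paired_comparison()] to every exotendon condition against the
#' natural condition with a Bonferroni family of size equal to the number
#' of conditions compared (four in the standard design).
#'
#' @param pct_table data.frame from [process_calorimetry()] (or any table
#'   with `subject`, `condition`, and a value column).
#' @param value column to compare (default `"net_wkg"`).
#' @param natural label of the reference condition.
#' @param alpha significance level.
#' @return list of `paired_stats_result`, one per exotendon condition.
#' @export
inlab_stats <- function(pct_table, value = "net_wkg", natural = "natural",
                        alpha = 0.05) {
  conds <- setdiff(unique(pct_table$condition), c(natural, "standing"))
  m <- length(conds)
  nat <- pct_table[pct_table$condition == natural, ]
  nat_v <- nat[[value]][order(nat$subject)]
  nat_excl <- nat$excluded[order(nat$subject)]
  if (!is.null(nat_excl)) nat_v[which(nat_excl)] <- NA
  res <- lapply(conds, function(cc) {
    cur <- pct_table[pct_table$condition == cc, ]
    v <- cur[[value]][order(cur$subject)]
    if (!is.null(cur$excluded)) v[which(cur$excluded[order(cur$subject)])] <- NA
    paired_comparison(v, nat_v, m = m, alpha = alpha,
                      label = sprintf("%s vs %s", cc, natural))
  })
  names(res) <- conds
  res
}

#' Track-session family: time, heart rate, cadence
#'
#' Paired exotendon-vs-natural comparisons of the three 5-km session
#' metrics with a Bonferroni family of three. Differences are exotendon
#' minus natural, so a faster assisted run gives a negative time
#' difference.
#'
#' @param sessions data.frame with `runner`, `condition`
#'   (`"natural"`/`"exotendon"`) and metric columns.
#' @param metrics metric column names.
#' @param alpha significance level.
#' @return named list of `paired_stats_result`, one per metric.
#' @export
track_session_compare <- function(sessions,
                                  metrics = c("time_s", "hr_bpm",
                                              "cadence_spm"),
                                  alpha = 0.05) {
  nat <- sessions[sessions$condition == "natural", ]
  exo <- sessions[sessions$condition == "exotendon", ]
  nat <- nat[order(nat$runner), ]; exo <- exo[order(exo$runner), ]
  common <- intersect(nat$runner, exo$runner)
  nat <- nat[nat$runner %in% common, ]; exo <- exo[exo$runner %in% common, ]
  m <- length(metrics)
  res <- lapply(metrics, function(mc) {
    paired_comparison(exo[[mc]], nat[[mc]], m = m, alpha = alpha,
                      label = sprintf("%s: exotendon vs natural", mc))
  })
  names(res) <- metrics
  res
}

#' JSON stats report
#'
#' @param results list of `paired_stats_result`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_stats_json <- function(results, path) {
  out <- lapply(results, function(r) r[setdiff(names(r), "label")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
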
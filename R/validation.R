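# Cohort-level validation report: per approach, the correlation of MTV/TLG
# with infiltration rate and beta2-microglobulin, the ordered trend across
# visual groups A/B/C, the high- vs standard-risk comparison, and ROC
# discrimination of the 60% plasma-cell dichotomy.

.require_columns <- function(cohort, cols) {
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
}

#' Run the full statistical validation over a cohort table
#'
#' For each requested approach, computes Spearman correlations of MTV and
#' TLG with the bone-marrow infiltration rate and beta2-microglobulin, the
#' Jonckheere-Terpstra trend across visual groups A < B < C, the Wilcoxon
#' rank-sum comparison of high-risk versus standard-risk cytogenetics, and
#' the ROC analysis (AUC with bootstrap CI, p versus 0.5, optimal cut point
#' with sensitivity/specificity/accuracy) for discriminating infiltration
#' >= 60% from < 60%.
#'
#' @param cohort a `cohort_table` data.frame; required columns:
#'   `infiltration_pct`, `beta2_microglobulin`, `group`, and `mtv_<k>` /
#'   `tlg_<k>` for every requested approach. `cyto_risk` is optional
#'   (high/standard); without it the risk comparison is skipped.
#' @param approaches integer approach ids to report (default 1:6).
#' @param boot bootstrap replicates for the AUC CI.
#' @param infiltration_cutoff dichotomy threshold in percent (default 60).
#' @return list of data.frames: `correlations`, `trend`, `risk`, `roc`.
#' @export
run_validation <- function(cohort, approaches = 1:6, boot = 2000L,
                           infiltration_cutoff = 60) {
  metric_cols <- c(paste0("mtv_", approaches), paste0("tlg_", approaches))
  .require_columns(cohort, c("infiltration_pct", "beta2_microglobulin",
                             "group", metric_cols))
  has_risk <- "cyto_risk" %in% names(cohort)
  hi <- cohort$infiltration_pct >= infiltration_cutoff

  cor_rows <- list(); trend_rows <- list(); risk_rows <- list()
  roc_rows <- list()
  for (k in approaches) {
    for (metric in c("mtv", "tlg")) {
      v <- cohort[[paste0(metric, "_", k)]]
      for (target in c("infiltration_pct", "beta2_microglobulin")) {
        sc <- spearman_corr(v, cohort[[target]])
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          approach = k, metric = toupper(metric), against = target,
          rho = sc$rho, p_value = sc$p_value, n = sc$n)
      }
      grp <- lapply(c("A", "B", "C"), function(g) v[cohort$group == g])
      grp <- grp[vapply(grp, length, 1L) > 0]
      if (length(grp) >= 2) {
        jt <- jonckheere_terpstra(grp)
        trend_rows[[length(trend_rows) + 1L]] <- data.frame(
          approach = k, metric = toupper(metric),
          jt_statistic = jt$jt_statistic, p_value = jt$p_value,
          method = jt$method)
      }
      if (has_risk) {
        a <- v[cohort$cyto_risk == "high"]
        b <- v[cohort$cyto_risk == "standard"]
        if (length(a) && length(b)) {
          wt <- wilcoxon_rank_sum(a, b)
          risk_rows[[length(risk_rows) + 1L]] <- data.frame(
            approach = k, metric = toupper(metric), statistic = wt$statistic,
            p_value = wt$p_value, method = wt$method)
        }
      }
      if (any(hi) && !all(hi)) {
        rr <- roc_analysis(v, hi, boot = boot)
        roc_rows[[length(roc_rows) + 1L]] <- data.frame(
          approach = k, metric = toupper(metric), auc = rr$auc,
          ci_lo = rr$ci_95[1], ci_hi = rr$ci_95[2], p_vs_half = rr$p_vs_half,
          cut_point = rr$cut_point, sensitivity = rr$sensitivity,
          specificity = rr$specificity, accuracy = rr$accuracy)
      }
    }
  }
  bindr <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(correlations = bindr(cor_rows), trend = bindr(trend_rows),
       risk = bindr(risk_rows), roc = bindr(roc_rows))
}
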
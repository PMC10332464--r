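#' Compare control and treated groups of brain summaries
#'
#' For each cluster and for the whole brain (`"total"`): group means and
#' SEM of FI, percent change computed on group means
#' `(mean_ctrl - mean_trt) / mean_ctrl * 100`, the two-tailed unpaired
#' t statistic and p-value, and the matching comparison of neuron counts.
#' A brain that lacks a cluster contributes 0 FI and 0 neurons for it.
#'
#' @param control,treated Lists of [summarize_brain()] results (>= 2 each).
#' @param alpha Significance level.
#' @param welch Use the Welch t-test instead of pooled-variance Student's.
#' @return An object of class `group_comparison`: data.frame with one row
#'   per cluster plus `"total"`.
#' @export
compare_groups <- function(control, treated, alpha = 0.05, welch = FALSE) {
  if (length(control) < 2L || length(treated) < 2L) {
    stop("need at least 2 brains per group")
  }
  clusters <- unique(unlist(lapply(c(control, treated),
                                   function(b) b$clusters$cluster)))
  clusters <- clusters[order(match(clusters, ALL_CLUSTERS))]

  pull <- function(brains, cl, what) {
    vapply(brains, function(b) {
      i <- match(cl, b$clusters$cluster)
      if (is.na(i)) 0 else b$clusters[[what]][i]
    }, 0)
  }
  row_for <- function(cl, fc, ft, cc, ct) {
    tt <- unpaired_t_test(fc, ft, alpha = alpha, welch = welch)
    ct_test <- unpaired_t_test(cc, ct, alpha = alpha, welch = welch)
    data.frame(
      cluster = cl, n_control = length(fc), n_treated = length(ft),
      mean_fi_control = mean(fc), sem_fi_control = sem(fc),
      mean_fi_treated = mean(ft), sem_fi_treated = sem(ft),
      pct_change = (mean(fc) - mean(ft)) / mean(fc) * 100,
      t = tt$statistic, df = tt$df, p_value = tt$p_value,
      significant = tt$significant,
      mean_count_control = mean(cc), mean_count_treated = mean(ct),
      count_p_value = ct_test$p_value)
  }
  rows <- lapply(clusters, function(cl) {
    row_for(cl,
            pull(control, cl, "cluster_fi"), pull(treated, cl, "cluster_fi"),
            pull(control, cl, "neuron_count"),
            pull(treated, cl, "neuron_count"))
  })
  rows[[length(rows) + 1L]] <- row_for(
    "total",
    vapply(control, `[[`, 0, "total_fi"),
    vapply(treated, `[[`, 0, "total_fi"),
    vapply(control, function(b) as.numeric(b$total_neurons), 0),
    vapply(treated, function(b) as.numeric(b$total_neurons), 0))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  df <- as.data.frame(x)
  show <- c("cluster", "mean_fi_control", "mean_fi_treated", "pct_change",
            "p_value", "mean_count_control", "mean_count_treated",
            "count_p_value")
  print(df[, show], digits = 4, ...)
  invisible(x)
}
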
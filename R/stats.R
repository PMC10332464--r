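## Inferential toolkit used by the assay: SEM, two-tailed unpaired t-test
## (pooled variance by default, Welch behind a flag), one-way ANOVA, and
## the Newman-Keuls step-down studentized-range procedure.  Studentized-
## range tail probabilities come from numerical integration
## (stats::ptukey/qtukey); no critical-value tables are embedded.

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#'
#' @param values Numeric vector, length >= 2.
#' @return Scalar SEM.
#' @export
sem <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("SEM undefined for fewer than 2 values")
  stats::sd(values) / sqrt(length(values))
}

comparison_result <- function(statistic, df, p_value, alpha, method) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 significant = is.finite(p_value) && p_value < alpha,
                 alpha = alpha, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g (%ssignificant at %g)\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Two-tailed unpaired t-test
#'
#' Student's pooled-variance t by default (the graphing-software default
#' this toolkit mirrors); set `welch = TRUE` for the unequal-variance form.
#' Two identical degenerate groups (zero pooled variance, zero difference)
#' return t = 0, p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param alpha Significance level.
#' @param welch Use the Welch-Satterthwaite correction.
#' @return A `comparison_result`.
#' @export
unpaired_t_test <- function(a, b, alpha = 0.05, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  v1 <- stats::var(a); v2 <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    if (!welch) df <- n1 + n2 - 2
  } else {
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  comparison_result(t, df, p, alpha,
                    if (welch) "welch_t_test" else "unpaired_t_test")
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with df (k - 1, N - k).  If every group is the
#' same constant, both mean squares vanish: the statistic is reported as
#' `NaN` with p = 1 by convention.
#'
#' @param groups Named or unnamed list of numeric vectors (k >= 2).
#' @param alpha Significance level.
#' @return A `comparison_result` with `ss` (sums of squares) attached.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) stop("ANOVA needs at least 2 groups")
  n <- vapply(groups, length, 0L)
  if (any(n < 2L)) stop("each group needs at least 2 observations")
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  if (msw == 0) {
    f <- if (msb == 0) NaN else Inf
    p <- if (msb == 0) 1 else 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  res <- comparison_result(f, c(df1, df2), p, alpha, "one_way_anova")
  res$ss <- c(between = ssb, within = ssw)
  res$ms_within <- msw
  res
}

#' Newman-Keuls multiple-comparison test
#'
#' Step-down studentized-range procedure after one-way ANOVA.  Group means
#' are sorted; for a pair spanning `p` ordered means,
#' `q = |m_i - m_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))` is compared to
#' the studentized-range critical value at stretch `p` and the within-group
#' df.  A pair is declared non-significant without testing if any enclosing
#' stretch was non-significant (step-down coherence).
#'
#' @param groups Named list of numeric vectors, k >= 3 (for two groups use
#'   [unpaired_t_test()]).
#' @param alpha Significance level.
#' @return data.frame, one row per pair: group labels, means, `stretch`,
#'   `q`, `q_crit`, `p_value` (NA where blocked by the step-down rule) and
#'   `significant`.
#' @export
newman_keuls <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L) {
    stop("Newman-Keuls needs >= 3 groups; use unpaired_t_test() for two")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  aov_res <- one_way_anova(groups, alpha)
  msw <- aov_res$ms_within
  dfw <- aov_res$df[2]
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  n <- vapply(groups, length, 0L)
  ord <- order(means)
  means <- means[ord]; n <- n[ord]; labs <- names(groups)[ord]

  sig <- matrix(NA, k, k)     # sig[i, j]: verdict for sorted pair (i, j)
  rows <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      blocked <- FALSE
      if (span < k) {
        for (i2 in seq_len(i)) for (j2 in j:k) {
          if ((j2 - i2) > (j - i) && identical(sig[i2, j2], FALSE)) {
            blocked <- TRUE
          }
        }
      }
      se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
      q <- if (se == 0) {
        if (means[j] == means[i]) 0 else Inf
      } else {
        (means[j] - means[i]) / se
      }
      q_crit <- stats::qtukey(1 - alpha, span, dfw)
      p <- if (blocked) NA_real_ else {
        stats::ptukey(q, span, dfw, lower.tail = FALSE)
      }
      sig[i, j] <- !blocked && is.finite(q_crit) && q >= q_crit
      rows[[length(rows) + 1L]] <- data.frame(
        group_lo = labs[i], group_hi = labs[j],
        mean_lo = means[i], mean_hi = means[j],
        stretch = span, q = q, q_crit = q_crit, p_value = p,
        blocked = blocked, significant = sig[i, j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ms_within") <- msw
  attr(out, "df_within") <- dfw
  attr(out, "alpha") <- alpha
  out
}
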
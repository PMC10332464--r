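test_that("sem matches hand arithmetic and guards n", {
  expect_equal(sem(c(2, 4, 6)), 2 / sqrt(3))
  expect_equal(sem(rep(5, 10)), 0)
  expect_error(sem(3), "SEM undefined")
})

test_that("pooled t-test matches the textbook formula and stats::t.test", {
  r <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)

  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    mine <- unpaired_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value)
    w <- unpaired_t_test(a, b, welch = TRUE)
    refw <- stats::t.test(a, b)
    expect_equal(w$statistic, unname(refw$statistic))
    expect_equal(w$df, unname(refw$parameter))
    expect_equal(w$p_value, refw$p.value)
  }
})

test_that("t-test symmetry and degenerate cases", {
  a <- c(1, 2, 3, 5); b <- c(4, 4, 6, 7)
  r1 <- unpaired_t_test(a, b); r2 <- unpaired_t_test(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  same <- unpaired_t_test(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches the lm oracle and t-squared identity", {
  set.seed(11)
  g <- list(a = rnorm(6), b = rnorm(5, 1), c = rnorm(7, 0.5))
  mine <- one_way_anova(g)
  d <- data.frame(y = unlist(g),
                  grp = rep(names(g), lengths(g)))
  ref <- anova(lm(y ~ grp, d))
  expect_equal(mine$statistic, ref$`F value`[1])
  expect_equal(mine$p_value, ref$`Pr(>F)`[1])
  expect_equal(unname(mine$df), c(2, 15))
  expect_equal(unname(mine$ss), ref$`Sum Sq`, ignore_attr = TRUE)

  # two groups: F = t^2
  t2 <- one_way_anova(g[1:2])
  tt <- unpaired_t_test(g$a, g$b)
  expect_equal(t2$statistic, tt$statistic^2)
  expect_equal(t2$p_value, tt$p_value)

  const <- one_way_anova(list(rep(1, 3), rep(1, 4)))
  expect_true(is.nan(const$statistic))
  expect_equal(const$p_value, 1)
})

test_that("Newman-Keuls flags the outlier and spares the inner pair", {
  set.seed(12)
  g <- list(low1 = rnorm(8, 0, 1), low2 = rnorm(8, 0.3, 1),
            high = rnorm(8, 4, 1))
  nk <- newman_keuls(g, alpha = 0.05)
  sig_of <- function(a, b) {
    i <- (nk$group_lo == a & nk$group_hi == b) |
      (nk$group_lo == b & nk$group_hi == a)
    nk$significant[i]
  }
  expect_true(sig_of("low1", "high"))
  expect_true(sig_of("low2", "high"))
  expect_false(sig_of("low1", "low2"))

  # Monte-Carlo studentized-range oracle for the critical values used
  dfw <- attr(nk, "df_within")
  set.seed(13)
  for (span in 2:3) {
    draws <- matrix(rnorm(1e5 * span), ncol = span)
    s <- sqrt(rchisq(1e5, dfw) / dfw)
    qsim <- (apply(draws, 1, max) - apply(draws, 1, min)) / s
    qc_mc <- unname(quantile(qsim, 0.95))
    qc <- qtukey(0.95, span, dfw)
    expect_equal(qc, qc_mc, tolerance = 0.02)
    # verdicts agree under the MC critical value too
    rows <- nk[nk$stretch == span & !nk$blocked, ]
    expect_equal(rows$q >= qc_mc, rows$significant)
  }
})

test_that("Newman-Keuls obeys step-down coherence and label symmetry", {
  set.seed(14)
  for (rep in 1:10) {
    g <- lapply(1:4, function(i) rnorm(6, sample(0:2, 1)))
    names(g) <- paste0("g", 1:4)
    nk <- newman_keuls(g)
    # no significant pair inside a blocked (non-significant) stretch
    expect_true(all(!nk$significant[nk$blocked]))
    perm <- sample(4)
    nk2 <- newman_keuls(g[perm])
    key <- function(x) {
      k <- paste(pmin(x$group_lo, x$group_hi),
                 pmax(x$group_lo, x$group_hi))
      x$significant[order(k)]
    }
    expect_equal(key(nk2), key(nk))
  }
  same <- newman_keuls(list(a = c(1, 1, 1), b = c(1, 1, 1),
                            c = c(1, 1, 1)))
  expect_false(any(same$significant))
  expect_error(newman_keuls(list(a = 1:3, b = 2:4)), "3 groups")
})

test_that("null type-I error of the t-test is near alpha", {
  set.seed(15)
  n <- 8; reps <- 1e4
  a <- matrix(rnorm(reps * n), nrow = reps)
  b <- matrix(rnorm(reps * n), nrow = reps)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  sp2 <- (va + vb) / 2
  t <- (ma - mb) / sqrt(sp2 * 2 / n)
  p <- 2 * pt(-abs(t), 2 * n - 2)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.15)
  # spot-check the vectorized null against the implementation
  r <- unpaired_t_test(a[1, ], b[1, ])
  expect_equal(r$statistic, t[1])
})
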
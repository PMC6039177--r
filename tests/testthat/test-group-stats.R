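# The statistical battery: t-tests, factorial and mixed ANOVA, Bonferroni.

test_that("unpaired t matches the textbook pooled-variance formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- t_unpaired(x, y, welch_if_unequal_var = FALSE)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, 4)
  expect_equal(r$p, p_hand)

  same <- c(3, 5, 7, 9)
  r0 <- t_unpaired(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
})

test_that("dissimilar variances trigger Welch with Satterthwaite df", {
  x <- c(10.0, 10.1, 9.9, 10.05, 9.95)
  y <- c(0, 25, -10, 40, 5)
  r <- t_unpaired(x, y)
  expect_identical(r$test_name, "Welch t-test")
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  df_welch <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  expect_equal(r$df, df_welch)
  expect_lt(r$df, length(x) + length(y) - 2)

  # similar variances stay pooled
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_identical(t_unpaired(a, b)$test_name, "unpaired t-test")
})

test_that("zero-variance samples are handled explicitly", {
  expect_error(t_unpaired(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  r <- t_unpaired(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("one-sample t against 100 matches the hand formula", {
  x <- c(102, 98, 110, 95, 100)
  r <- t_one_sample(x, 100)
  t_hand <- (mean(x) - 100) / (sd(x) / sqrt(length(x)))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE))

  r0 <- t_one_sample(rep(100, 5), 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(t_one_sample(rep(105, 5), 100), "degenerate")
})

test_that("paired t handles alignment and degenerate differences", {
  x <- c(5, 7, 9, 11); y <- c(4, 7, 7, 10)
  r <- t_paired(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(r$statistic, t_hand)
  expect_error(t_paired(1:4, 1:3), "equal length")
  expect_error(t_paired(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  expect_equal(t_paired(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("factorial ANOVA reproduces the balanced 2x2 SS decomposition", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   rep = 1:4, KEEP.OUT.ATTRS = FALSE)
  set.seed(21)
  d$y <- 5 + (d$A == "a2") * 2 + (d$B == "b2") * 1 +
    (d$A == "a2" & d$B == "b2") * 1.5 + rnorm(nrow(d))
  tab <- anova_factorial(d, "y", c("A", "B"))

  # textbook SS decomposition for the balanced design
  n_cell <- 4; grand <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  ss_a <- 2 * n_cell * sum((mA - grand)^2)
  ss_b <- 2 * n_cell * sum((mB - grand)^2)
  ss_ab <- n_cell * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_err <- sum((d$y - mAB[cbind(d$A, d$B)])^2)
  df_err <- nrow(d) - 4
  expect_equal(tab$F[tab$effect == "A"], (ss_a / 1) / (ss_err / df_err))
  expect_equal(tab$F[tab$effect == "B"], (ss_b / 1) / (ss_err / df_err))
  expect_equal(tab$F[tab$effect == "A:B"], (ss_ab / 1) / (ss_err / df_err))
  expect_true(all(tab$df_den == df_err))
})

test_that("identical cell distributions give F = 0", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- rep(c(1, 2, 3), each = 4)  # every cell holds {1,2,3}
  tab <- anova_factorial(d, "y", c("A", "B"))
  expect_true(all(abs(tab$F) < 1e-12))
})

test_that("two-group one-way ANOVA F equals the pooled t squared", {
  set.seed(31)
  d <- data.frame(g = rep(c("x", "y"), each = 7), y = rnorm(14))
  tab <- anova_factorial(d, "y", "g")
  r <- t_unpaired(d$y[d$g == "x"], d$y[d$g == "y"],
                  welch_if_unequal_var = FALSE)
  expect_equal(tab$F[tab$effect == "g"], r$statistic^2)
  expect_equal(tab$df_den[1], r$df)
})

test_that("an empty design cell is an error naming the cell", {
  d <- data.frame(A = c("a1", "a1", "a2", "a2"),
                  B = c("b1", "b2", "b1", "b1"), y = 1:4)
  expect_error(anova_factorial(d, "y", c("A", "B")), "a2:b2")
})

test_that("mixed ANOVA equals the independent split-plot oracle", {
  set.seed(41)
  d <- expand.grid(subject = sprintf("s%d", 1:8), block = c("t1", "t2", "t3"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:4), "ctl", "exp")
  d$y <- rnorm(nrow(d)) + (d$group == "exp") * 1.2 +
    (d$block == "t3") * 0.8
  tab <- anova_mixed(d, "y", "group", "block", "subject")
  oracle <- split_plot_oracle(d, "y", "group", "block", "subject")
  for (eff in oracle$effect) {
    got <- tab[tab$effect == eff, ]
    want <- oracle[oracle$effect == eff, ]
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$df_num, want$df_num)
    expect_equal(got$df_den, want$df_den)
  }
})

test_that("a time-constant outcome gives a within-factor F of zero", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), block = c("t1", "t2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:3), "a", "b")
  per_subject <- setNames(c(1, 2, 3, 7, 8, 9), sprintf("s%d", 1:6))
  d$y <- per_subject[d$subject]  # identical across blocks
  tab <- anova_mixed(d, "y", "group", "block", "subject")
  expect_lt(abs(tab$F[tab$effect == "block"]), 1e-12)
})

test_that("mixed ANOVA is invariant to uniform block relabeling", {
  set.seed(51)
  d <- expand.grid(subject = sprintf("s%d", 1:6),
                   block = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:3), "a", "b")
  d$y <- rnorm(nrow(d))
  tab1 <- anova_mixed(d, "y", "group", "block", "subject")
  relabel <- c(t1 = "t3", t2 = "t1", t3 = "t2")
  d2 <- d; d2$block <- relabel[d2$block]
  tab2 <- anova_mixed(d2, "y", "group", "block", "subject")
  expect_equal(tab1$F, tab2$F)
  expect_equal(tab1$p, tab2$p)
})

test_that("mixed ANOVA refuses incomplete within-subject data", {
  d <- expand.grid(subject = sprintf("s%d", 1:4), block = c("t1", "t2"),
                   stringsAsFactors = FALSE)
  d$group <- "a"; d$y <- rnorm(nrow(d))
  expect_error(anova_mixed(d[-1, ], "y", "group", "block", "subject"),
               "incomplete")
})

test_that("Bonferroni correction multiplies and caps p-values", {
  set.seed(61)
  cells <- list(a = rnorm(8), b = rnorm(8) + 1, c = rnorm(8))
  one <- bonferroni_pairwise(cells, list(c("a", "b")))
  expect_equal(one$p_adjusted, one$p_raw)
  two <- bonferroni_pairwise(cells, list(c("a", "b"), c("a", "c")))
  expect_equal(two$p_adjusted, pmin(1, two$p_raw * 2))
  # a comparison with raw p > 0.5 caps at 1 under many comparisons
  many <- bonferroni_pairwise(list(a = rnorm(5), b = rnorm(5)),
                              rep(list(c("a", "b")), 4))
  expect_true(all(many$p_adjusted <= 1))
  expect_error(bonferroni_pairwise(cells, list(c("a", "zz"))), "unknown")
})
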
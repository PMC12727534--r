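test_that("unpaired pooled t matches the closed form", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  cmp <- unpaired_t(a, b)
  oracle <- pooled_t_closed_form(a, b)
  expect_equal(cmp$statistic, unname(oracle["t"]), tolerance = 1e-10)
  expect_equal(cmp$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p.value, 0.2879, tolerance = 1e-3)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(2:12, 1))
    y <- rnorm(sample(2:12, 1), 0.5)
    got <- unpaired_t(x, y)
    want <- pooled_t_closed_form(x, y)
    expect_equal(got$statistic, unname(want["t"]), tolerance = 1e-10)
    expect_equal(got$p.value, unname(want["p"]), tolerance = 1e-10)
  }
})

test_that("identical samples give t = 0, p = 1; degenerate input errors", {
  x <- c(1, 2, 3, 4)
  cmp <- unpaired_t(x, x)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p.value, 1)
  expect_error(unpaired_t(rep(1, 3), rep(1, 3)),
               class = "photoflux_degenerate_error")
  expect_error(unpaired_t(1, c(1, 2)), class = "photoflux_param_error")
})

test_that("paired t works on differences and is antisymmetric", {
  a <- c(10, 11, 13, 12)
  b <- a + c(1, 1, 1, 2)
  cmp <- paired_t(b, a)
  d <- b - a
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$statistic, t_manual, tolerance = 1e-12)
  expect_equal(cmp$df, 3)
  expect_equal(paired_t(a, b)$statistic, -cmp$statistic)
  expect_error(paired_t(a, a), class = "photoflux_degenerate_error")
})

test_that("rank-sum exact path reproduces full enumeration up to n = 10", {
  cmp <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p.value, 0.1)
  expect_equal(cmp$method, "rank_sum_exact")
  set.seed(17)
  for (i in 1:30) {
    na <- sample(1:7, 1)
    nb <- sample(seq_len(10 - na), 1)
    x <- sample(seq(0.1, 50, by = 0.1), na + nb)  # distinct values, no ties
    a <- x[seq_len(na)]
    b <- x[-seq_len(na)]
    got <- rank_sum(a, b)
    expect_equal(got$method, "rank_sum_exact")
    expect_equal(got$p.value, ranksum_enumeration(a, b), tolerance = 1e-12)
    expect_equal(got$p.value, rank_sum(b, a)$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum falls back to the tie-corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 6, 7)
  b <- c(2, 4, 4, 5, 8, 9, 10)
  cmp <- rank_sum(a, b)
  expect_equal(cmp$method, "rank_sum_normal_approx")
  expect_gte(cmp$p.value, 0)
  expect_lte(cmp$p.value, 1)
  # exact and approximate paths agree closely at moderate n without ties
  set.seed(23)
  x <- rnorm(6)
  y <- rnorm(6, 0.3)
  p_exact <- rank_sum(x, y)$p.value
  p_approx <- rank_sum(x, y, exact_max = 0)$p.value
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("two-way ANOVA SS match the projection oracle on random layouts", {
  set.seed(31)
  for (i in 1:10) {
    la <- sample(2:3, 1)
    lb <- sample(2:3, 1)
    reps <- sample(2:4, 1)
    d <- expand.grid(A = factor(seq_len(la)), B = factor(seq_len(lb)),
                     r = seq_len(reps))
    d$y <- rnorm(nrow(d), mean = as.numeric(d$A) + 0.5 * as.numeric(d$B))
    fit <- two_way_anova(d, y, A, B)
    oracle <- anova_projection_oracle(d$y, d$A, d$B)
    eff <- tidy(fit)
    expect_lt(abs(eff$sumsq[eff$term == "A"] - oracle[["A"]]), 1e-8)
    expect_lt(abs(eff$sumsq[eff$term == "B"] - oracle[["B"]]), 1e-8)
    expect_lt(abs(eff$sumsq[eff$term == "A:B"] - oracle[["A:B"]]), 1e-8)
    expect_lt(abs(eff$sumsq[eff$term == "residual"] - oracle[["residual"]]), 1e-8)
  }
})

test_that("ANOVA rejects unbalanced layouts and zero residual variance", {
  d <- data.frame(A = factor(c(1, 1, 1, 2, 2)), B = factor(c(1, 2, 2, 1, 2)),
                  y = rnorm(5))
  expect_error(two_way_anova(d, y, A, B), class = "photoflux_param_error")
  d2 <- expand.grid(A = factor(1:2), B = factor(1:2), r = 1:2)
  d2$y <- ifelse(d2$A == 2 & d2$B == 2, 1, 0)  # zero within-cell variance
  expect_error(two_way_anova(d2, y, A, B),
               class = "photoflux_degenerate_error")
})

test_that("all-equal cells give F = 0 for the factor effects", {
  d <- expand.grid(A = factor(1:2), B = factor(1:3), r = 1:3)
  set.seed(2)
  noise <- rnorm(3)
  d$y <- noise[d$r]  # same replicate pattern in every cell
  fit <- two_way_anova(d, y, A, B)
  eff <- tidy(fit)
  expect_lt(max(abs(eff$statistic[eff$term != "residual"]), na.rm = TRUE), 1e-10)
})

test_that("Fisher LSD is the unadjusted residual-MS t-test", {
  set.seed(41)
  d <- expand.grid(A = factor(c("x", "y")), r = 1:6)
  d$y <- rnorm(nrow(d), as.numeric(d$A))
  fit <- two_way_anova(d, y, A)
  lsd <- fisher_lsd(fit, "x", "y")
  pooled <- unpaired_t(d$y[d$A == "x"], d$y[d$A == "y"])
  expect_equal(lsd$statistic, pooled$statistic, tolerance = 1e-10)
  expect_equal(lsd$p.value, pooled$p.value, tolerance = 1e-10)
  expect_equal(lsd$df, pooled$df)
  # self-comparison and unknown cells
  self <- fisher_lsd(fit, "x", "x")
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
  expect_error(fisher_lsd(fit, "x", "zzz"), class = "photoflux_param_error")

  # two-factor cells: p is the single-comparison (unadjusted) p
  d2 <- expand.grid(A = factor(1:2), B = factor(1:2), r = 1:4)
  d2$y <- rnorm(nrow(d2), ifelse(d2$A == 2 & d2$B == 2, 1, 0))
  fit2 <- two_way_anova(d2, y, A, B)
  lsd2 <- fisher_lsd(fit2, c("2", "2"), c("1", "1"))
  se <- sqrt(fit2$residual_ms * (1 / 4 + 1 / 4))
  m <- fit2$cells
  diff_means <- m$mean[m$A == "2" & m$B == "2"] - m$mean[m$A == "1" & m$B == "1"]
  expect_equal(lsd2$statistic, diff_means / se, tolerance = 1e-12)
  expect_equal(lsd2$p.value,
               2 * pt(abs(lsd2$statistic), fit2$residual_df, lower.tail = FALSE))
})

test_that("p-values decrease in |t| at fixed df and stay in [0, 1]", {
  ts <- seq(0, 5, by = 0.5)
  ps <- 2 * pt(ts, 10, lower.tail = FALSE)
  cmp <- list(unpaired_t(rnorm(5), rnorm(5)),
              paired_t(rnorm(5), rnorm(5)),
              rank_sum(rnorm(4), rnorm(4)))
  for (x in cmp) {
    expect_gte(x$p.value, 0)
    expect_lte(x$p.value, 1)
  }
  expect_true(all(diff(ps) < 0))
})

test_that("compare_groups splits a tibble and tidies the result", {
  d <- tibble::tibble(g = rep(c("ctrl", "exp"), each = 4),
                      v = c(1, 2, 3, 4, 3, 4, 5, 6))
  row <- compare_groups(d, v, g)
  expect_equal(row$method, "unpaired_t_student")
  expect_equal(row$group_1, "ctrl")
  expect_equal(row$n_1, 4)
  oracle <- pooled_t_closed_form(d$v[1:4], d$v[5:8])
  expect_equal(row$statistic, unname(oracle["t"]), tolerance = 1e-10)
  expect_equal(compare_groups(d, v, g, method = "ranksum")$method,
               "rank_sum_normal_approx")
  expect_error(compare_groups(dplyr::mutate(d, g = "one"), v, g),
               class = "photoflux_param_error")
})
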
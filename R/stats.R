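new_group_comparison <- function(method, statistic, df, p, groups, note = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p.value = p, groups = groups, note = note),
            class = "group_comparison")
}

group_summary_tbl <- function(samples, labels) {
  purrr::map2_dfr(samples, labels, function(x, lab) {
    tibble(group = lab, n = length(x), mean = mean(x), sd = sd(x))
  })
}

#' Two-sample and paired t-tests as group comparisons
#'
#' `unpaired_t()` runs the two-tailed two-sample t-test, by default the
#' Student form with pooled variance and `df = n_a + n_b - 2`; set
#' `var_equal = FALSE` for the Welch form. `paired_t()` runs the two-tailed
#' paired t-test on the differences with `df = n - 1`.
#'
#' @param a,b Numeric samples; both of length >= 2 (equal lengths for the
#'   paired test).
#' @param var_equal Pool the variances (Student, the default)?
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @examples
#' tidy(unpaired_t(c(1, 2, 3), c(2, 3, 4)))
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_param("Both samples need n >= 2.")
  }
  if (var_equal && var(a) + var(b) == 0) {
    abort_degenerate("Pooled variance is zero; t-test undefined.")
  }
  if (!var_equal && var(a) == 0 && var(b) == 0) {
    abort_degenerate("Both variances are zero; t-test undefined.")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_group_comparison(
    if (var_equal) "unpaired_t_student" else "unpaired_t_welch",
    unname(ht$statistic), unname(ht$parameter), ht$p.value,
    group_summary_tbl(list(a, b), c("a", "b")))
}

#' @rdname unpaired_t
#' @export
paired_t <- function(a, b) {
  n <- length(a)
  if (n < 2L || length(b) != n) {
    abort_param("Paired samples must have equal length >= 2.")
  }
  if (var(a - b) == 0) {
    abort_degenerate("Differences have zero variance; paired t undefined.")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  new_group_comparison("paired_t", unname(ht$statistic),
                       unname(ht$parameter), ht$p.value,
                       group_summary_tbl(list(a, b), c("a", "b")))
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Uses exact enumeration of the rank-sum distribution when the combined
#' sample size is at most `exact_max` and there are no ties; otherwise the
#' normal approximation with midranks and tie correction. The path taken is
#' recorded in the result's `method`.
#'
#' @param a,b Numeric samples (length >= 1).
#' @param exact_max Largest combined sample size for the exact path
#'   (default 12).
#' @return A `group_comparison`; the statistic is the Mann-Whitney U of the
#'   first sample.
#' @examples
#' tidy(rank_sum(c(1, 2, 3), c(4, 5, 6)))  # exact p = 0.1
#' @export
rank_sum <- function(a, b, exact_max = 12) {
  if (length(a) < 1L || length(b) < 1L) abort_param("Both samples need n >= 1.")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  new_group_comparison(
    if (exact) "rank_sum_exact" else "rank_sum_normal_approx",
    unname(ht$statistic), NA_real_, ht$p.value,
    group_summary_tbl(list(a, b), c("a", "b")))
}

#' Balanced fixed-effects ANOVA with one or two factors
#'
#' Fits the between-subject fixed-effects model on a balanced complete
#' layout (every cell with the same number of replicates, >= 2) and returns
#' the sums of squares, F statistics and p-values for each factor, the
#' interaction (two-factor case) and the residual. Unbalanced layouts are
#' rejected; fit such designs with a mixed/repeated-measures model instead,
#' which this package does not provide.
#'
#' @param data A data frame.
#' @param value Column with the response (tidy-eval).
#' @param factor_a,factor_b Factor columns (tidy-eval); omit `factor_b` for
#'   a one-factor layout.
#' @return An `anova_table`: effects tibble plus the cell structure needed
#'   by [fisher_lsd()].
#' @examples
#' df <- expand.grid(diet = c("NCD", "BFD"), sex = c("m", "f"),
#'                   rep = 1:3)
#' df$y <- rnorm(nrow(df))
#' tidy(two_way_anova(df, y, diet, sex))
#' @export
two_way_anova <- function(data, value, factor_a, factor_b = NULL) {
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  fa <- factor(rlang::eval_tidy(rlang::enquo(factor_a), data))
  qb <- rlang::enquo(factor_b)
  fb <- if (rlang::quo_is_null(qb)) NULL else
    factor(rlang::eval_tidy(qb, data))
  if (anyNA(v)) abort_data("Response contains missing values.")

  cells <- if (is.null(fb)) table(fa) else table(fa, fb)
  if (length(unique(as.vector(cells))) != 1L || min(cells) < 2L) {
    abort_param(paste("Layout is not balanced and complete with >= 2",
                      "replicates per cell; use a mixed-effects model",
                      "(out of scope here) for unbalanced designs."))
  }
  df_fit <- if (is.null(fb)) data.frame(y = v, A = fa) else
    data.frame(y = v, A = fa, B = fb)
  form <- if (is.null(fb)) y ~ A else y ~ A * B
  fit <- stats::aov(form, data = df_fit)
  tab <- summary(fit)[[1L]]
  terms_raw <- trimws(rownames(tab))
  label <- c(A = rlang::as_label(rlang::enquo(factor_a)),
             B = if (is.null(fb)) NA_character_ else rlang::as_label(qb))
  pretty <- vapply(terms_raw, function(tr) {
    if (tr == "Residuals") return("residual")
    tr <- sub("^A", label[["A"]], tr)
    if (!is.na(label[["B"]])) tr <- sub("B", label[["B"]], tr, fixed = TRUE)
    tr
  }, "")
  effects <- tibble(term = pretty, df = tab$Df, sumsq = tab$`Sum Sq`,
                    meansq = tab$`Mean Sq`, statistic = tab$`F value`,
                    p.value = tab$`Pr(>F)`)
  res <- effects[effects$term == "residual", ]
  total_ss <- sum(effects$sumsq)
  if (res$sumsq <= 1e-12 * max(total_ss, .Machine$double.eps)) {
    abort_degenerate("Residual sum of squares is zero; F tests undefined.")
  }
  cell_tbl <- dplyr::summarise(
    dplyr::group_by(df_fit, dplyr::across(dplyr::any_of(c("A", "B")))),
    n = dplyr::n(), mean = mean(.data$y), .groups = "drop")
  structure(list(effects = effects, cells = cell_tbl,
                 residual_ms = res$meansq, residual_df = res$df,
                 factor_labels = label),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("<anova_table> balanced fixed-effects ANOVA\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.group_comparison
#' @export
tidy.anova_table <- function(x, ...) x$effects

#' Fisher's LSD post hoc comparison of two cells
#'
#' Unadjusted pairwise t-test between two cell means of a fitted balanced
#' ANOVA, using the residual mean square as the pooled error variance and
#' the residual degrees of freedom. No multiplicity correction is applied
#' ("uncorrected" LSD); with a one-factor two-group design this reduces
#' exactly to the pooled unpaired t-test.
#'
#' @param anova An `anova_table` from [two_way_anova()].
#' @param cell_1,cell_2 Character vectors naming a cell: one level for a
#'   one-factor layout, `c(levelA, levelB)` for two factors.
#' @return A `group_comparison`.
#' @export
fisher_lsd <- function(anova, cell_1, cell_2) {
  stopifnot(inherits(anova, "anova_table"))
  pick <- function(cell) {
    cells <- anova$cells
    keys <- intersect(c("A", "B"), names(cells))
    if (length(cell) != length(keys)) {
      abort_param(sprintf("Each cell must name %d level(s).", length(keys)))
    }
    sel <- rep(TRUE, nrow(cells))
    for (i in seq_along(keys)) sel <- sel & cells[[keys[i]]] == cell[i]
    if (sum(sel) != 1L) {
      abort_param(sprintf("Cell (%s) is not in the design.",
                          paste(cell, collapse = ", ")))
    }
    cells[sel, ]
  }
  c1 <- pick(cell_1)
  c2 <- pick(cell_2)
  se <- sqrt(anova$residual_ms * (1 / c1$n + 1 / c2$n))
  tstat <- (c1$mean - c2$mean) / se
  p <- 2 * pt(abs(tstat), anova$residual_df, lower.tail = FALSE)
  new_group_comparison("fisher_lsd", tstat, anova$residual_df, p,
                       tibble(group = c(paste(cell_1, collapse = ":"),
                                        paste(cell_2, collapse = ":")),
                              n = c(c1$n, c2$n), mean = c(c1$mean, c2$mean),
                              sd = NA_real_),
                       note = "uncorrected")
}

#' Tidy group comparisons
#'
#' @param x A `group_comparison` or `anova_table`.
#' @param ... Unused.
#' @return One row per comparison with `method`, `statistic`, `df`,
#'   `p.value` and per-group n/mean columns.
#' @export
tidy.group_comparison <- function(x, ...) {
  g <- x$groups
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p.value = x$p.value,
         n_1 = g$n[1], n_2 = g$n[2], mean_1 = g$mean[1], mean_2 = g$mean[2])
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.na(x$df)) "NA" else format(x$df), x$p.value))
  invisible(x)
}

#' Compare two groups of per-animal values
#'
#' Tidy front end for the group tests: splits `data` by a two-level group
#' column and applies the chosen test to a value column.
#'
#' @param data A data frame with one row per animal.
#' @param value Value column (tidy-eval).
#' @param group Grouping column with exactly two levels (tidy-eval).
#' @param method `"student"` (pooled t), `"welch"`, or `"ranksum"`.
#' @return A one-row tibble as from [tidy.group_comparison()], with the
#'   group labels in `group_1`, `group_2`.
#' @export
compare_groups <- function(data, value, group,
                           method = c("student", "welch", "ranksum")) {
  method <- match.arg(method)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  lev <- unique(g)
  if (length(lev) != 2L) abort_param("`group` must have exactly two levels.")
  a <- v[g == lev[1]]
  b <- v[g == lev[2]]
  cmp <- switch(method,
                student = unpaired_t(a, b, var_equal = TRUE),
                welch = unpaired_t(a, b, var_equal = FALSE),
                ranksum = rank_sum(a, b))
  dplyr::mutate(tidy(cmp), group_1 = lev[1], group_2 = lev[2],
                .after = "method")
}
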
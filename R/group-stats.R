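# Statistical battery for cohort outcomes: t-tests (pooled / Welch /
# paired / one-sample), Type-III factorial ANOVA, split-plot mixed ANOVA,
# and Bonferroni-corrected pairwise comparisons. All p-values are
# two-sided; sphericity corrections are not applied (reported dfs are the
# uncorrected balanced-design ones).

test_result <- function(statistic, df, p, test_name, effect_label = "") {
  structure(list(statistic = as.numeric(statistic), df = as.numeric(df),
                 p = as.numeric(p), test_name = test_name,
                 effect_label = effect_label),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s%s: t(%s) = %.3f, p = %.4g\n", x$test_name,
              if (nzchar(x$effect_label)) paste0(" [", x$effect_label, "]")
              else "",
              format(x$df, digits = 4), x$statistic, x$p))
  invisible(x)
}

#' Unpaired two-sample t-test with automatic Welch correction
#'
#' Pooled-variance t by default; when the two sample variances are
#' dissimilar (two-sided F-ratio test at `alpha_var`) the Welch
#' (Satterthwaite) form is used instead, mirroring the common reporting
#' convention "Welch's correction was used if variances were not similar".
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param welch_if_unequal_var Apply the Welch trigger? `FALSE` forces the
#'   pooled test.
#' @param alpha_var Significance level of the variance-dissimilarity F test.
#' @param effect_label Optional label carried into the result.
#' @return A `test_result` (statistic, df -- fractional under Welch --,
#'   two-sided p).
#' @export
t_unpaired <- function(x, y, welch_if_unequal_var = TRUE, alpha_var = 0.05,
                       effect_label = "") {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(test_result(0, length(x) + length(y) - 2, 1,
                         "unpaired t-test", effect_label))
    }
    stop("both samples have zero variance with different means",
         call. = FALSE)
  }
  welch <- FALSE
  if (welch_if_unequal_var && vx > 0 && vy > 0) {
    welch <- stats::var.test(x, y)$p.value < alpha_var
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (welch) "Welch t-test" else "unpaired t-test",
              effect_label)
}

#' Paired t-test
#'
#' @param x,y Paired numeric samples of equal length (n >= 2 pairs).
#' @param effect_label Optional label.
#' @return A `test_result`. Differences with zero standard deviation are a
#'   degenerate input: zero differences give t = 0, p = 1; a constant
#'   nonzero difference is an error (infinite t).
#' @export
t_paired <- function(x, y, effect_label = "") {
  if (length(x) != length(y)) stop("paired samples must have equal length",
                                   call. = FALSE)
  stopifnot(length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(test_result(0, length(d) - 1, 1, "paired t-test", effect_label))
    }
    stop("paired differences are a nonzero constant (degenerate t)",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              "paired t-test", effect_label)
}

#' One-sample t-test
#'
#' Default null value 100, the no-revaluation anchor for percent-of-baseline
#' scores.
#'
#' @param x Numeric sample (n >= 2).
#' @param mu0 Null value.
#' @param effect_label Optional label.
#' @return A `test_result`.
#' @export
t_one_sample <- function(x, mu0 = 100, effect_label = "") {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) {
    if (mean(x) == mu0) {
      return(test_result(0, length(x) - 1, 1, "one-sample t-test",
                         effect_label))
    }
    stop("sample is constant and unequal to mu0 (degenerate t)",
         call. = FALSE)
  }
  ht <- stats::t.test(x, mu = mu0)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              "one-sample t-test", effect_label)
}

anova_table <- function(effect, df_num, df_den, F, p) {
  structure(data.frame(effect = effect, df_num = df_num, df_den = df_den,
                       F = F, p = p, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("anova_table", "data.frame"))
}

#' Between-subjects factorial ANOVA (Type III)
#'
#' One- or two-way between-subjects ANOVA using Type-III sums of squares on
#' the cell-means model (sum-to-zero contrasts), the convention matching
#' unbalanced behavioral designs. Reports all main effects and, for two
#' factors, the interaction.
#'
#' @param data `data.frame` holding the outcome and factor columns.
#' @param outcome Name of the numeric outcome column.
#' @param between Character vector of 1 or 2 between-subjects factor
#'   columns; every factor needs >= 2 levels and every cell must be
#'   non-empty.
#' @return An `anova_table` with columns `effect`, `df_num`, `df_den`, `F`,
#'   `p`.
#' @export
anova_factorial <- function(data, outcome, between) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(between %in% names(data)),
            length(between) >= 1, length(between) <= 2)
  for (b in between) data[[b]] <- factor(data[[b]])
  for (b in between) {
    if (nlevels(data[[b]]) < 2) {
      stop("factor ", b, " needs at least 2 levels", call. = FALSE)
    }
  }
  cells <- table(data[between])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell: ",
         paste(apply(empty, 1, function(i) {
           paste(mapply(function(f, k) dimnames(cells)[[f]][k],
                        seq_along(between), i), collapse = ":")
         }), collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(between, collapse = "*")))
  contr <- stats::setNames(replicate(length(between), "contr.sum",
                                     simplify = FALSE), between)
  fit <- stats::lm(fml, data = data, contrasts = contr)
  tab <- car::Anova(fit, type = 3)
  keep <- !(rownames(tab) %in% c("(Intercept)", "Residuals"))
  df_den <- tab["Residuals", "Df"]
  anova_table(effect = rownames(tab)[keep], df_num = tab$Df[keep],
              df_den = df_den, F = tab$`F value`[keep],
              p = tab$`Pr(>F)`[keep])
}

#' Mixed (split-plot) ANOVA with one within-subjects factor
#'
#' Least-squares partitioning with subject-within-group error strata:
#' between-subjects effects are tested against the subject stratum,
#' the within factor and its interactions against the subject-by-within
#' residual stratum. Requires balanced, complete data (every subject
#' observed at every within level exactly once); no imputation and no
#' sphericity correction.
#'
#' @param data Long-format `data.frame`.
#' @param outcome Name of the numeric outcome column.
#' @param between Character vector of 1 or 2 between-subjects factor
#'   columns.
#' @param within Name of the within-subjects factor column (e.g. time
#'   block).
#' @param subject Name of the subject-identifier column.
#' @return An `anova_table` with all main effects and interactions.
#' @export
anova_mixed <- function(data, outcome, between, within, subject) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(c(between, within, subject) %in% names(data)),
            length(between) >= 1, length(between) <= 2)
  for (f in c(between, within, subject)) data[[f]] <- factor(data[[f]])
  cross <- table(data[[subject]], data[[within]])
  if (any(cross != 1)) {
    bad <- which(cross != 1, arr.ind = TRUE)[1, ]
    stop("incomplete within-subject data: subject ",
         rownames(cross)[bad[1]], " at level ", colnames(cross)[bad[2]],
         call. = FALSE)
  }
  rhs <- paste(paste(c(between, within), collapse = "*"))
  fml <- stats::as.formula(
    paste(outcome, "~", rhs, "+ Error(", subject, ")"))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)
  # scale for detecting numerically-zero effect SS (degenerate effects)
  grand_ss <- sum(vapply(sm, function(st) sum(st[[1]]$`Sum Sq`),
                         numeric(1)))
  ss_tol <- 1e-10 * max(grand_ss, 1e-300)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    nm <- trimws(rownames(tab))
    res <- which(nm == "Residuals")
    df_den <- tab$Df[res]
    for (i in setdiff(seq_len(nrow(tab)), res)) {
      f_val <- tab$`F value`[i]
      p_val <- tab$`Pr(>F)`[i]
      if (tab$`Sum Sq`[i] <= ss_tol) {
        # no variation attributable to the effect: degenerate 0/0 ratios
        # are reported as no effect
        f_val <- 0
        p_val <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = nm[i], df_num = tab$Df[i], df_den = df_den,
        F = f_val, p = p_val, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  anova_table(out$effect, out$df_num, out$df_den, out$F, out$p)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Pairwise t-tests between named cells with p-values multiplied by the
#' number of comparisons (capped at 1).
#'
#' @param cell_data Named list of numeric vectors, one per design cell.
#' @param comparisons List of length-2 character vectors naming the cells
#'   to compare.
#' @param ... Passed to [t_unpaired()].
#' @return `data.frame` with one row per comparison: `comparison`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted`, `test_name`.
#' @export
bonferroni_pairwise <- function(cell_data, comparisons, ...) {
  stopifnot(is.list(cell_data), !is.null(names(cell_data)),
            is.list(comparisons), length(comparisons) >= 1)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    if (!all(cmp %in% names(cell_data))) {
      stop("unknown cell: ", paste(setdiff(cmp, names(cell_data)),
                                   collapse = ", "), call. = FALSE)
    }
    r <- t_unpaired(cell_data[[cmp[1]]], cell_data[[cmp[2]]], ...,
                    effect_label = paste(cmp, collapse = " vs "))
    data.frame(comparison = r$effect_label, statistic = r$statistic,
               df = r$df, p_raw = r$p, p_adjusted = min(1, r$p * m),
               test_name = r$test_name, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
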
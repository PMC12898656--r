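#' Group summary of one variable
#'
#' The (n, mean, SD, median) unit in which case-control results are
#' reported, and from which the summary-statistic mode of the comparison
#' chain operates when raw data are unavailable.
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd sample standard deviation (n-1 denominator, >= 0).
#' @param median optional group median.
#' @return An object of class `tsp_group_summary`.
#' @export
group_summary <- function(n, mean, sd, median = NA_real_) {
  if (!is_count(n) || n < 2) {
    stop_speechtsp("group size n must be an integer >= 2",
                   "speechtsp_validation_error")
  }
  if (!is.finite(sd) || sd < 0) {
    stop_speechtsp("sd must be finite and >= 0", "speechtsp_validation_error")
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd, median = median),
            class = "tsp_group_summary")
}

#' Summarize raw values into a group summary
#'
#' Missing values are excluded; `n` reflects the exclusion.
#'
#' @param values numeric vector with at least 2 non-missing entries.
#' @return A [group_summary()].
#' @export
summarize_values <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) {
    stop_speechtsp(sprintf(
      "need >= 2 non-missing values to summarize, got %d", length(v)),
      "speechtsp_validation_error")
  }
  group_summary(length(v), mean(v), sd(v), stats::median(v))
}

comparison_result <- function(variable, test, statistic, df = NA_real_,
                              z = NA_real_, p, effect_size_d = NA_real_,
                              significant_at = 0.05) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 df = df, z = z, p = p, effect_size_d = effect_size_d,
                 significant_at = significant_at,
                 significant = is.finite(p) && p <= significant_at),
            class = "tsp_comparison")
}

#' @export
print.tsp_comparison <- function(x, ...) {
  lab <- switch(x$test,
                pooled_t = sprintf("t(%g) = %.3f", x$df, x$statistic),
                welch_t = sprintf("Welch t(%.3f) = %.3f", x$df, x$statistic),
                mann_whitney_u = sprintf("U = %g, z = %.3f", x$statistic, x$z),
                sprintf("stat = %.3f", x$statistic))
  cat(sprintf("%s: %s, p = %.4g%s%s\n",
              x$variable %||% "comparison", lab, x$p,
              if (is.finite(x$effect_size_d))
                sprintf(", d = %.3f", x$effect_size_d) else "",
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Two-sample pooled-variance t test from group summaries
#'
#' Classical equal-variance t with `df = n_a + n_b - 2`, two-tailed. The
#' statistic's sign follows `mean_a - mean_b` with the control group
#' conventionally listed first — note this is the *opposite* sign
#' convention from [cohens_d()], which reports case minus control.
#'
#' @param a,b [group_summary()] objects (`a` = control/reference first).
#' @param variable optional variable name carried into the result.
#' @return A `tsp_comparison`.
#' @examples
#' pooled_t(group_summary(31, 9.647, 1.551), group_summary(34, 7.877, 2.038))
#' @export
pooled_t <- function(a, b, variable = NA_character_) {
  stopifnot(inherits(a, "tsp_group_summary"), inherits(b, "tsp_group_summary"))
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    stop_speechtsp("both SDs zero with equal means: t undefined",
                   "speechtsp_degenerate_error")
  }
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  tt <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  comparison_result(variable, "pooled_t", tt, df = df,
                    p = 2 * pt(-abs(tt), df),
                    effect_size_d = (b$mean - a$mean) / sqrt(sp2))
}

#' Welch's unequal-variance t test from group summaries
#'
#' Welch-Satterthwaite degrees of freedom; two-tailed p. Effect size is
#' still the pooled-SD Cohen's d (the reporting convention).
#'
#' @inheritParams pooled_t
#' @return A `tsp_comparison`.
#' @examples
#' welch_t(group_summary(31, 1.512, 0.897), group_summary(34, 2.831, 1.695))
#' @export
welch_t <- function(a, b, variable = NA_character_) {
  stopifnot(inherits(a, "tsp_group_summary"), inherits(b, "tsp_group_summary"))
  if (a$sd == 0 && b$sd == 0) {
    stop_speechtsp("both SDs zero: Welch t undefined",
                   "speechtsp_degenerate_error")
  }
  v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
  tt <- (a$mean - b$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  comparison_result(variable, "welch_t", tt, df = df,
                    p = 2 * pt(-abs(tt), df),
                    effect_size_d = cohens_d(a, b))
}

#' Cohen's d from group summaries
#'
#' `d = (mean_case - mean_control) / s_pooled` with (n-1)-weighted pooled
#' SD. Sign convention: case (second argument) minus control (first), so
#' a variable elevated in cases has positive d.
#'
#' @param a control-group [group_summary()].
#' @param b case-group [group_summary()].
#' @return Numeric effect size.
#' @export
cohens_d <- function(a, b) {
  stopifnot(inherits(a, "tsp_group_summary"), inherits(b, "tsp_group_summary"))
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) {
    stop_speechtsp("pooled SD is zero: Cohen's d undefined",
                   "speechtsp_degenerate_error")
  }
  (b$mean - a$mean) / sqrt(sp2)
}

#' Choose the two-sample test for raw data
#'
#' The decision rule of the reporting convention: if either group fails
#' normality at `alpha_normality` (Shapiro-Wilk by default, or
#' Lilliefors-corrected Kolmogorov-Smirnov), use the Mann-Whitney U
#' test; otherwise gate on variance equality with Levene's test
#' (mean-centered): unequal variances give Welch's t, equal give the
#' pooled t. Degenerate (constant) groups fall through to Mann-Whitney.
#'
#' @param a_raw,b_raw numeric vectors (>= 3 values each).
#' @param normality_method `"shapiro"` or `"lilliefors"`.
#' @param alpha_normality,alpha_variance gate levels (default 0.05).
#' @return One of `"pooled_t"`, `"welch_t"`, `"mann_whitney_u"`.
#' @export
choose_test <- function(a_raw, b_raw,
                        normality_method = c("shapiro", "lilliefors"),
                        alpha_normality = 0.05, alpha_variance = 0.05) {
  normality_method <- match.arg(normality_method)
  a_raw <- a_raw[!is.na(a_raw)]; b_raw <- b_raw[!is.na(b_raw)]
  stopifnot(length(a_raw) >= 3L, length(b_raw) >= 3L)
  norm_p <- function(x) {
    tryCatch(
      if (normality_method == "shapiro") shapiro.test(x)$p.value
      else nortest::lillie.test(x)$p.value,
      error = function(e) 0)   # constant / degenerate: treat as non-normal
  }
  if (norm_p(a_raw) < alpha_normality || norm_p(b_raw) < alpha_normality) {
    return("mann_whitney_u")
  }
  lev <- tryCatch(
    car::leveneTest(c(a_raw, b_raw),
                    factor(rep(c("a", "b"), c(length(a_raw), length(b_raw)))),
                    center = mean)[["Pr(>F)"]][1L],
    error = function(e) 1)
  if (is.finite(lev) && lev < alpha_variance) "welch_t" else "pooled_t"
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Reports `U` for the first group (number of (a, b) pairs with a > b,
#' ties counting one half) and the z statistic under the tie-corrected
#' normal approximation without continuity correction — the convention
#' of the major statistical packages for moderate samples. An exact-U
#' p-value (via [stats::wilcox.test()]) can be requested instead for
#' small tie-free samples via `exact_limit`.
#'
#' @param a_raw,b_raw numeric vectors (>= 1 value each).
#' @param variable optional variable name.
#' @param exact_limit per-group size at or below which the exact U
#'   distribution replaces the normal approximation for the p-value
#'   (default 0: always use the normal approximation).
#' @return A `tsp_comparison` with `statistic` = U, `z`, and `p`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a_raw, b_raw, variable = NA_character_,
                         exact_limit = 0L) {
  a_raw <- a_raw[!is.na(a_raw)]; b_raw <- b_raw[!is.na(b_raw)]
  stopifnot(length(a_raw) >= 1L, length(b_raw) >= 1L)
  n1 <- length(a_raw); n2 <- length(b_raw); N <- n1 + n2
  rk <- rank(c(a_raw, b_raw))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a_raw, b_raw))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (v > 0) (u - mu) / sqrt(v) else 0
  p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  if (n1 <= exact_limit && n2 <= exact_limit && !any(duplicated(c(a_raw, b_raw)))) {
    p <- suppressWarnings(
      stats::wilcox.test(a_raw, b_raw, exact = TRUE)$p.value)
  }
  comparison_result(variable, "mann_whitney_u", u, z = z, p = p)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (the convention of the reporting
#' software for moderate samples).
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `statistic`, `df` (= 1), `p`.
#' @examples
#' chi_square_2x2(matrix(c(7, 27, 11, 20), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_speechtsp("chi-square undefined: zero marginal total",
                   "speechtsp_degenerate_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = 1L, p = ht$p.value)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`, with a `rounded` attribute at 4 decimals (the
#'   form in which such thresholds are reported).
#' @examples
#' bonferroni(0.05, 11)   # 0.004545..., reported as 0.0045
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is_count(m) || m < 1) {
    stop_speechtsp("m must be an integer >= 1", "speechtsp_validation_error")
  }
  structure(alpha / m, rounded = round(alpha / m, 4))
}

#' Prune highly correlated variables
#'
#' Greedy scan in relevance order over the Pearson correlation matrix
#' (pairwise-complete observations): a variable is kept unless its
#' absolute correlation with an already-kept variable exceeds
#' `threshold`, in which case it is dropped and its kept proxy recorded.
#' Deterministic given the relevance order, and invariant to the input
#' column order. Constant columns (undefined correlations) are set aside
#' in `$constant`, neither kept nor dropped.
#'
#' @param ft feature table (data frame); only `variables` columns are
#'   used.
#' @param threshold absolute-correlation threshold (default 0.9).
#' @param relevance character vector giving the scan order, most relevant
#'   first. Default: variables sorted by decreasing absolute Cohen's d
#'   between the two groups of `ft` (the operational reading of "most
#'   relevant").
#' @param variables which columns to consider (default [tsp_names()]
#'   intersected with `ft`).
#' @param group_col grouping column used for the default relevance order.
#' @return An object of class `tsp_pruning`: `kept`, `dropped`
#'   (data frame variable/proxy/r), `constant`, `correlation_matrix`,
#'   `threshold`, `relevance`.
#' @export
prune_correlated <- function(ft, threshold = 0.9, relevance = NULL,
                             variables = intersect(tsp_names(), names(ft)),
                             group_col = "group") {
  x <- as.data.frame(ft)[, variables, drop = FALSE]
  if (sum(stats::complete.cases(x)) < 3L) {
    stop_speechtsp("need >= 3 complete rows to estimate correlations",
                   "speechtsp_validation_error")
  }
  sds <- vapply(x, function(col) stats::sd(col, na.rm = TRUE), 0)
  constant <- names(sds)[!is.finite(sds) | sds == 0]
  active <- setdiff(variables, constant)
  cm <- suppressWarnings(
    stats::cor(x[, active, drop = FALSE], use = "pairwise.complete.obs"))

  if (is.null(relevance)) {
    g <- factor(as.data.frame(ft)[[group_col]])
    if (nlevels(g) == 2L) {
      dvals <- vapply(active, function(v) {
        a <- x[[v]][g == levels(g)[1L]]; b <- x[[v]][g == levels(g)[2L]]
        tryCatch(abs(cohens_d(summarize_values(a), summarize_values(b))),
                 error = function(e) 0)
      }, 0)
      relevance <- active[order(-dvals)]
    } else {
      relevance <- active
    }
  }
  relevance <- c(intersect(relevance, active),
                 setdiff(active, relevance))   # unlisted variables last
  kept <- character()
  dropped <- data.frame(variable = character(), proxy = character(),
                        r = numeric())
  for (v in relevance) {
    if (length(kept) > 0L) {
      rv <- cm[v, kept]
      if (any(abs(rv) > threshold, na.rm = TRUE)) {
        j <- which.max(abs(rv))
        dropped <- rbind(dropped,
                         data.frame(variable = v, proxy = kept[j],
                                    r = unname(rv[j])))
        next
      }
    }
    kept <- c(kept, v)
  }
  structure(list(kept = kept, dropped = dropped, constant = constant,
                 correlation_matrix = cm, threshold = threshold,
                 relevance = relevance),
            class = "tsp_pruning")
}

#' @export
print.tsp_pruning <- function(x, ...) {
  cat(sprintf("Correlation pruning (|r| > %g): %d kept, %d dropped%s\n",
              x$threshold, length(x$kept), nrow(x$dropped),
              if (length(x$constant) > 0L)
                sprintf(", %d constant set aside", length(x$constant)) else ""))
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped) > 0L) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  dropped %s (r = %.3f with %s)\n",
                  x$dropped$variable[i], x$dropped$r[i], x$dropped$proxy[i]))
    }
  }
  invisible(x)
}

#' Compare all temporal parameters between two groups
#'
#' One comparison per parameter, in canonical order. Two modes:
#' \describe{
#'   \item{raw}{`ft` is a per-subject feature table with a group column.
#'     Each variable is tested with the test chosen by [choose_test()]
#'     (normality gate, then variance gate).}
#'   \item{summary}{`ft` is a summary table with columns `variable`,
#'     `n_a`, `mean_a`, `sd_a`, `n_b`, `mean_b`, `sd_b` (a = control,
#'     b = case). Only the t family is available; the variance gate is a
#'     two-sided F test on the summary variances at `alpha_variance`,
#'     which reproduces the pooled/Welch split of standard practice.}
#' }
#'
#' @param ft feature table (raw mode) or summary table (summary mode).
#' @param mode `"raw"` or `"summary"`.
#' @param group_col,control group column name and which level is the
#'   control/reference group (raw mode). Default control: first level.
#' @param alpha significance level flagged in the report.
#' @param normality_method passed to [choose_test()] (raw mode).
#' @param alpha_variance level of the variance-equality gate.
#' @return An object of class `tsp_comparison_table`: a data frame with
#'   one row per variable (test, statistic, df, z, p, d, significance and
#'   effect-size class: |d| >= 0.8 large, >= 0.5 medium, else small).
#' @examples
#' path <- system.file("extdata", "group_summaries.csv",
#'                     package = "speechtsp")
#' compare_all(utils::read.csv(path), mode = "summary")
#' @export
compare_all <- function(ft, mode = c("raw", "summary"), group_col = "group",
                        control = NULL, alpha = 0.05,
                        normality_method = "shapiro",
                        alpha_variance = 0.05) {
  mode <- match.arg(mode)
  results <- list()
  if (mode == "summary") {
    need <- c("variable", "n_a", "mean_a", "sd_a", "n_b", "mean_b", "sd_b")
    if (!all(need %in% names(ft))) {
      stop_speechtsp(sprintf("summary table must have columns: %s",
                             paste(need, collapse = ", ")),
                     "speechtsp_validation_error")
    }
    for (i in seq_len(nrow(ft))) {
      a <- group_summary(ft$n_a[i], ft$mean_a[i], ft$sd_a[i])
      b <- group_summary(ft$n_b[i], ft$mean_b[i], ft$sd_b[i])
      ## two-sided F gate on summary variances
      welch <- FALSE
      if (a$sd > 0 && b$sd > 0) {
        f <- (a$sd^2) / (b$sd^2)
        pf1 <- pf(f, a$n - 1, b$n - 1)
        welch <- 2 * min(pf1, 1 - pf1) < alpha_variance
      } else if (a$sd != b$sd) welch <- TRUE
      results[[i]] <- if (welch) welch_t(a, b, ft$variable[i])
      else pooled_t(a, b, ft$variable[i])
      results[[i]]$significant_at <- alpha
      results[[i]]$significant <- results[[i]]$p <= alpha
    }
  } else {
    g <- factor(as.data.frame(ft)[[group_col]])
    if (nlevels(g) != 2L) {
      stop_speechtsp(sprintf("raw mode needs exactly 2 groups, found %d",
                             nlevels(g)), "speechtsp_validation_error")
    }
    control <- control %||% levels(g)[1L]
    if (!control %in% levels(g)) {
      stop_speechtsp(sprintf("unknown control group '%s'", control),
                     "speechtsp_validation_error")
    }
    case <- setdiff(levels(g), control)
    vars <- intersect(tsp_names(), names(ft))
    for (i in seq_along(vars)) {
      v <- vars[i]
      a <- ft[[v]][g == control]; b <- ft[[v]][g == case]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      test <- choose_test(a, b, normality_method = normality_method,
                          alpha_variance = alpha_variance)
      res <- switch(test,
                    pooled_t = pooled_t(summarize_values(a),
                                        summarize_values(b), v),
                    welch_t = welch_t(summarize_values(a),
                                      summarize_values(b), v),
                    mann_whitney_u = mann_whitney(a, b, v))
      res$significant_at <- alpha
      res$significant <- res$p <= alpha
      results[[i]] <- res
    }
  }
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(variable = r$variable, test = r$test,
               statistic = r$statistic, df = r$df, z = r$z, p = r$p,
               effect_size_d = r$effect_size_d,
               significant = r$significant,
               effect_class = if (!is.finite(r$effect_size_d)) NA_character_
               else if (abs(r$effect_size_d) >= 0.8) "large"
               else if (abs(r$effect_size_d) >= 0.5) "medium"
               else "small")
  }))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("tsp_comparison_table", "data.frame")
  out
}

#' @export
print.tsp_comparison_table <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison of %d variables (%d significant at alpha = %g)\n\n",
              nrow(x), sum(x$significant), attr(x, "alpha") %||% 0.05))
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, digits)
  df$df <- round(df$df, digits)
  df$z <- round(df$z, digits)
  df$p <- signif(df$p, digits)
  df$effect_size_d <- round(df$effect_size_d, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
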
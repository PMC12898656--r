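#' Empirical AUC (Mann-Whitney probability estimator)
#'
#' The area under the empirical ROC curve equals the probability that a
#' random positive score exceeds a random negative score, with ties
#' counting one half: pairs with `pos > neg` count 1, ties 0.5, divided
#' by `n_pos * n_neg`. Computed via midranks, which is algebraically
#' identical to the all-pairs count.
#'
#' @param pos scores of the positive (case) class.
#' @param neg scores of the negative (control) class.
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(2, 4), c(1, 3))   # 0.75
#' @export
empirical_auc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_speechtsp("both classes must be non-empty",
                   "speechtsp_validation_error")
  }
  rk <- rank(c(pos, neg))
  (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' The closed-form nonparametric SE with `Q1 = A/(2-A)` and
#' `Q2 = 2A^2/(1+A)`:
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg)`.
#'
#' @param auc AUC in `[0, 1]`.
#' @param n_pos,n_neg class sizes (>= 1).
#' @return Standard error (>= 0).
#' @examples
#' auc_se(0.5, 10, 10)   # ~0.1323
#' @export
auc_se <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  sqrt(max(v, 0))
}

#' Asymptotic significance of an AUC
#'
#' Two-tailed normal test of `H0: AUC = 0.5` with `z = (AUC - 0.5)/SE`.
#' By convention, `SE = 0` gives p = 1 when AUC = 0.5 and p = 0
#' otherwise.
#'
#' @param auc AUC estimate.
#' @param se its standard error.
#' @return p-value.
#' @export
auc_asymptotic_p <- function(auc, se) {
  if (se <= 0) return(if (auc == 0.5) 1 else 0)
  2 * pnorm(-abs(auc - 0.5) / se)
}

#' Youden-index optimal cut-point
#'
#' Candidate cut-points are the midpoints between consecutive distinct
#' sorted scores plus `-Inf`/`Inf` sentinels (the "coordinates of the
#' curve" convention). The cut-point maximizing
#' `J = sensitivity + specificity - 1` is returned; ties are broken
#' toward higher sensitivity, then toward the lower cut-off. Under
#' `direction = "higher_is_positive"` a subject is called positive when
#' its score exceeds the cut-off; under `"lower_is_positive"`, when it
#' falls below.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @param direction `"higher_is_positive"` or `"lower_is_positive"`.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   and the full candidate `curve` (cutpoint, sensitivity,
#'   one_minus_specificity).
#' @examples
#' youden_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
youden_cutpoint <- function(scores, labels,
                            direction = c("higher_is_positive",
                                          "lower_is_positive")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  if (!any(labels) || !any(!labels)) {
    stop_speechtsp("both classes must be present",
                   "speechtsp_validation_error")
  }
  s <- sort(unique(scores))
  if (length(s) == 1L) {
    warning("all scores identical; cut-point degenerate with J = 0")
    return(list(cutoff = s, sensitivity = 1, specificity = 0, youden = 0,
                curve = data.frame(cutpoint = s, sensitivity = 1,
                                   one_minus_specificity = 1)))
  }
  cand <- c(-Inf, (s[-1L] + s[-length(s)]) / 2, Inf)
  pos <- scores[labels]; neg <- scores[!labels]
  if (direction == "higher_is_positive") {
    sens <- vapply(cand, function(c) mean(pos > c), 0)
    spec <- vapply(cand, function(c) mean(neg <= c), 0)
  } else {
    sens <- vapply(cand, function(c) mean(pos < c), 0)
    spec <- vapply(cand, function(c) mean(neg >= c), 0)
  }
  j <- sens + spec - 1
  ## maximize J; ties -> higher sensitivity, then lower cutoff
  best <- order(-j, -sens, cand)[1L]
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best],
       curve = data.frame(cutpoint = cand, sensitivity = sens,
                          one_minus_specificity = 1 - spec))
}

#' Per-variable ROC analysis of a feature table
#'
#' For each variable in `kept`: the orientation is set from the group
#' means (case mean higher gives `higher_is_positive`), the empirical
#' AUC, Hanley-McNeil SE and asymptotic p are computed on the oriented
#' scores, the Bonferroni gate `p <= alpha/m` is applied, and the
#' Youden cut-point with its sensitivity/specificity is reported.
#' Results are sorted by AUC, descending. Missing cells are dropped per
#' variable with a message.
#'
#' @param ft feature table with a group column.
#' @param kept character vector of variables to analyze (e.g. the `kept`
#'   set of [prune_correlated()]); defaults to all temporal parameters
#'   present.
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons for the Bonferroni gate (default
#'   `length(kept)`).
#' @param group_col,positive group column and which level is the
#'   positive/case class (default: the level that is not the first).
#' @return An object of class `tsp_roc_batch`: a data frame with one row
#'   per variable (direction, auc, se, p_asymptotic,
#'   significant_after_bonferroni, youden cut-point columns), with the
#'   per-variable curves in `attr(, "curves")`.
#' @export
roc_batch <- function(ft, kept = intersect(tsp_names(), names(ft)),
                      alpha = 0.05, m = length(kept),
                      group_col = "group", positive = NULL) {
  ftd <- as.data.frame(ft)
  g <- factor(ftd[[group_col]])
  if (nlevels(g) != 2L) {
    stop_speechtsp(sprintf("ROC analysis needs exactly 2 groups, found %d",
                           nlevels(g)), "speechtsp_validation_error")
  }
  missing_vars <- setdiff(kept, names(ftd))
  if (length(missing_vars) > 0L) {
    stop_speechtsp(sprintf("variables not in table: %s",
                           paste(missing_vars, collapse = ", ")),
                   "speechtsp_validation_error")
  }
  positive <- positive %||% levels(g)[2L]
  gate <- bonferroni(alpha, m)
  curves <- list()
  rows <- lapply(kept, function(v) {
    pos <- ftd[[v]][g == positive]
    neg <- ftd[[v]][g != positive]
    n_dropped <- sum(is.na(pos)) + sum(is.na(neg))
    if (n_dropped > 0L) {
      message(sprintf("roc_batch: %s: dropping %d missing cell(s)",
                      v, n_dropped))
    }
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
    direction <- if (mean(pos) >= mean(neg)) "higher_is_positive"
    else "lower_is_positive"
    oriented_pos <- if (direction == "higher_is_positive") pos else -pos
    oriented_neg <- if (direction == "higher_is_positive") neg else -neg
    auc <- empirical_auc(oriented_pos, oriented_neg)
    se <- auc_se(auc, length(pos), length(neg))
    p <- auc_asymptotic_p(auc, se)
    yc <- youden_cutpoint(c(pos, neg),
                          rep(c(TRUE, FALSE), c(length(pos), length(neg))),
                          direction = direction)
    curves[[v]] <<- yc$curve
    data.frame(variable = v, direction = direction, auc = auc, se = se,
               p_asymptotic = p,
               significant_after_bonferroni = p <= as.numeric(gate),
               youden_cutoff = yc$cutoff, sensitivity = yc$sensitivity,
               specificity = yc$specificity, youden = yc$youden)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  attr(out, "threshold") <- as.numeric(gate)
  class(out) <- c("tsp_roc_batch", "data.frame")
  out
}

#' @export
print.tsp_roc_batch <- function(x, digits = 3, ...) {
  cat(sprintf(
    "ROC analysis of %d variables (Bonferroni gate p <= %.4f, m = %d)\n\n",
    nrow(x), attr(x, "threshold"), attr(x, "m")))
  df <- as.data.frame(x)[, c("variable", "direction", "auc", "se",
                             "p_asymptotic", "significant_after_bonferroni",
                             "youden_cutoff", "sensitivity", "specificity")]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) signif(col, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot empirical ROC curves
#'
#' One curve per analyzed variable, drawn from the stored curve
#' coordinates; the diagonal marks chance performance.
#'
#' @param x a [roc_batch()] result.
#' @param variables which variables to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.tsp_roc_batch <- function(x, variables = x$variable, ...) {
  curves <- attr(x, "curves")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "Empirical ROC curves", ...)
  cols <- grDevices::hcl.colors(max(length(variables), 2L), "Dark 3")
  for (i in seq_along(variables)) {
    cv <- curves[[variables[i]]]
    o <- order(cv$one_minus_specificity, cv$sensitivity)
    graphics::lines(cv$one_minus_specificity[o], cv$sensitivity[o],
                    col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", variables,
                                    x$auc[match(variables, x$variable)]),
                   col = cols[seq_along(variables)], lwd = 2, cex = 0.7,
                   bty = "n")
  invisible(x)
}
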
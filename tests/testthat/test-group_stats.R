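test_that("summaries use sample SD and respect missing values", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(c(s$n, s$mean, s$sd, s$median), c(3, 2, 1, 2))
  expect_equal(summarize_values(c(5, 5, 5, 5))$sd, 0)
  s2 <- summarize_values(c(1, NA, 2, 4))
  expect_equal(s2$n, 3L)
  expect_error(summarize_values(c(1, NA)), "2 non-missing")
})

test_that("pooled and Welch t from summaries match closed-form checks", {
  a <- group_summary(31, 9.647, 1.551)
  b <- group_summary(34, 7.877, 2.038)
  r <- pooled_t(a, b)
  expect_equal(r$df, 63)
  expect_equal(r$statistic, 3.9111, tolerance = 1e-4)
  expect_equal(r$p, 2 * pt(-abs(r$statistic), 63))

  w <- welch_t(group_summary(31, 1.512, 0.897),
               group_summary(34, 2.831, 1.695))
  expect_equal(w$statistic, -3.9687, tolerance = 1e-4)
  expect_equal(w$df, 51.084, tolerance = 1e-3)

  ## Welch df bounds and pooled-df reduction
  expect_equal(welch_t(group_summary(10, 1, 2),
                       group_summary(10, 0, 2))$df, 18)
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    w <- welch_t(group_summary(n1, rnorm(1), runif(1, 0.1, 3)),
                 group_summary(n2, rnorm(1), runif(1, 0.1, 3)))
    expect_gte(w$df, min(n1, n2) - 1)
    expect_lte(w$df, n1 + n2 - 2 + 1e-9)
  }

  expect_equal(pooled_t(group_summary(5, 1, 1),
                        group_summary(5, 1, 1))$statistic, 0)
  expect_error(pooled_t(group_summary(5, 1, 0), group_summary(5, 1, 0)),
               class = "speechtsp_degenerate_error")

  ## cross-check against t.test on raw data
  set.seed(77)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  r2 <- pooled_t(summarize_values(x), summarize_values(y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  w2 <- welch_t(summarize_values(x), summarize_values(y))
  wt <- t.test(x, y)
  expect_equal(w2$df, unname(wt$parameter), tolerance = 1e-10)
})

test_that("Cohen's d signs case-minus-control and ties to t", {
  a <- group_summary(31, 9.647, 1.551); b <- group_summary(34, 7.877, 2.038)
  expect_equal(cohens_d(a, b), -0.9712, tolerance = 1e-4)
  expect_equal(cohens_d(group_summary(31, 34.336, 9.568),
                        group_summary(34, 46.025, 12.984)),
               1.0178, tolerance = 1e-4)
  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(group_summary(4, 1, 0), group_summary(4, 1, 0)),
               class = "speechtsp_degenerate_error")
  ## |t| = |d| * sqrt(n1 n2 / N) for the pooled test
  r <- pooled_t(a, b)
  expect_equal(abs(r$statistic),
               abs(cohens_d(a, b)) * sqrt(31 * 34 / 65), tolerance = 1e-10)
})

test_that("test selection gates on normality then variance equality", {
  set.seed(42)
  picks <- replicate(50, {
    choose_test(rnorm(30), rnorm(30))
  })
  expect_gt(mean(picks == "pooled_t"), 0.7)

  ## strong variance inequality under normality -> Welch
  set.seed(43)
  picks_w <- replicate(50, choose_test(rnorm(40, sd = 1), rnorm(40, sd = 4)))
  expect_gt(mean(picks_w == "welch_t"), 0.7)

  ## heavy-tailed data fail the normality gate most of the time
  set.seed(44)
  picks_mw <- replicate(200, choose_test(rexp(30), rnorm(30)))
  expect_gte(mean(picks_mw == "mann_whitney_u"), 0.8)

  ## constants are degenerate: fall through to the rank test
  expect_equal(choose_test(rep(1, 10), rep(1, 10)), "mann_whitney_u")

  ## Lilliefors route works too
  expect_true(choose_test(rnorm(30), rnorm(30),
                          normality_method = "lilliefors") %in%
                c("pooled_t", "welch_t", "mann_whitney_u"))
})

test_that("Mann-Whitney U and z match hand computation and are antisymmetric", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$z, -4.5 / sqrt(3 * 3 * 7 / 12), tolerance = 1e-10)

  expect_equal(mann_whitney(c(1, 2), c(1, 2))$z, 0)
  expect_equal(mann_whitney(1, 2)$statistic, 0)

  set.seed(9)
  x <- rnorm(15); y <- rnorm(18, 0.8)
  expect_equal(mann_whitney(x, y)$z, -mann_whitney(y, x)$z,
               tolerance = 1e-12)

  ## U agrees with wilcox.test's W; tie-corrected z p matches the
  ## package's normal-approximation p without continuity correction
  xt <- c(x, x[1:3])  # introduce ties
  r2 <- mann_whitney(xt, y)
  wt <- suppressWarnings(wilcox.test(xt, y, exact = FALSE, correct = FALSE))
  expect_equal(r2$statistic, unname(wt$statistic))
  expect_equal(r2$p, wt$p.value, tolerance = 1e-10)
})

test_that("2x2 chi-square is Pearson without continuity correction", {
  r <- chi_square_2x2(matrix(c(7, 27, 11, 20), 2, byrow = TRUE))
  expect_equal(r$statistic, 1.7968, tolerance = 1e-4)
  expect_equal(r$df, 1L)
  ## proportional rows give 0; perfect association gives N
  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  ## permutation invariance
  m <- matrix(c(3, 9, 14, 5), 2)
  expect_equal(chi_square_2x2(m)$statistic,
               chi_square_2x2(m[2:1, 2:1])$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "speechtsp_degenerate_error")
})

test_that("Bonferroni thresholds divide alpha and report 4 decimals", {
  b <- bonferroni(0.05, 11)
  expect_equal(as.numeric(b), 0.05 / 11)
  expect_equal(attr(b, "rounded"), 0.0045)
  expect_equal(as.numeric(bonferroni(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni(0.05, 10)), 0.005)
  expect_error(bonferroni(0.05, 0))
})

test_that("correlation pruning is greedy in relevance order and order-invariant", {
  set.seed(12)
  n <- 40
  a <- rnorm(n)
  b <- a + rnorm(n, sd = 0.05)          # r(A,B) ~ 0.998
  c_ <- rnorm(n)
  ft <- data.frame(subject_id = as.character(1:n),
                   group = rep(c("g1", "g2"), n / 2),
                   A = a, B = b, C = c_)
  pr <- prune_correlated(ft, threshold = 0.9, relevance = c("A", "B", "C"),
                         variables = c("A", "B", "C"))
  expect_equal(pr$kept, c("A", "C"))
  expect_equal(pr$dropped$variable, "B")
  expect_equal(pr$dropped$proxy, "A")
  expect_gt(abs(pr$dropped$r), 0.9)

  ## all weakly correlated: everything kept
  ft2 <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  pr2 <- prune_correlated(ft2, variables = c("A", "B", "C"),
                          relevance = c("A", "B", "C"))
  expect_equal(pr2$kept, c("A", "B", "C"))

  ## chain case: r(A,B), r(B,C) above threshold, r(A,C) below ->
  ## greedy keeps {A, C}, drops B against A. Exact sample correlations
  ## built by rotating an orthonormal basis with a Cholesky factor.
  R <- matrix(c(1, 0.93, 0.75,
                0.93, 1, 0.93,
                0.75, 0.93, 1), 3, 3)
  m0 <- scale(matrix(rnorm(n * 3), n), center = TRUE, scale = FALSE)
  z <- qr.Q(qr(m0))   # orthonormal, zero-mean columns
  xyz <- z %*% chol(R)
  ft3 <- data.frame(A = xyz[, 1], B = xyz[, 2], C = xyz[, 3])
  expect_equal(cor(ft3$A, ft3$B), 0.93, tolerance = 1e-10)
  pr3 <- prune_correlated(ft3, relevance = c("A", "B", "C"),
                          variables = c("A", "B", "C"))
  expect_equal(pr3$kept, c("A", "C"))
  expect_equal(pr3$dropped$variable, "B")
  expect_equal(pr3$dropped$proxy, "A")

  ## column order of the input never changes the result
  pr4 <- prune_correlated(ft[, c("subject_id", "group", "C", "B", "A")],
                          threshold = 0.9, relevance = c("A", "B", "C"),
                          variables = c("C", "B", "A"))
  expect_equal(sort(pr4$kept), sort(pr$kept))
  expect_equal(pr4$dropped$variable, pr$dropped$variable)

  ## constant columns are set aside
  ft$K <- 1
  pr5 <- prune_correlated(ft, variables = c("A", "B", "C", "K"),
                          relevance = c("A", "B", "C"))
  expect_equal(pr5$constant, "K")
  expect_false("K" %in% c(pr5$kept, pr5$dropped$variable))
})

test_that("compare_all in summary mode reproduces the published table structure", {
  cmp <- compare_all(table3_summaries(), mode = "summary")
  expect_equal(nrow(cmp), 15L)
  expect_equal(sum(cmp$significant), 10L)
  st <- cmp[cmp$variable == "speech_tempo", ]
  expect_equal(st$test, "pooled_t")
  expect_equal(st$effect_class, "large")
  expect_equal(cmp$effect_class[cmp$variable == "total_pause_frequency"],
               "small")
  expect_false(cmp$significant[cmp$variable == "total_pause_frequency"])
  ## the pooled/Welch split matches the published degrees of freedom
  welch_vars <- cmp$variable[cmp$test == "welch_t"]
  expect_setequal(welch_vars, c(
    "filled_pause_occurrence_rate", "silent_pause_duration_rate",
    "filled_pause_duration_rate", "filled_pause_frequency",
    "total_pause_frequency", "silent_pause_average_duration",
    "total_pause_average_duration"))
})

test_that("compare_all raw mode handles identical groups and missing cells", {
  set.seed(66)
  coh <- simulate_cohort(cohort_spec(c(control = 15L, aud = 15L), seed = 6))
  ft <- coh$features
  cmp <- compare_all(ft, mode = "raw", group_col = "group")
  expect_equal(nrow(cmp), 15L)
  expect_true(all(cmp$test %in%
                    c("pooled_t", "welch_t", "mann_whitney_u")))

  ## identical "groups": nothing significant beyond alpha by construction
  ft2 <- ft
  ft2$group <- rep(c("x", "y"), 15)   # arbitrary relabel within cohort rows
  ## build truly identical groups: duplicate control block
  ctrl <- ft[ft$group == "control", ]
  dup <- ctrl; dup$group <- "fake"; dup$subject_id <- paste0(dup$subject_id, "b")
  cmp2 <- compare_all(rbind(ctrl, dup), mode = "raw")
  expect_equal(sum(cmp2$significant), 0L)

  expect_error(compare_all(ft[ft$group == "aud", ], mode = "raw"),
               "2 groups")
})
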
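test_that("binarize_response maps CR/PR to responder", {
  expect_true(all(binarize_response(c("CR", "PR"))))
  expect_false(any(binarize_response(c("SD", "PD"))))
  expect_error(binarize_response("XX"), "must be")
})

test_that("performance computes the triple with whole-percent reporting", {
  p <- performance(confusion_table(18, 0, 4, 17))
  expect_equal(p$accuracy, 90)
  expect_equal(p$sensitivity, 82)
  expect_equal(p$specificity, 100)
  expect_equal(p$sensitivity_transposed, 100)

  p2 <- performance(confusion_table(20, 0, 2, 17))
  expect_equal(unlist(p2[1:3]), c(accuracy = 95, sensitivity = 91,
                                  specificity = 100))

  perfect <- performance(confusion_table(10, 0, 0, 10))
  expect_equal(unlist(perfect[1:3]),
               c(accuracy = 100, sensitivity = 100, specificity = 100))

  raw <- performance(confusion_table(18, 0, 4, 17), round = FALSE)
  expect_equal(raw$sensitivity, 100 * 18 / 22)
  expect_error(performance(confusion_table(0, 3, 0, 4)), "sensitivity")
  expect_error(performance(confusion_table(3, 0, 4, 0)), "specificity")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(81.5), 82)
  expect_equal(round_half_away(-65.5), -66)
  expect_equal(round_half_away(23.53), 24)
  expect_equal(round_half_away(95.45), 95)
  expect_equal(round_half_away(3.14159, 2), 3.14)
})

test_that("table reconstruction enumerates and filters by marginals", {
  all_tables <- reconstruct_table(c(22, 17), c(18, 21))
  expect_length(all_tables, 18 - max(0, 18 - 17) + 1)
  for (tab in all_tables) {
    expect_equal(tab$tp + tab$fp, 18)
    expect_equal(tab$tp + tab$fn, 22)
    expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, 39)
  }
  expect_error(reconstruct_table(c(22, 17), c(18, 22)), "disagree")
})

test_that("the printed marginals pin unique confusion tables", {
  # 18/39 responders, a printed 100 % metric forces the zero cell
  t_recist <- reconstruct_table(c(22, 17), c(18, 21),
                                list(list(cell = "fp", value = 0)))
  expect_length(t_recist, 1)
  expect_equal(unlist(t_recist[[1]]), c(tp = 18, fp = 0, fn = 4, tn = 17))

  t_vol <- reconstruct_table(c(22, 17), c(20, 19),
                             list(list(cell = "fp", value = 0)))
  expect_length(t_vol, 1)
  expect_equal(unlist(t_vol[[1]]), c(tp = 20, fp = 0, fn = 2, tn = 17))

  # 34/5 responders: six feasible tables, the printed 24 % pins one
  feasible <- reconstruct_table(c(22, 17), c(34, 5))
  expect_length(feasible, 6)
  t_choi <- reconstruct_table(c(22, 17), c(34, 5),
                              list(list(metric = "specificity", value = 24)))
  expect_length(t_choi, 1)
  expect_equal(unlist(t_choi[[1]]), c(tp = 21, fp = 13, fn = 1, tn = 4))
  expect_equal(performance(t_choi[[1]])$accuracy, 64)
  # the printed accuracy alone pins the same table
  t_choi2 <- reconstruct_table(c(22, 17), c(34, 5),
                               list(list(metric = "accuracy", value = 64)))
  expect_length(t_choi2, 1)
  expect_equal(unlist(t_choi2[[1]]), unlist(t_choi[[1]]))

  # early-prediction subset: 14/30 responders with the forced zero cell
  t_early <- reconstruct_table(c(19, 11), c(14, 16),
                               list(list(cell = "fp", value = 0)))
  expect_length(t_early, 1)
  expect_equal(unlist(t_early[[1]]), c(tp = 14, fp = 0, fn = 5, tn = 11))
})

test_that("kappa matches a direct contingency oracle and its fixed points", {
  expect_equal(cohens_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)

  # 30/39 observed agreement with marginals of the published assessment
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(16, 6, 3, 14))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(16, 6, 3, 14))
  expect_equal(round_half_away(cohens_kappa(a, b), 2), 0.54)

  # oracle: kappa recomputed from raw cell counts, no factor machinery
  kappa_oracle <- function(x, y) {
    n <- length(x)
    po <- mean(x == y)
    pe <- (sum(x) * sum(y) + sum(!x) * sum(!y)) / n^2
    (po - pe) / (1 - pe)
  }
  set.seed(31)
  for (i in 1:25) {
    x <- runif(40) < runif(1, 0.2, 0.8)
    y <- ifelse(runif(40) < 0.7, x, runif(40) < 0.5)
    if (mean(x == y) == 1) next
    expect_equal(cohens_kappa(x, y), kappa_oracle(x, y), tolerance = 1e-10)
  }

  # independence with balanced marginals: near zero at large n
  set.seed(32)
  x <- runif(4000) < 0.5; y <- runif(4000) < 0.5
  expect_lt(abs(cohens_kappa(x, y)), 0.05)
  expect_error(cohens_kappa(c(TRUE, FALSE), TRUE), "length")
})

test_that("ICC(2,1) matches the aov mean-squares oracle", {
  icc_oracle <- function(a, b) {
    n <- length(a); k <- 2
    df <- data.frame(y = c(a, b),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(33)
  for (i in 1:10) {
    a <- rnorm(20, 100, 25)
    b <- a + rnorm(20, sd = 5) + runif(1, -4, 4)
    expect_equal(icc_absolute_agreement(a, b), icc_oracle(a, b),
                 tolerance = 1e-10)
  }

  a <- rnorm(15)
  expect_equal(icc_absolute_agreement(a, a), 1)
  # absolute agreement penalizes a systematic offset
  expect_lt(icc_absolute_agreement(a, a + 10), 0.2)
  expect_error(icc_absolute_agreement(rep(1, 5), rep(1, 5)), "constant")
  expect_error(icc_absolute_agreement(1:2, 1:2), "three")
})

test_that("Mann-Whitney exact mode equals the rank-split enumeration", {
  res <- mann_whitney_u(1:3, 4:6)
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")

  expect_equal(mann_whitney_u(5, 5)$p_value, 1)

  # independent route: wilcox.test exact p on tie-free data
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1), mean = runif(1, 0, 2))
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact p at moderate n", {
  set.seed(35)
  for (i in 1:20) {
    x <- rnorm(6, 0, 2); y <- rnorm(6, 1, 2)
    exact <- mann_whitney_u(x, y, exact_limit = 12)$p_value
    approx <- mann_whitney_u(x, y, exact_limit = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(confusion_table(3, 1, 1, 3)), 17 / 35)
  expect_equal(fisher_exact(confusion_table(0, 0, 4, 5)), 1)
  expect_equal(fisher_exact(confusion_table(5, 5, 5, 5)), 1)

  set.seed(36)
  for (i in 1:25) {
    cells <- rpois(4, 5)
    if (sum(cells) == 0) next
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(c(cells[1], cells[3], cells[2], cells[4]),
                                     2, 2))$p.value
    expect_equal(fisher_exact(tab), ref, tolerance = 1e-9)
    # invariant to transposing rows with columns
    swapped <- confusion_table(cells[1], cells[3], cells[2], cells[4])
    expect_equal(fisher_exact(swapped), fisher_exact(tab), tolerance = 1e-12)
    expect_gt(fisher_exact(tab), 0)
    expect_lte(fisher_exact(tab), 1)
  }
})

test_that("tabulate_response cross-tabulates predictions against labels", {
  resp <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  ben <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  tab <- tabulate_response(resp, ben)
  expect_equal(unlist(tab), c(tp = 2, fp = 1, fn = 1, tn = 1))
})
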
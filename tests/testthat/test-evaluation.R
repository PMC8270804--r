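test_that("ROC handles the canonical special cases", {
  lab <- rep(c("malignant", "benign"), each = 4)
  r <- roc_curve(c(4, 3, 5, 6, 1, 2, 0, 0.5), lab)
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(rep(0.3, 8), lab)
  expect_equal(r2$auc, 0.5)
  expect_error(roc_curve(1:4, rep("malignant", 4)), "both classes")
  # 6-point toy set with one inversion: hand count 8.5 of 9 pairs? no:
  # malignant {0.9, 0.8, 0.3}, benign {0.7, 0.2, 0.1}: concordant 8 of 9
  s <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  l <- rep(c("malignant", "benign"), each = 3)
  expect_equal(roc_curve(s, l)$auc, 8 / 9)
  expect_equal(roc_curve(s, l)$auc, oracle_auc_pairs(s, l))
})

test_that("trapezoid AUC equals exhaustive pair counting on random data", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    lab <- c("malignant", "benign",
             sample(c("malignant", "benign"), n - 2, replace = TRUE))
    s <- round(rnorm(n), sample(0:2, 1))   # coarse rounding induces ties
    expect_equal(roc_curve(s, lab)$auc, oracle_auc_pairs(s, lab),
                 tolerance = 1e-12)
  }
})

test_that("high-sensitivity cutoffs maximize specificity under the constraint", {
  s <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  l <- rep(c("malignant", "benign"), each = 3)
  th <- find_sensitivity_cutoff(s, l, 1.0)
  expect_equal(as.numeric(th), 0.2)
  expect_equal(attr(th, "sensitivity"), 1.0)
  expect_equal(attr(th, "specificity"), 2 / 3, tolerance = 1e-12)
  # exhaustive enumeration oracle
  cands <- c(-Inf, sort(unique(s)))
  sens <- sapply(cands, function(t) mean(s[l == "malignant"] > t))
  spec <- sapply(cands, function(t) mean(s[l == "benign"] <= t))
  best <- max(spec[sens >= 1])
  expect_equal(attr(th, "specificity"), best)
  # perfect separation -> specificity 1
  th2 <- find_sensitivity_cutoff(c(5, 6, 1, 2), c("malignant", "malignant",
                                                  "benign", "benign"), 1)
  expect_equal(attr(th2, "specificity"), 1.0)
  # relaxing the constraint can only raise specificity
  set.seed(23)
  for (i in 1:20) {
    sc <- rnorm(30)
    lb <- sample(c("malignant", "benign"), 30, replace = TRUE,
                 prob = c(0.6, 0.4))
    if (length(unique(lb)) < 2) next
    t100 <- find_sensitivity_cutoff(sc, lb, 1.0)
    t95 <- find_sensitivity_cutoff(sc, lb, 0.95)
    expect_gte(attr(t95, "specificity"), attr(t100, "specificity"))
  }
  expect_error(find_sensitivity_cutoff(s, l, 0), "min_sensitivity")
})

test_that("Clopper-Pearson intervals are exact and match binom.test", {
  expect_equal(unname(clopper_pearson(0, 20)[1]), 0)
  expect_equal(unname(clopper_pearson(20, 20)[2]), 1)
  expect_equal(unname(clopper_pearson(88, 88)[1]), 0.025^(1 / 88),
               tolerance = 1e-12)
  for (x in c(0, 3, 10, 69)) {
    ci <- clopper_pearson(x, 69)
    bt <- binom.test(x, 69)$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-9)
  }
  expect_equal(round(100 * clopper_pearson(10, 69), 1),
               c(lower = 7.2, upper = 25.0))
  expect_error(clopper_pearson(5, 3), "invalid")
})

test_that("Clopper-Pearson coverage is at least nominal minus slack", {
  set.seed(77)
  x <- rbinom(2000, 200, 0.3)
  cover <- vapply(x, function(xi) {
    ci <- clopper_pearson(xi, 200)
    ci[1] <= 0.3 && 0.3 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.94)
})

test_that("contingency metrics reproduce the benchmark table rows", {
  c1 <- contingency_metrics(tp = 88, fp = 59, tn = 10, fn = 0)
  expect_equal(100 * c1$sensitivity, 100)
  expect_equal(round(100 * c1$specificity, 1), 14.5)
  expect_equal(100 * c1$ppv, 88 / 147 * 100, tolerance = 1e-12)
  expect_equal(100 * c1$npv, 100)
  expect_equal(round(100 * c1$accuracy, 1), 62.4)
  expect_equal(round(c1$plr, 1), 1.2)
  expect_equal(c1$nlr, 0)
  expect_equal(c1$avoidable_biopsy_fraction, c1$specificity)
  c2 <- contingency_metrics(tp = 84, fp = 44, tn = 25, fn = 4)
  expect_equal(round(100 * c2$sensitivity, 1), 95.5)
  expect_equal(round(100 * c2$specificity, 1), 36.2)
  expect_equal(round(100 * c2$ppv, 1), 65.6)
  expect_equal(round(100 * c2$npv, 1), 86.2)
  expect_equal(round(100 * c2$accuracy, 1), 69.4)
  expect_equal(round(c2$plr, 1), 1.5)
  expect_equal(round(c2$nlr, 1), 0.1)
  # degenerate all-correct table
  all1 <- contingency_metrics(1, 0, 1, 0)
  expect_equal(all1$sensitivity, 1); expect_equal(all1$specificity, 1)
  expect_false(all1$plr_defined)
  expect_true(is.infinite(all1$plr))
  expect_error(contingency_metrics(-1, 0, 1, 0), "nonnegative")
})

test_that("the Wilson option reproduces the training-row intervals", {
  w1 <- contingency_metrics(207, 96, 10, 0, ci_method = "wilson")
  expect_equal(round(100 * w1$specificity_ci, 1),
               c(lower = 5.2, upper = 16.5))
  w2 <- contingency_metrics(197, 61, 45, 10, ci_method = "wilson")
  expect_equal(round(100 * w2$specificity_ci, 1),
               c(lower = 33.5, upper = 52.0))
})

test_that("cutoff evaluation is monotone and audits false negatives", {
  set.seed(55)
  s <- runif(60)
  l <- sample(c("malignant", "benign"), 60, replace = TRUE)
  ids <- sprintf("L%02d", 1:60)
  reps <- evaluate_cutoffs(s, l, c(C1 = 0.2, C2 = 0.5), ids)
  expect_named(reps, c("C1", "C2"))
  expect_gte(reps$C2$counts["fn"], reps$C1$counts["fn"])
  expect_gte(reps$C2$counts["tn"], reps$C1$counts["tn"])
  expect_identical(reps$C2$false_negative_ids,
                   ids[s <= 0.5 & l == "malignant"])
  expect_error(evaluate_cutoffs(s, l, NULL), "thresholds")
  # all-benign test set: rates reported as not applicable, no error
  rb <- evaluate_cutoffs(runif(5), rep("benign", 5), c(C1 = 0.5))
  expect_true(is.na(rb$C1$sensitivity))
})

test_that("the benchmark table recomputes from raw counts at one decimal", {
  tab <- reproduce_reference_metrics()
  expect_equal(tab$sensitivity, c(100, 95.2, 100, 95.5))
  expect_equal(tab$specificity, c(9.4, 42.5, 14.5, 36.2))
  expect_equal(tab$avoidable_biopsy_pct, tab$specificity)
  test_rows <- tab[tab$split == "test", ]
  expect_equal(test_rows$ppv, c(59.9, 65.6))
  expect_equal(test_rows$npv, c(100, 86.2))
  expect_equal(test_rows$accuracy, c(62.4, 69.4))
})
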
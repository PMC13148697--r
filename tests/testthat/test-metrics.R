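test_that("auroc matches spec examples and handles ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "one class")
})

test_that("auprc matches spec examples", {
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 1, 0)), 1.0)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(0, 1, 1)), 7 / 12)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "no positives")
})

test_that("auprc of uninformative scores approximates prevalence", {
  set.seed(42)
  n <- 5000
  prev <- 0.3
  labels <- rbinom(n, 1, prev)
  scores <- runif(n)
  expect_lt(abs(auprc(scores, labels) - mean(labels)), 0.03)
})

test_that("rank-based metrics match brute-force oracles to 1e-12", {
  set.seed(101)
  for (i in 1:120) {
    inst <- random_binary_instance()
    expect_equal(auroc(inst$scores, inst$labels),
                 bf_auroc(inst$scores, inst$labels), tolerance = 1e-12)
    if (any(inst$labels == 1)) {
      expect_equal(auprc(inst$scores, inst$labels),
                   bf_auprc(inst$scores, inst$labels), tolerance = 1e-12)
    }
  }
})

test_that("balanced accuracy matches examples and oracle", {
  expect_equal(balanced_accuracy(diag(c(5, 3, 2))), 1.0)
  expect_equal(balanced_accuracy(matrix(c(8, 2, 5, 5), 2, byrow = TRUE)), 0.65)
  # one-class predictor over 3 balanced classes
  cm <- matrix(0, 3, 3)
  cm[, 1] <- 10
  expect_equal(balanced_accuracy(cm), 1 / 3)
  expect_error(balanced_accuracy(matrix(0, 2, 2)), "empty")
  set.seed(7)
  for (i in 1:40) {
    true <- sample(0:3, 30, replace = TRUE)
    pred <- sample(0:3, 30, replace = TRUE)
    cm <- confusion_matrix(true, pred, 4)
    expect_equal(suppressWarnings(balanced_accuracy(cm)),
                 bf_balacc(true, pred, 4), tolerance = 1e-12)
  }
})

test_that("macro/micro AUROC match examples and oracle", {
  # perfect probabilistic classifier
  labels <- c(0, 1, 2, 0, 1, 2)
  probs <- diag(3)[labels + 1, ]
  mm <- macro_micro_auroc(probs, labels)
  expect_equal(mm$macro, 1.0)
  expect_equal(mm$micro, 1.0)
  # uniform probabilities -> micro 0.5
  mm_u <- macro_micro_auroc(matrix(1 / 3, 6, 3), labels)
  expect_equal(mm_u$micro, 0.5)
  set.seed(11)
  for (i in 1:30) {
    labels <- sample(0:2, 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    probs <- matrix(runif(36), 12, 3)
    probs <- probs / rowSums(probs)
    got <- suppressWarnings(macro_micro_auroc(probs, labels))
    want <- bf_macro_micro(probs, labels)
    expect_equal(got$macro, want$macro, tolerance = 1e-12)
    expect_equal(got$micro, want$micro, tolerance = 1e-12)
  }
  expect_error(macro_micro_auroc(matrix(1, 3, 2), c(1, 1, 1)), "fewer than 2")
})

test_that("youden threshold matches exhaustive search and spec examples", {
  # perfect separation: smallest positive-class score, J = 1
  s <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  th <- youden_threshold(s, y)
  expect_equal(th, 0.8)
  ss <- sens_spec_at_threshold(s, y, th)
  expect_equal(ss$sensitivity + ss$specificity - 1, 1)
  expect_equal(youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.35)
  set.seed(19)
  for (i in 1:100) {
    inst <- random_binary_instance()
    got <- youden_threshold(inst$scores, inst$labels)
    want <- bf_youden(inst$scores, inst$labels)
    expect_equal(got, want$threshold)
    # self-consistency: the threshold achieves the maximal validation J
    ss <- sens_spec_at_threshold(inst$scores, inst$labels, got)
    expect_equal(ss$sensitivity + ss$specificity - 1, want$j,
                 tolerance = 1e-12)
  }
})

test_that("youden J is near zero under the null", {
  set.seed(23)
  s <- runif(4000)
  y <- rbinom(4000, 1, 0.5)
  th <- youden_threshold(s, y)
  ss <- sens_spec_at_threshold(s, y, th)
  expect_lt(ss$sensitivity + ss$specificity - 1, 0.1)
})

test_that("sens/spec at threshold match direct counts", {
  expect_equal(sens_spec_at_threshold(c(0.2, 0.6, 0.7, 0.9), c(0, 0, 1, 1), 0.65),
               list(sensitivity = 1.0, specificity = 1.0))
  lo <- sens_spec_at_threshold(c(0.2, 0.6), c(0, 1), 0.1)
  expect_equal(lo, list(sensitivity = 1, specificity = 0))
  hi <- sens_spec_at_threshold(c(0.2, 0.6), c(0, 1), 0.95)
  expect_equal(hi, list(sensitivity = 0, specificity = 1))
})

test_that("ensembling averages probabilities and is permutation invariant", {
  mk <- function(sc) data.frame(scan_id = c("a", "b"), fold_index = 1:2,
                                prognosis_score = sc, grade_prob_0 = sc / 2)
  sets <- lapply(list(c(0.2, 1), c(0.4, 1), c(0.6, 1), c(0.8, 1), c(1.0, 1)),
                 mk)
  ens <- ensemble_predictions(sets)
  expect_equal(ens$prognosis_score[ens$scan_id == "a"], 0.6)
  ens_perm <- ensemble_predictions(rev(sets))
  expect_equal(ens, ens_perm)
  ident <- ensemble_predictions(list(sets[[1]], sets[[1]]))
  expect_equal(ident$prognosis_score, sets[[1]]$prognosis_score)
  expect_error(ensemble_predictions(list()), "no prediction")
})

test_that("delong test: identical curves, antisymmetry, sane p-values", {
  set.seed(31)
  s <- runif(40)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  expect_warning(res <- delong_test(s, s, y), "zero variance")
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  s2 <- runif(40)
  a <- delong_test(s, s2, y)
  b <- delong_test(s2, s, y)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_true(a$p > 0 && a$p <= 1)
  expect_equal(a$n, 40)
})

test_that("subgroup report covers the pooled-exceeds-both construction", {
  one <- subgroup_report(c(0.4, 0.6, 0.2), c(0, 1, 0), rep("all", 3))
  expect_equal(one$auroc, auroc(c(0.4, 0.6, 0.2), c(0, 1, 0)))
  # a single-class subgroup is skipped with a warning
  expect_warning(
    r <- subgroup_report(c(0.1, 0.2, 0.9, 0.8), c(0, 0, 1, 0),
                         c("x", "x", "y", "y")),
    "single outcome class")
  expect_false("x" %in% r$subgroup)
  # pooled AUROC can exceed both within-subgroup AUROCs
  scores <- c(0.2, 0.15, 0.1, 0.9, 0.85, 0.8)
  labels <- c(0, 1, 0, 1, 0, 1)
  groups <- c("A", "A", "A", "B", "B", "B")
  r <- subgroup_report(scores, labels, groups)
  pooled <- auroc(scores, labels)
  expect_true(all(pooled > r$auroc))
})

test_that("forgetting report exposes deltas and rare-class recall", {
  set.seed(5)
  labels <- c(rep(0L, 6), rep(1L, 6), rep(2L, 2))
  perfect <- diag(3)[labels + 1, ] * 0.9 + 0.05
  ref <- forgetting_report(list(), perfect, labels)
  expect_equal(ref$reference$delta, 0)
  # majority-class predictor: zero recall on the rare class
  majority <- matrix(rep(c(0.8, 0.15, 0.05), length(labels)),
                     ncol = 3, byrow = TRUE)
  rep2 <- forgetting_report(list(maj = majority), perfect, labels)
  expect_equal(unname(rep2$maj$per_class_recall[3]), 0)
  expect_lt(rep2$maj$delta, 0)
})
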
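test_that("score_pairs joins scores with labels and reports dropped pairs", {
  pm <- random_profile_matrix(6, 10, seed = 1)
  sm <- similarity_matrix(pm, "dcor")
  gs <- structure(list(
    positives = data.frame(id1 = c("p001", "p002"), id2 = c("p002", "p003")),
    negatives = data.frame(id1 = c("p004", "p001"), id2 = c("p005", "ghost")),
    flavor = "fun", min_dist = 5, provenance = ""
  ), class = "gold_standard")
  expect_message(sp <- score_pairs(sm, gs), "dropped 0 TP and 1 TN")
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$score[1], sm["p001", "p002"])
  expect_equal(attr(sp, "dropped"), c(TP = 0L, TN = 1L))
  gs$positives <- data.frame(id1 = "nope", id2 = "ghost")
  gs$negatives <- gs$positives
  expect_error(suppressMessages(score_pairs(sm, gs)), "no gold-standard pair")
})

test_that("binned ROC handles perfect, degenerate and mixed separations", {
  perfect <- make_scored(c(0.95, 0.95, 0.05, 0.05),
                         c("TP", "TP", "TN", "TN"))
  roc <- binned_roc(perfect)
  expect_equal(roc$points, data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))
  expect_equal(roc$auc, 1.0)
  # all scores identical -> only the two endpoints
  flat <- make_scored(rep(0.45, 6), rep(c("TP", "TN"), 3))
  roc2 <- binned_roc(flat)
  expect_equal(roc2$points, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  expect_equal(roc2$auc, 0.5)
  expect_error(binned_roc(make_scored(c(0.1, 0.2), c("TP", "TP"))),
               "each class")
})

test_that("the printed toy scores match the rank-statistic oracle", {
  sp <- make_scored(c(0.85, 0.55, 0.15, 0.65, 0.25, 0.05),
                    c("TP", "TP", "TP", "TN", "TN", "TN"))
  roc <- binned_roc(sp)
  expect_equal(roc$auc, oracle_rank_auc(c(0.85, 0.55, 0.15),
                                        c(0.65, 0.25, 0.05)))
  expect_equal(roc$auc, 2 / 3)
  # pROC as an independent library oracle on the same six scores
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = c(1, 1, 1, 0, 0, 0),
    predictor = c(0.85, 0.55, 0.15, 0.65, 0.25, 0.05),
    quiet = TRUE, direction = "<"
  )))
  expect_equal(exact_roc(sp)$auc, proc_auc, tolerance = 1e-12)
})

test_that("trapezoid AUC matches reference integration and flags disorder", {
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1)
  expect_equal(auc_trapezoid(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  for (s in 1:10) {
    set.seed(s)
    x <- c(0, sort(runif(8)), 1)
    y <- c(0, sort(runif(8)), 1)
    expect_equal(auc_trapezoid(data.frame(fpr = x, tpr = y)),
                 oracle_trapz(x, y), tolerance = 1e-12)
  }
  expect_error(auc_trapezoid(data.frame(fpr = c(0.4, 0.2), tpr = c(0, 1))),
               "ordered")
})

test_that("the exact step ROC equals the normalized Mann-Whitney statistic", {
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    label <- rep(c("TP", "TN"), each = n / 2)
    score <- runif(n)
    if (s %% 2 == 0) score <- round(score, 1)  # exercise ties
    sp <- make_scored(score, label)
    expect_equal(exact_roc(sp)$auc,
                 oracle_rank_auc(score[label == "TP"], score[label == "TN"]),
                 tolerance = 1e-12)
  }
})

test_that("binned AUC approaches the exact AUC for moderately large samples", {
  set.seed(42)
  n <- 300
  label <- rep(c("TP", "TN"), each = n / 2)
  score <- pmin(pmax(ifelse(label == "TP", rnorm(n, 0.6, 0.2),
                            rnorm(n, 0.4, 0.2)), 0), 1)
  sp <- make_scored(score, label)
  expect_lt(abs(binned_roc(sp)$auc - exact_roc(sp)$auc), 0.05)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(7)
  score <- runif(60)
  label <- sample(rep(c("TP", "TN"), 30))
  base <- exact_roc(make_scored(score, label))$auc
  for (f in list(function(s) s^3, function(s) exp(2 * s), function(s) 5 * s - 1)) {
    expect_equal(exact_roc(make_scored(f(score), label))$auc, base,
                 tolerance = 1e-12)
  }
})

test_that("Pearson scores sweep the full [-1, 1] range", {
  sp <- make_scored(c(-0.85, 0.9, -0.2, 0.3), c("TN", "TP", "TN", "TP"),
                    metric = "pc")
  roc <- binned_roc(sp)
  expect_equal(range(roc$thresholds), c(-1, 1))
  expect_equal(roc$auc, 1)
  # mutual information range extends to cover the maximum score
  spmi <- make_scored(c(1.37, 0.4, 0.05), c("TP", "TN", "TN"), metric = "mi")
  expect_equal(max(binned_roc(spmi)$thresholds), 1.4)
})

test_that("ten-fold cross-validation is seeded, near-equal and reproducible", {
  set.seed(10)
  score <- runif(100)
  label <- sample(rep(c("TP", "TN"), 50))
  sp <- make_scored(score, label)
  cv <- ten_fold_cv(sp, seed = 5)
  expect_equal(tabulate(cv$folds, 10), rep(10L, 10))
  expect_identical(ten_fold_cv(sp, seed = 5)$fold_auc, cv$fold_auc)
  expect_false(identical(ten_fold_cv(sp, seed = 6)$folds, cv$folds))
  # perfectly separating scores -> every fold AUC is 1
  sep <- make_scored(c(runif(50, 0.8, 0.9), runif(50, 0.1, 0.2)),
                     rep(c("TP", "TN"), each = 50))
  expect_equal(ten_fold_cv(sep, seed = 1)$fold_auc, rep(1, 10))
  expect_error(ten_fold_cv(sp), "seed")
  expect_error(ten_fold_cv(make_scored(runif(12), rep(c("TP", "TN"), 6)),
                           seed = 1), "at least")
})

test_that("severely imbalanced classes trigger the stratified fallback", {
  set.seed(3)
  label <- c(rep("TP", 10), rep("TN", 490))
  sp <- make_scored(c(runif(10, 0.5, 1), runif(490, 0, 0.6)), label)
  cv <- ten_fold_cv(sp, seed = 2, max_retries = 2)
  expect_true(cv$stratified)
  expect_true(all(vapply(1:10, function(f) {
    any(sp$label[cv$folds == f] == "TP")
  }, logical(1))))
})

test_that("metric comparison requires identical folds and reports differences", {
  set.seed(8)
  label <- sample(rep(c("TP", "TN"), 40))
  s1 <- make_scored(runif(80), label, metric = "dcor")
  s2 <- make_scored(runif(80), label, metric = "pc")
  r1 <- ten_fold_cv(s1, seed = 4)
  r2 <- ten_fold_cv(s2, seed = 4)
  cmpn <- compare_metrics(list(r1, r2))
  expect_equal(dim(cmpn$fold_auc), c(10L, 2L))
  expect_equal(colnames(cmpn$fold_auc), c("dcor", "pc"))
  expect_equal(cmpn$differences[, 1], r1$fold_auc - r2$fold_auc,
               ignore_attr = TRUE)
  expect_equal(cmpn$boxstats["median", "dcor"], stats::median(r1$fold_auc))
  expect_error(compare_metrics(list(r1)), "at least two")
  r3 <- ten_fold_cv(s2, seed = 99)
  expect_error(compare_metrics(list(r1, r3)), "identical folds")
})
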
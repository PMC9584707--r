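# linearly separable two-cluster toy set: clusters 10 SDs apart
toy_set <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    label = rep(c("low", "high"), each = n_per_class),
    s_1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, 10)),
    s_2 = c(rnorm(n_per_class, 0), rnorm(n_per_class, -10))
  ))
}

test_that("confusion-count metrics match hand-computed values exactly", {
  m <- classification_metrics(5, 0, 5, 0)
  expect_equal(unlist(m[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 100, recall = 100, f1 = 100, accuracy = 100))

  m2 <- classification_metrics(3, 1, 4, 2)
  expect_equal(m2$precision, 75)
  expect_equal(m2$recall, 60)
  expect_equal(m2$f1, 100 * 2 * 3 / (2 * 3 + 1 + 2))
  expect_equal(m2$accuracy, 70)
  expect_false(m2$degenerate)

  expect_error(classification_metrics(-1, 0, 1, 0), "non-negative")
  expect_error(classification_metrics(0, 0, 0, 0), "total count")
})

test_that("degenerate denominators report 0 with a warning flag", {
  expect_warning(m <- classification_metrics(0, 0, 4, 1), "precision undefined")
  expect_equal(m$precision, 0)
  expect_true(m$degenerate)
})

test_that("F1 equals the harmonic mean of precision and recall when defined", {
  withr::with_seed(8, {
    for (i in 1:25) {
      counts <- as.list(rpois(4, 5) + c(1, 0, 0, 1))  # tp,fn >= 1 keeps all defined
      m <- do.call(classification_metrics, stats::setNames(counts, c("tp", "fp", "tn", "fn")))
      hm <- 2 * m$precision * m$recall / (m$precision + m$recall)
      expect_equal(m$f1, hm, tolerance = 1e-12)
    }
  })
})

test_that("training separates a 10-SD two-cluster toy set and is seeded", {
  toy <- toy_set()
  spec <- mlp_spec(hidden = c(8), epochs = 200, seed = 3)
  fit <- fit_mlp(toy, spec)
  expect_s3_class(fit, "mmdisten_mlp")
  pred <- predict(fit, toy, type = "prob")
  expect_equal(mean((pred > 0.5) == (toy$label == "high")), 1)  # 100% training accuracy

  fit2 <- fit_mlp(toy, spec)
  expect_identical(fit$W, fit2$W)          # seeded determinism: identical weights

  one_class <- toy[toy$label == "low", ]
  expect_error(fit_mlp(one_class, spec), "single class")
})

test_that("stratified cross-validation partitions trials and hits 100% on separable data", {
  toy <- toy_set(25, seed = 2)
  spec <- mlp_spec(hidden = c(8), epochs = 150, seed = 4)
  rep <- cross_validate(toy, spec, k = 5)
  expect_equal(nrow(rep$folds), 5)
  expect_equal(sum(rep$folds$n_test), nrow(toy))          # folds partition the data
  expect_equal(rep$folds$tp + rep$folds$fp + rep$folds$tn + rep$folds$fn,
               rep$folds$n_test)
  expect_equal(glance(rep)$accuracy_mean, 100)
  expect_equal(glance(rep)$accuracy_sd, 0)

  expect_error(cross_validate(toy_set(4), spec, k = 10), "smaller k")
})

test_that("label swap leaves accuracy unchanged and swaps the complementary metrics", {
  # metrics level: relabelling the positive class maps (tp,fp,tn,fn) -> (tn,fn,tp,fp)
  m <- classification_metrics(3, 1, 4, 2)
  msw <- classification_metrics(4, 2, 3, 1)
  expect_equal(m$accuracy, msw$accuracy)
  expect_equal(msw$precision, 100 * 4 / (4 + 2))   # NPV of the original view
  expect_equal(msw$recall, 100 * 4 / (4 + 1))      # specificity of the original view

  # one fixed classifier, both confusion views of the same predictions
  toy <- toy_set(20, seed = 5)
  fit <- fit_mlp(toy, mlp_spec(hidden = c(8), epochs = 150, seed = 6))
  pred_hi <- predict(fit, toy, type = "prob") > 0.5
  truth_hi <- toy$label == "high"
  hi <- classification_metrics(sum(pred_hi & truth_hi), sum(pred_hi & !truth_hi),
                               sum(!pred_hi & !truth_hi), sum(!pred_hi & truth_hi))
  lo <- classification_metrics(hi$tn, hi$fn, hi$tp, hi$fp)
  expect_equal(hi$accuracy, lo$accuracy)
})

test_that("tidy and glance expose fold-level and summary views", {
  toy <- toy_set(15, seed = 9)
  rep <- cross_validate(toy, mlp_spec(hidden = 4, epochs = 100, seed = 1), k = 3)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("accuracy_mean", "accuracy_sd", "f1_mean", "k") %in% names(gl)))

  fit <- fit_mlp(toy, mlp_spec(hidden = 4, epochs = 50, seed = 1))
  expect_equal(nrow(tidy(fit)), glance(fit)$epochs_run)
})
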
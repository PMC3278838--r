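test_that("confusion counts are conserved and oriented correctly", {
  expect_equal(unlist(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  expect_equal(unlist(confusion_counts(c(1, 1, 0, 0), c(0, 0, 1, 1))),
               c(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  withr::with_seed(3, {
    y <- rbinom(50, 1, 0.4); p <- rbinom(50, 1, 0.5)
  })
  expect_equal(sum(unlist(confusion_counts(y, p))), 50)
  expect_error(confusion_counts(c(1, 0), 1), "length")
  expect_error(confusion_counts(c(1, 2), c(0, 1)), "binary")
})

test_that("metrics match their defining formulas", {
  perfect <- classification_metrics(confusion_counts(c(1, 0), c(1, 0)))
  expect_equal(unlist(perfect),
               c(sensitivity = 1, specificity = 1, bacc = 1, mcc = 1))
  m <- classification_metrics(tibble::tibble(tp = 8, fn = 2, tn = 8,
                                             fp = 2))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$bacc, 0.8)
  expect_equal(m$mcc, 0.6)  # (64 - 4) / sqrt(10^4)
  # zero-denominator convention and NA sentinels
  expect_equal(classification_metrics(
    tibble::tibble(tp = 3, fn = 0, tn = 0, fp = 2))$mcc, 0)
  no_pos <- classification_metrics(
    tibble::tibble(tp = 0, fn = 0, tn = 4, fp = 1))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$bacc))
})

test_that("MCC flips sign under prediction inversion", {
  withr::with_seed(11, {
    for (i in 1:20) {
      y <- c(1L, 0L, rbinom(30, 1, 0.5))
      p <- c(rbinom(16, 1, 0.7 * y[1:16] + 0.1), rbinom(16, 1, 0.5))
      m1 <- classification_metrics(confusion_counts(y, p))
      m2 <- classification_metrics(confusion_counts(y, 1L - p))
      expect_equal(m1$mcc, -m2$mcc, tolerance = 1e-12)
      expect_equal(m1$bacc, (m1$sensitivity + m1$specificity) / 2)
    }
  })
})

test_that("ROC curves run (0,0) to (1,1) and collapse ties", {
  y <- c(1, 1, 0, 0)
  curve <- roc_points(c(0.9, 0.8, 0.2, 0.1), y)
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1)) # perfect separation
  # total tie: exactly (0,0) and (1,1)
  flat <- roc_points(rep(0.5, 4), y)
  expect_equal(nrow(flat), 2)
  expect_equal(flat$fpr, c(0, 1)); expect_equal(flat$tpr, c(0, 1))
  # point count bounded by distinct scores + 1; monotone coordinates
  withr::with_seed(4, s <- round(runif(40), 1))
  curve2 <- roc_points(s, rep(c(1, 0), 20))
  expect_lte(nrow(curve2), length(unique(s)) + 1)
  expect_true(all(diff(curve2$fpr) >= 0))
  expect_true(all(diff(curve2$tpr) >= 0))
  expect_error(roc_points(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 4), c(1, 1, 0, 0)), 0.5)
  withr::with_seed(21, {
    for (i in 1:10) {
      y <- rep(c(1L, 0L), each = 100)
      s <- rnorm(200, mean = 0.4 * y)
      if (i %% 2 == 0) s <- round(s, 1)  # force ties
      expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-9)
    }
  })
})

test_that("AUC complements under score negation without ties", {
  withr::with_seed(31, {
    y <- rep(c(1L, 0L), each = 30)
    s <- runif(60)
  })
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    y <- rep(c(1L, 0L), each = 75)
    s <- rnorm(150, mean = 0.8 * y)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-9)
})

test_that("quadrant classification follows the (0.5, 0.5) split", {
  expect_equal(roc_quadrant(fpr = 0.198, tpr = 0.823), "II")
  expect_equal(roc_quadrant(fpr = 0.11, tpr = 0.32), "III")
  expect_equal(roc_quadrant(fpr = 0.6, tpr = 0.9), "I")
  expect_equal(roc_quadrant(fpr = 0.7, tpr = 0.2), "IV")
  # boundary convention: diagonal centre point goes to IV
  expect_equal(roc_quadrant(fpr = 0.5, tpr = 0.5), "IV")
  expect_equal(roc_quadrant(fpr = 0.5, tpr = 0.9), "I")
  expect_equal(roc_quadrant(fpr = 0.2, tpr = 0.5), "III")
  expect_error(roc_quadrant(1.2, 0.5), "0, 1")
})

test_that("evaluation reports bundle counts, metrics, ROC and quadrant", {
  withr::with_seed(51, {
    d <- tibble::tibble(label = rep(c(1L, 0L), each = 50))
    d$score <- rnorm(100, mean = 1.5 * d$label, sd = 0.7)
  })
  rep_ <- evaluate_predictions(d)
  g <- glance(rep_)
  expect_equal(g$tp + g$fn, 50)
  expect_equal(g$bacc, (g$sensitivity + g$specificity) / 2)
  expect_equal(g$quadrant, "II")
  expect_equal(rep_$auc, oracle_auc(d$score, d$label), tolerance = 1e-9)
  expect_equal(tidy(rep_), rep_$roc)
  # JSON and CSV outputs
  tmp <- withr::local_tempfile(fileext = ".json")
  write_evaluation(rep_, tmp)
  parsed <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(parsed$metrics$mcc, g$mcc, tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_roc_csv(rep_, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(rep_$roc))
})

test_that("plot methods return ggplot objects", {
  withr::with_seed(61, {
    d <- tibble::tibble(label = rep(c(1L, 0L), each = 20))
    d$score <- runif(40) + 0.3 * d$label
  })
  rep_ <- evaluate_predictions(d)
  expect_s3_class(ggplot2::autoplot(rep_), "ggplot")
  pts <- tibble::tibble(fpr = c(0.198, 0.11), tpr = c(0.823, 0.32),
                        method = c("PM3", "FoldAmyloid"))
  expect_s3_class(plot_quadrants(pts), "ggplot")
})
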
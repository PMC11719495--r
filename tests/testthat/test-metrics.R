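test_that("scores reproduce the published confusion-count examples", {
  # 150x210 / Adam / 0.0002 test counts
  r <- score(confusion_matrix(tp = 1054, fp = 40, fn = 64, tn = 1435))
  expect_equal(round(unlist(r), 4),
               c(accuracy = 0.9599, sensitivity = 0.9428, specificity = 0.9729,
                 precision = 0.9634, f1 = 0.9530))
  # 100x140 / Adam / 0.0002 accuracy
  r2 <- score(confusion_matrix(tp = 1051, fp = 50, fn = 62, tn = 1430))
  expect_equal(round(100 * r2$accuracy, 2), 95.68)
  # 50x70 sensitivity from its epilepsy-row counts
  r3 <- score(confusion_matrix(tp = 766, fp = 146, fn = 336, tn = 1325))
  expect_equal(round(100 * r3$sensitivity, 2), 69.51)
})

test_that("a perfect classifier scores 1 everywhere", {
  r <- score(confusion_matrix(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(unlist(r) == 1))
})

test_that("confusion counts match a brute-force pairwise tally", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    cm <- confusion(yt, yp)
    brute <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in seq_len(n)) {
      key <- if (yt[i] == 1 && yp[i] == 1) "tp" else if (yt[i] == 0 && yp[i] == 1) "fp"
             else if (yt[i] == 1 && yp[i] == 0) "fn" else "tn"
      brute[key] <- brute[key] + 1
    }
    expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), brute)
  }
  # label-coded vectors count identically, epilepsy = positive
  cm <- confusion(c("epilepsy", "normal"), c("epilepsy", "normal"))
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(1, 1, 0, 0))
  cm2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(c(cm2$fp, cm2$fn), c(1, 1))
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "lengths differ")
})

test_that("zero denominators report 0 with a warning instead of crashing", {
  cm <- confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 10)
  w <- capture_warnings(r <- score(cm))
  expect_match(w, "sensitivity", all = FALSE)
  expect_match(w, "precision", all = FALSE)
  expect_equal(r$sensitivity, 0)
  expect_equal(r$precision, 0)
  expect_equal(r$f1, 0) # precision + sensitivity = 0 convention
  expect_error(score(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("algebraic identities among the five scores hold on random counts", {
  set.seed(77)
  for (rep in 1:25) {
    counts <- sample(1:500, 4)
    cm <- confusion_matrix(counts[1], counts[2], counts[3], counts[4])
    r <- score(cm)
    pos <- cm$tp + cm$fn
    neg <- cm$tn + cm$fp
    # accuracy is the prevalence-weighted mix of sensitivity and specificity
    expect_equal(r$accuracy,
                 (pos * r$sensitivity + neg * r$specificity) / (pos + neg))
    # f1 is the harmonic mean and never exceeds the larger ingredient
    expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$sensitivity))
    expect_lte(r$f1, max(r$precision, r$sensitivity) + 1e-12)
    # swapping (tp<->tn, fp<->fn) swaps sensitivity and specificity
    sw <- score(confusion_matrix(cm$tn, cm$fn, cm$fp, cm$tp))
    expect_equal(sw$sensitivity, r$specificity)
    expect_equal(sw$specificity, r$sensitivity)
  }
})

test_that("report rows format percentages at two decimals", {
  r <- score(confusion_matrix(tp = 1054, fp = 40, fn = 64, tn = 1435))
  row <- report_row(r, c(150, 210), "adam", 2e-4)
  expect_equal(row$accuracy, 95.99)
  expect_equal(row$sensitivity, 94.28)
  expect_equal(row$specificity, 97.29)
  expect_equal(row$precision, 96.34)
  expect_equal(row$f1, 95.30)
})
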
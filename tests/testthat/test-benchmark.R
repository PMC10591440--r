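test_that("jaccard and f1 match hand-computed values", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(f1_score(c("a", "b"), c("b", "c")), 0.5)
  expect_equal(jaccard(c("a", "a", "b"), c("a", "b")), 1)  # set semantics
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(f1_score(character(0), character(0)), 1)
  expect_equal(jaccard(character(0), "a"), 0)
  expect_equal(f1_score("a", character(0)), 0)
  expect_equal(jaccard(letters[1:4], letters[3:6]), 2 / 6)
  expect_equal(f1_score(letters[1:4], letters[3:6]), 0.5)
})

test_that("jaccard and f1 agree with brute-force set formulas", {
  set.seed(5)
  universe <- letters
  for (i in 1:20) {
    p <- sample(universe, sample(0:10, 1))
    t <- sample(universe, sample(0:10, 1))
    inter <- sum(p %in% t)
    uni <- length(unique(c(p, t)))
    expect_equal(jaccard(p, t), if (uni == 0) 1 else inter / uni)
    prec <- if (length(p)) inter / length(p) else 0
    rec <- if (length(t)) inter / length(t) else 0
    f_oracle <- if (length(p) == 0 && length(t) == 0) 1 else
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(f1_score(p, t), f_oracle)
  }
})

test_that("threshold sweep averages per-sample detection metrics", {
  ab <- matrix(c(300, 150, 0,
                 300, 0, 40),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  truth <- list(s1 = c("A", "B"), s2 = "A")
  sw <- threshold_sweep(ab, truth, c(50, 200))
  # threshold 50: s1 predicts {A,B} (J=1), s2 predicts {A} (J=1)
  expect_equal(sw$jaccard_mean[1], 1)
  expect_equal(sw$f1_mean[1], 1)
  # threshold 200: s1 predicts {A} -> J=1/2, F1=2/3; s2 exact
  expect_equal(sw$jaccard_mean[2], mean(c(0.5, 1)))
  expect_equal(sw$f1_mean[2], mean(c(2 / 3, 1)))
  expect_equal(sw$jaccard_sd[2], stats::sd(c(0.5, 1)))
  expect_error(threshold_sweep(ab, truth, c(200, 50)), "ascending")
  expect_error(threshold_sweep(ab, truth, numeric(0)), "non-empty")
  expect_error(threshold_sweep(unname(ab), truth, 50), "rownames")
})

test_that("threshold at the read count is inclusive", {
  ab <- matrix(200, 1, 1, dimnames = list("s1", "A"))
  sw <- threshold_sweep(ab, list(s1 = "A"), c(200, 201))
  expect_equal(sw$jaccard_mean, c(1, 0))
})

test_that("ROC handles perfect separation and ties", {
  r <- roc_curve(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  # all scores tied: single diagonal segment, AUC one half
  r2 <- roc_curve(c(5, 5, 5, 5), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.5)
  expect_equal(nrow(r2$points), 2)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "at least one")
  expect_error(roc_curve(1:3, c(TRUE, FALSE)), "equal length")
})

test_that("trapezoid AUC equals the pairwise concordance estimator", {
  set.seed(9)
  for (i in 1:10) {
    n <- 30
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n, mean = ifelse(labels, 1, 0)), 1)
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, pairwise_auc(scores, labels))
  }
})

test_that("ROC AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  labels <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(0.4, 0.6))
  labels[1:2] <- c(TRUE, FALSE)
  scores <- round(stats::rnorm(50, mean = ifelse(labels, 0.8, 0)), 1)
  r <- roc_curve(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
  expect_equal(r$auc, as.numeric(ref))
})
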
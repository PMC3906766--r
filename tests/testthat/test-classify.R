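test_that("MCC follows its closed form and the zero-denominator convention", {
  expect_equal(mcc(tp = 5, fp = 0, tn = 7, fn = 0), 1.0)   # perfect
  expect_equal(mcc(tp = 0, fp = 7, tn = 0, fn = 5), -1.0)  # perfect inverse
  expect_equal(mcc(tp = 0, fp = 0, tn = 12, fn = 0), 0)    # degenerate
  expect_equal(mcc(tp = 2, fp = 1, tn = 3, fn = 1),
               mcc_pearson_oracle(2, 1, 3, 1), tolerance = 1e-12)
})

test_that("MCC equals the Pearson correlation of indicator vectors", {
  withr::with_seed(61, {
    for (i in 1:1000) {
      counts <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
      got <- mcc(counts[1], counts[2], counts[3], counts[4])
      expect_equal(got,
                   mcc_pearson_oracle(counts[1], counts[2],
                                      counts[3], counts[4]),
                   tolerance = 1e-9)
    }
  })
})

test_that("rank AUC equals brute-force pair counting, with tie handling", {
  # perfect ranking and all-tied scores
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  withr::with_seed(67, {
    for (i in 1:300) {
      n <- sample(4:50, 1)
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, TRUE) # many ties
      expect_equal(auc(scores, labels), auc_pairs_oracle(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("the majority classifier predicts the modal class with fixed tie order", {
  train <- tibble::tibble(
    label = factor(c("none", "none", "MTS"), levels = SIGNAL_CLASSES),
    f1 = c(1, 2, 3)
  )
  m <- majority_classifier(train)
  pred <- predict(m, tibble::tibble(f1 = c(0, 9)))
  expect_equal(as.character(pred), c("none", "none"))
  # tie: MTS comes before none in the fixed class order
  train_tie <- tibble::tibble(
    label = factor(c("none", "MTS"), levels = SIGNAL_CLASSES), f1 = 1:2
  )
  expect_equal(as.character(predict(majority_classifier(train_tie),
                                    tibble::tibble(f1 = 1))), "MTS")
  # constant posterior scores give AUC exactly 0.5; constant predictions MCC 0
  post <- predict(m, train, type = "posterior")
  expect_true(all(post == post[1, 1]))
  expect_equal(auc(post[, "MTS"], train$label == "MTS"), 0.5)
  pred_all <- predict(m, train)
  expect_equal(mcc(tp = sum(pred_all == "none" & train$label == "none"),
                   fp = sum(pred_all == "none" & train$label != "none"),
                   tn = sum(pred_all != "none" & train$label != "none"),
                   fn = sum(pred_all != "none" & train$label == "none")), 0)
})

test_that("the SVM separates separable data and solves XOR", {
  dat <- separable_data(20, seed = 71)
  m <- fit_classifier(dat, classifier_config("svm"))
  expect_equal(mean(as.character(predict(m, dat)) == as.character(dat$label)), 1.0)
  # XOR pattern: only a non-linear kernel can fit the training set
  withr::with_seed(73, {
    xor_dat <- tibble::tibble(
      f1 = rep(c(0, 0, 1, 1), each = 10) + rnorm(40, sd = 0.05),
      f2 = rep(c(0, 1, 0, 1), each = 10) + rnorm(40, sd = 0.05)
    )
    xor_dat$label <- factor(ifelse(round(xor_dat$f1) == round(xor_dat$f2),
                                   "MTS", "none"), levels = SIGNAL_CLASSES)
  })
  mx <- fit_classifier(xor_dat, classifier_config("svm"))
  expect_equal(mean(as.character(predict(mx, xor_dat)) == as.character(xor_dat$label)), 1.0)
  expect_error(fit_classifier(dplyr::mutate(dat, label = "MTS"),
                              classifier_config("svm")), "one class")
})

test_that("a 3-class SVM exposes exactly K(K-1)/2 pairwise machines", {
  withr::with_seed(79, {
    dat <- tibble::tibble(
      label = factor(rep(c("MTS", "SP", "none"), each = 15),
                     levels = SIGNAL_CLASSES),
      f1 = rnorm(45, rep(c(-2, 0, 2), each = 15), 0.5),
      f2 = rnorm(45, rep(c(2, -2, 0), each = 15), 0.5)
    )
  })
  m <- fit_classifier(dat, classifier_config("svm"))
  dec <- predict(m, dat[1:2, ], type = "decision")
  expect_equal(ncol(dec), 3L)
  pairs <- sort(colnames(dec))
  expect_setequal(unique(unlist(strsplit(pairs, "/"))), c("MTS", "SP", "none"))
  # decision tree baseline fits the same data
  mt <- fit_classifier(dat, classifier_config("tree"))
  expect_gt(mean(as.character(predict(mt, dat)) == as.character(dat$label)), 0.9)
  expect_error(predict(mt, dat, type = "decision"), "only available")
})

test_that("exponential loss decoding favors the class its scores favor", {
  # all-zero scores: complete symmetry
  s0 <- c("MTS/SP" = 0, "MTS/none" = 0, "SP/none" = 0)
  d0 <- loss_decode(s0)
  expect_equal(unname(d0$loss[1, ]), rep(2 * exp(0), 3))
  expect_equal(unname(d0$posterior[1, ]), rep(1 / 3, 3))
  # scores strongly favoring MTS in both its pairs
  s1 <- c("MTS/SP" = 3, "MTS/none" = 3, "SP/none" = 0)
  d1 <- loss_decode(s1)
  expect_equal(as.character(d1$label), "MTS")
  expect_true(all(d1$loss[1, "MTS"] < d1$loss[1, c("SP", "none")]))
  # 2-class case: posterior is a monotone function of the single score
  scores <- seq(-2, 2, by = 0.5)
  post <- sapply(scores, function(s) {
    loss_decode(c("MTS/none" = s))$posterior[1, "MTS"]
  })
  expect_true(all(diff(post) > 0))
})

test_that("influence is zero iff decodings coincide, and symmetric", {
  s <- c("MTS/SP" = 1.2, "MTS/none" = 0.4, "SP/none" = -0.7)
  same <- influence_score(s, s)
  expect_equal(same$influence, 0)
  expect_equal(same$label_with, same$label_without)
  # sign-reversed scores flip the decoded label and give positive influence
  flip <- influence_score(s, -s)
  expect_gt(flip$influence, 0)
  expect_false(flip$label_with == flip$label_without)
  # symmetry in the two arguments
  ba <- influence_score(-s, s)
  expect_equal(flip$influence, ba$influence)
  expect_equal(flip$label_with, ba$label_without)
})

test_that("influence ranking flags examples engineered to depend on divergence", {
  # divergence columns informative, classical columns pure noise: removing
  # divergence should change many decoded labels
  withr::with_seed(83, {
    n <- 60
    label <- factor(rep(c("MTS", "none"), each = n / 2),
                    levels = SIGNAL_CLASSES)
    ft <- tibble::tibble(
      id = sprintf("p%02d", 1:n), label = label,
      NCdiff = ifelse(label == "MTS", 1.5, -1.5) + rnorm(n, sd = 0.3),
      N20 = ifelse(label == "MTS", 1, -1) + rnorm(n, sd = 0.3),
      pos20 = rnorm(n), hphob20 = rnorm(n)
    )
  })
  rk <- influence_ranking(ft, folds = 3, seed = 5)
  expect_equal(nrow(rk), 60L)
  expect_true(all(diff(rk$influence) <= 0))
  expect_gt(mean(rk$flipped), 0.2)
  expect_true(all(rk$influence >= 0 & rk$influence <= 1))
})
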
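# PCA, the classifier bank, metrics and cross-validation.

separable_data <- function(n_per = 60, seed = 1, gap = 6) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), n_per, 2),
             matrix(rnorm(2 * n_per, mean = gap), n_per, 2))
  list(X = X, y = rep(c("healthy", "infested"), each = n_per))
}

test_that("PCA captures a rank-1 structure in a single component", {
  set.seed(2)
  t_ <- rnorm(30)
  X <- cbind(2 * t_, -t_, 0.5 * t_) + 5
  m <- fit_pca(X, var_target = 0.5)
  expect_equal(m$explained_variance_ratio[1], 1.0, tolerance = 1e-12)
  expect_identical(ncol(m$loadings), 1L)
  m99 <- fit_pca(X, var_target = 0.999)
  expect_identical(ncol(m99$loadings), 1L)
})

test_that("an isotropic 2-d sample splits variance roughly evenly", {
  set.seed(3)
  X <- matrix(rnorm(4000), 2000, 2)
  m <- fit_pca(X, ncomp = 2)
  expect_equal(m$explained_variance_ratio, c(0.5, 0.5), tolerance = 0.05)
})

test_that("eigenvalues and scores agree with an SVD oracle", {
  set.seed(4)
  X <- matrix(rnorm(100), 20, 5)
  m <- fit_pca(X, ncomp = 5)
  sv <- svd(scale(X, scale = FALSE))
  expect_equal(m$eigenvalues, sv$d^2 / 19, tolerance = 1e-8)
  # orthonormal loadings
  expect_equal(unname(crossprod(m$loadings)), diag(5), tolerance = 1e-10)
  # score covariance diagonal equals the eigenvalues
  sc <- transform_pca(m, X)
  expect_equal(unname(diag(stats::cov(sc))), unname(m$eigenvalues),
               tolerance = 1e-8)
  expect_error(fit_pca(X, ncomp = 6), class = "calyxscan_parameter_error")
})

test_that("projection behaves like an orthogonal projection", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  m <- fit_pca(X, ncomp = 2)
  expect_equal(unname(drop(transform_pca(m, matrix(m$mean, 1)))), c(0, 0),
               tolerance = 1e-10)
  sc <- transform_pca(m, X)
  xhat <- sweep(sc %*% t(m$loadings), 2, m$mean, `+`)
  for (i in 1:5) {
    expect_lte(sum((X[i, ] - xhat[i, ])^2),
               sum((X[i, ] - m$mean)^2) + 1e-12)
  }
  expect_error(transform_pca(m, X[, 1:3]), class = "calyxscan_alignment_error")
})

test_that("every classifier separates well-separated Gaussian clusters", {
  d <- separable_data(seed = 6)
  for (tag in c("lda", "knn", "svm", "rf", "gtb", "plsda", "adaboost")) {
    hp <- switch(tag, rf = list(ntree = 60), gtb = list(nrounds = 40),
                 adaboost = list(nstumps = 20), list())
    m <- train_classifier(tag, d$X, d$y, hp, seed = 1)
    expect_identical(evaluate(m, d$X, d$y, "train")$accuracy, 1,
                     label = tag)
  }
})

test_that("1-NN memorizes its training set", {
  set.seed(7)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c("healthy", "infested"), 15)
  m <- train_classifier("knn", X, y, list(k = 1))
  expect_identical(evaluate(m, X, y)$accuracy, 1)
})

test_that("label permutation drives CV accuracy to chance", {
  set.seed(8)
  X <- matrix(rnorm(400), 200, 2)
  y <- sample(rep(c("healthy", "infested"), 100))  # independent of X
  cv <- cross_validate("lda", X, y, folds = 5, seed = 8)
  band <- qnorm(0.995) * sqrt(0.25 / 200)
  expect_gt(cv$mean_accuracy, 0.5 - band - 0.05)
  expect_lt(cv$mean_accuracy, 0.5 + band + 0.05)
})

test_that("degenerate labels and unknown tags are rejected", {
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  expect_error(train_classifier("lda", X, rep("healthy", 20)),
               class = "calyxscan_degenerate_label_error")
  expect_error(train_classifier("mystery", X,
                                rep(c("healthy", "infested"), 10)))
})

test_that("report metrics match a hand-counted confusion matrix", {
  # TP=9, FP=1, FN=3, TN=7 with infested positive
  truth <- c(rep("infested", 12), rep("healthy", 8))
  pred <- c(rep("infested", 9), rep("healthy", 3),
            rep("infested", 1), rep("healthy", 7))
  rep_ <- classification_report(truth, pred)
  inf <- rep_$metrics[rep_$metrics$class == "infested", ]
  expect_equal(inf$precision, 0.9)
  expect_equal(inf$recall, 0.75)
  expect_equal(inf$f1, 0.8182, tolerance = 1e-4)
  expect_equal(rep_$accuracy, 0.8)
  # consistency: accuracy recomputed from the confusion matrix
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / sum(rep_$confusion),
               tolerance = 1e-12)
  # harmonic mean of equals is the value itself
  expect_equal(f1_score(0.83, 0.83), 0.83)
  expect_identical(f1_score(0, 0), 0)
})

test_that("stratified folds are balanced and CV is exactly reproducible", {
  d <- separable_data(n_per = 33, seed = 10)
  cv <- cross_validate("lda", d$X, d$y, folds = 5, seed = 3)
  expect_equal(cv$mean_accuracy, 1)
  expect_identical(cv$sd_accuracy, 0)
  sizes <- table(cv$fold_assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(sum(sizes), 66L)
  for (k in 1:5) {
    expect_identical(
      length(unique(d$y[cv$fold_assignment == k])), 2L)
  }
  cv2 <- cross_validate("lda", d$X, d$y, folds = 5, seed = 3)
  expect_identical(cv$fold_accuracies, cv2$fold_accuracies)
})

test_that("CV accuracy equals an explicit loop over the same folds", {
  set.seed(11)
  X <- matrix(rnorm(240), 120, 2)
  y <- rep(c("healthy", "infested"), 60)
  X[y == "infested", 1] <- X[y == "infested", 1] + 1.5
  cv <- cross_validate("lda", X, y, folds = 4, seed = 5)
  fa <- cv$fold_assignment
  acc <- numeric(4)
  for (k in 1:4) {
    fit <- MASS::lda(X[fa != k, ], grouping = factor(y[fa != k]))
    pred <- predict(fit, X[fa == k, ])$class
    acc[k] <- mean(as.character(pred) == y[fa == k])
  }
  expect_equal(cv$fold_accuracies, acc, tolerance = 1e-12)
  expect_equal(cv$mean_accuracy, mean(acc), tolerance = 1e-12)
  expect_equal(cv$sd_accuracy, sd(acc), tolerance = 1e-12)
})

test_that("a nonlinear class boundary favors trees over LDA", {
  # XOR-style mixture: linearly inseparable, tree-separable
  set.seed(12)
  n <- 80
  X <- rbind(matrix(rnorm(n, 0, 0.4), n / 2, 2),
             matrix(rnorm(n, 4, 0.4), n / 2, 2),
             cbind(rnorm(n / 2, 0, 0.4), rnorm(n / 2, 4, 0.4)),
             cbind(rnorm(n / 2, 4, 0.4), rnorm(n / 2, 0, 0.4)))
  y <- rep(c("healthy", "infested"), each = n)
  sp <- kennard_stone(X, 0.7)
  lda_m <- train_classifier("lda", X[sp$train_idx, ], y[sp$train_idx])
  gtb_m <- train_classifier("gtb", X[sp$train_idx, ], y[sp$train_idx],
                            list(nrounds = 60), seed = 1)
  lda_acc <- evaluate(lda_m, X[sp$val_idx, ], y[sp$val_idx])$accuracy
  gtb_acc <- evaluate(gtb_m, X[sp$val_idx, ], y[sp$val_idx])$accuracy
  expect_gt(gtb_acc, lda_acc)
  expect_gte(gtb_acc, 0.95)
})

test_that("raw-band and PCA-score inputs yield reports of identical schema", {
  d <- separable_data(n_per = 40, seed = 13)
  pca <- fit_pca(d$X, ncomp = 2)
  r_raw <- evaluate(train_classifier("lda", d$X, d$y), d$X, d$y)
  r_pca <- evaluate(train_classifier("lda", transform_pca(pca, d$X), d$y),
                    transform_pca(pca, d$X), d$y)
  expect_identical(names(r_raw), names(r_pca))
  expect_identical(names(r_raw$metrics), names(r_pca$metrics))
})
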
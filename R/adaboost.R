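# AdaBoost (discrete SAMME, two classes) over depth-1 rpart stumps.

fit_adaboost_stumps <- function(X, y, nstumps = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  yy <- ifelse(y == "infested", 1, -1)
  w <- rep(1 / n, n)
  stumps <- vector("list", nstumps)
  alphas <- numeric(nstumps)
  df <- data.frame(X)
  used <- 0L
  for (m in seq_len(nstumps)) {
    fit <- rpart::rpart(
      yfac ~ ., data = cbind(df, yfac = factor(yy)), weights = w,
      method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                                     minbucket = 1, xval = 0))
    pred <- as.numeric(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) break  # stump no better than chance; stop boosting
    used <- m
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) break  # perfect stump; further rounds add nothing
  }
  cs_assert(used >= 1, "AdaBoost found no stump better than chance",
            "calyxscan_degenerate_label_error")
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
       feature_names = colnames(df))
}

predict_adaboost_stumps <- function(fit, X) {
  df <- data.frame(as.matrix(X))
  colnames(df) <- fit$feature_names
  score <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- as.numeric(as.character(
      stats::predict(fit$stumps[[m]], df, type = "class")))
    score <- score + fit$alphas[m] * pred
  }
  ifelse(score > 0, "infested", "healthy")
}
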
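# The seven classifiers: toy geometry, solver cross-agreement, oracles.

toy2 <- list(X = matrix(c(-1, 0, 1, 0), 2, byrow = TRUE),
             y = c(-1, 1))

test_that("all SVM solvers put the two-point boundary at the midpoint", {
  for (kind in c("ls_svm", "qp_svm", "smo_svm")) {
    model <- train_classifier(toy2$X, toy2$y, classifier_spec(kind))
    expect_equal(predict(model, toy2$X, type = "numeric"), c(-1, 1),
                 label = kind)
    # decision value at the midpoint is 0; sign flips across it
    expect_equal(decision_values(model, matrix(c(0, 0), 1)), 0,
                 tolerance = 1e-6, label = kind)
    expect_lt(decision_values(model, matrix(c(-0.5, 0), 1)), 0)
    expect_gt(decision_values(model, matrix(c(0.5, 0), 1)), 0)
  }
})

test_that("LS-SVM satisfies its KKT linear system to solver precision", {
  b <- blobs(n = 30, d = 3, seed = 2)
  spec <- classifier_spec("ls_svm")
  model <- train_ls_svm(b$X, b$y, spec)
  n <- nrow(b$X)
  K <- b$X %*% t(b$X)
  A <- rbind(c(0, b$y), cbind(b$y, (b$y %*% t(b$y)) * K + diag(n) / spec$gamma))
  resid <- A %*% c(model$pars$b, model$pars$alpha) - c(0, rep(1, n))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("QP dual solution is feasible and KKT-consistent", {
  b <- blobs(n = 40, d = 2, sep = 3, seed = 3)
  spec <- classifier_spec("qp_svm", cost = 1)
  model <- train_qp_svm(b$X, b$y, spec)
  a <- model$pars$alpha
  expect_true(all(a >= -1e-6 & a <= spec$cost + 1e-6))
  expect_lt(abs(sum(a * b$y)), 1e-6 * length(a))
  # margin constraints: free SVs sit on the margin
  f <- decision_values(model, b$X)
  free <- a > 1e-4 & a < spec$cost - 1e-4
  if (any(free)) expect_equal(b$y[free] * f[free], rep(1, sum(free)),
                              tolerance = 1e-3)
})

test_that("SMO reaches the QP dual optimum on separable and noisy sets", {
  dual_obj <- function(alpha, X, y) {
    K <- X %*% t(X)
    sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y)))
  }
  for (sep in c(4, 1.5)) {
    b <- blobs(n = 40, d = 2, sep = sep, seed = 4)
    qp <- train_qp_svm(b$X, b$y)
    smo <- train_smo_svm(b$X, b$y)
    expect_equal(dual_obj(smo$pars$alpha, b$X, b$y),
                 dual_obj(qp$pars$alpha, b$X, b$y), tolerance = 1e-4)
  }
})

test_that("LS, QP and SMO predictions agree on separable problems (>= 99%)", {
  agree <- function(a, b) mean(a == b)
  for (seed in 1:3) {
    b <- blobs(n = 40, d = 2, sep = 8, seed = seed)
    test_pts <- blobs(n = 200, d = 2, sep = 8, seed = seed + 100)$X
    p_ls <- predict(train_ls_svm(b$X, b$y), test_pts)
    p_qp <- predict(train_qp_svm(b$X, b$y), test_pts)
    p_smo <- predict(train_smo_svm(b$X, b$y), test_pts)
    expect_gte(agree(p_ls, p_qp), 0.99)
    expect_gte(agree(p_qp, p_smo), 0.99)
  }
})

test_that("SVM predictions agree with an independent reference SVM", {
  skip_if_not_installed("e1071")
  b <- blobs(n = 60, d = 4, sep = 4, seed = 8)
  ref <- e1071::svm(b$X, factor(b$y), kernel = "linear", cost = 1,
                    scale = FALSE)
  p_ref <- as.numeric(as.character(predict(ref, b$X)))
  p_qp <- predict(train_qp_svm(b$X, b$y), b$X, type = "numeric")
  p_smo <- predict(train_smo_svm(b$X, b$y), b$X, type = "numeric")
  expect_gte(mean(p_ref == p_qp), 0.99)
  expect_gte(mean(p_ref == p_smo), 0.99)
})

test_that("k-NN matches a brute-force all-pairs sort and resolves ties by the nearest", {
  set.seed(10)
  X <- matrix(rnorm(60 * 48), 60)
  y <- rep(c(1, -1), 30)
  Q <- matrix(rnorm(20 * 48), 20)
  model <- train_knn(X, y, classifier_spec("knn", k = 10))
  pred <- predict(model, Q, type = "numeric")
  # independent oracle: explicit distance loop per query
  oracle <- vapply(seq_len(nrow(Q)), function(i) {
    d <- sqrt(colSums((t(X) - Q[i, ])^2))
    nb <- sort.int(d, index.return = TRUE)$ix[1:10]
    s <- sum(y[nb])
    if (s == 0) y[nb[1]] else sign(s)
  }, numeric(1))
  expect_equal(pred, oracle)
  # query equal to a training point with k = 1 returns that point's label
  m1 <- train_knn(X, y, classifier_spec("knn", k = 1))
  expect_equal(predict(m1, X[3, , drop = FALSE], type = "numeric"), y[3])
  # k = n with imbalance: majority class everywhere
  Xi <- rbind(X, X[1:10, ] + 5)
  yi <- c(y, rep(1, 10))
  mn <- train_knn(Xi, yi, classifier_spec("knn", k = nrow(Xi)))
  expect_true(all(predict(mn, Q, type = "numeric") == 1))
})

test_that("gaussian NB matches direct Bayes-rule evaluation and a reference", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40, 0, 1), 20), matrix(rnorm(40, 2, 1.5), 20))
  y <- rep(c(-1, 1), each = 20)
  model <- train_naive_bayes(X, y)
  Q <- matrix(rnorm(30, 1), 15)
  s <- decision_values(model, Q)
  # direct density-product oracle
  post <- function(q, cl) {
    Xi <- X[y == cl, , drop = FALSE]
    sum(dnorm(q, colMeans(Xi), apply(Xi, 2, sd), log = TRUE)) +
      log(mean(y == cl))
  }
  oracle <- vapply(seq_len(nrow(Q)),
                   function(i) post(Q[i, ], 1) - post(Q[i, ], -1), numeric(1))
  expect_equal(s, oracle, tolerance = 1e-9)
  skip_if_not_installed("e1071")
  ref <- e1071::naiveBayes(X, factor(y))
  p_ref <- as.numeric(as.character(predict(ref, Q)))
  expect_equal(predict(model, Q, type = "numeric"), p_ref)
})

test_that("NB separates symmetric classes; flat features are inert", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
  y <- rep(c(-1, 1), each = 20)
  m <- train_naive_bayes(X, y)
  expect_lt(decision_values(m, matrix(c(-2, -2), 1)), 0)
  expect_gt(decision_values(m, matrix(c(2, 2), 1)), 0)
  # add a feature identical in both classes: predictions unchanged
  flat <- rep(c(1, 2), 20)
  m2 <- train_naive_bayes(cbind(X, flat), y)
  Q <- matrix(rnorm(40, 0, 3), 20)
  expect_equal(predict(m, Q),
               predict(m2, cbind(Q, rep(1.5, 20))))
})

test_that("trainers are deterministic and order-invariant", {
  b <- blobs(n = 30, d = 5, seed = 13)
  perm <- sample(seq_len(nrow(b$X)))
  Q <- matrix(rnorm(5 * 10), 10)
  for (spec in list(classifier_spec("ls_svm"), classifier_spec("smo_svm"),
                    classifier_spec("knn", k = 3),
                    classifier_spec("naive_bayes"))) {
    m1 <- train_classifier(b$X, b$y, spec)
    m2 <- train_classifier(b$X, b$y, spec)
    expect_identical(decision_values(m1, Q), decision_values(m2, Q))
    m3 <- train_classifier(b$X[perm, ], b$y[perm], spec)
    expect_equal(predict(m1, Q), predict(m3, Q))
  }
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(10), 5)
  expect_error(train_ls_svm(X, rep(1, 5)), "per class")
  expect_error(train_knn(X, rep(c(1, -1), c(3, 2)),
                         classifier_spec("knn", k = 6)), "exceeds")
  expect_error(classifier_spec("knn"))
  expect_error(train_naive_bayes(X, c(1, 1, 1, 1, 2)), "labels")
})

test_that("models survive a JSON save/load round trip", {
  b <- blobs(n = 20, d = 3, seed = 14)
  Q <- matrix(rnorm(9), 3)
  tmp <- tempfile(fileext = ".json")
  for (spec in list(classifier_spec("ls_svm"),
                    classifier_spec("naive_bayes"),
                    classifier_spec("knn", k = 3))) {
    m <- train_classifier(b$X, b$y, spec)
    model_save(m, tmp)
    m2 <- model_load(tmp)
    expect_equal(predict(m2, Q), predict(m, Q), label = spec$kind)
  }
})
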
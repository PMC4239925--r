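## Seven classifiers behind one train/predict contract. The three SVM
## variants share the same soft-margin decision function and differ only in
## how the training problem is solved: LS-SVM replaces the inequality
## constraints with equalities and solves one linear (KKT) system; QP-SVM
## solves the standard dual quadratic program with an interior-point solver;
## SMO optimizes the same dual by analytic two-variable coordinate steps.
## Labels are encoded pre_movement = +1, rest = -1 throughout.

#' Classifier specification
#'
#' @param kind One of `"ls_svm"`, `"qp_svm"`, `"smo_svm"`, `"knn"`,
#'   `"naive_bayes"`.
#' @param k Neighbour count (k-NN only); the benchmark uses 10, 20 and 30.
#' @param kernel `"linear"` (default) or `"rbf"` (SVMs).
#' @param cost Soft-margin box constraint C > 0 (QP/SMO SVM).
#' @param gamma LS-SVM regularization weight > 0 (larger fits tighter).
#' @param rbf_sigma RBF kernel bandwidth (if `kernel = "rbf"`).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("ls_svm", "qp_svm", "smo_svm", "knn",
                                     "naive_bayes"),
                            k = NULL, kernel = c("linear", "rbf"),
                            cost = 1, gamma = 1, rbf_sigma = 1) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, gamma > 0, rbf_sigma > 0)
  if (kind == "knn") {
    stopifnot(!is.null(k), k >= 1)
    k <- as.integer(k)
  }
  structure(list(kind = kind, k = k, kernel = kernel, cost = cost,
                 gamma = gamma, rbf_sigma = rbf_sigma),
            class = "classifier_spec")
}

#' The seven benchmark classifiers
#'
#' @return Named list of [classifier_spec()] objects: LS-SVM, QP-SVM,
#'   SMO-SVM, 10-NN, 20-NN, 30-NN and Gaussian naive Bayes.
#' @export
paper_classifiers <- function() {
  list(
    "LS"    = classifier_spec("ls_svm"),
    "QP"    = classifier_spec("qp_svm"),
    "SMO"   = classifier_spec("smo_svm"),
    "10-NN" = classifier_spec("knn", k = 10),
    "20-NN" = classifier_spec("knn", k = 20),
    "30-NN" = classifier_spec("knn", k = 30),
    "NB"    = classifier_spec("naive_bayes")
  )
}

# accept character labels or +/-1; return +/-1 numeric
.encode_labels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be +/-1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("pre_movement", "rest"))) {
    stop("labels must be 'pre_movement'/'rest' or +/-1")
  }
  ifelse(y == "pre_movement", 1, -1)
}

.decode_labels <- function(s) ifelse(s >= 0, "pre_movement", "rest")

.kernel_matrix <- function(X, Y, spec) {
  if (spec$kernel == "linear") return(X %*% t(Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * X %*% t(Y)
  exp(-pmax(d2, 0) / (2 * spec$rbf_sigma^2))
}

.new_model <- function(spec, pars, X = NULL, y = NULL) {
  structure(list(spec = spec, pars = pars, X = X, y = y),
            class = "erd_model")
}

#' @export
print.erd_model <- function(x, ...) {
  cat("<erd_model> ", x$spec$kind,
      if (x$spec$kind == "knn") paste0(" (k=", x$spec$k, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Train a least-squares SVM
#'
#' Solves the LS-SVM training problem exactly as one linear system: with
#' `Omega = (y y') * K(X, X)` the KKT conditions are
#' \deqn{\begin{pmatrix} 0 & y^T \\ y & \Omega + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ 1 \end{pmatrix}}
#' and the decision is `sign(sum_k alpha_k y_k K(x, x_k) + b)`.
#'
#' @param X Feature matrix (rows = samples).
#' @param y Labels (`pre_movement`/`rest` or +/-1), both classes present.
#' @param spec A [classifier_spec()] with `kind = "ls_svm"`.
#' @return An `erd_model`.
#' @export
train_ls_svm <- function(X, y, spec = classifier_spec("ls_svm")) {
  X <- as.matrix(X)
  y <- .encode_labels(y)
  if (length(unique(y)) < 2) stop("need at least one sample per class")
  n <- nrow(X)
  K <- .kernel_matrix(X, X, spec)
  A <- rbind(c(0, y), cbind(y, (y %*% t(y)) * K + diag(n) / spec$gamma))
  sol <- tryCatch(solve(A, c(0, rep(1, n))),
                  error = function(e) stop("LS-SVM KKT system is singular: ",
                                           conditionMessage(e)))
  .new_model(spec, list(alpha = sol[-1], b = sol[1]), X, y)
}

# dual objective pieces shared by QP and SMO: minimize 0.5 a'Qa - 1'a,
# 0 <= a <= C, y'a = 0, with Q = (yy') * K
.svm_bias <- function(alpha, y, K, C) {
  f0 <- as.vector(K %*% (alpha * y))
  free <- alpha > 1e-6 * C & alpha < C * (1 - 1e-6)
  if (any(free)) return(mean(y[free] - f0[free]))
  # no free support vectors: midpoint of the feasible bias interval
  up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
  lo <- (y == 1 & alpha > 1e-12) | (y == -1 & alpha < C - 1e-12)
  m <- max(y[up] - f0[up])
  M <- min(y[lo] - f0[lo])
  (m + M) / 2
}

#' Train a soft-margin SVM by solving the dual quadratic program
#'
#' Maximizes the margin by solving the standard dual
#' `min 0.5 a'Qa - 1'a` subject to `0 <= a <= C`, `y'a = 0`
#' (`Q = (yy') * K`) with the interior-point QP solver [kernlab::ipop()];
#' dual feasibility is verified after the solve.
#'
#' @inheritParams train_ls_svm
#' @param spec A [classifier_spec()] with `kind = "qp_svm"`.
#' @param tol Feasibility tolerance for the post-hoc KKT check.
#' @return An `erd_model`.
#' @export
train_qp_svm <- function(X, y, spec = classifier_spec("qp_svm"), tol = 1e-6) {
  X <- as.matrix(X)
  y <- .encode_labels(y)
  if (length(unique(y)) < 2) stop("need at least one sample per class")
  n <- nrow(X)
  C <- spec$cost
  K <- .kernel_matrix(X, X, spec)
  # tiny Gram-scaled ridge keeps the interior-point iterations well posed
  Q <- (y %*% t(y)) * K + diag(mean(diag(K)) * 1e-8 + 1e-12, n)
  sv <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0, sigf = 7,
                      maxiter = 200)
  if (!grepl("converged", kernlab::how(sv))) {
    stop("QP solver did not converge: ", kernlab::how(sv))
  }
  alpha <- kernlab::primal(sv)
  alpha <- pmin(pmax(alpha, 0), C)
  if (abs(sum(alpha * y)) > tol * max(1, C) * n) {
    stop("QP solver failed dual feasibility: sum(alpha*y) = ",
         sum(alpha * y))
  }
  .new_model(spec, list(alpha = alpha, b = .svm_bias(alpha, y, K, C)), X, y)
}

#' Train a soft-margin SVM by sequential minimal optimization
#'
#' Optimizes the identical dual as [train_qp_svm()] by repeatedly solving
#' analytic two-variable subproblems over the maximal-violating pair,
#' stopping when the KKT violation gap falls below `tol`.
#'
#' @inheritParams train_ls_svm
#' @param spec A [classifier_spec()] with `kind = "smo_svm"`.
#' @param tol Stopping tolerance on the violation gap.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An `erd_model`.
#' @export
train_smo_svm <- function(X, y, spec = classifier_spec("smo_svm"),
                          tol = 1e-6, max_iter = 100000) {
  X <- as.matrix(X)
  y <- .encode_labels(y)
  if (length(unique(y)) < 2) stop("need at least one sample per class")
  n <- nrow(X)
  C <- spec$cost
  K <- .kernel_matrix(X, X, spec)
  alpha <- rep(0, n)
  G <- rep(-1, n)  # gradient of the dual: Q alpha - 1
  for (it in seq_len(max_iter)) {
    yG <- -y * G
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == 1 & alpha > 1e-12) | (y == -1 & alpha < C - 1e-12)
    i <- which(up)[which.max(yG[up])]
    j <- which(lo)[which.min(yG[lo])]
    m <- yG[i]; M <- yG[j]
    if (m - M < tol) {
      b <- .svm_bias(alpha, y, K, C)
      return(.new_model(spec, list(alpha = alpha, b = b, iterations = it),
                        X, y))
    }
    # direction alpha_i += y_i t, alpha_j -= y_j t keeps y'alpha constant
    quad <- max(K[i, i] + K[j, j] - 2 * K[i, j], 1e-12)
    t_star <- (m - M) / quad
    t_max_i <- if (y[i] == 1) C - alpha[i] else alpha[i]
    t_max_j <- if (y[j] == 1) alpha[j] else C - alpha[j]
    t_step <- min(t_star, t_max_i, t_max_j)
    dai <- y[i] * t_step
    daj <- -y[j] * t_step
    alpha[i] <- alpha[i] + dai
    alpha[j] <- alpha[j] + daj
    G <- G + (y * K[, i]) * (y[i] * dai) + (y * K[, j]) * (y[j] * daj)
  }
  stop("SMO failed to converge within ", max_iter, " iterations")
}

#' Train a k-nearest-neighbour classifier
#'
#' Stores the training set; prediction takes the majority label among the k
#' Euclidean nearest neighbours. With two classes and even k a tie is
#' resolved by the label of the single nearest neighbour, which is
#' deterministic and distance-respecting.
#'
#' @inheritParams train_ls_svm
#' @param spec A [classifier_spec()] with `kind = "knn"` and `k` set.
#' @return An `erd_model`.
#' @export
train_knn <- function(X, y, spec = classifier_spec("knn", k = 10)) {
  X <- as.matrix(X)
  y <- .encode_labels(y)
  if (spec$k > nrow(X)) stop("k exceeds the number of training samples")
  .new_model(spec, list(), X, y)
}

#' Train a Gaussian naive Bayes classifier
#'
#' Per class and per feature an independent Gaussian with the empirical mean
#' and variance (variance floored at 1e-9); prediction maximizes the log
#' prior plus the sum of per-feature log densities.
#'
#' @inheritParams train_ls_svm
#' @param spec A [classifier_spec()] with `kind = "naive_bayes"`.
#' @return An `erd_model`.
#' @export
train_naive_bayes <- function(X, y, spec = classifier_spec("naive_bayes")) {
  X <- as.matrix(X)
  y <- .encode_labels(y)
  if (length(unique(y)) < 2) stop("need at least one sample per class")
  classes <- c(1, -1)
  stats_by <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mean = colMeans(Xi),
         var = pmax(apply(Xi, 2, stats::var), 1e-9),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(stats_by) <- c("pos", "neg")
  .new_model(spec, stats_by)
}

#' Train any benchmark classifier
#'
#' Dispatches on `spec$kind` to the matching trainer. All trainers are
#' deterministic given `(X, y, spec)`.
#'
#' @inheritParams train_ls_svm
#' @param spec A [classifier_spec()].
#' @return An `erd_model`.
#' @export
train_classifier <- function(X, y, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  switch(spec$kind,
         ls_svm = train_ls_svm(X, y, spec),
         qp_svm = train_qp_svm(X, y, spec),
         smo_svm = train_smo_svm(X, y, spec),
         knn = train_knn(X, y, spec),
         naive_bayes = train_naive_bayes(X, y, spec))
}

#' Decision values of a trained model
#'
#' @param model An `erd_model`.
#' @param X New feature matrix.
#' @return Numeric vector; positive values vote `pre_movement`.
#' @export
decision_values <- function(model, X) {
  X <- as.matrix(X)
  spec <- model$spec
  if (spec$kind %in% c("ls_svm", "qp_svm", "smo_svm")) {
    K <- .kernel_matrix(X, model$X, spec)
    return(as.vector(K %*% (model$pars$alpha * model$y) + model$pars$b))
  }
  if (spec$kind == "knn") {
    d2 <- outer(rowSums(X^2), rowSums(model$X^2), `+`) - 2 * X %*% t(model$X)
    return(apply(d2, 1, function(row) {
      nb <- order(row)[seq_len(spec$k)]
      s <- sum(model$y[nb])
      if (s == 0) model$y[nb[1]] else s
    }))
  }
  # naive Bayes: log-posterior difference
  loglik <- function(st) {
    z2 <- sweep(sweep(X, 2, st$mean)^2, 2, st$var, `/`)
    ll <- -0.5 * z2 - 0.5 * log(2 * pi) -
      matrix(0.5 * log(st$var), nrow(X), ncol(X), byrow = TRUE)
    rowSums(ll) + st$logprior
  }
  loglik(model$pars$pos) - loglik(model$pars$neg)
}

#' Predict epoch labels
#'
#' @param object An `erd_model`.
#' @param newdata Feature matrix.
#' @param type `"label"` (default) for `pre_movement`/`rest`, `"numeric"`
#'   for +/-1.
#' @param ... Unused.
#' @return Predicted labels.
#' @export
predict.erd_model <- function(object, newdata, type = c("label", "numeric"),
                              ...) {
  type <- match.arg(type)
  s <- decision_values(object, newdata)
  if (type == "numeric") ifelse(s >= 0, 1, -1) else .decode_labels(s)
}
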
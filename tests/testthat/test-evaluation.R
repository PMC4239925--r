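# Rates, leave-one-run-out folds, aggregation and ANOVA machinery.

test_that("TPR and FPR follow their defining count ratios", {
  # counts (TP, FN, FP, TN) = (3, 1, 2, 6) -> TPR 75, FPR 25
  pred <- c(rep(1, 3), -1, 1, 1, rep(-1, 6))
  y <- c(rep(1, 4), rep(-1, 8))
  r <- compute_rates(pred, y)
  expect_equal(unlist(r[, c("tp", "fn", "fp", "tn")], use.names = FALSE),
               c(3, 1, 2, 6))
  expect_equal(r$tpr, 75)
  expect_equal(r$fpr, 25)
  # 10 pre-movement, 8 detected -> TPR 80; 20 rest, none called -> FPR 0
  r2 <- compute_rates(c(rep(1, 8), rep(-1, 2), rep(-1, 20)),
                      c(rep(1, 10), rep(-1, 20)))
  expect_equal(r2$tpr, 80)
  expect_equal(r2$fpr, 0)
})

test_that("leave-one-run-out makes one fold per run and a true partition", {
  s <- small_session()
  fe <- session_features(s)
  cv <- cross_validate(fe, classifier_spec("ls_svm"))
  expect_equal(nrow(cv), 3)
  expect_setequal(cv$fold_id, unique(fe$run_id))
  # every epoch tested exactly once across folds
  expect_equal(sum(cv$tp + cv$fn + cv$fp + cv$tn), nrow(fe))
  per_run <- table(fe$run_id)
  expect_equal(unname(cv$tp + cv$fn + cv$fp + cv$tn),
               unname(as.vector(per_run[cv$fold_id])))
})

test_that("an always-positive classifier scores TPR 100 and FPR 100", {
  s <- small_session()
  fe <- session_features(s)
  for (r in unique(fe$run_id)) {
    te <- fe$run_id == r
    rates <- compute_rates(rep(1, sum(te)), fe$label[te], r)
    expect_equal(rates$tpr, 100)
    expect_equal(rates$fpr, 100)
  }
})

test_that("aggregation reproduces the published per-user arithmetic", {
  # subject with mean TPR 75.7 / FPR 18.5 -> GAP 4.1 at one decimal
  folds <- data.frame(classifier = "LS", subject = "A",
                      tpr = c(75.7, 75.7), fpr = c(18.5, 18.5))
  sm <- summarize_benchmark(folds)
  expect_equal(round_half_up(sm$per_subject$gap), 4.1)
  expect_equal(sm$per_subject$tpr_sd, 0)
  # six published per-subject GAPs of the LS row average to 2.8
  expect_equal(round_half_up(mean(c(4.1, 2.9, 2.3, 3.7, 2.3, 1.5))), 2.8)
})

test_that("all-users aggregation is the mean of per-subject means, sds and GAPs", {
  set.seed(20)
  folds <- expand.grid(classifier = c("LS", "NB"), subject = c("A", "B"),
                       fold = 1:4, stringsAsFactors = FALSE)
  folds$tpr <- runif(nrow(folds), 50, 90)
  folds$fpr <- runif(nrow(folds), 10, 40)
  sm <- summarize_benchmark(folds)
  for (cl in c("LS", "NB")) {
    p <- sm$per_subject[sm$per_subject$classifier == cl, ]
    a <- sm$all_users[sm$all_users$classifier == cl, ]
    expect_equal(a$tpr_mean, mean(p$tpr_mean))
    expect_equal(a$tpr_sd, mean(p$tpr_sd))
    expect_equal(a$gap, mean(p$tpr_mean / p$fpr_mean))
    # and per-subject sd is the sd over that subject's folds
    f <- folds[folds$classifier == cl & folds$subject == "A", ]
    expect_equal(p$tpr_sd[p$subject == "A"], sd(f$tpr))
  }
})

test_that("zero FPR yields an infinite GAP excluded from the average", {
  folds <- data.frame(classifier = "LS", subject = c("A", "A", "B", "B"),
                      tpr = c(80, 90, 70, 80), fpr = c(0, 0, 20, 20))
  expect_warning(sm <- summarize_benchmark(folds), "infinite GAP")
  expect_true(is.infinite(sm$per_subject$gap[sm$per_subject$subject == "A"]))
  expect_equal(sm$all_users$gap, 75 / 20)
})

test_that("one-way ANOVA matches hand-derived reference values", {
  # identical groups: F = 0, p = 1
  r0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # groups (1,2,3) vs (11,12,13): SSB = 150, SSW = 4, F = 150/(4/4) = 150
  r <- one_way_anova(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 150, tolerance = 1e-12)
  expect_equal(r$p, pf(150, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(c(r$df1, r$df2), c(1, 4))
})

test_that("pairwise ANOVAs fill the upper triangle without correction", {
  set.seed(21)
  v <- rnorm(21)
  g <- rep(c("LS", "QP", "NB"), each = 7)
  m <- pairwise_anova(v, g)
  expect_equal(dim(m), c(3, 3))
  expect_true(all(is.na(m[lower.tri(m, diag = TRUE)])))
  expect_equal(m["LS", "QP"],
               one_way_anova(v[1:14], g[1:14])$p)
})

test_that("report files carry the benchmark-table shape and rounding", {
  folds <- expand.grid(classifier = c("LS", "NB"),
                       subject = c("A", "B"), fold = 1:3,
                       stringsAsFactors = FALSE)
  set.seed(22)
  folds$tpr <- runif(nrow(folds), 60, 90)
  folds$fpr <- runif(nrow(folds), 10, 40)
  sm <- summarize_benchmark(folds)
  an <- anova_report(list(summary = sm, folds = folds))
  dir <- tempfile()
  paths <- render_report(sm, an, dir = dir)
  tab <- read.delim(file.path(dir, "benchmark_table.tsv"),
                    check.names = FALSE)
  expect_equal(colnames(tab), c("Method", "Metric", "A", "B", "AllUsers"))
  expect_equal(nrow(tab), 2 * 3)  # 2 classifiers x TPR/FPR/GAP
  expect_match(tab$A[1], "^\\d+\\.\\d±\\d+\\.\\d$")
  js <- jsonlite::read_json(file.path(dir, "benchmark.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(js$all_users$classifier), c("LS", "NB"))
  expect_equal(js$anova$fpr$p, an$fpr$p, tolerance = 1e-12)
  # rounding convention: half away from zero
  expect_equal(round_half_up(c(0.25, -0.25, 2.849)), c(0.3, -0.3, 2.8))
})

test_that("permuted labels drive both rates to chance equality", {
  s <- small_session()
  fe <- session_features(s)
  diffs <- numeric(10)
  set.seed(33)
  for (i in 1:10) {
    fe$label <- sample(fe$label)
    cv <- cross_validate(fe, classifier_spec("ls_svm"))
    diffs[i] <- mean(cv$tpr) - mean(cv$fpr)
  }
  expect_lt(abs(mean(diffs)), 10)
})
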
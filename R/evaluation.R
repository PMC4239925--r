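## Leave-one-run-out cross-validation and the benchmark report.
##
## Each recording run is one fold: a classifier is trained on the epochs of
## the other runs and tested on the held-out run. Detection quality per fold:
##   TPR = 100 * (pre-movement epochs detected as pre-movement) / (all pre-movement)
##   FPR = 100 * (rest epochs detected as pre-movement) / (all rest)
## and the combined index GAP = mean TPR / mean FPR (should exceed 1; the
## larger the better).

#' Detection rates from predictions and reference labels
#'
#' @param predictions Predicted labels (`pre_movement`/`rest` or +/-1).
#' @param labels Reference labels.
#' @param fold_id Identifier stored with the result.
#' @return One-row data frame: `fold_id`, counts `tp`, `fn`, `fp`, `tn`,
#'   and percentages `tpr`, `fpr` (`NA` when a class is absent).
#' @export
compute_rates <- function(predictions, labels, fold_id = "fold1") {
  p <- .encode_labels(predictions)
  y <- .encode_labels(labels)
  stopifnot(length(p) == length(y))
  tp <- sum(p == 1 & y == 1); fn <- sum(p == -1 & y == 1)
  fp <- sum(p == 1 & y == -1); tn <- sum(p == -1 & y == -1)
  data.frame(fold_id = fold_id, tp = tp, fn = fn, fp = fp, tn = tn,
             tpr = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
             fpr = if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_)
}

# z-scoring fit on the training fold only (no leakage)
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
.apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, `/`)

#' Leave-one-run-out cross-validation of one classifier
#'
#' Every run identifier in the feature table becomes one test fold; the
#' classifier is trained on all epochs of the remaining runs. Optional
#' per-feature z-scoring is fitted on the training folds only.
#'
#' @param features Feature table from [epoch_features()] (or
#'   [session_features()]): metadata columns plus numeric feature columns.
#' @param spec A [classifier_spec()].
#' @param normalize Z-score features within each fold's training set
#'   (default `FALSE`).
#' @return Data frame of per-fold rates as in [compute_rates()], one row per
#'   run, plus the epoch counts. A test fold missing one class yields `NA`
#'   for the corresponding rate (with a warning).
#' @export
cross_validate <- function(features, spec, normalize = FALSE) {
  runs <- unique(features$run_id)
  if (length(runs) < 2) stop("cross-validation needs at least 2 runs")
  fcols <- .feature_cols(features)
  X <- as.matrix(features[, fcols, drop = FALSE])
  y <- features$label
  out <- NULL
  for (r in runs) {
    te <- features$run_id == r
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (normalize) {
      sc <- .fit_scaler(Xtr)
      Xtr <- .apply_scaler(Xtr, sc)
      Xte <- .apply_scaler(Xte, sc)
    }
    model <- train_classifier(Xtr, y[!te], spec)
    rates <- compute_rates(predict(model, Xte), y[te], fold_id = r)
    if (anyNA(rates[, c("tpr", "fpr")])) {
      warning("fold ", r, ": one class absent; rate undefined")
    }
    out <- rbind(out, rates)
  }
  out
}

#' Round half away from zero
#'
#' Report-table rounding convention (`0.25 -> 0.3`), unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate per-fold rates into the benchmark summary
#'
#' Per classifier and subject: mean and sd of TPR and FPR over folds and
#' GAP = mean TPR / mean FPR. The all-users row uses the conventions of the
#' published six-subject benchmark: unweighted mean of per-subject means, of
#' per-subject sds, and of per-subject GAPs (not the ratio of the pooled
#' means). A subject with zero mean FPR has infinite GAP; it is excluded
#' from the all-users GAP with a warning.
#'
#' @param folds Data frame with columns `classifier`, `subject`, `tpr`,
#'   `fpr` (one row per fold; see [cross_validate()]).
#' @return List with `per_subject` and `all_users` data frames (unrounded).
#' @export
summarize_benchmark <- function(folds) {
  stopifnot(all(c("classifier", "subject", "tpr", "fpr") %in% colnames(folds)))
  agg <- function(df) {
    data.frame(tpr_mean = mean(df$tpr, na.rm = TRUE),
               tpr_sd = stats::sd(df$tpr[!is.na(df$tpr)]),
               fpr_mean = mean(df$fpr, na.rm = TRUE),
               fpr_sd = stats::sd(df$fpr[!is.na(df$fpr)]))
  }
  keys <- unique(folds[, c("classifier", "subject")])
  per <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- folds$classifier == keys$classifier[i] &
      folds$subject == keys$subject[i]
    cbind(keys[i, , drop = FALSE], agg(folds[sel, ]))
  }))
  per$gap <- ifelse(per$fpr_mean > 0, per$tpr_mean / per$fpr_mean, Inf)
  if (any(!is.finite(per$gap))) {
    warning("zero FPR: infinite GAP excluded from the all-users average")
  }
  rownames(per) <- NULL
  all_users <- do.call(rbind, lapply(unique(per$classifier), function(cl) {
    p <- per[per$classifier == cl, ]
    data.frame(classifier = cl,
               tpr_mean = mean(p$tpr_mean), tpr_sd = mean(p$tpr_sd),
               fpr_mean = mean(p$fpr_mean), fpr_sd = mean(p$fpr_sd),
               gap = mean(p$gap[is.finite(p$gap)]))
  }))
  list(per_subject = per, all_users = all_users)
}

#' One-way ANOVA on classifier metrics
#'
#' Classic equal-variance one-way analysis of variance ([stats::oneway.test]
#' with `var.equal = TRUE`), used to test whether a metric differs between
#' classifiers.
#'
#' @param values Numeric observations (e.g. per-subject mean rates).
#' @param groups Grouping factor (e.g. classifier), one per observation.
#' @return List with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}

#' Pairwise two-group ANOVAs between classifiers
#'
#' Runs a two-group one-way ANOVA for every unordered classifier pair, with
#' no multiple-testing correction (matching the published uncorrected
#' comparison table).
#'
#' @param values Numeric observations.
#' @param groups Grouping factor with >= 2 levels.
#' @return Upper-triangular matrix of p-values (rows/columns = classifiers,
#'   `NA` on and below the diagonal).
#' @export
pairwise_anova <- function(values, groups) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  lv <- levels(groups)
  m <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(length(lv) - 1)) {
    for (j in (i + 1):length(lv)) {
      sel <- groups %in% lv[c(i, j)]
      m[i, j] <- one_way_anova(values[sel], droplevels(groups[sel]))$p
    }
  }
  m
}

#' ANOVA report for a benchmark
#'
#' Omnibus and pairwise comparisons of TPR and FPR across classifiers. The
#' observation unit is the per-subject fold-mean rate (one value per subject
#' and classifier); with a single subject it falls back to the per-fold
#' rates, the only replication available.
#'
#' @param x Result of [benchmark_session()] (list with `folds` and
#'   `summary`) or of [summarize_benchmark()].
#' @return List with `tpr` and `fpr`, each holding the omnibus `F`/`p`/dfs,
#'   the `pairwise` p-value matrix, and the observation `unit` used.
#' @export
anova_report <- function(x) {
  summary <- if (!is.null(x$summary)) x$summary else x
  per <- summary$per_subject
  if (length(unique(per$subject)) >= 2) {
    obs <- per
    obs$tpr <- obs$tpr_mean
    obs$fpr <- obs$fpr_mean
    unit <- "per-subject fold mean"
  } else {
    if (is.null(x$folds)) {
      stop("single subject: per-fold rates needed; pass the ",
           "benchmark_session() result")
    }
    obs <- x$folds
    unit <- "per-fold rate"
  }
  one <- function(v) c(one_way_anova(v, obs$classifier),
                       list(pairwise = pairwise_anova(v, obs$classifier),
                            unit = unit))
  list(tpr = one(obs$tpr), fpr = one(obs$fpr))
}

#' Write the benchmark report to disk
#'
#' Emits a benchmark table shaped like the published six-subject comparison
#' (rows = classifier x metric, columns = subjects then "AllUsers";
#' `mean±sd` to one decimal, GAP to one decimal, rounding half away from
#' zero), the pairwise p-value matrix to three decimals, and a
#' machine-readable JSON with the unrounded numbers.
#'
#' @param summary Result of [summarize_benchmark()].
#' @param anova Optional result of [anova_report()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"benchmark"`).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(summary, anova = NULL, dir = ".",
                          prefix = "benchmark") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- summary$per_subject
  subjects <- unique(per$subject)
  classifiers <- unique(per$classifier)
  fmt_ms <- function(m, s) sprintf("%.1f±%.1f", round_half_up(m),
                                   round_half_up(s))
  rows <- list()
  for (cl in classifiers) {
    p <- per[per$classifier == cl, ][match(subjects,
                                           per$subject[per$classifier == cl]), ]
    a <- summary$all_users[summary$all_users$classifier == cl, ]
    rows[[length(rows) + 1]] <- c(cl, "TPR", fmt_ms(p$tpr_mean, p$tpr_sd),
                                  fmt_ms(a$tpr_mean, a$tpr_sd))
    rows[[length(rows) + 1]] <- c(cl, "FPR", fmt_ms(p$fpr_mean, p$fpr_sd),
                                  fmt_ms(a$fpr_mean, a$fpr_sd))
    rows[[length(rows) + 1]] <- c(cl, "GAP",
                                  sprintf("%.1f", round_half_up(p$gap)),
                                  sprintf("%.1f", round_half_up(a$gap)))
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("Method", "Metric", subjects, "AllUsers")
  paths <- file.path(dir, paste0(prefix, c("_table.tsv", "_anova.tsv",
                                           ".json")))
  utils::write.table(tab, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(anova)) {
    pm <- round(anova$fpr$pairwise, 3)
    utils::write.table(cbind(classifier = rownames(pm), as.data.frame(pm)),
                       paths[2], sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "X")
  }
  payload <- list(per_subject = summary$per_subject,
                  all_users = summary$all_users)
  if (!is.null(anova)) {
    payload$anova <- list(
      tpr = list(F = anova$tpr$F, p = anova$tpr$p),
      fpr = list(F = anova$fpr$F, p = anova$fpr$p,
                 pairwise = anova$fpr$pairwise))
  }
  jsonlite::write_json(payload, paths[3], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(paths[c(TRUE, !is.null(anova), TRUE)])
}
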
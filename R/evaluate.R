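# Metric protocol: lesion-level confusion metrics over the three score
# classes, existence/abnormality ROC curves, F1-maximizing decision
# thresholds, percentile-bootstrap confidence intervals, stratified
# splitting with largest-remainder allocation, and the hierarchical
# (lesion / feature / phantom) evaluation report.

#' Multiclass confusion metrics over score classes
#'
#' @param truth,pred numeric vectors with values in \{0, 0.5, 1\}
#' @return list with `confusion` (3 x 3, rows = truth), `accuracy`,
#'   `per_class` (precision/recall/F1 per class, zero-division reported as
#'   0 with a flag), and `macro_f1`
#' @export
confusion_metrics <- function(truth, pred) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(pred)) stop("length mismatch")
  lv <- c(0, 0.5, 1)
  if (!all(truth %in% lv) || !all(pred %in% lv))
    stop("labels must be 0, 0.5 or 1")
  ft <- factor(truth, levels = lv); fp <- factor(pred, levels = lv)
  cm <- table(truth = ft, pred = fp)
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(seq_along(lv), function(i) {
    tp <- cm[i, i]
    prec_den <- sum(cm[, i]); rec_den <- sum(cm[i, ])
    precision <- if (prec_den > 0) tp / prec_den else 0
    recall <- if (rec_den > 0) tp / rec_den else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    list(class = lv[i], precision = precision, recall = recall, f1 = f1,
         support = rec_den,
         zero_division = prec_den == 0 || rec_den == 0)
  })
  names(per) <- paste0("score_", lv)
  list(confusion = unclass(cm), accuracy = acc, per_class = per,
       macro_f1 = mean(vapply(per, `[[`, 0, "f1")))
}

#' @keywords internal
roc_curve <- function(score, label) {
  # threshold sweep over unique scores; returns monotone (fpr, tpr) points
  # and the trapezoidal AUC
  np <- sum(label == 1); nn <- sum(label == 0)
  if (np == 0 || nn == 0)
    stop("ROC undefined: both classes must be present")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- label[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tpr <- c(0, tp[keep] / np); fpr <- c(0, fp[keep] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr,
       thresholds = c(Inf, s[keep]), auc = auc)
}

#' ROC curve and AUC for lesion existence
#'
#' Tiles scored 1.0 or 0.5 are positives (a lesion is present), 0.0 tiles
#' are negatives; the sweep runs over `p_exist`.
#'
#' @param preds data frame with `p_exist`, `p_abnormal` (as returned by
#'   [predict.phantom_scorer()])
#' @param truths numeric scores in \{0, 0.5, 1\}
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`
#' @export
roc_existence <- function(preds, truths) {
  if (!nrow(preds) || !length(truths)) stop("empty input")
  label <- as.integer(truths %in% c(0.5, 1))
  roc_curve(preds$p_exist, label)
}

#' ROC curve and AUC for lesion abnormality
#'
#' Restricted to tiles whose true score is 0.5 or 1.0 (0.0 tiles provide
#' no basis for abnormality and are excluded); 0.5 is the positive class,
#' the sweep runs over `p_abnormal`.
#'
#' @inheritParams roc_existence
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`
#' @export
roc_abnormality <- function(preds, truths) {
  keep <- truths %in% c(0.5, 1)
  if (!any(keep)) stop("no tiles left after excluding 0.0 scores")
  roc_curve(preds$p_abnormal[keep], as.integer(truths[keep] == 0.5))
}

#' @keywords internal
best_f1_threshold <- function(score, label) {
  # candidates: below the minimum, between consecutive unique scores
  u <- sort(unique(score))
  cand <- c(u[1] - 1e-6, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)
  f1 <- vapply(cand, function(t) {
    p <- score >= t
    tp <- sum(p & label == 1)
    if (tp == 0) return(0)
    prec <- tp / sum(p); rec <- tp / sum(label == 1)
    2 * prec * rec / (prec + rec)
  }, 0)
  list(threshold = cand[which.max(f1)], f1 = max(f1))  # ties: smallest
}

#' F1-maximizing decision thresholds for both outputs
#'
#' The existence threshold maximizes the binary F1 of lesion presence over
#' all tiles; the abnormality threshold maximizes the F1 of 0.5 detection
#' among tiles scored 0.5/1.0. Ties resolve to the smallest threshold;
#' degenerate inputs (a single class for an output) fall back to 0.5 with
#' a warning.
#'
#' @inheritParams roc_existence
#' @return list with `t_exist`, `t_abnormal` and the achieved F1s
#' @export
pick_thresholds <- function(preds, truths) {
  lab_e <- as.integer(truths %in% c(0.5, 1))
  keep <- truths %in% c(0.5, 1)
  lab_a <- as.integer(truths[keep] == 0.5)
  out <- list(t_exist = 0.5, t_abnormal = 0.5,
              f1_exist = NA_real_, f1_abnormal = NA_real_)
  if (length(unique(lab_e)) == 2) {
    r <- best_f1_threshold(preds$p_exist, lab_e)
    out$t_exist <- r$threshold; out$f1_exist <- r$f1
  } else warning("existence labels degenerate; threshold defaults to 0.5")
  if (length(unique(lab_a)) == 2) {
    r <- best_f1_threshold(preds$p_abnormal[keep], lab_a)
    out$t_abnormal <- r$threshold; out$f1_abnormal <- r$f1
  } else warning("abnormality labels degenerate; threshold defaults to 0.5")
  out
}

#' Percentile bootstrap confidence interval
#'
#' Resamples cases (with replacement) and recomputes the metric; returns
#' the percentile interval. Resamples on which the metric is undefined
#' (error or NA) are redrawn and counted.
#'
#' @param metric_fn function(indices) -> scalar, evaluated on a resample
#'   of `seq_len(n)`
#' @param n number of cases to resample
#' @param resamples number of bootstrap resamples
#' @param level confidence level
#' @param seed RNG seed
#' @return list with `low`, `high`, `point` (metric on the full sample),
#'   `redrawn` (count of redrawn resamples)
#' @export
bootstrap_ci <- function(metric_fn, n, resamples = 10000, level = 0.95,
                         seed = 1L) {
  if (n < 1) stop("empty data")
  point <- metric_fn(seq_len(n))
  vals <- numeric(resamples)
  redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(resamples)) {
      repeat {
        v <- tryCatch(metric_fn(sample.int(n, n, replace = TRUE)),
                      error = function(e) NA_real_)
        if (!is.na(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100 * resamples) stop("metric undefined on most resamples")
      }
      vals[b] <- v
    }
  })
  a <- (1 - level) / 2
  q <- stats::quantile(vals, c(a, 1 - a), names = FALSE)
  list(low = q[1], high = q[2], point = point, redrawn = redrawn)
}

#' Stratified split with largest-remainder allocation
#'
#' Allocates each stratum across the subsets by rounding fraction x size
#' down and assigning the remaining units to the largest fractional
#' remainders, so the allocations of every stratum sum exactly to its
#' size; assignment within a stratum is randomized by seed.
#'
#' @param sizes named integer vector of stratum sizes (e.g. pass/fail)
#' @param fractions numeric vector summing to 1 (e.g. train/test/eval)
#' @param seed RNG seed for within-stratum shuffling
#' @return object of class `split_assignment`: `counts` (strata x subsets
#'   matrix) and `assignment` (per stratum, a subset index for each unit)
#' @export
stratified_split <- function(sizes, fractions = c(train = 0.7, test = 0.1,
                                                  eval = 0.2), seed = 1L) {
  if (any(sizes < 0)) stop("negative stratum sizes")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  counts <- t(vapply(sizes, function(nz) {
    exact <- fractions * nz
    base <- floor(exact)
    rem <- nz - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    base
  }, numeric(length(fractions))))
  colnames(counts) <- names(fractions)
  rownames(counts) <- names(sizes)
  assignment <- with_seed(seed, lapply(seq_along(sizes), function(i) {
    lab <- rep(seq_along(fractions), counts[i, ])
    sample(lab)
  }))
  names(assignment) <- names(sizes)
  structure(list(counts = counts, assignment = assignment,
                 fractions = fractions, seed = seed),
            class = "split_assignment")
}

#' Hierarchical evaluation of a scorer on a labelled dataset
#'
#' Scores every tile of every phantom, then reports lesion-level confusion
#' metrics per lesion type (with macro-F1), existence/abnormality ROC and
#' AUC when dual probabilities are available, F1-maximizing thresholds,
#' and feature- and phantom-level pass/fail precision/recall/accuracy.
#'
#' @param scorer either a `phantom_scorer` (dual probabilities, decoded
#'   via its thresholds) or a function mapping a `subimage` to a score
#' @param dataset list of cases, each a list with `subs` (16 subimages)
#'   and `truth` (16 numeric scores, NA allowed; NA tiles are excluded
#'   from lesion-level metrics)
#' @param layout layout map
#' @param bootstrap_resamples resamples for the macro-F1 CI (0 disables)
#' @param seed seed for the bootstrap
#' @return object of class `phantom_eval_report`
#' @export
evaluate_system <- function(scorer, dataset, layout = phantom_layout(),
                            bootstrap_resamples = 0, seed = 1L) {
  if (!length(dataset)) stop("empty dataset")
  is_dual <- inherits(scorer, "phantom_scorer")
  per_case <- lapply(dataset, function(case) {
    if (is_dual) {
      pr <- predict.phantom_scorer(scorer, case$subs)
      dec <- vapply(seq_len(nrow(pr)), function(i)
        decode_prediction(list(p_exist = pr$p_exist[i],
                               p_abnormal = pr$p_abnormal[i]),
                          scorer$thresholds), 0)
      list(pred = dec, prob = pr, truth = case$truth)
    } else {
      list(pred = vapply(case$subs, scorer, 0), prob = NULL,
           truth = case$truth)
    }
  })
  types <- layout$cells$lesion_type
  lesion_level <- lapply(c("fiber", "specks", "mass"), function(tp) {
    sel <- which(types == tp)
    tr <- unlist(lapply(per_case, function(x) x$truth[sel]))
    pd <- unlist(lapply(per_case, function(x) x$pred[sel]))
    keep <- !is.na(tr) & !is.na(pd)
    cm <- confusion_metrics(tr[keep], pd[keep])
    if (bootstrap_resamples > 0) {
      trk <- tr[keep]; pdk <- pd[keep]
      ci <- bootstrap_ci(function(idx)
        confusion_metrics(trk[idx], pdk[idx])$macro_f1,
        n = sum(keep), resamples = bootstrap_resamples, seed = seed)
      cm$macro_f1_ci <- c(ci$low, ci$high)
    }
    cm
  })
  names(lesion_level) <- c("fiber", "specks", "mass")
  roc <- NULL; thresholds <- NULL
  if (is_dual) {
    allprob <- do.call(rbind, lapply(per_case, `[[`, "prob"))
    alltruth <- unlist(lapply(per_case, `[[`, "truth"))
    keep <- !is.na(alltruth)
    roc <- list(
      existence = tryCatch(roc_existence(allprob[keep, ], alltruth[keep]),
                           error = function(e) NULL),
      abnormality = tryCatch(roc_abnormality(allprob[keep, ], alltruth[keep]),
                             error = function(e) NULL))
    thresholds <- tryCatch(
      suppressWarnings(pick_thresholds(allprob[keep, ], alltruth[keep])),
      error = function(e) NULL)
  }
  binary_metrics <- function(tr, pd) {
    tp <- sum(tr & pd); fp <- sum(!tr & pd); fn <- sum(tr & !pd)
    list(accuracy = mean(tr == pd),
         precision = if (tp + fp > 0) tp / (tp + fp) else 0,
         recall = if (tp + fn > 0) tp / (tp + fn) else 0)
  }
  feat_truth <- vapply(per_case, function(x)
    vapply(qualify_phantom(x$truth, layout)$per_feature, `[[`, TRUE,
           "passed"), logical(3))
  feat_pred <- vapply(per_case, function(x)
    vapply(qualify_phantom(x$pred, layout)$per_feature, `[[`, TRUE,
           "passed"), logical(3))
  feature_level <- lapply(1:3, function(i)
    binary_metrics(feat_truth[i, ], feat_pred[i, ]))
  names(feature_level) <- rownames(feat_truth)
  phantom_level <- binary_metrics(apply(feat_truth, 2, all),
                                  apply(feat_pred, 2, all))
  structure(list(lesion_level = lesion_level, roc = roc,
                 thresholds = thresholds, feature_level = feature_level,
                 phantom_level = phantom_level, n_cases = length(dataset)),
            class = "phantom_eval_report")
}

#' @export
print.phantom_eval_report <- function(x, ...) {
  cat("<phantom_eval_report>", x$n_cases, "cases\n")
  for (tp in names(x$lesion_level)) {
    ll <- x$lesion_level[[tp]]
    cat(sprintf("  %-6s accuracy %.4f  macro-F1 %.4f\n", tp, ll$accuracy,
                ll$macro_f1))
  }
  if (!is.null(x$roc) && !is.null(x$roc$existence))
    cat(sprintf("  AUC existence %.4f", x$roc$existence$auc))
  if (!is.null(x$roc) && !is.null(x$roc$abnormality))
    cat(sprintf("  abnormality %.4f", x$roc$abnormality$auc))
  if (!is.null(x$roc)) cat("\n")
  cat(sprintf("  phantom-level accuracy %.4f\n", x$phantom_level$accuracy))
  invisible(x)
}
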
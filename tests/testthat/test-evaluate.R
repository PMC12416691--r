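test_that("confusion metrics match a hand-computed 12-sample example", {
  truth <- c(1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0, 0, 0, 0)
  pred  <- c(1, 1, 1, 0.5, 0, 0.5, 0.5, 1, 0, 0, 0.5, 0)
  cm <- confusion_metrics(truth, pred)
  expect_equal(cm$accuracy, 8 / 12)
  expect_equal(cm$confusion["1", "1"], 3)
  expect_equal(cm$confusion["0.5", "1"], 1)
  # hand-computed per-class precision/recall
  expect_equal(cm$per_class$score_1$precision, 3 / 4)
  expect_equal(cm$per_class$score_1$recall, 3 / 5)
  expect_equal(cm$per_class$score_0.5$precision, 2 / 4)
  expect_equal(cm$per_class$score_0.5$recall, 2 / 3)
  expect_equal(cm$per_class$score_0$precision, 3 / 4)
  expect_equal(cm$per_class$score_0$recall, 3 / 4)
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(cm$macro_f1,
               mean(c(f1(3/4, 3/4), f1(2/4, 2/3), f1(3/4, 3/5))))
  # trace / total equals accuracy by construction
  expect_equal(sum(diag(cm$confusion)) / sum(cm$confusion), cm$accuracy)
  # identity predictions: everything perfect
  cmp <- confusion_metrics(truth, truth)
  expect_equal(cmp$accuracy, 1)
  expect_equal(cmp$macro_f1, 1)
  # degenerate single-class predictions: zero-division flagged as 0
  cm0 <- confusion_metrics(truth, rep(1, 12))
  expect_equal(cm0$per_class$score_1$recall, 1)
  expect_equal(cm0$per_class$score_0$precision, 0)
  expect_true(cm0$per_class$score_0$zero_division)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
  expect_error(confusion_metrics(c(0.2), c(1)), "labels")
})

test_that("AUC equals the concordant-pair (Mann-Whitney) count on small instances", {
  # 6-point hand example with a tie
  pred <- data.frame(p_exist = c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2),
                     p_abnormal = 0.5)
  truth <- c(1, 0.5, 0, 1, 0, 0)
  r <- roc_existence(pred, truth)
  mw <- function(score, label) {
    pos <- score[label == 1]; neg <- score[label == 0]
    pr <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pr)
  }
  expect_equal(r$auc, mw(pred$p_exist, as.integer(truth %in% c(0.5, 1))))
  # random small instances, exhaustive pairing
  set.seed(14)
  for (k in 1:25) {
    n <- sample(4:20, 1)
    sc <- round(runif(n), 2)
    lb <- sample(c(0, 0.5, 1), n, replace = TRUE)
    if (length(unique(lb %in% c(0.5, 1))) < 2) next
    p <- data.frame(p_exist = sc, p_abnormal = 0)
    expect_equal(roc_existence(p, lb)$auc,
                 mw(sc, as.integer(lb %in% c(0.5, 1))))
  }
  # cross-check against an independent ROC implementation
  set.seed(15)
  sc <- runif(60); lb <- sample(c(0, 1), 60, replace = TRUE)
  p <- data.frame(p_exist = sc, p_abnormal = 0)
  expect_equal(roc_existence(p, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("existence ROC separates perfect scorers and is 0.5 under the null", {
  p <- data.frame(p_exist = c(0.9, 0.8, 0.7, 0.2, 0.1), p_abnormal = 0)
  t <- c(1, 1, 0.5, 0, 0)
  expect_equal(roc_existence(p, t)$auc, 1)
  set.seed(2)
  n <- 2000
  pn <- data.frame(p_exist = runif(n), p_abnormal = 0)
  tn <- sample(c(0, 1), n, replace = TRUE)
  expect_lt(abs(roc_existence(pn, tn)$auc - 0.5), 0.03)
  expect_error(roc_existence(pn, rep(1, n)), "both classes")
})

test_that("abnormality ROC excludes 0.0-scored tiles and 0.5 is positive", {
  p <- data.frame(p_exist = 0.9,
                  p_abnormal = c(0.9, 0.8, 0.2, 0.1, 0.99, 0.97))
  t <- c(0.5, 0.5, 1, 1, 0, 0)
  r <- roc_abnormality(p, t)
  expect_equal(r$auc, 1)  # 0.0 tiles (highest p_abnormal) are excluded
  # adding 0.0-labelled tiles never changes the curve
  p2 <- rbind(p, data.frame(p_exist = 0.5, p_abnormal = runif(10)))
  t2 <- c(t, rep(0, 10))
  r2 <- roc_abnormality(p2, t2)
  expect_identical(r[c("fpr", "tpr", "auc")], r2[c("fpr", "tpr", "auc")])
  expect_error(roc_abnormality(data.frame(p_exist = 1, p_abnormal = 1), 0),
               "no tiles left")
})

test_that("F1-maximizing thresholds match an exhaustive scan", {
  p <- data.frame(p_exist = c(0.95, 0.9, 0.7, 0.65, 0.5, 0.3, 0.2, 0.1),
                  p_abnormal = c(0.9, 0.2, 0.8, 0.3, 0.7, 0.6, 0.4, 0.1))
  t <- c(1, 1, 0.5, 1, 0, 0.5, 0, 0)
  th <- pick_thresholds(p, t)
  # brute force over a fine grid
  brute <- function(score, label) {
    grid <- seq(0, 1, by = 1e-3)
    f1 <- vapply(grid, function(x) {
      pr <- score >= x
      tp <- sum(pr & label == 1)
      if (tp == 0) return(0)
      prec <- tp / sum(pr); rec <- tp / sum(label == 1)
      2 * prec * rec / (prec + rec)
    }, 0)
    max(f1)
  }
  expect_equal(th$f1_exist, brute(p$p_exist, as.integer(t %in% c(0.5, 1))))
  keep <- t %in% c(0.5, 1)
  expect_equal(th$f1_abnormal,
               brute(p$p_abnormal[keep], as.integer(t[keep] == 0.5)))
  # perfectly separated: returns a threshold inside the gap (smallest tie)
  ps <- data.frame(p_exist = c(0.9, 0.8, 0.2, 0.1), p_abnormal = 0.5)
  ts <- c(1, 1, 0, 0)
  th2 <- suppressWarnings(pick_thresholds(ps, ts))
  expect_gt(th2$t_exist, 0.2)
  expect_lte(th2$t_exist, 0.5)
  expect_equal(th2$f1_exist, 1)
  # degenerate labels fall back to 0.5 with a warning per output
  w <- capture_warnings(th3 <- pick_thresholds(ps, c(1, 1, 1, 1)))
  expect_length(w, 2)
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(th3$t_exist, 0.5)
})

test_that("bootstrap intervals are seeded, contain the point, and match theory", {
  # constant metric: zero-width interval
  ci <- bootstrap_ci(function(idx) 1, n = 30, resamples = 200, seed = 3)
  expect_equal(ci$low, 1); expect_equal(ci$high, 1)
  # sample mean of normal draws: width close to the t-interval
  set.seed(10)
  x <- rnorm(100)
  ci2 <- bootstrap_ci(function(idx) mean(x[idx]), n = 100,
                      resamples = 4000, seed = 4)
  tw <- 2 * qt(0.975, 99) * sd(x) / sqrt(100)
  expect_lt(abs((ci2$high - ci2$low) - tw) / tw, 0.15)
  expect_gte(ci2$point, ci2$low)
  expect_lte(ci2$point, ci2$high)
  # same seed, same interval
  ci3 <- bootstrap_ci(function(idx) mean(x[idx]), n = 100,
                      resamples = 4000, seed = 4)
  expect_identical(ci2, ci3)
  # undefined resamples are redrawn and counted
  flaky <- function(idx) if (idx[1] %% 5 == 0) NA_real_ else mean(x[idx])
  ci4 <- bootstrap_ci(flaky, n = 100, resamples = 300, seed = 5)
  expect_gte(ci4$redrawn, 1)
})

test_that("stratified split uses largest-remainder rounding and conserves strata", {
  # the 70/10/20 split of a 4029/1784 pass-fail corpus
  sp <- stratified_split(c(pass = 4029, fail = 1784),
                         c(train = 0.7, test = 0.1, eval = 0.2), seed = 1)
  expect_equal(sp$counts["pass", ], c(train = 2820, test = 403, eval = 806))
  expect_equal(sp$counts["fail", ], c(train = 1249, test = 178, eval = 357))
  expect_equal(rowSums(sp$counts), c(pass = 4029, fail = 1784))
  expect_equal(table(sp$assignment$pass)[["1"]], 2820)
  # everything into the first subset under fractions (1, 0, 0)
  sp1 <- stratified_split(c(a = 57), c(1, 0, 0), seed = 2)
  expect_equal(unname(sp1$counts[1, ]), c(57, 0, 0))
  # conservation and near-exact global proportions on random inputs
  set.seed(6)
  for (k in 1:20) {
    sizes <- sample(1000:5000, 3)
    sp2 <- stratified_split(sizes, c(0.7, 0.1, 0.2), seed = k)
    expect_equal(unname(rowSums(sp2$counts)), sizes)
    glob <- colSums(sp2$counts) / sum(sizes)
    expect_true(all(abs(glob - c(0.7, 0.1, 0.2)) < 0.001))
  }
  expect_error(stratified_split(c(-1, 5), c(0.5, 0.5)), "negative")
  expect_error(stratified_split(c(10, 5), c(0.5, 0.4)), "sum to 1")
})

test_that("system evaluation is exact for the rule scorer on noiseless renders", {
  lay <- test_layout(); calib <- test_calib()
  # fully-visible-or-absent lesions: labels are unambiguous by construction
  dist <- sampling_distribution(p_full = 0.85, p_absent = 0.15)
  specs <- sample_specs(10, dist, seed = 21, noise_sigma = 0, layout = lay)
  dataset <- lapply(specs, function(s) {
    std <- run_pipeline(render_phantom(s, lay)$image)
    truth <- vapply(s$lesions, derive_guideline_score, 0, layout = lay)
    list(subs = split_grid(std, lay), truth = truth)
  })
  rep1 <- evaluate_system(rules_scorer(layout = lay, calib = calib),
                          dataset, lay)
  for (tp in c("fiber", "specks", "mass"))
    expect_equal(rep1$lesion_level[[tp]]$accuracy, 1)
  expect_equal(rep1$phantom_level$accuracy, 1)
  expect_output(print(rep1), "phantom-level accuracy 1")
  expect_error(evaluate_system(rules_scorer(), list()), "empty")
})

test_that("a truth-blind scorer scores near the phantom-level base rate", {
  lay <- test_layout()
  set.seed(8)
  specs <- sample_specs(40, seed = 22, layout = lay)
  dataset <- lapply(specs, function(s) {
    truth <- vapply(s$lesions, derive_guideline_score, 0, layout = lay)
    list(subs = split_grid(matrix(0, 224, 224), lay), truth = truth)
  })
  # scorer ignores the tile entirely: always the majority label
  rep0 <- evaluate_system(function(sub) 1, dataset, lay)
  base <- mean(vapply(dataset, function(d)
    qualify_phantom(d$truth, lay)$qualified, TRUE))
  expect_equal(rep0$phantom_level$recall, 1)
  expect_equal(rep0$phantom_level$accuracy, base)
})
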
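# Feature-level pass thresholds of the national QA criteria: a phantom
# qualifies when at least the four largest fibers, three largest speck
# groups and three largest masses are clearly visualized.
.feature_thresholds <- c(fiber = 4.0, specks = 3.0, mass = 3.0)
.feature_lengths <- c(fiber = 6L, specks = 5L, mass = 5L)

#' Sequential feature total and pass flag
#'
#' Walks the lesions of one feature from the largest (rank 1) downward:
#' every consecutive 1.0 adds a full point; the first lesion that does not
#' score 1.0 contributes its own value (N/A contributes `na_value`) and
#' stops the walk — smaller lesions are ignored during qualification.
#'
#' @param scores numeric vector ordered by rank (largest first), length 6
#'   for fibers, 5 for specks/masses; entries in \{0, 0.5, 1, NA\}
#' @param lesion_type "fiber", "specks" or "mass"
#' @param na_value contribution of an N/A at the stopping position
#'   (default 0; 0.5 available for sensitivity analysis)
#' @return object of class `feature_result`: list with `lesion_type`,
#'   `total`, `contributing_ranks` and `passed`
#' @export
feature_total <- function(scores, lesion_type, na_value = 0) {
  lesion_type <- match.arg(lesion_type, names(.feature_lengths))
  if (length(scores) != .feature_lengths[[lesion_type]])
    stop("expected ", .feature_lengths[[lesion_type]], " scores for ",
         lesion_type)
  ok <- is.na(scores) | scores %in% c(0, 0.5, 1)
  if (!all(ok)) stop("scores must be 0, 0.5, 1 or NA")
  total <- 0; contributing <- integer(0)
  for (i in seq_along(scores)) {
    contributing <- c(contributing, i)
    s <- scores[i]
    if (!is.na(s) && s == 1) { total <- total + 1; next }
    total <- total + if (is.na(s)) na_value else s
    break
  }
  structure(list(lesion_type = lesion_type, total = total,
                 contributing_ranks = contributing,
                 passed = total >= .feature_thresholds[[lesion_type]]),
            class = "feature_result")
}

#' Phantom-level qualification from 16 lesion scores
#'
#' Computes the three sequential feature totals and the overall verdict:
#' the phantom qualifies iff the fiber total is at least 4.0 and the speck
#' and mass totals are each at least 3.0. A phantom is disqualified if any
#' of its features is disqualified.
#'
#' @param scores numeric vector of 16 lesion scores in grid-cell order, or
#'   a named list with components `fiber`, `specks`, `mass`
#' @param layout layout map giving the cell-to-lesion assignment
#' @param na_value see [feature_total()]
#' @return object of class `qualification_result`: `per_feature` (list of
#'   three `feature_result`) and `qualified`
#' @export
qualify_phantom <- function(scores, layout = phantom_layout(), na_value = 0) {
  if (is.list(scores) && !is.null(scores$fiber)) {
    by_type <- scores[c("fiber", "specks", "mass")]
  } else {
    scores <- unlist(scores)
    if (length(scores) != 16) stop("expected 16 lesion scores")
    by_type <- lapply(c("fiber", "specks", "mass"), function(tp) {
      sel <- layout$cells$lesion_type == tp
      scores[layout$cells$cell[sel]][order(layout$cells$rank[sel])]
    })
    names(by_type) <- c("fiber", "specks", "mass")
  }
  per <- lapply(names(by_type), function(tp)
    feature_total(by_type[[tp]], tp, na_value = na_value))
  names(per) <- names(by_type)
  structure(list(per_feature = per,
                 qualified = all(vapply(per, `[[`, TRUE, "passed"))),
            class = "qualification_result")
}

#' @export
print.qualification_result <- function(x, ...) {
  t3 <- vapply(x$per_feature, `[[`, 0, "total")
  cat(sprintf("fiber: %.1f  specks: %.1f  mass: %.1f  -> %s\n",
              t3[["fiber"]], t3[["specks"]], t3[["mass"]],
              if (x$qualified) "Qualified" else "Unqualified"))
  invisible(x)
}

#' Qualification with early termination of scoring
#'
#' Scores lesions feature by feature in rank order, stopping each feature
#' as soon as a lesion fails to earn a full point (its score is 0.5, 0.0 or
#' N/A); unscored smaller lesions cannot change the sequential total, so
#' the verdict is identical to scoring all 16 lesions. Useful when each
#' scorer invocation is expensive.
#'
#' @param scorer function taking a `subimage` and returning a score in
#'   \{0, 0.5, 1, NA\}
#' @param subs list of 16 `subimage` objects (grid order)
#' @param layout layout map
#' @param na_value see [feature_total()]
#' @return a `qualification_result` with an extra field `calls` (number of
#'   scorer invocations) and `scores` (16 values, NA_real_ where skipped)
#' @export
qualify_early_stop <- function(scorer, subs, layout = phantom_layout(),
                               na_value = 0) {
  if (length(subs) != 16) stop("expected 16 subimages")
  scores <- rep(NA_real_, 16)
  calls <- 0L
  by_type <- list()
  for (tp in c("fiber", "specks", "mass")) {
    sel <- layout$cells$lesion_type == tp
    cells <- layout$cells$cell[sel][order(layout$cells$rank[sel])]
    vals <- rep(NA_real_, length(cells))
    for (i in seq_along(cells)) {
      s <- scorer(subs[[cells[i]]])
      calls <- calls + 1L
      scores[cells[i]] <- s
      vals[i] <- s
      if (is.na(s) || s != 1) break
    }
    by_type[[tp]] <- vals
  }
  res <- qualify_phantom(by_type, layout = layout, na_value = na_value)
  res$calls <- calls
  res$scores <- scores
  res
}
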
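# Figures for evaluation reports: confusion heatmaps and ROC curves in
# the layout conventions of QA model reports.

#' Confusion-matrix heatmap for one lesion type
#'
#' @param cm result of [confusion_metrics()]
#' @param title plot title
#' @return a ggplot object
#' @export
plot_confusion <- function(cm, title = "Lesion score confusion") {
  m <- cm$confusion
  df <- data.frame(
    truth = factor(rep(rownames(m), times = ncol(m)),
                   levels = rev(rownames(m))),
    pred = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    n = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted score", y = "True score", title = title,
                  subtitle = sprintf("accuracy %.4f, macro-F1 %.4f",
                                     cm$accuracy, cm$macro_f1)) +
    ggplot2::theme_minimal()
}

#' Existence/abnormality ROC curves
#'
#' @param roc_exist result of [roc_existence()] (or NULL)
#' @param roc_abn result of [roc_abnormality()] (or NULL)
#' @param title plot title
#' @return a ggplot object
#' @export
plot_roc <- function(roc_exist = NULL, roc_abn = NULL,
                     title = "ROC: lesion existence and abnormality") {
  dfs <- list()
  if (!is.null(roc_exist))
    dfs$exist <- data.frame(fpr = roc_exist$fpr, tpr = roc_exist$tpr,
                            output = sprintf("existence (AUC %.3f)",
                                             roc_exist$auc))
  if (!is.null(roc_abn))
    dfs$abn <- data.frame(fpr = roc_abn$fpr, tpr = roc_abn$tpr,
                          output = sprintf("abnormality (AUC %.3f)",
                                           roc_abn$auc))
  if (!length(dfs)) stop("no ROC curve to plot")
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$output)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c("darkorange", "forestgreen")) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = title, color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Interpretation-sweep probability curves
#'
#' Solid segments mark probabilities at or above the decision threshold,
#' dotted segments below it, following the display convention of the
#' manipulation figures.
#'
#' @param sweep data frame from [interpretation_sweep()]
#' @param title plot title
#' @return a ggplot object
#' @export
plot_sweep <- function(sweep, title = "Interpretation sweep") {
  long <- rbind(
    data.frame(param = sweep$param, p = sweep$p_exist, output = "existence",
               above = sweep$above_exist),
    data.frame(param = sweep$param, p = sweep$p_abnormal,
               output = "abnormality", above = sweep$above_abnormal))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$param, y = .data$p,
                                     color = .data$output,
                                     linetype = .data$above)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$output)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dotted"),
                                   guide = "none") +
    ggplot2::scale_color_manual(values = c("darkorange", "forestgreen")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Manipulation parameter", y = "Probability",
                  title = title, color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
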
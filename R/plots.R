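# ggplot2 displays for the package's result types.

#' Plot a population graph's adjacency
#'
#' Heatmap of the weighted adjacency with subjects ordered by diagnosis,
#' so class-assortative edge functions show a block structure.
#'
#' @param object A `population_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_graph
#' @export
autoplot.population_graph <- function(object, ...) {
  ord <- order(factor(object$diagnosis, levels = c("CN", "MCI", "AD")))
  a <- object$A[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(ncol(a)))
  df$weight <- a[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0("Adjacency, ", edge_label(object$edge_spec)),
                  x = "subject (by diagnosis)", y = "subject (by diagnosis)",
                  fill = "weight") +
    ggplot2::theme_minimal()
}

#' Plot GCN training history
#'
#' Training loss and validation accuracy per epoch, with the restored
#' best epoch marked.
#'
#' @param object A `gcn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gcn_fit
#' @export
autoplot.gcn_fit <- function(object, ...) {
  df <- object$history %>%
    tidyr::pivot_longer(c("loss", "val_acc"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Tile plot with counts, rows = true class, columns = predicted class;
#' darker diagonal tiles indicate better staging.
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(rownames(object)))
  df$pred <- factor(df$pred, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true, fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot an experiment results table
#'
#' Dot-and-error-bar display of mean test accuracy (+/- SD over seeds)
#' per edge-assigning function.
#'
#' @param results The `results` tibble from an experiment runner.
#' @return A ggplot object.
#' @export
plot_experiment_results <- function(results) {
  df <- results %>% mutate(edge = factor(.data$edge, levels = rev(.data$edge)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$acc_mean, y = .data$edge)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$acc_mean - .data$acc_sd,
                                         xmax = .data$acc_mean + .data$acc_sd),
                            height = 0.2) +
    ggplot2::labs(x = "test accuracy (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot DenseNet training history
#'
#' @param object A `densenet_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot densenet_model
#' @export
autoplot.densenet_model <- function(object, ...) {
  df <- object$history %>%
    tidyr::pivot_longer(-"epoch", names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
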
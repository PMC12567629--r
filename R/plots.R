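# Optional ggplot2 conveniences; the package's numerics never depend on them.

#' Confusion-matrix heat map
#' @param ev an `irkd_eval` report.
#' @return a ggplot object.
#' @export
plot_confusion <- function(ev) {
  need_ggplot()
  df <- as.data.frame(as.table(ev$confusion))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = pred, y = true,
                                   fill = n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("accuracy %.2f%%, macro-F1 %.3f",
                                  ev$accuracy, ev$macro_f1))
}

#' Weight-interpolation accuracy curve
#' @param curve a [parametric_curve()] result.
#' @return a ggplot object.
#' @export
plot_parametric <- function(curve) {
  need_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(x = eta)) +
    ggplot2::geom_line(ggplot2::aes(y = train_acc, colour = "train")) +
    ggplot2::geom_line(ggplot2::aes(y = test_acc, colour = "test")) +
    ggplot2::labs(x = expression(eta), y = "accuracy (%)", colour = NULL)
}

#' t-SNE scatter of learned features
#' @param emb an `n x 2` embedding (see [tsne_embed()]).
#' @param labels class labels for colouring.
#' @return a ggplot object.
#' @export
plot_tsne <- function(emb, labels) {
  need_ggplot()
  df <- data.frame(x = emb[, 1], y = emb[, 2], class = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   colour = class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}
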
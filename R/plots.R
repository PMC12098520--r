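# Report figures (ggplot2, suggested dependency).

#' Plot per-fold test accuracy
#'
#' @param fold_accuracy Numeric vector of per-fold accuracies (as in the
#'   output of [aggregate_folds()]).
#' @return A ggplot object.
#' @export
plot_fold_accuracy <- function(fold_accuracy) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(fold = factor(seq_along(fold_accuracy)),
                   accuracy = fold_accuracy)
  ggplot2::ggplot(df, ggplot2::aes(x = fold, y = accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(fold_accuracy), linetype = 2) +
    ggplot2::labs(x = "Held-out subject (fold)", y = "Accuracy",
                  title = "Leave-one-subject-out test accuracy per fold") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param history Data frame from [train_fold()] (`epoch`, `l_cla`, `l_d`,
#'   `l_all`, `acc`).
#' @return A ggplot object.
#' @export
plot_training_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  keep <- c("l_cla", if (!all(is.na(history$l_d))) "l_d", "l_all")
  long <- do.call(rbind, lapply(keep, function(k)
    data.frame(epoch = history$epoch, loss = history[[k]], term = k)))
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = loss, colour = term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Training epoch", y = "Loss",
                  title = "Adversarial training losses") +
    ggplot2::theme_minimal()
}
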
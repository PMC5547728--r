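# ggplot2 displays for predictions and evaluation results.

#' @describeIn dcc_success Success rate versus cutoff distance D.
#' @param object A `nucsite_dcc`.
#' @param ... Ignored.
#' @method autoplot nucsite_dcc
#' @export
autoplot.nucsite_dcc <- function(object, ...) {
  ggplot2::ggplot(object$rates, ggplot2::aes(x = .data$D, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "cutoff distance D (Å)",
      y = "success rate",
      title = paste0("Center-distance success (", object$protocol, ")")
    )
}

#' @describeIn predict_sites Residue binding scores, top sites annotated.
#' @param object A `nucsite_prediction`.
#' @param max_residues Show at most this many top-scoring residues; default 30.
#' @param ... Ignored.
#' @method autoplot nucsite_prediction
#' @export
autoplot.nucsite_prediction <- function(object, max_residues = 30L, ...) {
  res <- head(object$residues, max_residues)
  res$label <- paste0(res$chain, res$res_num, ":", res$res_name)
  res$label <- factor(res$label, levels = rev(res$label))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$score, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "poses contacted",
      y = NULL,
      title = sprintf("Residue binding scores (%d poses, %d sites)",
                      length(object$poses), nrow(object$sites))
    )
}
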
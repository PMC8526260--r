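#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ECG leads with optional fiducial marks
#'
#' @param object An `ecg_record`.
#' @param leads Leads to draw (default `c("II", "V2")`).
#' @param fiducials Optional fiducial tibble from [delineate_record()];
#'   marked points are overlaid per lead.
#' @param window Time window in seconds (`c(from, to)`), default all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, leads = c("II", "V2"),
                                fiducials = NULL, window = NULL, ...) {
  fs <- ecg_fs(object)
  long <- tidyr::pivot_longer(object, cols = -"time",
                              names_to = "lead", values_to = "mV")
  long <- long[long$lead %in% leads, ]
  if (!is.null(window)) {
    long <- long[long$time >= window[1] & long$time <= window[2], ]
  }
  long$lead <- factor(long$lead, levels = leads)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(fiducials)) {
    fl <- fiducials[fiducials$lead %in% leads, ]
    marks <- tidyr::pivot_longer(
      fl[, c("lead", "i", "q", "r", "s", "j", "t_start", "t_peak", "t_end")],
      cols = -"lead", names_to = "point", values_to = "idx")
    marks$time <- (marks$idx - 1) / fs
    m <- ecg_matrix(object)
    marks$mV <- m[cbind(marks$idx, match(marks$lead, colnames(m)))]
    if (!is.null(window)) {
      marks <- marks[marks$time >= window[1] & marks$time <= window[2], ]
    }
    marks$lead <- factor(marks$lead, levels = leads)
    p <- p + ggplot2::geom_point(
      data = marks,
      ggplot2::aes(colour = .data$point), size = 1.5)
  }
  p
}

#' Confusion heat map of a cross-validation result
#'
#' @param object An `mi_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_cv <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "beats") +
    ggplot2::theme_minimal()
}
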
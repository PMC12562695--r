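#' Agreement plots: area scatter and Bland-Altman
#'
#' Produces the standard validation figure pair for lesion-area agreement:
#' manual versus automated areas with the identity line, and a
#' Bland-Altman plot (difference manual - automated against the pair mean)
#' with the bias and 1.96-sd limits of agreement.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param file optional PNG path; when given the combined figure is saved.
#' @return A patchwork/ggplot object (invisibly when \code{file} is set).
#' @export
plotAgreement <- function(report, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotAgreement requires the ggplot2 package")
  ps <- report@perScan
  gg <- ggplot2::ggplot(ps, ggplot2::aes(x = area_auto_mm2,
                                         y = area_manual_mm2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = has_nAMD), alpha = 0.7) +
    ggplot2::labs(x = "automated area (mm²)", y = "manual area (mm²)",
                  colour = "nAMD",
                  title = sprintf("r² = %.3f", report@r2)) +
    ggplot2::theme_minimal()
  ps$avg <- (ps$area_auto_mm2 + ps$area_manual_mm2) / 2
  ps$diff <- ps$area_manual_mm2 - ps$area_auto_mm2
  ba <- ggplot2::ggplot(ps, ggplot2::aes(x = avg, y = diff)) +
    ggplot2::geom_hline(yintercept = report@bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = report@loa, linetype = 2,
                        colour = "indianred") +
    ggplot2::geom_point(ggplot2::aes(colour = has_nAMD), alpha = 0.7) +
    ggplot2::labs(x = "mean of manual and automated (mm²)",
                  y = "manual - automated (mm²)",
                  colour = "nAMD",
                  title = sprintf("bias %.3f, LOA [%.3f, %.3f]", report@bias,
                                  report@loa[1], report@loa[2])) +
    ggplot2::theme_minimal()
  combined <- if (requireNamespace("patchwork", quietly = TRUE))
    patchwork::wrap_plots(gg, ba, ncol = 2) else gg
  if (!is.null(file)) {
    ggplot2::ggsave(file, combined, width = 10, height = 4.5, dpi = 150)
    return(invisible(combined))
  }
  combined
}

utils::globalVariables(c("area_auto_mm2", "area_manual_mm2", "has_nAMD",
                         "avg", "diff"))
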
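#' Plot a pKa profile along the membrane normal
#'
#' Per-bin pKa estimates with bootstrap error bars against insertion depth;
#' the membrane-internal region (`d > 0`, below the phosphate plane) is
#' shaded.  Requires ggplot2.
#'
#' @param profiles a `pka_profile_set` from [build_profiles()].
#' @param pka_water optional water-phase pKa drawn as a dashed reference.
#' @return a ggplot object.
#' @export
plot_pka_profile <- function(profiles, pka_water = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ok <- profiles$pka_profile[profiles$pka_profile$status == "ok", ]
  if (!nrow(ok)) stop_data("no ok bins to plot")
  g <- ggplot2::ggplot(ok, ggplot2::aes(x = d_center, y = pka)) +
    ggplot2::annotate("rect", xmin = 0, xmax = Inf, ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pka - bootstrap_se,
                                        ymax = pka + bootstrap_se),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "insertion depth d (Å, positive = membrane interior)",
                  y = "pKa") +
    ggplot2::theme_minimal()
  if (!is.null(pka_water))
    g <- g + ggplot2::geom_hline(yintercept = pka_water, linetype = "dashed")
  g
}

#' Plot protonation and abundance along the insertion axis
#'
#' Two-panel view per pH: mean charge (protonation) per depth bin, and the
#' normalised abundance histogram of insertion depths.  Requires ggplot2.
#'
#' @param profiles a `pka_profile_set`.
#' @return a list of two ggplot objects, `charge` and `abundance`.
#' @export
plot_insertion_profiles <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ch <- profiles$charge
  ab <- profiles$abundance
  p1 <- ggplot2::ggplot(ch, ggplot2::aes(x = d_center, y = mean_charge,
                                         colour = factor(pH))) +
    ggplot2::annotate("rect", xmin = 0, xmax = Inf, ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "insertion depth d (Å)", y = "mean charge",
                  colour = "pH") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(ab, ggplot2::aes(x = d_center, y = fraction,
                                         fill = factor(pH))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "insertion depth d (Å)", y = "fraction of frames",
                  fill = "pH") +
    ggplot2::theme_minimal()
  list(charge = p1, abundance = p2)
}
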
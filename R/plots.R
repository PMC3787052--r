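#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_col geom_abline scale_fill_gradient2 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a time series (RMSD or COM distance)
#'
#' Raw trace with an optional smoothed overlay, the usual way RMSD drift
#' and tail-docking distance signals are displayed.
#'
#' @param object An `md_series`.
#' @param smooth_window Odd window for the smoothed overlay; `NULL`
#'   suppresses it.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.md_series <- function(object, smooth_window = 51, ...) {
  p <- ggplot(object, aes(x = .data$time / 1000, y = .data$value)) +
    geom_line(colour = "grey55") +
    labs(
      x = "time (ns)",
      y = sprintf("%s (%s)", attr(object, "label"), attr(object, "unit"))
    ) +
    theme_minimal()
  if (!is.null(smooth_window) && nrow(object) > smooth_window) {
    sm <- smooth_series(object, smooth_window)
    p <- p + geom_line(
      data = sm, aes(x = .data$time / 1000, y = .data$value),
      colour = "black"
    )
  }
  p
}

#' Plot an inter-residue energy map
#'
#' Residue-by-residue heat map of time-averaged interaction energies; both
#' triangles are drawn for the familiar symmetric IEM look.
#'
#' @param object An `energy_map`.
#' @param limit Symmetric colour saturation limit, kcal/mol.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_map <- function(object, limit = 30, ...) {
  df <- tidy(object)
  df <- bind_rows(
    df,
    dplyr::rename(df, res_i = "res_j", res_j = "res_i")
  )
  ggplot(df, aes(x = .data$res_i, y = .data$res_j, fill = .data$energy)) +
    geom_tile() +
    scale_fill_gradient2(
      low = "blue", mid = "white", high = "red",
      limits = c(-limit, limit), oob = scales_squish
    ) +
    labs(x = "residue", y = "residue", fill = "E (kcal/mol)") +
    theme_minimal()
}

# minimal squish so scales is not a hard dependency
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot a NOE report
#'
#' Effective distance against upper bound per restraint; points above the
#' dashed `upper + margin` line are the violations.
#'
#' @param object A `noe_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noe_report <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$upper, y = .data$r_eff, colour = .data$violated)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = "solid") +
    geom_abline(slope = 1, intercept = object$margin, linetype = "dashed") +
    labs(
      x = "upper bound (A)", y = "effective distance (A)",
      colour = "violated"
    ) +
    theme_minimal()
}

#' Plot cluster populations over time
#'
#' @param object A `cluster_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(
    x = .data$time / 1000, y = factor(.data$cluster),
    colour = factor(.data$cluster)
  )) +
    geom_point(show.legend = FALSE) +
    labs(x = "time (ns)", y = "cluster") +
    theme_minimal()
}
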
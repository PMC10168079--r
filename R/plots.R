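# biplot figures; every figure has a plain-text coordinate table
# counterpart produced by the pipeline, so plots are never the only record

#' AMMI1 biplot (mean yield vs IPCA1)
#'
#' @param fit an [ammi()] fit.
#' @return a ggplot object.
#' @export
ammi1_biplot <- function(fit) {
  co <- ammi1_coordinates(fit)
  pts <- rbind(cbind(co$genotypes, set = "genotype"),
               cbind(co$environments, set = "environment"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$ipca1,
                                    colour = .data$set, shape = .data$set)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = co$grand_mean, linewidth = 0.3,
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.6,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Mean yield (t/ha)", y = "IPCA1 score",
                  title = sprintf("AMMI1 biplot (IPCA1 %.1f%% of GxE)",
                                  fit$pct[1L])) +
    ggplot2::theme_minimal()
}

#' @rdname ammi1_biplot
#' @param x an `ammi_fit`.
#' @param ... ignored.
#' @export
plot.ammi_fit <- function(x, ...) ammi1_biplot(x)

#' GGE biplot views
#'
#' `type = "scores"` draws genotypes and environment vectors;
#' `"discrimination"` adds the average-environment axis and concentric
#' circles (vector length = discriminating ability, angle to the AEA =
#' representativeness); `"which-won-where"` draws the genotype convex
#' hull and the perpendicular sector rays.
#'
#' @param fit a [gge()] fit.
#' @param type one of `"scores"`, `"discrimination"`,
#'   `"which-won-where"`.
#' @return a ggplot object.
#' @export
gge_biplot <- function(fit, type = c("scores", "discrimination",
                                     "which-won-where")) {
  type <- match.arg(type)
  gp <- data.frame(label = rownames(fit$gen_scores),
                   x = fit$gen_scores[, 1L], y = fit$gen_scores[, 2L])
  ep <- data.frame(label = rownames(fit$env_scores),
                   x = fit$env_scores[, 1L], y = fit$env_scores[, 2L])
  base <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_segment(data = ep,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_text(data = ep,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       colour = "steelblue", size = 3, vjust = -0.5) +
    ggplot2::geom_point(data = gp, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = gp,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       size = 3, vjust = 1.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", fit$pct[1L]),
                  y = sprintf("PC2 (%.1f%%)", fit$pct[2L])) +
    ggplot2::theme_minimal()
  if (type == "scores") return(base)
  if (type == "discrimination") {
    dg <- environment_diagnostics(fit)
    aea <- colMeans(fit$env_scores[, 1:2, drop = FALSE])
    aea <- aea / sqrt(sum(aea^2))
    rmax <- max(dg$vector_length)
    circ <- do.call(rbind, lapply(rmax * c(0.25, 0.5, 0.75, 1), function(r) {
      t <- seq(0, 2 * pi, length.out = 181)
      data.frame(x = r * cos(t), y = r * sin(t), r = r)
    }))
    return(base +
      ggplot2::geom_path(data = circ,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$r),
                         colour = "grey80", linewidth = 0.25) +
      ggplot2::geom_segment(ggplot2::aes(x = -rmax * aea[1L],
                                         y = -rmax * aea[2L],
                                         xend = rmax * aea[1L],
                                         yend = rmax * aea[2L]),
                            colour = "darkred",
                            arrow = grid::arrow(length = grid::unit(2, "mm"))) +
      ggplot2::labs(title = "Discrimination & representativeness (AEA in red)"))
  }
  # which-won-where
  ww <- which_won_where(fit)
  hull <- as.data.frame(ww$gen_points[ww$hull_vertices, , drop = FALSE])
  names(hull) <- c("x", "y")
  hull <- rbind(hull, hull[1L, ])
  rmax <- max(sqrt(rowSums(ww$gen_points^2)), sqrt(rowSums(ww$env_points^2)))
  rays <- data.frame(x = rmax * cos(ww$rays$angle),
                     y = rmax * sin(ww$rays$angle))
  base +
    ggplot2::geom_path(data = hull, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "black", linewidth = 0.4) +
    ggplot2::geom_segment(data = rays,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          linetype = 3, colour = "grey40") +
    ggplot2::labs(title = "Which-won-where")
}

#' @rdname gge_biplot
#' @param x a `gge_fit`.
#' @param ... passed to `gge_biplot` (e.g. `type`).
#' @export
plot.gge_fit <- function(x, ...) gge_biplot(x, ...)
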
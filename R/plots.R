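#' Plot electronic population series
#'
#' Population of each state against time, optionally overlaid with a
#' kinetic-model fit (thin lines).
#'
#' @param series an `sh_population_series`.
#' @param fit optional `sh_kinetic_fit` whose fitted series is overlaid.
#' @param file optional PNG path; when given, the plot is written there.
#' @return invisibly, the input series.
#' @export
plot_populations <- function(series, fit = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  pp <- series$populations
  cols <- grDevices::hcl.colors(ncol(pp), "Dark 3")
  graphics::matplot(series$times, pp, type = "l", lty = 1, lwd = 2.5,
                    col = cols, xlab = "time (fs)", ylab = "population",
                    ylim = c(0, 1))
  if (!is.null(fit) && !is.null(fit$model_populations)) {
    mp <- fit$model_populations
    common <- intersect(colnames(pp), colnames(mp$populations))
    graphics::matlines(mp$times, mp$populations[, common, drop = FALSE],
                       lty = 2, lwd = 1, col = cols[match(common,
                                                          colnames(pp))])
  }
  graphics::legend("topright", colnames(pp), col = cols, lty = 1, lwd = 2)
  invisible(series)
}

#' Plot manifold decay with its exponential fit
#'
#' @param series an `sh_population_series`.
#' @param exp_fit an `sh_exp_fit` for the same manifold.
#' @param manifold state labels summed into the manifold population.
#' @param file optional PNG path.
#' @return invisibly, the fitted lifetime (fs).
#' @export
plot_manifold_fit <- function(series, exp_fit,
                              manifold = c("S0", "S1", "S2"), file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  pres <- intersect(manifold, colnames(series$populations))
  s <- rowSums(series$populations[, pres, drop = FALSE])
  graphics::plot(series$times, s, type = "l", lwd = 2.5, ylim = c(0, 1),
                 xlab = "time (fs)", ylab = "manifold population")
  graphics::lines(series$times, exp(-series$times / exp_fit$tau_fs),
                  lty = 2, lwd = 1.5)
  graphics::legend("topright",
                   c("ensemble", sprintf("exp fit, tau = %.0f fs",
                                         exp_fit$tau_fs)),
                   lty = c(1, 2), lwd = c(2.5, 1.5))
  invisible(exp_fit$tau_fs)
}

#' Dot plot of hop-geometry projections
#'
#' Per-mode mean +/- standard deviation of the hop-inducing geometry
#' projections, optionally with MECP projections overlaid as crosses.
#'
#' @param stats an `sh_hop_geometry_stats`.
#' @param mecp optional comparison table from [compare_to_mecp()].
#' @param file optional PNG path.
#' @return invisibly, `stats`.
#' @export
plot_hop_projections <- function(stats, mecp = NULL, file = NULL) {
  if (stats$empty) stop("plot_hop_projections: empty statistics")
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  n <- length(stats$mu)
  graphics::plot(seq_len(n), stats$mu, pch = 19,
                 ylim = range(c(stats$mu - stats$sigma,
                                stats$mu + stats$sigma,
                                if (!is.null(mecp)) mecp$p_mecp)),
                 xaxt = "n", xlab = "mode", ylab = "projection (Angstrom)",
                 main = paste(stats$transition, collapse = " -> "))
  graphics::axis(1, at = seq_len(n), labels = names(stats$mu))
  graphics::arrows(seq_len(n), stats$mu - stats$sigma,
                   seq_len(n), stats$mu + stats$sigma,
                   angle = 90, code = 3, length = 0.04)
  if (!is.null(mecp))
    graphics::points(seq_len(n), mecp$p_mecp, pch = 4, cex = 1.5)
  graphics::abline(h = 0, lty = 3)
  invisible(stats)
}

#' Heat map of time-resolved mode-projection density
#'
#' Binned trajectory density of one mode's projection against time, with
#' the signed (solid) and unsigned (dashed) ensemble means overlaid.
#'
#' @param coherence an `sh_coherence_series`.
#' @param mode mode name (column of the series) or index.
#' @param file optional PNG path.
#' @return invisibly, `coherence`.
#' @export
plot_coherence <- function(coherence, mode = 1, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  if (is.character(mode)) mode <- match(mode, colnames(coherence$signed_mean))
  dm <- coherence$density[[mode]]
  edges <- attr(dm, "edges")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  graphics::image(coherence$times, mids, t(dm),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  xlab = "time (fs)", ylab = "projection (Angstrom)",
                  main = paste("mode", colnames(coherence$signed_mean)[mode]))
  graphics::lines(coherence$times, coherence$signed_mean[, mode],
                  col = "orange", lwd = 2)
  graphics::lines(coherence$times, coherence$unsigned_mean[, mode],
                  col = "black", lwd = 2, lty = 2)
  invisible(coherence)
}
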
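#' Heat map of a sweep quantity
#'
#' Draws a colour map of `pi_v1` or `delta_ego` over two parameter axes of a
#' sweep table, with a diverging palette centred at the neutral value (0.5
#' for `pi_v1`, 0 for `delta_ego`) so that the sign structure — which side of
#' neutrality a cell falls on — is directly readable. Blue marks cells above
#' the centre (prevalent positive valence, or prevalent egosyntonicity) and
#' coral cells below it. For mismatch-by-inertia axes the quadrant boundary
#' lines are drawn and the four phenotype quadrants annotated (BH, SD, CT,
#' TH).
#'
#' @param table An `"ego_sweep"` data frame ([run_sweep()] or
#'   [slice_mismatch()]).
#' @param quantity Column to map: `"pi_v1"` or `"delta_ego"`.
#' @param axes Axis pair: `"alpha_beta"` (a fixed (r, omega) layer of a full
#'   sweep) or `"mismatch_r"` (a [slice_mismatch()] table).
#' @param annotate Draw quadrant lines and class labels (mismatch axes
#'   only).
#' @param palette Two-colour endpoints of the diverging scale, low then
#'   high.
#' @param main Plot title; a default is built from the quantity.
#' @return Invisibly, the plotted value matrix (rows = y axis, columns = x
#'   axis).
#' @examples
#' sl <- slice_mismatch(omega = 0.5, grid = phenotype_grid(c(0.1, 0.5, 0.9)))
#' plot_sweep_map(sl, "pi_v1", axes = "mismatch_r")
#' @export
plot_sweep_map <- function(table, quantity = c("pi_v1", "delta_ego"),
                           axes = c("mismatch_r", "alpha_beta"),
                           annotate = TRUE,
                           palette = c("coral", "white", "steelblue"),
                           main = NULL) {
  quantity <- match.arg(quantity)
  axes <- match.arg(axes)
  if (!quantity %in% names(table)) {
    stop("column '", quantity, "' not present in table", call. = FALSE)
  }
  xy <- switch(axes, mismatch_r = c("mismatch", "r"),
               alpha_beta = c("alpha", "beta"))
  if (!all(xy %in% names(table))) {
    stop("table lacks the requested axes (", paste(xy, collapse = ", "),
         ")", call. = FALSE)
  }
  xv <- sort(unique(table[[xy[1]]]))
  yv <- sort(unique(table[[xy[2]]]))
  z <- matrix(NA_real_, length(xv), length(yv))
  ix <- match(table[[xy[1]]], xv)
  iy <- match(table[[xy[2]]], yv)
  z[cbind(ix, iy)] <- table[[quantity]]

  centre <- if (quantity == "pi_v1") 0.5 else 0
  # symmetric limits about the centre so the palette midpoint is the centre
  half <- max(abs(range(z, na.rm = TRUE) - centre), 1e-12)
  cols <- grDevices::colorRampPalette(palette)(101)
  if (is.null(main)) {
    main <- if (quantity == "pi_v1") {
      expression(pi[V1] ~ "(steady-state positive valence)")
    } else {
      expression(delta[ego] ~ "(egosyntonicity balance)")
    }
  }
  graphics::image(xv, yv, z, zlim = centre + c(-half, half), col = cols,
                  xlab = xy[1], ylab = xy[2], main = main, useRaster = FALSE)
  if (annotate && axes == "mismatch_r") {
    graphics::abline(v = 0, lty = 2)
    graphics::abline(h = 0.5, lty = 2)
    ux <- max(xv) * 0.7; lx <- min(xv) * 0.7
    labs <- if (quantity == "pi_v1") {
      # pi_v1 quadrants: sign follows mismatch, independent of r
      c("BH/TH", "SD/CT")
    } else {
      c("BH/SD", "CT/TH")
    }
    graphics::text(c(ux, lx), rep(mean(range(yv)), 2), labs, cex = 0.9)
  }
  invisible(t(z))
}

#' @export
plot.valence_model <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(s$pi_bar, names.arg = state_labels(), las = 2,
                    ylab = "stationary probability",
                    main = "Stationary distribution over (V, M, E)", ...)
  graphics::abline(h = 0, lwd = 0.5)
  invisible(s$pi_bar)
}

#' @export
plot.ego_sweep <- function(x, quantity = "pi_v1", ...) {
  axes <- if ("mismatch" %in% names(x)) "mismatch_r" else "alpha_beta"
  plot_sweep_map(x, quantity = quantity, axes = axes, ...)
}
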
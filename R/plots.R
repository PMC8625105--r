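## Figure rendering: the ternary Mandala and the pairwise-axis panels.
## Base graphics, deterministic layout, SVG or PNG chosen by file extension.

.openDevice <- function(path, width, height) {
    dir <- dirname(path)
    if (!dir.exists(dir))
        stopEem("eemMissingFile", "output directory does not exist: %s", dir)
    if (grepl("\\.png$", path, ignore.case = TRUE))
        grDevices::png(path, width = width * 96, height = height * 96,
                       res = 96)
    else
        grDevices::svg(path, width = width, height = height)
}

.habitatPalette <- function(habitats) {
    levels <- sort(unique(habitats))
    pal <- grDevices::hcl.colors(max(length(levels), 3L), "Dark 3")
    stats::setNames(pal[seq_along(levels)], levels)
}

# barycentric (D, lambda, epsilon) -> 2D; D at lower-left, lambda at
# lower-right, epsilon at top (axes read counter-clockwise)
.ternaryXY <- function(tern) {
    vD <- c(0, 0); vL <- c(1, 0); vE <- c(0.5, sqrt(3) / 2)
    cbind(x = tern[, 1L] * vD[1L] + tern[, 2L] * vL[1L] + tern[, 3L] * vE[1L],
          y = tern[, 1L] * vD[2L] + tern[, 2L] * vL[2L] + tern[, 3L] * vE[2L])
}

.drawTernaryFrame <- function() {
    tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
    plot.new()
    plot.window(xlim = c(-0.15, 1.15), ylim = c(-0.12, sqrt(3) / 2 + 0.12),
                asp = 1)
    for (f in seq(0.2, 0.8, by = 0.2)) {   # grid lines parallel to each side
        a <- .ternaryXY(rbind(c(f, 1 - f, 0), c(f, 0, 1 - f)))
        b <- .ternaryXY(rbind(c(1 - f, f, 0), c(0, f, 1 - f)))
        d <- .ternaryXY(rbind(c(1 - f, 0, f), c(0, 1 - f, f)))
        graphics::segments(a[1, 1], a[1, 2], a[2, 1], a[2, 2],
                           col = "grey85")
        graphics::segments(b[1, 1], b[1, 2], b[2, 1], b[2, 2],
                           col = "grey85")
        graphics::segments(d[1, 1], d[1, 2], d[2, 1], d[2, 2],
                           col = "grey85")
    }
    graphics::lines(tri[, 1L], tri[, 2L], col = "grey30")
    graphics::text(0, -0.05, "D", col = "steelblue4", font = 2)
    graphics::text(1, -0.05, expression(lambda), col = "darkgreen", font = 2)
    graphics::text(0.5, sqrt(3) / 2 + 0.06, expression(epsilon),
                   col = "firebrick", font = 2)
}

#' Render the ternary Mandala
#'
#' Points with any missing axis are omitted from the plot (they stay in the
#' tabular output with their flags). Output is deterministic for a fixed
#' input set.
#'
#' @param set a [MandalaSet-class].
#' @param path output file, `.svg` or `.png`.
#' @return `path`, invisibly.
#' @export
renderMandala <- function(set, path) {
    stopifnot(is(set, "MandalaSet"))
    pts <- set@points
    keep <- is.finite(pts$tern_D)
    if (!any(keep))
        stopEem("eemTooFewPoints", "no points with complete ternary coordinates")
    pts <- pts[keep, , drop = FALSE]
    xy <- .ternaryXY(as.matrix(pts[, c("tern_D", "tern_lambda",
                                       "tern_epsilon")]))
    pal <- .habitatPalette(pts$habitat)
    .openDevice(path, 7, 6.5)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 1, 2, 1))
    .drawTernaryFrame()
    pch <- ifelse(pts$scope == "community", 19, 17)
    graphics::points(xy[, 1L], xy[, 2L], col = pal[pts$habitat], pch = pch,
                     cex = 1.4)
    lab <- ifelse(is.na(pts$phylum), pts$site, pts$phylum)
    graphics::text(xy[, 1L], xy[, 2L], lab, pos = 3, cex = 0.65,
                   col = "grey20")
    graphics::legend("topleft", legend = names(pal), col = pal, pch = 19,
                     bty = "n", cex = 0.8)
    graphics::title("Eco-Evo Mandala")
    invisible(path)
}

#' Render pairwise-axis panels
#'
#' Three panels of raw axis values (D-lambda, D-epsilon, epsilon-lambda) and,
#' when any point carries a Taylor exponent, a fourth nu-epsilon-lambda
#' association panel (nu against epsilon, with lambda mapped to symbol size).
#'
#' @param set a [MandalaSet-class].
#' @param path output file, `.svg` or `.png`.
#' @return `path`, invisibly.
#' @export
renderPairwise <- function(set, path) {
    stopifnot(is(set, "MandalaSet"))
    pts <- set@points
    pal <- .habitatPalette(pts$habitat)
    hasNu <- any(is.finite(pts$nu))
    panels <- if (hasNu) 4L else 3L
    .openDevice(path, 3.2 * panels, 3.6)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, panels), mar = c(4, 4, 2, 1))
    panel <- function(xcol, ycol, xlab, ylab) {
        ok <- is.finite(pts[[xcol]]) & is.finite(pts[[ycol]])
        if (!any(ok)) {
            graphics::plot.new()
            graphics::title(main = sprintf("%s vs %s: no data", ylab, xlab))
            return(invisible())
        }
        graphics::plot(pts[[xcol]][ok], pts[[ycol]][ok],
                       col = pal[pts$habitat[ok]],
                       pch = ifelse(pts$scope[ok] == "community", 19, 17),
                       xlab = xlab, ylab = ylab, cex = 1.2)
    }
    panel("D_raw", "lambda_raw", "D", "lambda")
    panel("D_raw", "epsilon_raw", "D", "epsilon")
    panel("epsilon_raw", "lambda_raw", "epsilon", "lambda")
    if (hasNu) {
        ok <- is.finite(pts$nu) & is.finite(pts$epsilon_raw)
        lam <- pts$lambda_raw
        sz <- rep(1.2, nrow(pts))
        if (any(is.finite(lam)))
            sz <- 0.8 + 1.2 * (lam - min(lam, na.rm = TRUE)) /
                max(1e-12, diff(range(lam, na.rm = TRUE)))
        sz[!is.finite(sz)] <- 0.8
        graphics::plot(pts$epsilon_raw[ok], pts$nu[ok],
                       col = pal[pts$habitat[ok]], pch = 19,
                       cex = sz[ok], xlab = "epsilon", ylab = "nu",
                       main = "nu-epsilon (size: lambda)")
    }
    invisible(path)
}
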
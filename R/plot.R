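#' Asymmetric dual-fold contact map plot
#'
#' Fold a's unique contacts are drawn in the upper triangle (light gray),
#' fold b's in the lower triangle (black), common contacts mirrored on
#' both sides (medium gray), interchain contacts as smaller symbols in
#' their fold's color. Predicted contacts, if given, are drawn in teal:
#' opaque circles where they match an experimental contact category,
#' translucent diamonds where unobserved.
#'
#' @param x A [build_dual_fold_map()] object.
#' @param categorized Optional [categorize_predictions()] overlay.
#' @param tol Unused; kept for symmetry with categorization calls.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dual_fold_map <- function(x, categorized = NULL, tol = 2,
                               main = NULL, ...) {
  L <- x$L
  if (is.null(main))
    main <- sprintf("%s (upper) vs %s (lower)", x$source_ids[1],
                    x$source_ids[2])
  graphics::plot(NA, xlim = c(1, L), ylim = c(1, L), xlab = "residue",
                 ylab = "residue", main = main, asp = 1, ...)
  graphics::abline(a = 0, b = 1, col = "gray80")
  up <- function(df) if (nrow(df)) cbind(df$j, df$i) else NULL
  lo <- function(df) if (nrow(df)) cbind(df$i, df$j) else NULL
  pts <- function(xy, ...) if (!is.null(xy)) graphics::points(xy, ...)
  pts(up(x$unique_a), pch = 16, col = "gray70", cex = 0.9)
  pts(lo(x$unique_b), pch = 16, col = "black", cex = 0.9)
  pts(up(x$common), pch = 16, col = "gray45", cex = 0.9)
  pts(lo(x$common), pch = 16, col = "gray45", cex = 0.9)
  pts(up(x$inter_a), pch = 16, col = "gray70", cex = 0.45)
  pts(lo(x$inter_b), pch = 16, col = "black", cex = 0.45)
  if (!is.null(categorized)) {
    teal <- "#008080"
    teal_t <- grDevices::adjustcolor(teal, alpha.f = 0.35)
    ok <- rbind(categorized$dominant, categorized$alternative,
                categorized$common)
    if (nrow(ok)) {
      pts(up(ok), pch = 16, col = teal, cex = 0.6)
      pts(lo(ok), pch = 16, col = teal, cex = 0.6)
    }
    if (nrow(categorized$unobserved)) {
      pts(up(categorized$unobserved), pch = 18, col = teal_t, cex = 0.7)
      pts(lo(categorized$unobserved), pch = 18, col = teal_t, cex = 0.7)
    }
  }
  invisible(x)
}
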
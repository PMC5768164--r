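# open a graphics device for a file path, dispatching on format
.open_device <- function(path, format = c("svg", "pdf", "png"),
                         width = 7, height = 6) {
  format <- match.arg(format)
  switch(format,
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100,
                              height = height * 100, res = 100))
}

.converged_results <- function(results) {
  res <- as.data.frame(results)
  res <- res[res$converged & is.finite(res$theta1), , drop = FALSE]
  if (nrow(res) == 0L) stop("no converged enrichment results to plot")
  res
}

#' Volcano plot of enrichment results
#'
#' Significance against directionality: x = the fitted score coefficient
#' theta1, y = -log10 of the (by default adjusted) p-value. Sets passing the
#' p threshold are highlighted; the `top_n` most significant sets are
#' labelled by name; an inset bar panel shows the distribution of all
#' coefficients. Output is deterministic for fixed input, so vector formats
#' are byte-reproducible.
#'
#' @param results Enrichment results data frame ([enrich_all()]).
#' @param p_threshold Significance threshold (default 0.05).
#' @param top_n Number of most-significant sets to label (default 15).
#' @param use_adjusted Plot adjusted (default) or raw p-values.
#' @param output_path Optional file path; when NULL, draws on the current
#'   device.
#' @param image_format `"svg"`, `"pdf"` or `"png"` (used with `output_path`).
#' @param main Plot title.
#' @return Invisibly, the data frame of plotted sets with a `significant`
#'   column and a `labelled` column.
#' @export
plot_volcano <- function(results, p_threshold = 0.05, top_n = 15L,
                         use_adjusted = TRUE, output_path = NULL,
                         image_format = c("svg", "pdf", "png"),
                         main = "miRNA gene-set enrichment") {
  stopifnot(p_threshold > 0, p_threshold <= 1, top_n >= 1)
  res <- .converged_results(results)
  p <- if (use_adjusted) res$adjusted_p else res$p_value
  keep <- !is.na(p)
  res <- res[keep, , drop = FALSE]
  p <- p[keep]
  if (nrow(res) == 0L) stop("no converged enrichment results to plot")
  res$significant <- p < p_threshold
  logp <- -log10(pmax(p, 1e-300))
  ord <- order(p, -abs(res$theta1), res$set_name)
  lab_idx <- utils::head(ord, top_n)
  res$labelled <- seq_len(nrow(res)) %in% lab_idx

  if (!is.null(output_path)) {
    .open_device(output_path, match.arg(image_format))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(4.5, 4.5, 3, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::plot(res$theta1, logp,
                 pch = 19, cex = 0.7,
                 col = ifelse(res$significant, "#2166AC", "grey60"),
                 xlab = expression(hat(theta)[1] ~ "(log-odds per unit score)"),
                 ylab = if (use_adjusted) {
                   expression(-log[10] ~ "adjusted p")
                 } else {
                   expression(-log[10] ~ "p")
                 },
                 main = main)
  graphics::abline(h = -log10(p_threshold), lty = 2, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey70")
  if (length(lab_idx)) {
    graphics::text(res$theta1[lab_idx], logp[lab_idx],
                   labels = res$set_name[lab_idx],
                   pos = 3, cex = 0.55, xpd = NA)
  }
  # inset: distribution of all fitted coefficients
  usr <- graphics::par("usr")
  h <- graphics::hist(res$theta1, plot = FALSE)
  ix0 <- usr[1] + 0.02 * (usr[2] - usr[1])
  ix1 <- usr[1] + 0.30 * (usr[2] - usr[1])
  iy0 <- usr[3] + 0.70 * (usr[4] - usr[3])
  iy1 <- usr[3] + 0.97 * (usr[4] - usr[3])
  xs <- ix0 + (h$breaks - min(h$breaks)) /
    diff(range(h$breaks)) * (ix1 - ix0)
  ys <- iy0 + h$counts / max(h$counts, 1) * (iy1 - iy0) * 0.9
  graphics::rect(ix0, iy0, ix1, iy1, col = "white", border = "grey50")
  for (i in seq_along(h$counts)) {
    graphics::rect(xs[i], iy0, xs[i + 1], ys[i],
                   col = "#67A9CF", border = "grey30")
  }
  graphics::text((ix0 + ix1) / 2, iy1,
                 expression("all" ~ hat(theta)[1]), pos = 1, cex = 0.55)
  invisible(res)
}

#' Bar graph of top enriched gene sets
#'
#' Ranks sets by absolute coefficient, keeps the top `top_n` (after an
#' optional significance filter), and draws coefficient +/- standard-error
#' bars. Ties in |theta1| are broken by set name so the selection is
#' deterministic.
#'
#' @param results Enrichment results data frame.
#' @param top_n Number of sets to show (default 50).
#' @param signif_only Keep only sets with adjusted p < `p_threshold`.
#' @param p_threshold Threshold used with `signif_only` (default 0.05).
#' @param horizontal Horizontal bars (default) or vertical.
#' @param output_path,image_format As in [plot_volcano()].
#' @param main Plot title.
#' @return Invisibly, the plotted subset in plotting order.
#' @export
plot_bar <- function(results, top_n = 50L, signif_only = FALSE,
                     p_threshold = 0.05, horizontal = TRUE,
                     output_path = NULL,
                     image_format = c("svg", "pdf", "png"),
                     main = "Top gene sets by |coefficient|") {
  stopifnot(top_n >= 1)
  res <- .converged_results(results)
  if (signif_only) {
    res <- res[!is.na(res$adjusted_p) & res$adjusted_p < p_threshold, ,
               drop = FALSE]
    if (nrow(res) == 0L) {
      stop("no gene set passes the filter: adjusted p < ", p_threshold)
    }
  }
  res <- res[order(-abs(res$theta1), res$set_name), , drop = FALSE]
  res <- utils::head(res, top_n)
  if (!is.null(output_path)) {
    ht <- if (horizontal) max(4, 0.28 * nrow(res) + 1.5) else 6
    .open_device(output_path, match.arg(image_format), width = 7,
                 height = ht)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- ifelse(res$theta1 >= 0, "#2166AC", "#B2182B")
  if (horizontal) {
    op <- graphics::par(mar = c(4.5, 14, 3, 2))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    ord <- rev(seq_len(nrow(res)))  # largest on top
    lim <- range(c(0, res$theta1 - res$se_theta1,
                   res$theta1 + res$se_theta1))
    mid <- graphics::barplot(res$theta1[ord], horiz = TRUE,
                             names.arg = res$set_name[ord],
                             col = cols[ord], border = NA, las = 1,
                             cex.names = 0.55, xlim = lim,
                             xlab = expression(hat(theta)[1] %+-% "SE"),
                             main = main)
    graphics::segments(res$theta1[ord] - res$se_theta1[ord], mid,
                       res$theta1[ord] + res$se_theta1[ord], mid,
                       lwd = 1.2)
    graphics::abline(v = 0, col = "grey30")
  } else {
    op <- graphics::par(mar = c(9, 4.5, 3, 1))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    lim <- range(c(0, res$theta1 - res$se_theta1,
                   res$theta1 + res$se_theta1))
    mid <- graphics::barplot(res$theta1, names.arg = res$set_name,
                             col = cols, border = NA, las = 2,
                             cex.names = 0.55, ylim = lim,
                             ylab = expression(hat(theta)[1] %+-% "SE"),
                             main = main)
    graphics::segments(mid, res$theta1 - res$se_theta1,
                       mid, res$theta1 + res$se_theta1, lwd = 1.2)
    graphics::abline(h = 0, col = "grey30")
  }
  invisible(res)
}
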
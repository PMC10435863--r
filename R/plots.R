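# Plot renderers: data series only; a plotting failure must never corrupt
# the CSV artifacts, so every renderer is wrapped by render_safely().

render_safely <- function(path, expr) {
  ok <- tryCatch({
    grDevices::png(path, width = 900, height = 650)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    TRUE
  }, error = function(e) {
    warning("plot skipped (", conditionMessage(e), ")", call. = FALSE)
    FALSE
  })
  invisible(ok)
}

#' Render a tornado bar chart
#' @param tor a `tornado_result` from [tornado()].
#' @param path output PNG path.
#' @return TRUE on success, invisibly.
#' @export
plot_tornado <- function(tor, path) {
  render_safely(path, function() {
    tor <- tor[!tor$flagged & tor$width > 0, ]
    if (nrow(tor) == 0L) stop("no tornado entries to draw")
    tor <- tor[order(tor$width), ]        # widest bar on top
    base <- attr(tor, "base_icer")
    oldpar <- graphics::par(mar = c(5, 14, 2, 2)); on.exit(graphics::par(oldpar))
    lo <- pmin(tor$icer_low, tor$icer_high)
    hi <- pmax(tor$icer_low, tor$icer_high)
    graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                   ylim = c(0.5, nrow(tor) + 0.5), yaxt = "n",
                   xlab = "ICER (USD/QALY)", ylab = "")
    graphics::axis(2, at = seq_len(nrow(tor)), labels = tor$parameter_id,
                   las = 1, cex.axis = 0.7)
    graphics::rect(lo, seq_len(nrow(tor)) - 0.35, hi,
                   seq_len(nrow(tor)) + 0.35, col = "steelblue")
    graphics::abline(v = base, lty = 2)
  })
}

#' Render cost-effectiveness acceptability curves
#' @param ceac_df data frame with `wtp` and `probability_*` columns.
#' @param path output PNG path.
#' @return TRUE on success, invisibly.
#' @export
plot_ceac <- function(ceac_df, path) {
  render_safely(path, function() {
    cols <- setdiff(names(ceac_df), "wtp")
    if (length(cols) == 0L || nrow(ceac_df) == 0L) stop("empty CEAC input")
    graphics::plot(NULL, xlim = range(ceac_df$wtp), ylim = c(0, 1),
                   xlab = "Willingness to pay (USD/QALY)",
                   ylab = "Probability cost-effective")
    for (j in seq_along(cols))
      graphics::lines(ceac_df$wtp, ceac_df[[cols[j]]], col = j, lwd = 2)
    graphics::legend("bottomright", legend = cols, col = seq_along(cols),
                     lwd = 2, cex = 0.8)
  })
}

#' Render an incremental cost vs incremental QALY scatter
#' @param psa a `psa_result` from [run_psa()].
#' @param wtp willingness-to-pay threshold; drawn as the oblique line.
#' @param path output PNG path.
#' @return TRUE on success, invisibly.
#' @export
plot_psa_scatter <- function(psa, wtp, path) {
  render_safely(path, function() {
    pr <- psa$comparisons[[1L]]
    tag <- paste0(pr[1L], "_vs_", pr[2L])
    dq <- psa$samples[[paste0("delta_qaly_", tag)]]
    dc <- psa$samples[[paste0("delta_cost_", tag)]]
    if (length(dq) == 0L) stop("empty PSA input")
    graphics::plot(dq, dc, pch = 16, cex = 0.5, col = "grey30",
                   xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                   main = paste(pr[1L], "vs", pr[2L]))
    graphics::abline(h = 0, v = 0, col = "grey70")
    graphics::abline(a = 0, b = wtp, lty = 2, col = "red")
  })
}

#' Render a scenario line chart
#' @param sg a `scenario_grid` from [scenario_sweep()] or [icer_by_cycle()].
#' @param path output PNG path.
#' @return TRUE on success, invisibly.
#' @export
plot_scenario <- function(sg, path) {
  render_safely(path, function() {
    xcol <- names(sg)[1L]
    cols <- grep("^icer_", names(sg), value = TRUE)
    if (nrow(sg) == 0L) stop("empty scenario input")
    graphics::plot(NULL, xlim = range(sg[[xcol]]),
                   ylim = range(unlist(sg[cols]), na.rm = TRUE),
                   xlab = attr(sg, "axis_name"), ylab = "ICER (USD/QALY)")
    for (j in seq_along(cols))
      graphics::lines(sg[[xcol]], sg[[cols[j]]], col = j, lwd = 2, type = "b")
    graphics::legend("topright", legend = cols, col = seq_along(cols),
                     lwd = 2, cex = 0.8)
  })
}
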
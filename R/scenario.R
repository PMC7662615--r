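#' Scenario (sensitivity) table of conditional loss-group distributions
#'
#' For every joint configuration of the chosen conditioning predictors,
#' computes the exact posterior distribution of the loss group by variable
#' elimination, alongside the unconditional baseline ("initial") distribution.
#' This reproduces the layout of the published sensitivity tables:
#' conditioning values as leading label columns, then one column per loss
#' group.
#'
#' @param net a fitted `discrete_bn` containing `loss_group`.
#' @param conditioning character vector of predictor names (possibly empty).
#' @param target outcome variable, default `"loss_group"`.
#' @return a `scenario_table`: data frame of probabilities (not percentages)
#'   with attributes `baseline` (named probability vector) and `conditioning`.
#' @examples
#' net <- as_bn(default_generating_model())
#' scenario_table(net, c("gender", "age_group"))
#' @export
scenario_table <- function(net, conditioning = character(), target = "loss_group") {
  stopifnot(inherits(net, "discrete_bn"))
  if (target %in% conditioning) stop("cannot condition on the outcome itself")
  bad <- setdiff(conditioning, net$dag$nodes)
  if (length(bad)) stop("unknown conditioning variable(s): ",
                        paste(bad, collapse = ", "))
  states <- net$schema[[target]]
  baseline <- query_posterior(net, target, list())
  if (length(conditioning)) {
    ## first conditioning variable varies slowest (published table layout)
    grid <- rev(expand.grid(rev(setNames(
      lapply(conditioning, function(v) net$schema[[v]]), conditioning)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    probs <- t(vapply(seq_len(nrow(grid)), function(i)
      query_posterior(net, target, as.list(grid[i, , drop = FALSE])),
      numeric(length(states))))
    out <- cbind(grid, as.data.frame(probs))
  } else {
    out <- as.data.frame(as.list(baseline))
  }
  names(out)[(ncol(out) - length(states) + 1L):ncol(out)] <- states
  structure(out, baseline = baseline, conditioning = conditioning,
            target = target, class = c("scenario_table", "data.frame"))
}

#' @export
print.scenario_table <- function(x, digits = 2, ...) {
  cond <- attr(x, "conditioning")
  states <- names(attr(x, "baseline"))
  cat("scenario table: P(", attr(x, "target"), " | ",
      if (length(cond)) paste(cond, collapse = ", ") else "-", ")\n", sep = "")
  cat("baseline (%):", paste(sprintf(paste0("%.", digits, "f"),
                                     100 * attr(x, "baseline")), collapse = "  "), "\n")
  y <- as.data.frame(x)
  y[states] <- round(100 * y[states], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Single-predictor scenario tables (the "initial probabilities" view)
#'
#' One scenario table per predictor of the network, plus the common baseline —
#' the layout of the published initial-probability table.
#'
#' @param net a fitted `discrete_bn`.
#' @param target outcome variable, default `"loss_group"`.
#' @return named list of `scenario_table`s with attribute `baseline`.
#' @export
initial_probability_table <- function(net, target = "loss_group") {
  preds <- setdiff(net$dag$nodes, target)
  tabs <- lapply(preds, function(v) scenario_table(net, v, target))
  names(tabs) <- preds
  structure(tabs, baseline = query_posterior(net, target, list()),
            class = "initial_probability_table")
}

#' @export
print.initial_probability_table <- function(x, digits = 2, ...) {
  cat("initial loss-group probabilities (%)\n")
  cat("baseline:", paste(sprintf(paste0("%.", digits, "f"),
                                 100 * attr(x, "baseline")), collapse = "  "), "\n")
  for (v in names(x)) {
    cat("\nby ", v, ":\n", sep = "")
    y <- as.data.frame(x[[v]])
    states <- names(attr(x[[v]], "baseline"))
    y[states] <- round(100 * y[states], digits)
    print.data.frame(y, row.names = FALSE)
  }
  invisible(x)
}

#' Probability of the best-hearing group per scenario
#'
#' Projects a scenario table onto its first outcome state (group I, no
#' measurable loss), keeping the configuration labels — the quantity plotted
#' in the published summary figure.
#'
#' @param table a [scenario_table()].
#' @return data frame with the conditioning columns and `p_best`.
#' @export
best_hearing_summary <- function(table) {
  stopifnot(inherits(table, "scenario_table"))
  cond <- attr(table, "conditioning")
  states <- names(attr(table, "baseline"))
  out <- cbind(as.data.frame(table)[cond],
               p_best = as.data.frame(table)[[states[1L]]])
  structure(out, baseline_best = unname(attr(table, "baseline")[1L]),
            class = c("best_hearing_summary", "data.frame"))
}

#' Plot the best-hearing probabilities of a scenario table
#'
#' Grouped bar chart of `P(group I)` per configuration, with the baseline as
#' a dashed reference line.
#'
#' @param x a [best_hearing_summary()] (or a `scenario_table`, which is
#'   summarized first).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.best_hearing_summary <- function(x, ...) {
  labs <- apply(as.data.frame(x)[, setdiff(names(x), "p_best"), drop = FALSE],
                1L, paste, collapse = "\n")
  bp <- barplot(x$p_best, names.arg = labs, las = 2, cex.names = 0.6,
                ylim = c(0, 1), ylab = "P(best hearing, group I)", ...)
  if (!is.null(attr(x, "baseline_best")))
    lines(range(bp) + c(-1, 1), rep(attr(x, "baseline_best"), 2), lty = 2)
  invisible(bp)
}

#' @export
plot.scenario_table <- function(x, ...) plot(best_hearing_summary(x), ...)
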
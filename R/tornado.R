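# One-way sensitivity analysis: tornado-diagram data.

#' One-way sensitivity sweep (tornado diagram data)
#'
#' For each uncertain parameter relevant to a scenario, evaluates the
#' scenario's net benefit with that parameter at its low and at its high
#' value while every other parameter sits at its midpoint.  Correlations
#' are deliberately ignored (each parameter moves alone).  Parameters of
#' stoves outside the scenario are excluded, as are degenerate
#' parameters; the traditional wood stove always counts as involved
#' because it defines the baseline energy demand.
#'
#' @param catalog A `stove_catalog`.
#' @param scn A `cba_scenario`.
#' @param options A `cba_options` list.
#' @return Data frame with columns `parameter`, `low_outcome`,
#'   `high_outcome`, `swing` (absolute difference) and `baseline`
#'   (all-midpoint net benefit, identical in every row), ordered by
#'   decreasing swing.
#' @examples
#' t <- tornado(default_catalog(), scenario("wood_ics", perspective = "social"))
#' head(t, 3)
#' @export
tornado <- function(catalog, scn, options = model_options()) {
  stopifnot(inherits(scn, "cba_scenario"))
  pt <- param_table(catalog)

  involved_stoves <- unique(c("wood_traditional", scn$baseline, scn$candidate))
  involved_fuels <- unique(vapply(involved_stoves,
                                  function(s) catalog$stoves[[s]]$fuel, ""))
  keep <- vapply(pt$id, function(id) {
    if (id %in% names(catalog$globals)) return(TRUE)
    if (startsWith(id, "price.")) {
      return(sub("^price\\.", "", id) %in% involved_fuels)
    }
    if (id == "gamma.electricity") {
      return("electricity" %in% involved_fuels)
    }
    sub("\\.[^.]+$", "", id) %in% involved_stoves
  }, TRUE)
  keep <- keep & pt$low < pt$high
  pt <- pt[keep, , drop = FALSE]
  if (nrow(pt) == 0) {
    return(data.frame(parameter = character(), low_outcome = numeric(),
                      high_outcome = numeric(), swing = numeric(),
                      baseline = numeric()))
  }

  # one vectorized evaluation: row j = parameter j at low, row k+j at
  # high, final row = all-midpoint baseline
  k <- nrow(pt)
  mid <- midpoint_draw(catalog)
  sweep <- mid[rep(1, 2 * k + 1), , drop = FALSE]
  rownames(sweep) <- NULL
  for (j in seq_len(k)) {
    sweep[j, pt$id[j]] <- pt$low[j]
    sweep[k + j, pt$id[j]] <- pt$high[j]
  }
  net <- evaluate(sweep, catalog, scn, options)$net

  out <- data.frame(parameter = pt$id,
                    low_outcome = net[seq_len(k)],
                    high_outcome = net[k + seq_len(k)],
                    swing = abs(net[k + seq_len(k)] - net[seq_len(k)]),
                    baseline = net[2 * k + 1],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  out
}

#' Plot tornado data as horizontal bars
#'
#' Convenience base-graphics rendering of [tornado()] output; the CSV is
#' the contract, the plot a visual aid.
#'
#' @param t Output of [tornado()].
#' @param top Number of parameters shown (largest swings first).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted subset.
#' @export
plot_tornado <- function(t, top = 15, ...) {
  t <- utils::head(t, top)
  t <- t[rev(seq_len(nrow(t))), ]
  lo <- pmin(t$low_outcome, t$high_outcome) - t$baseline
  hi <- pmax(t$low_outcome, t$high_outcome) - t$baseline
  graphics::barplot(rbind(lo, hi - lo), horiz = TRUE, names.arg = t$parameter,
                    las = 1, col = c(NA, "steelblue"), border = NA,
                    xlab = "net benefit relative to midpoint [US$/hh-month]",
                    ...)
  graphics::abline(v = 0, col = "red")
  invisible(t)
}
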
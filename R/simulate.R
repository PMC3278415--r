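# Monte Carlo experiment driver and distribution summaries.

#' Run the Monte Carlo experiment
#'
#' Draws one shared parameter matrix (common random numbers, so
#' cross-scenario contrasts are paired) and evaluates the cost-benefit
#' breakdown of every scenario on it.  Empirical percentiles use linear
#' interpolation between order statistics.
#'
#' @param catalog A `stove_catalog`.
#' @param scenarios A `cba_scenario` or list of them.
#' @param n_draws Number of Monte Carlo realizations (default 10,000; a
#'   warning is issued below 100).
#' @param seed Integer RNG seed.
#' @param probs Probabilities summarized for each scenario (must include
#'   enough to be useful; defaults to the 10th, 50th and 90th
#'   percentiles).
#' @param options A `cba_options` list.
#' @param draws Optional pre-built draw matrix (overrides `n_draws` and
#'   `seed` for sampling, e.g. to pair runs across calls).
#' @return An object of class `cba_run`: a list of per-scenario
#'   summaries (class `cba_summary`, each with percentiles, the fraction
#'   of positive outcomes, component means and the net-benefit draws)
#'   plus the run configuration.
#' @examples
#' run <- run_simulation(default_catalog(), scenario("wood_ics"),
#'                       n_draws = 500, seed = 1)
#' run$summaries[[1]]$percentiles
#' @export
run_simulation <- function(catalog, scenarios, n_draws = 10000, seed = 1,
                           probs = c(0.1, 0.5, 0.9),
                           options = model_options(), draws = NULL) {
  if (inherits(scenarios, "cba_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) > 0,
            all(vapply(scenarios, inherits, TRUE, "cba_scenario")))
  if (is.null(draws)) {
    if (n_draws < 100) {
      warning("n_draws < 100: percentile estimates will be unstable")
    }
    draws <- sample_draws(catalog, n_draws, seed)
  } else {
    n_draws <- nrow(draws)
    seed <- attr(draws, "seed")
  }
  summaries <- lapply(scenarios, function(scn) {
    bd <- evaluate(draws, catalog, scn, options)
    structure(list(
      scenario = scenario_id(scn),
      scenario_spec = scn,
      n_draws = n_draws,
      seed = seed,
      percentiles = stats::quantile(bd$net, probs = probs, type = 7,
                                    names = TRUE),
      fraction_positive = mean(bd$net > 0),
      component_means = colMeans(bd),
      net = bd$net
    ), class = "cba_summary")
  })
  names(summaries) <- vapply(summaries, `[[`, "", "scenario")
  structure(list(summaries = summaries, n_draws = n_draws, seed = seed,
                 options = options, probs = probs),
            class = "cba_run")
}

#' @export
print.cba_summary <- function(x, ...) {
  cat(sprintf("%s  (n = %d, seed = %s)\n", x$scenario, x$n_draws,
              format(x$seed)))
  q <- x$percentiles
  cat(sprintf("  net benefits [US$/hh-month]: %s\n",
              paste(sprintf("%s = %.2f", names(q), q), collapse = ", ")))
  cat(sprintf("  positive in %.1f%% of draws\n", 100 * x$fraction_positive))
  invisible(x)
}

#' @export
print.cba_run <- function(x, ...) {
  cat(sprintf("Monte Carlo run: %d scenario(s), n = %d, seed = %s\n",
              length(x$summaries), x$n_draws, format(x$seed)))
  for (s in x$summaries) print(s)
  invisible(x)
}

#' Tabulate the cumulative distribution of net benefits
#'
#' @param summary A `cba_summary` from [run_simulation()].
#' @param probs Probability grid (0 and 1 map to the sample minimum and
#'   maximum).
#' @return Data frame with columns `probability` and `net` (US$/hh-month),
#'   non-decreasing in `probability`.
#' @export
cdf_table <- function(summary, probs = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(summary, "cba_summary"),
            all(probs >= 0 & probs <= 1))
  data.frame(probability = probs,
             net = unname(stats::quantile(summary$net, probs = probs,
                                          type = 7)))
}

#' The study's seven stove transitions
#'
#' Six moves away from the traditional wood stove (improved wood,
#' unimproved and improved charcoal, kerosene, LPG, electric) plus the
#' move from the traditional to the improved charcoal stove.
#'
#' @inheritParams scenario
#' @return A list of seven `cba_scenario` objects.
#' @export
study_scenarios <- function(perspective = "private", accounting = "basic",
                            capital_subsidy = 0, carbon_offset = FALSE) {
  cands <- c("charcoal_traditional", "wood_ics", "charcoal_ics",
             "kerosene", "lpg", "electric")
  scns <- lapply(cands, scenario, baseline = "wood_traditional",
                 perspective = perspective, accounting = accounting,
                 capital_subsidy = capital_subsidy,
                 carbon_offset = carbon_offset)
  scns[[length(scns) + 1]] <- scenario("charcoal_ics",
                                       baseline = "charcoal_traditional",
                                       perspective = perspective,
                                       accounting = accounting,
                                       capital_subsidy = capital_subsidy,
                                       carbon_offset = carbon_offset)
  scns
}

.T4_BLOCKS <- c("private", "social_basic", "offset_basic", "offset_extended")

.t4_stove_label <- function(scn) {
  paste0(scn$candidate,
         if (scn$baseline == "charcoal_traditional") "_from_charcoal" else "")
}

#' Net-benefit percentile table across stoves and policy blocks
#'
#' Reproduces the headline summary of the analysis: for each of the
#' seven stove transitions, the 10th percentile, median and 90th
#' percentile of monthly net benefits under four policy blocks —
#' private (no subsidy unless given), social with basic carbon
#' accounting, private with the carbon-offset transfer under basic
#' accounting, and private with the offset under extended accounting.
#' All blocks share one draw matrix.
#'
#' @inheritParams run_simulation
#' @param capital_subsidy Capital-cost subsidy fraction applied in the
#'   private blocks.
#' @param blocks Subset of blocks to compute (default all four).
#' @return Data frame with columns `stove`, `block`, `low`, `median`,
#'   `high` (US$/hh-month).
#' @export
table4 <- function(catalog, n_draws = 10000, seed = 1, capital_subsidy = 0,
                   options = model_options(), blocks = .T4_BLOCKS,
                   draws = NULL) {
  blocks <- match.arg(blocks, .T4_BLOCKS, several.ok = TRUE)
  if (is.null(draws)) draws <- sample_draws(catalog, n_draws, seed)
  block_args <- list(
    private = list(perspective = "private", accounting = "basic",
                   carbon_offset = FALSE, capital_subsidy = capital_subsidy),
    social_basic = list(perspective = "social", accounting = "basic",
                        carbon_offset = FALSE, capital_subsidy = 0),
    offset_basic = list(perspective = "private", accounting = "basic",
                        carbon_offset = TRUE, capital_subsidy = capital_subsidy),
    offset_extended = list(perspective = "private", accounting = "extended",
                           carbon_offset = TRUE, capital_subsidy = capital_subsidy)
  )
  out <- list()
  for (blk in blocks) {
    scns <- do.call(study_scenarios, block_args[[blk]])
    run <- run_simulation(catalog, scns, options = options, draws = draws)
    for (s in run$summaries) {
      q <- s$percentiles
      out[[length(out) + 1]] <- data.frame(
        stove = .t4_stove_label(s$scenario_spec), block = blk,
        low = unname(q[["10%"]]), median = unname(q[["50%"]]),
        high = unname(q[["90%"]]), stringsAsFactors = FALSE)
    }
  }
  # present stoves in the customary order
  res <- do.call(rbind, out)
  stove_order <- c("charcoal_traditional", "wood_ics", "charcoal_ics",
                   "charcoal_ics_from_charcoal", "kerosene", "lpg",
                   "electric")
  res <- res[order(match(res$block, .T4_BLOCKS),
                   match(res$stove, stove_order)), ]
  rownames(res) <- NULL
  res
}

#' Published reference values for the percentile table
#'
#' The packaged reference against which [table4()] output can be
#' compared cell-wise.
#'
#' @return Data frame in the same layout as [table4()].
#' @export
table4_reference <- function() {
  utils::read.csv(.fixture_path("table4_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' Format a percentile table for display
#'
#' Wide layout, one row per stove, with monetary values rendered as
#' `$x.x` and negative outcomes in parentheses, e.g. `($1.1)`.
#'
#' @param t4 Output of [table4()].
#' @return A character data frame.
#' @export
format_table4 <- function(t4) {
  fmt <- function(x) ifelse(x < 0, sprintf("($%.1f)", abs(x)),
                            sprintf("$%.1f", x))
  wide <- NULL
  for (blk in unique(t4$block)) {
    sub <- t4[t4$block == blk, ]
    cols <- data.frame(low = fmt(sub$low), median = fmt(sub$median),
                       high = fmt(sub$high), stringsAsFactors = FALSE)
    names(cols) <- paste(blk, c("low", "median", "high"), sep = ".")
    wide <- if (is.null(wide)) cbind(data.frame(stove = sub$stove), cols)
            else cbind(wide, cols)
  }
  wide
}
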
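# Shared fixtures: the packaged catalog and a cached reference draw
# matrix (n = 10,000) reused across test files to keep the suite fast.

the_catalog <- default_catalog()
the_catalog_nocorr <- default_catalog(with_correlations = FALSE)
mid_draw <- midpoint_draw(the_catalog)

.test_cache <- new.env(parent = emptyenv())

test_draws <- function(n = 10000, seed = 101, catalog = the_catalog,
                       key = NULL) {
  key <- if (is.null(key)) sprintf("d_%d_%d", n, seed) else key
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- sample_draws(catalog, n, seed)
  }
  .test_cache[[key]]
}

# modify columns of a draw matrix
set_col <- function(draw, ...) {
  vals <- list(...)
  for (nm in names(vals)) draw[[nm]] <- vals[[nm]]
  draw
}

# empirical KS distance to the uniform law on [lo, hi]
ks_uniform <- function(x, lo, hi) {
  u <- sort((x - lo) / (hi - lo))
  n <- length(u)
  max(pmax(abs(seq_len(n) / n - u), abs(u - (seq_len(n) - 1) / n)))
}
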
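# Parameter catalog: uncertain ranges, stove specifications, fuel
# properties and correlation assumptions, with loading, validation and
# serialization.

STOVE_IDS <- c("wood_traditional", "wood_ics", "charcoal_traditional",
               "charcoal_ics", "kerosene", "lpg", "electric")
FUEL_IDS <- c("wood", "charcoal", "kerosene", "propane", "electricity")
BASELINE_IDS <- c("wood_traditional", "charcoal_traditional")

.STOVE_FIELDS <- c("cc", "lifespan", "eps_t", "eps_f", "eta_ari", "eta_copd")
# the pure-baseline wood stove has sunk capital: no cc/lifespan entries
.BASELINE_ONLY_OPTIONAL <- c("cc", "lifespan")

# parameters constrained to the unit interval (eps_t may reach 1.5:
# an "improved" stove can be slower than the traditional one)
.FRACTION_GLOBALS <- c("chi", "f_purch", "vt", "f_alri", "cfr_alri", "prev_copd")

#' Uncertain parameter range
#'
#' A low/mid/high triple describing one uncertain scalar of the model: the
#' support of a uniform distribution together with the central estimate
#' used for midpoint and one-way sensitivity evaluations.  The mid value
#' is the stated central estimate and need not equal `(low + high) / 2`
#' (stove capital costs, for instance, are strongly right-skewed).
#'
#' @param low,mid,high Numeric scalars, `low <= mid <= high`.
#' @param units Free-text unit label.
#' @return An object of class `param_range`.
#' @examples
#' param_range(5, 15, 50, "US$")
#' @export
param_range <- function(low, mid, high, units = "") {
  if (!is.numeric(low) || !is.numeric(mid) || !is.numeric(high) ||
      anyNA(c(low, mid, high))) {
    stop("param_range values must be finite numerics", call. = FALSE)
  }
  if (low > mid || mid > high) {
    stop(sprintf("invalid range (%g, %g, %g): need low <= mid <= high",
                 low, mid, high), call. = FALSE)
  }
  structure(list(low = as.numeric(low), mid = as.numeric(mid),
                 high = as.numeric(high), units = as.character(units)),
            class = "param_range")
}

#' @export
print.param_range <- function(x, ...) {
  cat(sprintf("[%g, %g, %g] %s\n", x$low, x$mid, x$high, x$units))
  invisible(x)
}

is_degenerate <- function(r) r$low == r$high

# unit normalization applied once at load: percent -> fraction,
# deaths per 10,000 -> probability
.normalize_range <- function(r) {
  scale <- switch(r$units, percent = 1e-2, per_10000 = 1e-4, 1)
  if (scale != 1) {
    r$low <- r$low * scale
    r$mid <- r$mid * scale
    r$high <- r$high * scale
    r$units <- switch(r$units, percent = "fraction", per_10000 = "probability")
  }
  r
}

.as_range <- function(node, name) {
  if (is.numeric(node) && length(node) == 1) {
    return(param_range(node, node, node))
  }
  if (!is.list(node) || !all(c("low", "mid", "high") %in% names(node))) {
    stop(sprintf("parameter '%s' must be a scalar or a {low, mid, high} map",
                 name), call. = FALSE)
  }
  r <- tryCatch(
    param_range(node$low, node$mid, node$high,
                if (is.null(node$units)) "" else node$units),
    error = function(e) {
      stop(sprintf("parameter '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  .normalize_range(r)
}

#' Load a parameter catalog
#'
#' Reads a YAML (or JSON) catalog with top-level keys `constants`,
#' `globals`, `stoves`, `fuels` and optionally `correlations`, normalizes
#' units (percentages to fractions, deaths per 10,000 to probabilities),
#' expands per-stove correlation placeholders and validates every
#' invariant.  Fields omitted from a stove block are filled from the
#' packaged default catalog.
#'
#' @param path Path to the catalog file.
#' @param correlations_path Optional path to a separate correlations file
#'   (used when the catalog itself carries no `correlations` key).
#' @param fill_defaults Fill omitted stove/global entries from the
#'   packaged fixture (default `TRUE`; disabled while loading the fixture
#'   itself).
#' @return An object of class `stove_catalog`.
#' @seealso [default_catalog()], [write_catalog()], [validate_catalog()]
#' @export
load_catalog <- function(path, correlations_path = NULL, fill_defaults = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("catalog file '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (key in c("globals", "stoves", "fuels")) {
    if (is.null(raw[[key]])) {
      stop(sprintf("catalog is missing the top-level key '%s'", key),
           call. = FALSE)
    }
  }
  if (!is.null(correlations_path)) {
    craw <- yaml::read_yaml(correlations_path)
    raw$correlations <- craw$correlations
  }
  if (fill_defaults) {
    def <- yaml::read_yaml(.fixture_path("table2_catalog.yaml"))
    raw$globals <- utils::modifyList(def$globals, raw$globals)
    raw$fuels <- utils::modifyList(def$fuels, raw$fuels)
    raw$constants <- utils::modifyList(def$constants,
                                       if (is.null(raw$constants)) list() else raw$constants)
    for (s in names(raw$stoves)) {
      if (s %in% names(def$stoves)) {
        raw$stoves[[s]] <- utils::modifyList(def$stoves[[s]], raw$stoves[[s]])
      }
    }
  }

  globals <- lapply(stats::setNames(names(raw$globals), names(raw$globals)),
                    function(g) .as_range(raw$globals[[g]], g))

  stoves <- list()
  for (s in names(raw$stoves)) {
    blk <- raw$stoves[[s]]
    if (is.null(blk$fuel)) {
      stop(sprintf("stove block '%s' does not declare a fuel", s),
           call. = FALSE)
    }
    fields <- intersect(.STOVE_FIELDS, names(blk))
    parsed <- lapply(stats::setNames(fields, fields),
                     function(f) .as_range(blk[[f]], paste(s, f, sep = ".")))
    stoves[[s]] <- c(list(fuel = blk$fuel), parsed)
  }

  fuels <- list()
  for (f in names(raw$fuels)) {
    blk <- raw$fuels[[f]]
    fuels[[f]] <- list(
      energy_content = as.numeric(blk$energy_content),
      price = .as_range(blk$price, paste0("price.", f)),
      gamma_basic = .as_range(blk$gamma_basic, paste0("gamma_basic.", f)),
      gamma_extended = .as_range(blk$gamma_extended, paste0("gamma_extended.", f))
    )
  }

  cat_obj <- structure(list(
    constants = list(
      days_per_month = as.numeric(raw$constants$days_per_month),
      learning_hours = as.numeric(raw$constants$learning_hours)
    ),
    globals = globals,
    stoves = stoves,
    fuels = fuels,
    correlations = .parse_correlations(raw$correlations)
  ), class = "stove_catalog")
  cat_obj$correlations <- expand_correlations(cat_obj)
  validate_catalog(cat_obj)
  cat_obj
}

.parse_correlations <- function(node) {
  if (is.null(node) || length(node) == 0) {
    return(data.frame(a = character(), b = character(), rho = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(node, function(p) {
    if (is.null(p$a) || is.null(p$b) || is.null(p$rho)) {
      stop("each correlation entry needs fields a, b, rho", call. = FALSE)
    }
    data.frame(a = p$a, b = p$b, rho = as.numeric(p$rho),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# Expand `stove.` placeholders into concrete per-stove column pairs; pairs
# naming a field a stove does not carry (e.g. cc of the traditional wood
# stove) are dropped for that stove only.
expand_correlations <- function(catalog) {
  spec <- catalog$correlations
  if (nrow(spec) == 0) return(spec)
  out <- list()
  for (i in seq_len(nrow(spec))) {
    a <- spec$a[i]; b <- spec$b[i]; rho <- spec$rho[i]
    if (abs(rho) > 1) {
      stop(sprintf("correlation (%s, %s) = %g outside [-1, 1]", a, b, rho),
           call. = FALSE)
    }
    a_st <- startsWith(a, "stove.")
    b_st <- startsWith(b, "stove.")
    if (!a_st && !b_st) {
      out[[length(out) + 1]] <- data.frame(a = a, b = b, rho = rho)
      next
    }
    for (s in names(catalog$stoves)) {
      aa <- if (a_st) paste0(s, ".", sub("^stove\\.", "", a)) else a
      bb <- if (b_st) paste0(s, ".", sub("^stove\\.", "", b)) else b
      fa <- if (a_st) sub("^stove\\.", "", a) else NULL
      fb <- if (b_st) sub("^stove\\.", "", b) else NULL
      if (!is.null(fa) && is.null(catalog$stoves[[s]][[fa]])) next
      if (!is.null(fb) && is.null(catalog$stoves[[s]][[fb]])) next
      out[[length(out) + 1]] <- data.frame(a = aa, b = bb, rho = rho)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "stovecba")
  if (p == "") {
    # during development before installation
    p <- file.path("inst", "extdata", file)
  }
  p
}

#' The packaged default catalog
#'
#' Loads the parameter ranges, stove specifications, fuel properties and
#' correlation assumptions shipped with the package.
#'
#' @param with_correlations Attach the packaged correlation assumptions
#'   (default `TRUE`); `FALSE` yields an independent-parameter catalog.
#' @return A `stove_catalog`.
#' @examples
#' cat <- default_catalog()
#' cat$stoves$wood_ics$cc
#' @export
default_catalog <- function(with_correlations = TRUE) {
  load_catalog(
    .fixture_path("table2_catalog.yaml"),
    correlations_path = if (with_correlations) {
      .fixture_path("table3_correlations.yaml")
    },
    fill_defaults = FALSE
  )
}

#' Validate a catalog
#'
#' Checks range ordering, fraction bounds, stove/fuel completeness,
#' extended-vs-basic carbon intensities and correlation magnitudes.
#' Errors name the offending stove or parameter.
#'
#' @param catalog A `stove_catalog`.
#' @return The catalog, invisibly, if valid.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "stove_catalog"))
  missing_stoves <- setdiff(STOVE_IDS, names(catalog$stoves))
  if (length(missing_stoves) > 0) {
    stop(sprintf("catalog is missing stove block(s): %s",
                 paste(missing_stoves, collapse = ", ")), call. = FALSE)
  }
  for (g in names(catalog$globals)) {
    r <- catalog$globals[[g]]
    if (g %in% .FRACTION_GLOBALS && (r$low < 0 || r$high > 1)) {
      stop(sprintf("global '%s' must lie in [0, 1]", g), call. = FALSE)
    }
  }
  for (s in names(catalog$stoves)) {
    blk <- catalog$stoves[[s]]
    required <- if (s == "wood_traditional") {
      setdiff(.STOVE_FIELDS, .BASELINE_ONLY_OPTIONAL)
    } else {
      .STOVE_FIELDS
    }
    miss <- setdiff(required, names(blk))
    if (length(miss) > 0) {
      stop(sprintf("stove '%s' is missing field(s): %s", s,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    if (!blk$fuel %in% names(catalog$fuels)) {
      stop(sprintf("stove '%s' references unknown fuel '%s'", s, blk$fuel),
           call. = FALSE)
    }
    for (f in intersect(c("eta_ari", "eta_copd"), names(blk))) {
      r <- blk[[f]]
      if (r$low < 0 || r$high > 1) {
        stop(sprintf("'%s.%s' must lie in [0, 1]", s, f), call. = FALSE)
      }
    }
    et <- blk$eps_t
    if (et$low < 0 || et$high > 1.5) {
      stop(sprintf("'%s.eps_t' must lie in [0, 1.5]", s), call. = FALSE)
    }
    if (blk$fuel != "electricity") {
      ef <- blk$eps_f
      if (ef$low <= 0 || ef$high > 1) {
        stop(sprintf("'%s.eps_f' must lie in (0, 1]", s), call. = FALSE)
      }
    }
  }
  for (f in names(catalog$fuels)) {
    fl <- catalog$fuels[[f]]
    if (!is.finite(fl$energy_content) || fl$energy_content <= 0) {
      stop(sprintf("fuel '%s' needs a positive energy content", f),
           call. = FALSE)
    }
    if (f %in% c("wood", "charcoal") &&
        fl$gamma_extended$mid < fl$gamma_basic$mid) {
      stop(sprintf("fuel '%s': extended carbon intensity below basic", f),
           call. = FALSE)
    }
  }
  if (nrow(catalog$correlations) > 0 &&
      any(abs(catalog$correlations$rho) > 1)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  invisible(catalog)
}

#' Write a catalog back to YAML
#'
#' Serializes a (normalized) catalog so that `load_catalog()` on the
#' result reproduces it exactly.
#'
#' @param catalog A `stove_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "stove_catalog"))
  rng <- function(r) list(low = r$low, mid = r$mid, high = r$high,
                          units = r$units)
  out <- list(
    constants = catalog$constants,
    globals = lapply(catalog$globals, rng),
    stoves = lapply(catalog$stoves, function(blk) {
      c(list(fuel = blk$fuel),
        lapply(blk[setdiff(names(blk), "fuel")], rng))
    }),
    fuels = lapply(catalog$fuels, function(fl) {
      list(energy_content = fl$energy_content, price = rng(fl$price),
           gamma_basic = rng(fl$gamma_basic),
           gamma_extended = rng(fl$gamma_extended))
    }),
    correlations = lapply(seq_len(nrow(catalog$correlations)), function(i) {
      list(a = catalog$correlations$a[i], b = catalog$correlations$b[i],
           rho = catalog$correlations$rho[i])
    })
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Tabulate every uncertain parameter of a catalog
#'
#' Enumerates the full parameter universe as one row per model symbol:
#' global parameters, per-stove parameters (`<stove>.<field>`), fuel
#' prices (`price.<fuel>`) and the electricity carbon intensity
#' (`gamma.electricity`).  This fixed ordering defines the columns of
#' every draw matrix.
#'
#' @param catalog A `stove_catalog`.
#' @return A data frame with columns `id`, `low`, `mid`, `high`, `units`.
#' @export
param_table <- function(catalog) {
  rows <- list()
  add <- function(id, r) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, low = r$low, mid = r$mid, high = r$high, units = r$units,
      stringsAsFactors = FALSE)
  }
  for (g in names(catalog$globals)) add(g, catalog$globals[[g]])
  for (s in names(catalog$stoves)) {
    blk <- catalog$stoves[[s]]
    for (f in intersect(.STOVE_FIELDS, names(blk))) {
      add(paste0(s, ".", f), blk[[f]])
    }
  }
  for (f in names(catalog$fuels)) add(paste0("price.", f), catalog$fuels[[f]]$price)
  add("gamma.electricity", catalog$fuels$electricity$gamma_basic)
  do.call(rbind, rows)
}

#' Midpoint parameter draw
#'
#' Resolves every parameter to its catalog mid value (the stated central
#' estimate, not the mean of the bounds).  The result is a one-row draw
#' matrix directly usable by the deterministic model, and is the
#' reference point of tornado diagrams.
#'
#' @param catalog A `stove_catalog`.
#' @return A one-row data frame with one column per parameter.
#' @examples
#' d <- midpoint_draw(default_catalog())
#' d$inc_ari   # 0.5 cases/person-yr
#' @export
midpoint_draw <- function(catalog) {
  pt <- param_table(catalog)
  draw <- as.data.frame(as.list(stats::setNames(pt$mid, pt$id)),
                        check.names = FALSE, optional = TRUE)
  names(draw) <- pt$id
  draw
}

#' Collapse a catalog to its midpoint
#'
#' Returns a degenerate catalog in which every range has
#' `low = mid = high`.  Monte Carlo simulation of a collapsed catalog
#' reproduces the midpoint evaluation exactly; used for consistency
#' checks.
#'
#' @param catalog A `stove_catalog`.
#' @return A `stove_catalog` with all ranges degenerate.
#' @export
collapse_catalog <- function(catalog) {
  squash <- function(r) { r$low <- r$mid; r$high <- r$mid; r }
  catalog$globals <- lapply(catalog$globals, squash)
  catalog$stoves <- lapply(catalog$stoves, function(blk) {
    blk[setdiff(names(blk), "fuel")] <-
      lapply(blk[setdiff(names(blk), "fuel")], squash)
    blk
  })
  catalog$fuels <- lapply(catalog$fuels, function(fl) {
    fl$price <- squash(fl$price)
    fl$gamma_basic <- squash(fl$gamma_basic)
    fl$gamma_extended <- squash(fl$gamma_extended)
    fl
  })
  catalog
}

#' @export
print.stove_catalog <- function(x, ...) {
  pt <- param_table(x)
  cat("Cookstove cost-benefit parameter catalog\n")
  cat(sprintf("  %d parameters (%d uncertain), %d stoves, %d fuels, %d correlation pairs\n",
              nrow(pt), sum(pt$low < pt$high), length(x$stoves),
              length(x$fuels), nrow(x$correlations)))
  invisible(x)
}

#' Symbols consumed by the cost-benefit equations
#'
#' The static list of parameter identifiers the deterministic model reads,
#' given the stoves and fuels of a catalog.  Used to assert symbol
#' closure: the model consumes exactly the parameter universe of
#' [param_table()], nothing more and nothing less.
#'
#' @param catalog A `stove_catalog`.
#' @return Character vector of parameter ids.
#' @export
model_symbols <- function(catalog) {
  globals <- c("delta_s", "delta_p", "cp", "chi", "cm", "cookt0", "fuelt0",
               "collt0", "prep", "f_purch", "hhsize", "inc_ari", "prev_copd",
               "coi_ari", "coi_copd", "copd_delay", "vsl", "f_alri",
               "cfr_alri", "drate_copd", "vt", "w", "ccarb", "ce")
  stove_syms <- unlist(lapply(names(catalog$stoves), function(s) {
    fields <- intersect(.STOVE_FIELDS, names(catalog$stoves[[s]]))
    paste0(s, ".", fields)
  }))
  c(globals, stove_syms, paste0("price.", names(catalog$fuels)),
    "gamma.electricity")
}
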
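#' Shared log-spaced concentration grid
#'
#' All concentration-response curves in the pipeline are evaluated on a
#' single log10-spaced grid spanning 1 pM to 100 mM (1e-6 to 1e5 uM),
#' i.e. 11 decades.
#'
#' @param points_per_decade Number of grid points per decade of
#'   concentration (default 10, giving 111 points).
#' @return An object of class `conc_grid`: a list with `conc` (uM,
#'   strictly increasing), `log10_conc`, and `points_per_decade`.
#' @examples
#' g <- build_grid()
#' length(g$conc)   # 111
#' range(g$conc)    # 1e-6 .. 1e5 uM
#' @export
build_grid <- function(points_per_decade = 10L) {
  points_per_decade <- as.integer(points_per_decade)
  if (is.na(points_per_decade) || points_per_decade < 1L)
    stop("points_per_decade must be a positive integer")
  lg <- seq(GRID_LOG10_MIN, GRID_LOG10_MAX, by = 1 / points_per_decade)
  structure(
    list(conc = 10^lg, log10_conc = lg,
         points_per_decade = points_per_decade),
    class = "conc_grid"
  )
}

# Grid bounds in log10(uM): 1 pM = 1e-6 uM, 100 mM = 1e5 uM.
GRID_LOG10_MIN <- -6
GRID_LOG10_MAX <- 5
GRID_DECADES <- GRID_LOG10_MAX - GRID_LOG10_MIN

#' @export
print.conc_grid <- function(x, ...) {
  cat(sprintf("<conc_grid> %d points, 1e%d..1e%d uM (%d/decade)\n",
              length(x$conc), GRID_LOG10_MIN, GRID_LOG10_MAX,
              x$points_per_decade))
  invisible(x)
}

#' Three-parameter Hill response
#'
#' Monotone Hill curve with zero baseline:
#' f(c) = top / (1 + (AC50 / c)^slope).
#' At c = AC50 the response is exactly top/2.
#'
#' @param top Maximal response (assay-native units, >= 0).
#' @param slope Hill coefficient (> 0).
#' @param ac50 Half-maximal concentration in uM (> 0).
#' @param conc Concentration(s) in uM (> 0); vectorized.
#' @return Response values, same length as `conc`.
#' @export
hill_response <- function(top, slope, ac50, conc) {
  if (!is.numeric(ac50) || any(ac50 <= 0)) stop("ac50 must be > 0")
  if (!is.numeric(conc) || any(conc <= 0)) stop("conc must be > 0")
  if (!is.numeric(slope) || any(slope <= 0)) stop("slope must be > 0")
  # computed in log space to avoid overflow for extreme slope*decades
  top / (1 + exp(slope * (log(ac50) - log(conc))))
}

#' All-zero response row for a no-response chemical
#'
#' Chemicals with no concentration response (absent fit parameters, or
#' constant activity at every tested concentration) get a flat curve:
#' zero response at every grid point.
#'
#' @param grid A `conc_grid`.
#' @return Numeric vector of zeros, one per grid point.
#' @export
flat_curve <- function(grid) {
  stopifnot(inherits(grid, "conc_grid"))
  numeric(length(grid$conc))
}

#' Reconstruct one chemical's curve on the grid
#'
#' Absent parameters (any of top/slope/ac50 missing) mean "no response"
#' and produce a flat curve. Negative raw responses are clipped to zero
#' before normalization, consistent with the conservative zeroing used
#' for missing data.
#'
#' @param fit A single-row curve-fit record (see [read_curve_fits()]).
#' @param grid A `conc_grid`.
#' @return Raw (unnormalized) response vector over the grid.
#' @export
reconstruct_curve <- function(fit, grid) {
  stopifnot(inherits(grid, "conc_grid"))
  if (is.na(fit$top) || is.na(fit$slope) || is.na(fit$ac50))
    return(flat_curve(grid))
  pmax(hill_response(fit$top, fit$slope, fit$ac50, grid$conc), 0)
}

#' Normalize an assay's raw response matrix to [0, 1]
#'
#' Divides every entry by the assay-wide maximum positive entry, so the
#' most responsive chemical/concentration cell maps to exactly 1 and
#' no-response rows stay at exactly 0. If the assay-wide maximum is <= 0
#' the whole surface is zero.
#'
#' @param raw Numeric matrix, one row per chemical, one column per grid
#'   point; rownames are chemical ids.
#' @param assay_id Assay identifier carried on the result.
#' @return A `response_surface`: list with `assay_id`, `values` (matrix
#'   in \[0,1\]), and `chem_ids`.
#' @export
normalize_assay <- function(raw, assay_id = NA_character_) {
  stopifnot(is.matrix(raw))
  vals <- pmax(raw, 0)
  m <- max(vals, 0)
  if (m > 0) vals <- vals / m
  structure(
    list(assay_id = assay_id, values = vals, chem_ids = rownames(raw)),
    class = "response_surface"
  )
}

#' Build normalized response surfaces for every assay
#'
#' Resolves multiple fits per chemical x assay to the best fit, evaluates
#' the Hill curve of each on the shared grid (flat for no-response), and
#' normalizes per assay. Chemicals absent from an assay are untested
#' there; they are only materialized later, as zero rows, when key-event
#' curves are composed.
#'
#' @param fits Curve-fit table from [read_curve_fits()].
#' @param grid A `conc_grid` (default [build_grid()]).
#' @return Named list of `response_surface`, one per assay.
#' @export
build_surfaces <- function(fits, grid = build_grid()) {
  best <- select_best_fits(fits)
  out <- lapply(split(best, best$assay_id), function(af) {
    raw <- t(vapply(seq_len(nrow(af)), function(i) {
      reconstruct_curve(af[i, ], grid)
    }, numeric(length(grid$conc))))
    rownames(raw) <- af$chem_id
    normalize_assay(raw, assay_id = af$assay_id[1])
  })
  out[order(names(out))]
}

#' Export a response surface as a wide data frame
#'
#' Columns are named by log10 concentration in uM.
#'
#' @param surface A `response_surface`.
#' @param grid The `conc_grid` it was built on.
#' @return data.frame with `chem_id` plus one column per grid point.
#' @export
surface_to_df <- function(surface, grid) {
  stopifnot(inherits(surface, "response_surface"))
  df <- as.data.frame(surface$values)
  names(df) <- sprintf("log10uM_%g", grid$log10_conc)
  cbind(chem_id = surface$chem_ids, df, stringsAsFactors = FALSE)
}
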
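#' Hill (four-parameter sigmoid) dose-response parameters for one cell
#'
#' Container for the four parameters of the sigmoidal dose-response model
#' \deqn{R(d) = E_{max} + \frac{E_0 - E_{max}}{1 + (d/EC_{50})^{HS}}}
#' where `e0` is the basal response (response at zero drug), `emax` the
#' response at infinite concentration, `ec50` the concentration producing the
#' half-maximal response change, and `hs` the Hill slope controlling the
#' steepness of the transition. No ordering of `e0` and `emax` is imposed:
#' resistant cells may have a higher plateau than other cells' basal level.
#'
#' @param e0 basal response (response units, e.g. log2(CNR)); finite.
#' @param emax response at infinite concentration (same units); finite.
#' @param ec50 half-maximal concentration in molar; strictly positive.
#' @param hs Hill slope (dimensionless); strictly positive.
#'
#' @return An object of class `"hill_params"`: a list with elements
#'   `e0`, `emax`, `ec50`, `hs`.
#' @examples
#' p <- hill_params(e0 = 1, emax = 0.16, ec50 = 10^-7.72, hs = 2^-1.02)
#' hill_response(p, c(0, 10^-7.72, 1e-5))
#' @export
hill_params <- function(e0, emax, ec50, hs) {
  for (nm in c("e0", "emax", "ec50", "hs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort(sprintf("`%s` must be a single finite number", nm))
  }
  if (ec50 <= 0) abort("`ec50` must be > 0")
  if (hs <= 0) abort("`hs` must be > 0")
  structure(list(e0 = e0, emax = emax, ec50 = ec50, hs = hs),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> E0 = %.4g, Emax = %.4g, EC50 = %.4g M (log10 = %.3f), HS = %.4g\n",
    x$e0, x$emax, x$ec50, log10(x$ec50), x$hs))
  invisible(x)
}

# coerce a hill_params object / 1-row parameter table to a plain list
as_hill <- function(params) {
  if (inherits(params, "hill_params")) return(params)
  if (is_cell_table(params)) {
    if (nrow(params) != 1L)
      abort("expected a single cell; got a table with more than one row")
    return(hill_params(params$e0, params$emax, params$ec50_molar,
                       params$hill_slope))
  }
  if (is.list(params) && all(c("e0", "emax", "ec50", "hs") %in% names(params)))
    return(hill_params(params$e0, params$emax, params$ec50, params$hs))
  abort("`params` must be a hill_params object or one row of a cell table")
}

check_doses <- function(dose) {
  if (!is.numeric(dose) || length(dose) == 0L)
    abort("doses must be a non-empty numeric vector")
  if (any(!is.finite(dose)))
    abort("doses must be finite")
  if (any(dose < 0))
    abort("doses must be non-negative")
  invisible(dose)
}

#' Evaluate the sigmoidal dose-response model
#'
#' Computes \eqn{R(d) = E_{max} + (E_0 - E_{max}) / (1 + (d/EC_{50})^{HS})}.
#' The untreated condition `dose = 0` is handled exactly and returns `e0`
#' (avoiding any `0^HS` ambiguity for fractional slopes).
#'
#' @param params a [hill_params()] object (or a single row of a cell
#'   parameter table).
#' @param dose drug concentration(s) in molar; non-negative and finite.
#'
#' @return Numeric vector of responses, one per dose.
#' @seealso [hill_curve()] for evaluation over a [dose_grid()];
#'   [inhibition_dose()] for the closed-form threshold inversion.
#' @export
hill_response <- function(params, dose) {
  p <- as_hill(params)
  check_doses(dose)
  r <- p$emax + (p$e0 - p$emax) / (1 + (dose / p$ec50)^p$hs)
  r[dose == 0] <- p$e0
  r
}

#' Log-spaced dose grid
#'
#' Builds a strictly increasing vector of concentrations. The default spans
#' the simulated range used throughout the package, 1e-11 to 1e-5 molar, with
#' 50 logarithmically spaced points.
#'
#' @param from,to grid endpoints in molar; `0 < from < to`.
#' @param n number of points (>= 2).
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
dose_grid <- function(from = 1e-11, to = 1e-5, n = 50) {
  check_number(from, "from", lower = 0, strict_lower = TRUE)
  check_number(to, "to", lower = from, strict_lower = TRUE)
  check_number(n, "n", lower = 2)
  10^seq(log10(from), log10(to), length.out = n)
}

check_grid <- function(grid) {
  check_doses(grid)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    abort("dose grid must be strictly increasing")
  invisible(grid)
}

#' Evaluate a Hill curve over a dose grid
#'
#' Elementwise [hill_response()] over an ordered dose grid.
#'
#' @inheritParams hill_response
#' @param grid strictly increasing vector of doses (molar, >= 0); the first
#'   entry may be exactly 0 (untreated).
#' @return Numeric vector of responses, same length as `grid`.
#' @export
hill_curve <- function(params, grid) {
  check_grid(grid)
  hill_response(params, grid)
}

# responses of many cells over a dose vector: n_cells x n_doses matrix
hill_matrix <- function(cells, doses) {
  if (!is_cell_table(cells)) abort("`cells` must be a cell parameter table")
  check_doses(doses)
  e0 <- cells$e0; emax <- cells$emax
  ec50 <- cells$ec50_molar; hs <- cells$hill_slope
  m <- matrix(NA_real_, nrow(cells), length(doses))
  for (j in seq_along(doses)) {
    d <- doses[j]
    m[, j] <- if (d == 0) e0 else emax + (e0 - emax) / (1 + (d / ec50)^hs)
  }
  m
}

#' Smallest dose inhibiting a cell below a fraction of its basal response
#'
#' Inverts the sigmoid in closed form: the smallest dose `d` at which
#' `hill_response(params, d) < threshold * e0` is
#' \deqn{d = EC_{50}\left(\frac{E_0 - E_{max}}{t E_0 - E_{max}} - 1\right)^{1/HS}}
#' whenever \eqn{E_{max} < t E_0 < E_0}. Two degenerate regimes are encoded
#' numerically: `Inf` ("never") when the cell's plateau lies at or above the
#' threshold (\eqn{t E_0 \le E_{max}}), and `0` ("always") when the threshold
#' lies at or above basal (\eqn{t E_0 \ge E_0}).
#'
#' @inheritParams hill_response
#' @param threshold fraction of the cell's own basal response, in (0, 1).
#' @return A single dose in molar; `Inf` if the threshold is never reached,
#'   `0` if it is met at arbitrarily small dose.
#' @export
inhibition_dose <- function(params, threshold) {
  p <- as_hill(params)
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (threshold >= 1) abort("`threshold` must be < 1")
  if (p$e0 <= 0)
    abort("threshold as a fraction of basal is undefined for e0 <= 0",
          class = "scdose_threshold_undefined")
  t_abs <- threshold * p$e0
  if (t_abs <= p$emax) return(Inf)   # plateau never falls below threshold
  if (t_abs >= p$e0) return(0)       # below threshold from the first dose on
  p$ec50 * ((p$e0 - p$emax) / (t_abs - p$emax) - 1)^(1 / p$hs)
}

#' Is a cell inhibited below a fraction of its basal response at a dose?
#'
#' Strict comparison: `hill_response(params, dose) < threshold * e0`.
#' Vectorized over the rows of a cell parameter table.
#'
#' @param params a [hill_params()] object or a cell parameter table (columns
#'   `e0`, `emax`, `ec50_molar`, `hill_slope`).
#' @param dose single concentration in molar, >= 0.
#' @param threshold fraction of each cell's own basal response, in (0, 1).
#' @return Logical: one value per cell.
#' @export
is_inhibited <- function(params, dose, threshold) {
  check_number(dose, "dose", lower = 0)
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (threshold >= 1) abort("`threshold` must be < 1")
  if (is_cell_table(params)) {
    if (any(params$e0 <= 0))
      abort("threshold as a fraction of basal is undefined for e0 <= 0",
            class = "scdose_threshold_undefined")
    resp <- drop(hill_matrix(params, dose))
    return(resp < threshold * params$e0)
  }
  p <- as_hill(params)
  if (p$e0 <= 0)
    abort("threshold as a fraction of basal is undefined for e0 <= 0",
          class = "scdose_threshold_undefined")
  hill_response(p, dose) < threshold * p$e0
}
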
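#' Threshold inhibition curve
#'
#' For each dose, the proportion of cells whose modeled response falls
#' strictly below `threshold` times their own basal response. Unlike the
#' population-averaged curve, this statistic is sensitive to the underlying
#' distribution of per-cell dose responses. Cells with `e0 <= 0` (for which a
#' fraction-of-basal threshold is undefined) are excluded with a warning.
#'
#' @param cells a cell parameter table (sampled or fitted).
#' @param grid dose grid in molar.
#' @param threshold fraction of each cell's basal response, in (0, 1);
#'   default 0.6 (inhibition below 60% of basal).
#' @return Numeric vector of inhibited proportions, one per grid dose, with
#'   attribute `n_cells` (cells actually used).
#' @export
inhibition_curve <- function(cells, grid = dose_grid(), threshold = 0.6) {
  if (!is_cell_table(cells) || nrow(cells) == 0L)
    abort("`cells` must be a non-empty cell parameter table")
  check_grid(grid)
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (threshold >= 1) abort("`threshold` must be < 1")
  bad <- cells$e0 <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with e0 <= 0 excluded from threshold analysis")
    cells <- cells[!bad, , drop = FALSE]
  }
  if (nrow(cells) == 0L)
    abort("no cells with positive basal response remain")
  resp <- hill_matrix(cells, grid)
  prop <- colMeans(resp < threshold * cells$e0)
  attr(prop, "n_cells") <- nrow(cells)
  prop
}

#' Threshold inhibition surface
#'
#' Stacks [inhibition_curve()] rows over a grid of thresholds (default 20% to
#' 90% of basal in steps of 1%), giving the inhibited proportion as a
#' function of both the required depth of inhibition and the applied dose.
#'
#' @inheritParams inhibition_curve
#' @param thresholds increasing vector of threshold fractions in (0, 1).
#' @return An object of class `"threshold_surface"`: list with `thresholds`,
#'   `doses`, `proportions` (threshold x dose matrix) and `n_cells`.
#' @export
inhibition_surface <- function(cells, grid = dose_grid(),
                               thresholds = seq(0.2, 0.9, by = 0.01)) {
  if (!is.numeric(thresholds) || length(thresholds) == 0L ||
      any(thresholds <= 0) || any(thresholds >= 1))
    abort("`thresholds` must lie strictly inside (0, 1)")
  if (is.unsorted(thresholds, strictly = TRUE))
    abort("`thresholds` must be strictly increasing")
  rows <- lapply(thresholds, function(t)
    suppressWarnings(inhibition_curve(cells, grid, t)))
  # e0 <= 0 exclusion is identical across rows; warn once
  n_used <- attr(rows[[1]], "n_cells")
  if (is_cell_table(cells) && n_used < nrow(cells))
    warning(nrow(cells) - n_used,
            " cell(s) with e0 <= 0 excluded from threshold analysis")
  prop <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(prop) <- list(threshold = format(thresholds),
                         dose = format(grid, digits = 4))
  structure(list(thresholds = thresholds, doses = grid,
                 proportions = prop, n_cells = n_used),
            class = "threshold_surface")
}

#' @export
print.threshold_surface <- function(x, ...) {
  cat(sprintf(
    "<threshold_surface> %d thresholds [%.2f, %.2f] x %d doses [%.3g, %.3g] M, %d cells\n",
    length(x$thresholds), min(x$thresholds), max(x$thresholds),
    length(x$doses), min(x$doses), max(x$doses), x$n_cells))
  invisible(x)
}

#' @export
as.data.frame.threshold_surface <- function(x, ...) {
  data.frame(
    threshold = rep(x$thresholds, times = length(x$doses)),
    dose_molar = rep(x$doses, each = length(x$thresholds)),
    proportion = as.vector(x$proportions),
    n_cells = x$n_cells)
}

#' Plot a threshold inhibition surface
#'
#' Filled image of inhibited proportion over log10(dose) (x) and threshold
#' (y), with contour lines overlaid.
#'
#' @param x a `threshold_surface`.
#' @param levels contour levels for the overlay.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.threshold_surface <- function(x, levels = seq(0.1, 0.9, by = 0.1), ...) {
  ld <- log10(x$doses)
  graphics::image(ld, x$thresholds, t(x$proportions),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "log10(dose [M])", ylab = "threshold (fraction of basal)",
                  ...)
  graphics::contour(ld, x$thresholds, t(x$proportions), levels = levels,
                    add = TRUE, col = "white")
  invisible(x)
}

#' Threshold inhibition surface from fitted single-cell parameters
#'
#' Applies [inhibition_surface()] to the Hill parameters fitted to an
#' experimental (or synthetic) population. Degenerate fits (flat responses,
#' for which EC50 is unidentifiable) are excluded by default.
#'
#' @param table a cell parameter table from [fit_cells()].
#' @param include_degenerate keep cells flagged as degenerate?
#' @inheritParams inhibition_surface
#' @return A `threshold_surface`.
#' @export
surface_from_fits <- function(table, grid = dose_grid(),
                              thresholds = seq(0.2, 0.9, by = 0.01),
                              include_degenerate = FALSE) {
  if (!is_cell_table(table)) abort("`table` must be a cell parameter table")
  if (!include_degenerate && "degenerate" %in% names(table))
    table <- table[!table$degenerate, , drop = FALSE]
  if (nrow(table) == 0L)
    abort("no usable cells after excluding degenerate fits")
  inhibition_surface(table, grid, thresholds)
}

# dose at which a curve first reaches proportion p (log-linear interpolation)
dose_at_proportion <- function(doses, prop, p) {
  if (prop[1] >= p) return(doses[1])
  i <- which(prop >= p)[1]
  if (is.na(i))
    abort(sprintf("proportion %.3g is never reached (plateau at %.3g)", p,
                  max(prop)),
          class = "scdose_not_reached", plateau = max(prop))
  # interpolate in log-dose between the bracketing grid points
  p1 <- prop[i - 1]; p2 <- prop[i]
  if (p2 == p1) return(doses[i])
  10^(log10(doses[i - 1]) +
        (p - p1) / (p2 - p1) * (log10(doses[i]) - log10(doses[i - 1])))
}

#' Dose-escalation factor read from a threshold inhibition surface
#'
#' How much more drug is needed to move the inhibited proportion from
#' `p_from` to `p_to` at a fixed threshold: the ratio `d(p_to) / d(p_from)`,
#' where `d(p)` is the dose at which the inhibited proportion first reaches
#' `p` (log-linear interpolation between grid doses, since grids are
#' log-spaced).
#'
#' @param surface a `threshold_surface`.
#' @param threshold a threshold present in `surface$thresholds`.
#' @param p_from,p_to proportions with `0 < p_from < p_to`.
#' @return A single fold-change in dose. If `p_to` is never reached (a
#'   resistant plateau), an error of class `"scdose_not_reached"` is signaled
#'   carrying the plateau proportion in its `plateau` field.
#' @export
dose_escalation_factor <- function(surface, threshold, p_from, p_to) {
  if (!inherits(surface, "threshold_surface"))
    abort("`surface` must be a threshold_surface")
  i <- which(abs(surface$thresholds - threshold) < 1e-9)
  if (length(i) != 1L)
    abort("`threshold` not found in the surface's threshold grid")
  check_number(p_from, "p_from", lower = 0, strict_lower = TRUE)
  check_number(p_to, "p_to", lower = 0, upper = 1)
  if (p_to <= p_from) abort("`p_to` must exceed `p_from`")
  prop <- surface$proportions[i, ]
  d_to <- dose_at_proportion(surface$doses, prop, p_to)
  d_from <- dose_at_proportion(surface$doses, prop, p_from)
  d_to / d_from
}

#' Export a threshold inhibition surface to CSV
#'
#' @param surface a `threshold_surface`.
#' @param path output CSV path.
#' @param format `"long"` (threshold, dose_molar, proportion, n_cells) or
#'   `"matrix"` (dense threshold x dose matrix, doses as column names).
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (!inherits(surface, "threshold_surface"))
    abort("`surface` must be a threshold_surface")
  if (format == "long") {
    write.csv(as.data.frame(surface), path, row.names = FALSE)
  } else {
    m <- cbind(threshold = surface$thresholds, surface$proportions)
    colnames(m) <- c("threshold", sprintf("%.6g", surface$doses))
    write.csv(m, path, row.names = FALSE)
  }
  invisible(path)
}
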
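#' Box constraints for sigmoid fitting
#'
#' Defaults match the constraints used for single-cell KTR fits: `e0` and
#' `emax` in \[-3, 3\] log2(CNR), `ec50` in (0, 40 uM\] and Hill slope in
#' (0, 100\]. The open lower ends are realized as small positive numbers.
#'
#' @param e0,emax,ec50,hs length-2 numeric `c(lo, hi)` with `lo < hi`;
#'   `ec50` and `hs` lower bounds must be > 0.
#' @return A list of class `"fit_bounds"`.
#' @export
fit_bounds <- function(e0 = c(-3, 3), emax = c(-3, 3),
                       ec50 = c(1e-12, 40e-6), hs = c(1e-3, 100)) {
  b <- list(e0 = e0, emax = emax, ec50 = ec50, hs = hs)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || v[1] >= v[2])
      abort(sprintf("`%s` bounds must be c(lo, hi) with lo < hi", nm))
  }
  if (b$ec50[1] <= 0) abort("`ec50` lower bound must be > 0")
  if (b$hs[1] <= 0) abort("`hs` lower bound must be > 0")
  structure(b, class = "fit_bounds")
}

# model on the optimizer's scale: theta = (e0, emax, log10(ec50), hs)
hill_theta <- function(theta, d) {
  r <- theta[2] + (theta[1] - theta[2]) / (1 + (d / 10^theta[3])^theta[4])
  r[d == 0] <- theta[1]
  r
}

#' Fit the sigmoidal dose-response model by bounded least squares
#'
#' Minimizes the sum of squared residuals of the four-parameter sigmoid over
#' box constraints using Levenberg-Marquardt ([minpack.lm::nls.lm()]). EC50 is
#' optimized on the log10 scale for conditioning and reported linear.
#' Initialization: `e0` from the response at the lowest dose, `emax` from the
#' response at the highest, EC50 from the dose whose response is nearest the
#' midpoint, HS = 1; the remaining `n_starts - 1` starts redraw log10(EC50)
#' uniformly over the bound range (seeded), and the best-of-all fit is
#' returned. Deterministic given `doses`, `responses`, `bounds`, `n_starts`
#' and `seed`.
#'
#' @param doses dose vector (molar, >= 0, strictly increasing; include the
#'   untreated condition as dose 0).
#' @param responses observed responses, same length as `doses`.
#' @param bounds a [fit_bounds()].
#' @param n_starts number of multi-start runs (>= 1).
#' @param seed seed for the restart draws (restored afterwards).
#' @return An object of class `"hill_fit"`: list with `params`
#'   ([hill_params()]), `residual_norm` (sum of squared residuals),
#'   `converged`, `degenerate`, `at_bound` (character vector of parameters
#'   pinned at a bound, within 1e-6 relative distance), and `n_points`.
#' @export
fit_hill <- function(doses, responses, bounds = fit_bounds(), n_starts = 5,
                     seed = 1) {
  check_grid(doses)
  if (!is.numeric(responses) || length(responses) != length(doses) ||
      any(!is.finite(responses)))
    abort("`responses` must be finite and match `doses` in length")
  if (!inherits(bounds, "fit_bounds")) abort("`bounds` must be a fit_bounds")
  if (length(doses) < 5L)
    abort("need at least 5 dose points to fit 4 parameters",
          class = "scdose_underdetermined")
  check_number(n_starts, "n_starts", lower = 1)

  lower <- c(bounds$e0[1], bounds$emax[1], log10(bounds$ec50[1]), bounds$hs[1])
  upper <- c(bounds$e0[2], bounds$emax[2], log10(bounds$ec50[2]), bounds$hs[2])
  clamp <- function(th) pmin(pmax(th, lower), upper)

  # flat data: EC50/HS carry no information
  if (length(unique(responses)) == 1L) {
    val <- min(max(responses[1], bounds$e0[1]), bounds$e0[2])
    pos <- doses[doses > 0]
    ec50 <- min(max(exp(mean(log(pos))), bounds$ec50[1]), bounds$ec50[2])
    return(structure(list(
      params = hill_params(val, val, ec50, 1),
      residual_norm = sum((responses - val)^2),
      converged = FALSE, degenerate = TRUE, at_bound = character(0),
      n_points = length(doses)), class = "hill_fit"))
  }

  mid <- (responses[1] + responses[length(responses)]) / 2
  pos <- doses[doses > 0]
  ec50_init <- pos[which.min(abs(responses[doses > 0] - mid))]
  starts <- list(clamp(c(responses[1], responses[length(responses)],
                         log10(ec50_init), 1)))
  if (n_starts > 1) {
    extra <- with_seed(seed, runif(n_starts - 1, lower[3], upper[3]))
    for (le in extra)
      starts[[length(starts) + 1L]] <-
        clamp(c(responses[1], responses[length(responses)], le, 1))
  }

  resid_fn <- function(th) responses - hill_theta(th, doses)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    abort("all optimization starts failed", class = "scdose_fit_failed")

  th <- clamp(best$par)
  rel <- abs(th - lower) / pmax(abs(lower), 1)
  rel_hi <- abs(th - upper) / pmax(abs(upper), 1)
  nm <- c("e0", "emax", "ec50", "hs")
  at_bound <- nm[rel < 1e-6 | rel_hi < 1e-6]
  structure(list(
    params = hill_params(th[1], th[2], 10^th[3], th[4]),
    residual_norm = best$deviance,
    converged = best$info %in% 1:4,
    degenerate = FALSE,
    at_bound = at_bound,
    n_points = length(doses)), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> RSS = %.4g over %d points; converged: %s%s\n",
    x$residual_norm, x$n_points, x$converged,
    if (x$degenerate) " (degenerate: flat responses)" else ""))
  print(x$params)
  if (length(x$at_bound))
    cat("  at bound:", paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the sigmoid to every cell in a dose-response table
#'
#' Fits [fit_hill()] independently to each cell (and channel, if a `channel`
#' column is present). Cells missing any dose level relative to the union of
#' observed doses are excluded with a message; cells with degenerate (flat)
#' responses are retained but flagged.
#'
#' @param table long-format `data.frame` with columns `cell_id`, `dose`,
#'   `response`, and optionally `channel` and `drug`.
#' @inheritParams fit_hill
#' @return A cell parameter table of class `"cell_param_table"`: one row per
#'   fitted cell with columns `cell_id` (plus `channel`/`drug` if supplied),
#'   `e0`, `emax`, `ec50_molar`, `hill_slope`, `rss`, `converged`,
#'   `degenerate`, `at_bound`, `n_points`. Excluded cell ids are kept in
#'   `attr(, "excluded")`.
#' @export
fit_cells <- function(table, bounds = fit_bounds(), n_starts = 5, seed = 1) {
  if (!is.data.frame(table) ||
      !all(c("cell_id", "dose", "response") %in% names(table)))
    abort("`table` must have columns cell_id, dose, response")
  if (nrow(table) == 0L) {
    out <- data.frame(cell_id = character(0), e0 = numeric(0),
                      emax = numeric(0), ec50_molar = numeric(0),
                      hill_slope = numeric(0), rss = numeric(0),
                      converged = logical(0), degenerate = logical(0),
                      at_bound = character(0), n_points = integer(0))
    class(out) <- c("cell_param_table", "data.frame")
    attr(out, "excluded") <- character(0)
    return(out)
  }
  has_channel <- "channel" %in% names(table)
  key <- if (has_channel) paste(table$cell_id, table$channel, sep = "\r")
         else as.character(table$cell_id)
  all_doses <- sort(unique(table$dose))
  groups <- split(seq_len(nrow(table)), key)
  rows <- list(); excluded <- character(0)
  for (g in names(groups)) {
    idx <- groups[[g]]
    sub <- table[idx, ]
    sub <- sub[order(sub$dose), ]
    if (!identical(sort(unique(sub$dose)), all_doses) ||
        nrow(sub) != length(all_doses)) {
      excluded <- c(excluded, g)
      next
    }
    fit <- fit_hill(sub$dose, sub$response, bounds = bounds,
                    n_starts = n_starts, seed = seed)
    row <- data.frame(
      cell_id = sub$cell_id[1],
      e0 = fit$params$e0, emax = fit$params$emax,
      ec50_molar = fit$params$ec50, hill_slope = fit$params$hs,
      rss = fit$residual_norm, converged = fit$converged,
      degenerate = fit$degenerate,
      at_bound = paste(fit$at_bound, collapse = ";"),
      n_points = fit$n_points)
    if (has_channel) row <- cbind(row[1], channel = sub$channel[1], row[-1])
    if ("drug" %in% names(table)) row$drug <- sub$drug[1]
    rows[[g]] <- row
  }
  if (length(excluded))
    message(length(excluded),
            " cell(s) excluded from fitting (incomplete dose coverage)")
  out <- if (length(rows)) do.call(rbind, rows) else {
    fit_cells(table[0, , drop = FALSE])
  }
  rownames(out) <- NULL
  class(out) <- c("cell_param_table", "data.frame")
  attr(out, "excluded") <- gsub("\r", "/", excluded)
  out
}

#' Count cells with EC50 above a cutoff
#'
#' The resistant-fraction summary: how many fitted cells require more than
#' `ec50_cutoff` (default 100 nM) to reach half-maximal inhibition, and the
#' corresponding proportion of the table.
#'
#' @param table a cell parameter table ([fit_cells()] output or
#'   [sample_population()] output).
#' @param ec50_cutoff cutoff in molar (default `1e-7`, i.e. 100 nM).
#' @return List with elements `count` and `proportion`.
#' @export
resistant_fraction <- function(table, ec50_cutoff = 1e-7) {
  if (!is_cell_table(table) || nrow(table) == 0L)
    abort("`table` must be a non-empty cell parameter table")
  check_number(ec50_cutoff, "ec50_cutoff", lower = 0)
  count <- sum(table$ec50_molar > ec50_cutoff)
  list(count = count, proportion = count / nrow(table))
}

#' Spearman correlations between single-point and dose-response parameters
#'
#' Rank correlations between the "single-point" parameters (`e0`, `emax`,
#' measurable at one dose) and the dose-response parameters (`log2(HS)`,
#' `log10(EC50)`, requiring titration), with two-sided p-values.
#'
#' @param table a cell parameter table with >= 3 rows.
#' @return `data.frame` with columns `single_point`, `dose_response`, `rho`,
#'   `p_value`; `rho` is `NA` (with a warning) for constant columns.
#' @export
param_correlations <- function(table) {
  if (!is_cell_table(table)) abort("`table` must be a cell parameter table")
  if (nrow(table) < 3L) abort("need at least 3 cells for rank correlations")
  cols <- list(e0 = table$e0, emax = table$emax,
               `log2(hs)` = log2(table$hill_slope),
               `log10(ec50)` = log10(table$ec50_molar))
  pairs <- expand.grid(single_point = c("e0", "emax"),
                       dose_response = c("log2(hs)", "log10(ec50)"),
                       stringsAsFactors = FALSE)
  pairs$rho <- NA_real_; pairs$p_value <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    x <- cols[[pairs$single_point[i]]]
    y <- cols[[pairs$dose_response[i]]]
    if (sd(x) == 0 || sd(y) == 0) {
      warning(sprintf("constant column in pair (%s, %s): rho undefined",
                      pairs$single_point[i], pairs$dose_response[i]))
      next
    }
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    pairs$rho[i] <- unname(ct$estimate)
    pairs$p_value[i] <- ct$p.value
  }
  pairs
}

#' Write or read a cell parameter table as CSV
#'
#' @param table a cell parameter table.
#' @param path CSV path.
#' @return `write_cell_params()` returns `path` invisibly;
#'   `read_cell_params()` returns a `cell_param_table`.
#' @export
write_cell_params <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_params
#' @export
read_cell_params <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!is_cell_table(out))
    abort("file does not contain a cell parameter table")
  class(out) <- c("cell_param_table", "data.frame")
  out
}
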
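#' Sampling distribution for one dose-response parameter
#'
#' One parameter of the per-cell Hill model is sampled as a normal draw on a
#' stated scale (`linear`, `log10` or `log2`) and back-transformed. Sampling
#' `ec50` on log10 and `hs` on log2 guarantees positive values.
#'
#' @param mean location on the sampling scale.
#' @param sd spread on the sampling scale; >= 0.
#' @param scale one of `"linear"`, `"log10"`, `"log2"`.
#' @return A list of class `"param_dist"`.
#' @export
param_dist <- function(mean, sd, scale = c("linear", "log10", "log2")) {
  scale <- match.arg(scale)
  check_number(mean, "mean")
  check_number(sd, "sd", lower = 0)
  structure(list(mean = mean, sd = sd, scale = scale), class = "param_dist")
}

sample_param <- function(dist, n) {
  x <- rnorm(n, dist$mean, dist$sd)
  switch(dist$scale, linear = x, log10 = 10^x, log2 = 2^x)
}

#' Specify a heterogeneous cell population
#'
#' A population is an ordered list of subpopulations; each subpopulation has a
#' cell count and one [param_dist()] per Hill parameter (`e0`, `emax`, `ec50`,
#' `hs`). Parameters are sampled independently within each cell.
#'
#' @param subpopulations list of subpopulations, each a list with elements
#'   `count` (>= 1), `label` (optional), and `e0`, `emax`, `ec50`, `hs`
#'   ([param_dist()] objects).
#' @param name label for the population.
#' @return An object of class `"population_spec"`.
#' @seealso [population_preset()] for the built-in mixture presets,
#'   [sample_population()] to draw cells.
#' @export
population_spec <- function(subpopulations, name = "custom") {
  if (!is.list(subpopulations) || length(subpopulations) == 0L)
    abort("`subpopulations` must be a non-empty list")
  subpopulations <- lapply(seq_along(subpopulations), function(i) {
    sp <- subpopulations[[i]]
    if (is.null(sp$count) || sp$count < 1)
      abort("each subpopulation needs a `count` >= 1")
    sp$count <- as.integer(sp$count)
    if (is.null(sp$label)) sp$label <- paste0("subpop", i)
    for (nm in c("e0", "emax", "ec50", "hs")) {
      if (is.null(sp[[nm]]))
        abort(sprintf("subpopulation %d is missing a `%s` distribution", i, nm))
      if (!inherits(sp[[nm]], "param_dist"))
        sp[[nm]] <- do.call(param_dist, as.list(sp[[nm]]))
    }
    sp[c("count", "label", "e0", "emax", "ec50", "hs")]
  })
  structure(list(name = name, subpopulations = subpopulations),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> '%s': %d subpopulation(s), %d cells total\n",
              x$name, length(x$subpopulations),
              sum(vapply(x$subpopulations, `[[`, 1L, "count"))))
  for (sp in x$subpopulations)
    cat(sprintf(
      "  %s (n=%d): E0~N(%g,%g), Emax~N(%g,%g), log10EC50~N(%g,%g), log2HS~N(%g,%g)\n",
      sp$label, sp$count, sp$e0$mean, sp$e0$sd, sp$emax$mean, sp$emax$sd,
      sp$ec50$mean, sp$ec50$sd, sp$hs$mean, sp$hs$sd))
  invisible(x)
}

# shorthand for the recurring Table-style rows
subpop <- function(count, label, e0_m = 1, e0_s = 0.1, emax_m = 0.16,
                   emax_s = 0.1, lec50_m = -7.72, lec50_s = 0.1,
                   lhs_m = -1.02, lhs_s = 0.1) {
  list(count = count, label = label,
       e0 = param_dist(e0_m, e0_s, "linear"),
       emax = param_dist(emax_m, emax_s, "linear"),
       ec50 = param_dist(lec50_m, lec50_s, "log10"),
       hs = param_dist(lhs_m, lhs_s, "log2"))
}

#' Built-in hypothetical population presets
#'
#' Four mixtures of per-cell Hill-parameter distributions, centred on a
#' population-level omipalisib/MCF-7 dose response (basal normalized to 1),
#' that produce nearly identical population-averaged dose responses while
#' differing sharply at the single-cell level:
#'
#' * `low_variance` — one mode, sd 0.1 on all sampling scales (1000 cells).
#' * `high_variance` — as above but sd 0.5 on log10(EC50) and log2(HS).
#' * `bimodal` — two modes of 500 cells, log10(EC50) means -6.72 / -8.72 and
#'   log2(HS) means -1.42 / -0.62.
#' * `resistant` — 950 bulk cells plus a 50-cell resistant subpopulation with
#'   Emax mean 0.46 and log10(EC50) mean -4.72.
#'
#' A fifth preset, `steep_unimodal`, models a population of near-switch-like
#' responders: steep individual slopes (log2(HS) mean 1.66, i.e. mean HS
#' 3.16) with a broad EC50 spread (sd 0.5 on both log scales), used to show
#' that the population-fitted Hill slope can represent almost no cell in the
#' population.
#'
#' @param name preset name.
#' @return A [population_spec()].
#' @export
population_preset <- function(name = c("low_variance", "high_variance",
                                       "bimodal", "resistant",
                                       "steep_unimodal")) {
  if (length(name) != 1L || !name %in% c("low_variance", "high_variance",
                                         "bimodal", "resistant",
                                         "steep_unimodal"))
    abort(paste0("unknown preset; choose one of low_variance, high_variance, ",
                 "bimodal, resistant, steep_unimodal"),
          class = "scdose_unknown_preset")
  spec <- switch(name,
    low_variance = list(subpop(1000L, "population1")),
    high_variance = list(subpop(1000L, "population1",
                                lec50_s = 0.5, lhs_s = 0.5)),
    bimodal = list(
      subpop(500L, "population1", lec50_m = -6.72, lhs_m = -1.42),
      subpop(500L, "population2", lec50_m = -8.72, lhs_m = -0.62)),
    resistant = list(
      subpop(950L, "population1"),
      subpop(50L, "population2", emax_m = 0.46, lec50_m = -4.72)),
    steep_unimodal = list(subpop(1000L, "population1",
                                 lec50_s = 0.5, lhs_m = 1.66, lhs_s = 0.5))
  )
  population_spec(spec, name = name)
}

#' Sample per-cell Hill parameters from a population specification
#'
#' Each subpopulation is visited in listed order; within a subpopulation the
#' parameters are drawn in the fixed order `e0`, `emax`, `ec50`, `hs`
#' (independently, each on its own scale, then back-transformed), so a seed
#' fully determines the output. `e0` and `emax` are sampled on the linear
#' scale without truncation; rare negative draws are kept.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream. The caller's RNG state is restored when a seed is given.
#' @param n_cells optionally rescale the total cell count, preserving the
#'   subpopulation proportions (rounded; first subpopulation absorbs the
#'   remainder).
#' @return A cell parameter table: `data.frame` with columns `cell_id`,
#'   `subpopulation`, `e0`, `emax`, `ec50_molar`, `hill_slope`.
#' @export
sample_population <- function(spec, seed = NULL, n_cells = NULL) {
  if (!inherits(spec, "population_spec"))
    abort("`spec` must be a population_spec")
  counts <- vapply(spec$subpopulations, `[[`, 1L, "count")
  if (!is.null(n_cells)) {
    check_number(n_cells, "n_cells", lower = 1)
    counts <- pmax(1L, as.integer(round(n_cells * counts / sum(counts))))
    counts[1] <- counts[1] + as.integer(n_cells) - sum(counts)
  }
  with_seed(seed, {
    parts <- lapply(seq_along(spec$subpopulations), function(i) {
      sp <- spec$subpopulations[[i]]
      n <- counts[i]
      data.frame(
        subpopulation = rep(sp$label, n),
        e0 = sample_param(sp$e0, n),
        emax = sample_param(sp$emax, n),
        ec50_molar = sample_param(sp$ec50, n),
        hill_slope = sample_param(sp$hs, n)
      )
    })
    out <- do.call(rbind, parts)
    out <- cbind(cell_id = sprintf("cell_%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Population-averaged dose response
#'
#' The population-level curve a bulk assay would report: the arithmetic mean
#' of every cell's Hill curve at each dose.
#'
#' @param cells a cell parameter table (see [sample_population()]).
#' @param grid dose grid in molar (see [dose_grid()]).
#' @return Numeric vector of mean responses, one per grid dose.
#' @export
population_average <- function(cells, grid = dose_grid()) {
  if (!is_cell_table(cells) || nrow(cells) == 0L)
    abort("`cells` must be a non-empty cell parameter table")
  check_grid(grid)
  colMeans(hill_matrix(cells, grid))
}

#' Read or write a population specification
#'
#' Specifications are stored as YAML or JSON (chosen by file extension) with
#' the layout `{name, subpopulations: [{count, label, e0: {mean, sd, scale},
#' emax: ..., ec50: ..., hs: ...}]}`.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @param spec a [population_spec()] (write only).
#' @return `read_population_spec()` returns a [population_spec()];
#'   `write_population_spec()` returns `path` invisibly.
#' @export
read_population_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  population_spec(raw$subpopulations,
                  name = if (is.null(raw$name)) "unnamed" else raw$name)
}

#' @rdname read_population_spec
#' @export
write_population_spec <- function(spec, path) {
  if (!inherits(spec, "population_spec"))
    abort("`spec` must be a population_spec")
  plain <- list(
    name = spec$name,
    subpopulations = lapply(spec$subpopulations, function(sp)
      lapply(sp, function(el) if (inherits(el, "param_dist"))
        unclass(el) else el))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(plain, path)
  invisible(path)
}
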
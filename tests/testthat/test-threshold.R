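test_that("inhibition curve equals the mean of per-cell indicator calls", {
  cells <- sample_population(population_preset("high_variance"), seed = 2,
                             n_cells = 100)
  grid <- dose_grid(n = 15)
  curve <- inhibition_curve(cells, grid, 0.6)
  byhand <- vapply(grid, function(d) mean(is_inhibited(cells, d, 0.6)),
                   numeric(1))
  expect_equal(as.numeric(curve), byhand)
  # nobody is inhibited at dose zero (response equals basal, strict <)
  expect_equal(inhibition_curve(cells, c(0, 1e-9), 0.6)[1], 0)
})

test_that("preset mixtures classify as expected at key doses", {
  bi <- sample_population(population_preset("bimodal"), seed = 6)
  curve <- inhibition_curve(bi, c(10^-7.72, 10^-5), 0.6)
  # sensitive mode inhibited, insensitive mode not: about half the cells
  expect_lt(abs(curve[1] - 0.5), 0.05)
  rs <- sample_population(population_preset("resistant"), seed = 6)
  top <- inhibition_curve(rs, c(1e-6, 1e-5), 0.6)[2]
  expect_lt(abs(top - 0.95), 0.03)
})

test_that("surfaces stack curves consistently and monotonically", {
  cells <- sample_population(population_preset("low_variance"), seed = 4,
                             n_cells = 200)
  surf <- inhibition_surface(cells)
  expect_equal(range(surf$thresholds), c(0.2, 0.9))
  expect_equal(dim(surf$proportions),
               c(length(surf$thresholds), length(surf$doses)))
  # the 60% row is bit-for-bit the standalone curve
  i60 <- which(abs(surf$thresholds - 0.6) < 1e-9)
  expect_identical(surf$proportions[i60, ],
                   setNames(as.numeric(inhibition_curve(cells, surf$doses, 0.6)),
                            colnames(surf$proportions)))
  # non-decreasing along dose (all cells have e0 > emax here) and threshold
  expect_true(all(apply(surf$proportions, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(surf$proportions, 2, function(c) all(diff(c) >= 0))))
  expect_true(all(surf$proportions >= 0 & surf$proportions <= 1))
})

test_that("cells with non-positive basal are excluded with a warning", {
  cells <- sample_population(population_preset("low_variance"), seed = 1,
                             n_cells = 20)
  cells$e0[1:3] <- -0.2
  expect_warning(curve <- inhibition_curve(cells, dose_grid(n = 5), 0.6),
                 "excluded")
  expect_equal(attr(curve, "n_cells"), 17L)
  cells$e0 <- -1
  expect_error(suppressWarnings(inhibition_curve(cells, dose_grid(n = 5), 0.6)),
               class = "scdose_invalid_input")
})

test_that("surfaces from fitted parameters reproduce true-parameter surfaces", {
  doses <- c(0, default_titration_schedule()$steps$concentration)
  cells <- sample_population(population_preset("low_variance"), seed = 13,
                             n_cells = 15)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    p <- hill_params(cells$e0[i], cells$emax[i], cells$ec50_molar[i],
                     cells$hill_slope[i])
    data.frame(cell_id = cells$cell_id[i], dose = doses,
               response = hill_response(p, doses))
  }))
  fits <- fit_cells(rows)
  grid <- dose_grid(n = 25)
  th <- seq(0.3, 0.8, by = 0.05)
  s_fit <- surface_from_fits(fits, grid, th)
  s_true <- inhibition_surface(cells, grid, th)
  # noiseless fits recover the parameters, so the surfaces agree cell-by-cell
  expect_lt(max(abs(s_fit$proportions - s_true$proportions)), 1 / 15 + 1e-9)
  # single-cell surface only takes values 0 or 1
  s1 <- surface_from_fits(fits[1, ], grid, th)
  expect_true(all(s1$proportions %in% c(0, 1)))
  # flagged degenerate cells are dropped from the cell count
  fits2 <- fits
  fits2$degenerate[1:2] <- TRUE
  expect_equal(surface_from_fits(fits2, grid, th)$n_cells, nrow(fits) - 2L)
})

test_that("dose-escalation factors match per-cell quantiles", {
  # homogeneous population: the curve is a step, factor ~ 1 within one grid cell
  hom <- sample_population(constant_spec(50), seed = 1)
  grid <- dose_grid(n = 50)
  s_hom <- inhibition_surface(hom, grid, seq(0.5, 0.7, by = 0.1))
  fac <- dose_escalation_factor(s_hom, 0.6, 0.4, 0.6)
  grid_step <- (1e-5 / 1e-11)^(1 / 49)
  expect_lt(fac, grid_step * (1 + 1e-9))
  expect_gte(fac, 1)
  # heterogeneous population: factor equals the ratio of inhibition-dose quantiles
  hv <- sample_population(population_preset("high_variance"), seed = 3)
  s_hv <- inhibition_surface(hv, grid, seq(0.5, 0.7, by = 0.1))
  fac2 <- dose_escalation_factor(s_hv, 0.6, 0.4, 0.5)
  dcrit <- vapply(seq_len(nrow(hv)), function(i)
    inhibition_dose(hill_params(hv$e0[i], hv$emax[i], hv$ec50_molar[i],
                                hv$hill_slope[i]), 0.6), numeric(1))
  q <- unname(quantile(dcrit, c(0.4, 0.5), type = 1))
  expect_lt(abs(log(fac2) - log(q[2] / q[1])), 2 * log(grid_step))
  # resistant plateau: the requested proportion is never reached
  rs <- sample_population(population_preset("resistant"), seed = 3)
  s_rs <- inhibition_surface(rs, grid, seq(0.5, 0.7, by = 0.1))
  err <- tryCatch(dose_escalation_factor(s_rs, 0.6, 0.5, 0.99),
                  scdose_not_reached = function(e) e)
  expect_s3_class(err, "scdose_not_reached")
  expect_lt(abs(err$plateau - 0.95), 0.03)
})

test_that("surfaces export to long and matrix CSV", {
  cells <- sample_population(constant_spec(10), seed = 2)
  surf <- inhibition_surface(cells, dose_grid(n = 8), seq(0.3, 0.5, by = 0.1))
  long_path <- file.path(tempdir(), "surf_long.csv")
  write_surface_csv(surf, long_path, "long")
  long <- read.csv(long_path)
  expect_equal(nrow(long), 3 * 8)
  expect_equal(sort(names(long)),
               sort(c("threshold", "dose_molar", "proportion", "n_cells")))
  mat_path <- file.path(tempdir(), "surf_mat.csv")
  write_surface_csv(surf, mat_path, "matrix")
  expect_equal(dim(read.csv(mat_path, check.names = FALSE)), c(3L, 9L))
})
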
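const_traj <- function(value = 0.8, cadence = 3,
                       schedule = default_titration_schedule(),
                       cell_id = "c1", channel = "Akt") {
  tt <- seq(schedule$pre_drug_start, max(schedule$steps$time) + 60,
            by = cadence)
  data.frame(cell_id = cell_id, channel = channel, time_min = tt,
             log2_cnr = value)
}

test_that("dosing schedules validate and match the default titration", {
  expect_error(dosing_schedule(c(10, 5), c(1e-9, 2e-9)),
               class = "scdose_invalid_input")
  expect_error(dosing_schedule(c(5, 10), c(2e-9, 1e-9)),
               class = "scdose_invalid_input")
  sched <- default_titration_schedule()
  expect_equal(sched$steps$concentration,
               c(0.15e-9, 0.6e-9, 2.4e-9, 9.8e-9, 39e-9, 156e-9, 625e-9,
                 2.5e-6, 10e-6, 40e-6))
  expect_equal(nrow(sched$steps), 10L)
  expect_equal(diff(sched$steps$time), rep(60, 9))
  expect_equal(sched$pre_drug_start, 0)
})

test_that("complete-track filtering keeps full-span, gap-free trajectories", {
  sched <- default_titration_schedule()
  full <- const_traj()
  short <- const_traj(cell_id = "c2")
  short <- short[short$time_min < 400, ]
  gappy <- const_traj(cell_id = "c3")
  gappy <- gappy[gappy$time_min < 300 | gappy$time_min > 312, ]
  traj <- rbind(full, short, gappy)
  expect_message(kept <- filter_complete_tracks(traj, sched), "excluded")
  expect_equal(unique(kept$cell_id), "c1")
  expect_equal(attr(kept, "n_excluded"), 2L)
  # generator dropouts: survivors agree with the ground-truth bookkeeping
  out <- synth_trajectories(population_preset("low_variance"),
                            kinetics = kinetics_spec(noise_sd = 0),
                            seed = 12, dropout_fraction = 0.2, n_cells = 40)
  kept2 <- suppressMessages(filter_complete_tracks(out$trajectories, sched))
  expect_setequal(unique(kept2$cell_id),
                  names(which(out$ground_truth$complete)))
})

test_that("baseline is the pre-dose window mean", {
  sched <- default_titration_schedule()
  expect_equal(baseline_activity(const_traj(0.8), sched), 0.8)
  set.seed(14)
  noisy <- const_traj(0)
  noisy$log2_cnr <- 1.3 + rnorm(nrow(noisy), 0, 0.05)
  k <- sum(noisy$time_min >= 10 & noisy$time_min < 20)
  expect_lt(abs(baseline_activity(noisy, sched) - 1.3), 3 * 0.05 / sqrt(k))
  late <- const_traj()
  late <- late[late$time_min >= 25, ]
  expect_error(baseline_activity(late, sched),
               class = "scdose_missing_baseline")
})

test_that("per-dose extraction reads the closing window of each hold", {
  sched <- default_titration_schedule()
  flat <- extract_per_dose_response(const_traj(0.42), sched)
  expect_equal(flat$dose, c(0, sched$steps$concentration))
  expect_equal(flat$response, rep(0.42, 11))
  # fast relaxation: window means sit on the steady states
  p <- hill_params(1, 0.16, 10^-7.72, 2^-1.02)
  fast <- synth_trajectories(constant_spec(1), sched,
                             kinetics_spec(tau = 10, noise_sd = 0), seed = 1)
  got_fast <- extract_per_dose_response(fast$trajectories, sched)
  truth <- c(p$e0, hill_response(p, sched$steps$concentration))
  err_fast <- max(abs(got_fast$response - truth))
  expect_lt(err_fast, 0.01)
  # slow relaxation: measurably displaced from the steady states
  slow <- synth_trajectories(constant_spec(1), sched,
                             kinetics_spec(tau = 60, noise_sd = 0), seed = 1)
  got_slow <- extract_per_dose_response(slow$trajectories, sched)
  err_slow <- max(abs(got_slow$response - truth))
  expect_gt(err_slow, 2 * err_fast)
  # a hole over a window is a named error
  holed <- const_traj()
  holed <- holed[!(holed$time_min >= 70 & holed$time_min < 80), ]
  expect_error(extract_per_dose_response(holed, sched),
               class = "scdose_missing_window")
})

test_that("extraction tolerates acquisition jitter", {
  sched <- default_titration_schedule()
  out <- synth_trajectories(constant_spec(1), sched,
                            kinetics_spec(tau = 10, noise_sd = 0), seed = 2)
  base <- extract_per_dose_response(out$trajectories, sched)
  set.seed(99)
  jit <- out$trajectories
  jit$time_min <- jit$time_min + runif(nrow(jit), -0.5, 0.5)
  jit <- jit[order(jit$time_min), ]
  shifted <- extract_per_dose_response(jit, sched)
  expect_lt(max(abs(shifted$response - base$response)), 0.02)
})

test_that("the dose-response table covers cells x channels x 11 levels", {
  sched <- default_titration_schedule()
  one <- const_traj(0.5)
  tab1 <- suppressMessages(build_dose_response_table(one, sched))
  expect_equal(nrow(tab1), 11L)
  akt <- synth_trajectories(population_preset("low_variance"), sched,
                            kinetics_spec(noise_sd = 0.05), seed = 3,
                            channel = "Akt", n_cells = 8)
  erk <- synth_trajectories(population_preset("low_variance"), sched,
                            kinetics_spec(noise_sd = 0.05), seed = 4,
                            channel = "ERK", n_cells = 8)
  tab <- build_dose_response_table(rbind(akt$trajectories, erk$trajectories),
                                   sched)
  expect_equal(nrow(tab), 8 * 2 * 11)
  # round trip: table -> per-cell fits -> surface
  fits <- fit_cells(tab[tab$channel == "Akt", ])
  surf <- surface_from_fits(fits, dose_grid(n = 10), seq(0.4, 0.7, 0.1))
  expect_s3_class(surf, "threshold_surface")
  expect_equal(surf$n_cells, 8L)
})

test_that("distribution comparison reports KDEs, means and shift", {
  set.seed(31)
  a <- rnorm(200, 0.5, 0.2)
  same <- compare_distributions(a, a)
  expect_equal(same$shift, 0)
  expect_equal(same$kde_a$y, same$kde_b$y)
  off <- compare_distributions(a, a + 1)
  expect_equal(off$shift, 1)
  b <- rnorm(200, 0.5, 0.2)
  expect_lt(abs(compare_distributions(a, b)$shift), 3 * 0.2 * sqrt(2 / 200))
  expect_error(compare_distributions(a, c(1, 2)),
               class = "scdose_invalid_input")
  with_test <- compare_distributions(a, b, test = TRUE)
  expect_true(is.numeric(with_test$test$p.value))
})

test_that("trajectories and schedules round-trip through disk", {
  sched <- default_titration_schedule()
  spath <- file.path(tempdir(), "schedule.yaml")
  write_schedule(sched, spath)
  expect_equal(read_schedule(spath), sched)
  traj <- const_traj(0.8)
  tpath <- file.path(tempdir(), "traj.csv")
  write_trajectories(traj, tpath)
  expect_equal(read_trajectories(tpath), traj)
})
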
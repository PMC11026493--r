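#' Signal relaxation kinetics for the trajectory generator
#'
#' Synthetic cells relax exponentially toward each dose's steady state with
#' time constant `tau`; measurement noise is additive Gaussian on the
#' log2(CNR) scale. Two presets reflect the qualitative kinetics of the cell
#' lines the generator emulates: `"fast"` (tau = 10 min, MCF-7-like, at steady
#' state well within a 60-min hold) and `"slow"` (tau = 60 min,
#' Vari-068-like, still relaxing after hours).
#'
#' @param tau relaxation time constant in minutes, > 0.
#' @param noise_sd additive measurement noise sd on log2(CNR), >= 0.
#' @return A list of class `"kinetics_spec"`.
#' @export
kinetics_spec <- function(tau = 10, noise_sd = 0.05) {
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(tau = tau, noise_sd = noise_sd), class = "kinetics_spec")
}

#' @rdname kinetics_spec
#' @param name `"fast"` or `"slow"`.
#' @export
kinetics_preset <- function(name = c("fast", "slow"), noise_sd = 0.05) {
  name <- match.arg(name)
  kinetics_spec(tau = if (name == "fast") 10 else 60, noise_sd = noise_sd)
}

# exact piecewise-exponential signal of one cell at the sample times
relax_signal <- function(params, schedule, kinetics, times) {
  steps <- schedule$steps
  targets <- vapply(steps$concentration, function(d)
    hill_response(params, d), numeric(1))
  seg_start <- c(schedule$pre_drug_start, steps$time)
  seg_target <- c(params$e0, targets)
  # signal value at the start of each segment (continuous across boundaries)
  s0 <- numeric(length(seg_start))
  s0[1] <- params$e0
  for (k in seq_along(seg_start)[-1]) {
    dt <- seg_start[k] - seg_start[k - 1]
    s0[k] <- seg_target[k - 1] +
      (s0[k - 1] - seg_target[k - 1]) * exp(-dt / kinetics$tau)
  }
  seg <- findInterval(times, seg_start)
  seg[seg < 1] <- 1
  seg_target[seg] +
    (s0[seg] - seg_target[seg]) * exp(-(times - seg_start[seg]) / kinetics$tau)
}

#' Generate synthetic dose-titration trajectories with ground truth
#'
#' For each cell: Hill parameters are sampled from `spec`; each dose step
#' defines a steady-state target `hill_response(params, dose)` (the same code
#' path used everywhere else in the package); the signal relaxes toward the
#' current target as \eqn{s(t) = target + (s(t_0) - target) e^{-(t-t_0)/\tau}};
#' samples are taken every `cadence` minutes with additive Gaussian noise.
#' Optionally a fraction of cells drops out (track lost) at a uniform random
#' time. Bit-reproducible under a fixed seed.
#'
#' @param spec a [population_spec()].
#' @param schedule a [dosing_schedule()]; default
#'   [default_titration_schedule()].
#' @param kinetics a [kinetics_spec()].
#' @param seed integer seed (caller RNG state restored); `NULL` uses the
#'   current stream.
#' @param cadence acquisition interval in minutes (default 3).
#' @param channel channel label attached to the trajectories.
#' @param dropout_fraction fraction of cells losing tracking mid-experiment.
#' @param n_cells optionally rescale the population size (see
#'   [sample_population()]).
#' @return List with `trajectories` (long `data.frame`: `cell_id`, `channel`,
#'   `time_min`, `log2_cnr`) and `ground_truth` (list: `params` cell
#'   parameter table, `steady_states` per cell x dose incl. 0,
#'   `dropout_time` named vector, `complete` named logical).
#' @export
synth_trajectories <- function(spec, schedule = default_titration_schedule(),
                               kinetics = kinetics_spec(), seed = NULL,
                               cadence = 3, channel = "Akt",
                               dropout_fraction = 0, n_cells = NULL) {
  if (!inherits(schedule, "dosing_schedule"))
    abort("`schedule` must be a dosing_schedule")
  if (!inherits(kinetics, "kinetics_spec"))
    abort("`kinetics` must be a kinetics_spec")
  check_number(cadence, "cadence", lower = 0, strict_lower = TRUE)
  check_number(dropout_fraction, "dropout_fraction", lower = 0, upper = 1)
  t_end <- schedule_end(schedule)
  times <- seq(schedule$pre_drug_start, t_end, by = cadence)
  with_seed(seed, {
    cells <- sample_population(spec, seed = NULL, n_cells = n_cells)
    n <- nrow(cells)
    drop_flag <- runif(n) < dropout_fraction
    drop_time <- ifelse(drop_flag,
                        runif(n, schedule$steps$time[1], t_end), Inf)
    rows <- vector("list", n)
    ss <- vector("list", n)
    for (i in seq_len(n)) {
      p <- hill_params(cells$e0[i], cells$emax[i], cells$ec50_molar[i],
                       cells$hill_slope[i])
      tt <- times[times < drop_time[i]]
      sig <- relax_signal(p, schedule, kinetics, tt)
      if (kinetics$noise_sd > 0)
        sig <- sig + rnorm(length(sig), 0, kinetics$noise_sd)
      rows[[i]] <- data.frame(cell_id = cells$cell_id[i], channel = channel,
                              time_min = tt, log2_cnr = sig)
      ss[[i]] <- data.frame(
        cell_id = cells$cell_id[i],
        dose = c(0, schedule$steps$concentration),
        response = c(p$e0, hill_response(p, schedule$steps$concentration)))
    }
    list(
      trajectories = do.call(rbind, rows),
      ground_truth = list(
        params = cells,
        steady_states = do.call(rbind, ss),
        dropout_time = setNames(drop_time, cells$cell_id),
        complete = setNames(!drop_flag, cells$cell_id)))
  })
}

#' Generate synthetic single-point (one-dose) trajectories
#'
#' One-step variant of [synth_trajectories()]: 20 minutes of pre-drug
#' imaging, then a single dose held for 60 minutes. `dose = 0` produces
#' pure baseline trajectories centred on each cell's sampled basal response.
#' Enables the titration-vs-single-point distribution comparison.
#'
#' @inheritParams synth_trajectories
#' @param dose the single concentration in molar (>= 0; 0 = untreated).
#' @return As [synth_trajectories()].
#' @export
synth_single_point <- function(spec, dose, kinetics = kinetics_spec(),
                               seed = NULL, cadence = 3, channel = "Akt",
                               n_cells = NULL) {
  check_number(dose, "dose", lower = 0)
  if (dose == 0) {
    # untreated: reuse the machinery with a vanishingly small dose, which
    # leaves every cell at its basal steady state
    sched <- dosing_schedule(times = 20, concentrations = 1e-300,
                             pre_drug_start = 0)
  } else {
    sched <- dosing_schedule(times = 20, concentrations = dose,
                             pre_drug_start = 0)
  }
  out <- synth_trajectories(spec, sched, kinetics, seed = seed,
                            cadence = cadence, channel = channel,
                            n_cells = n_cells)
  if (dose == 0) out$ground_truth$steady_states$dose <- 0
  out
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, ]
}

#' Render a synthetic two-channel image stack from trajectories
#'
#' Builds a microscopy-like fixture with exact ground truth: each cell is a
#' bright nuclear disk (nuclear-marker channel) surrounded by a perinuclear
#' annulus in each reporter channel whose intensity is chosen so that the
#' region means reproduce that cell's log2(CNR) at that frame exactly
#' (`cytoplasm = nuclear_reporter * 2^log2_cnr`). Cells sit on a jittered
#' grid and perform a small random walk between frames. Optional Gaussian
#' pixel noise emulates shot noise.
#'
#' @param trajectories long trajectory `data.frame` (all cells sampled at the
#'   same times in every channel).
#' @param geometry list overriding any of: `nucleus_radius` (px, default 7),
#'   `ring_width` (rendered annulus width beyond the nucleus, default 8; must
#'   exceed the measurement ring radius so rings stay inside the rendered
#'   annulus), `spacing` (grid pitch, default 40), `margin` (default 24),
#'   `drift_sd` (random-walk step sd in px/frame, default 0.3),
#'   `nuclear_intensity` (default 0.9), `nuclear_reporter` (reporter
#'   intensity inside the nucleus, default 0.4), `background` (default 0.1).
#' @param seed integer seed for placement jitter, drift and pixel noise.
#' @param noise_sd Gaussian pixel noise sd (default 0 = noise-free).
#' @return List with `nuclear` (rows x cols x frames array), `reporters`
#'   (named list of arrays, one per channel), `times`, `masks` (per-frame
#'   ground-truth [labeled_mask()], label k = k-th cell), `cells` (cell ids
#'   in label order) and `positions` (cells x 2 x frames array of centres).
#' @export
synth_image_stack <- function(trajectories, geometry = list(), seed = NULL,
                              noise_sd = 0) {
  check_trajectories(trajectories)
  g <- modifyList(list(nucleus_radius = 7, ring_width = 8, spacing = 40,
                       margin = 24, drift_sd = 0.3, nuclear_intensity = 0.9,
                       nuclear_reporter = 0.4, background = 0.1), geometry)
  cells <- unique(trajectories$cell_id)
  channels <- unique(trajectories$channel)
  times <- sort(unique(trajectories$time_min))
  n <- length(cells); n_frames <- length(times)
  # all cells must share the time base in every channel
  vals <- array(NA_real_, c(n, length(channels), n_frames),
                dimnames = list(cells, channels, NULL))
  for (r in seq_len(nrow(trajectories))) {
    vals[trajectories$cell_id[r], trajectories$channel[r],
         match(trajectories$time_min[r], times)] <- trajectories$log2_cnr[r]
  }
  if (any(is.na(vals)))
    abort("all cells must be sampled at the same times in every channel")
  reach <- g$nucleus_radius + g$ring_width
  if (g$spacing < 2 * reach + 2 || g$margin < reach + 2)
    abort("infeasible packing: increase spacing/margin or shrink cells")
  ncg <- ceiling(sqrt(n)); nrg <- ceiling(n / ncg)
  nr <- 2 * g$margin + (nrg - 1) * g$spacing
  nc <- 2 * g$margin + (ncg - 1) * g$spacing
  base_y <- g$margin + g$spacing * ((seq_len(n) - 1) %/% ncg)
  base_x <- g$margin + g$spacing * ((seq_len(n) - 1) %% ncg)

  with_seed(seed, {
    jig <- matrix(runif(2 * n, -2, 2), n, 2)
    pos <- array(NA_real_, c(n, 2, n_frames))
    pos[, 1, 1] <- base_y + jig[, 1]
    pos[, 2, 1] <- base_x + jig[, 2]
    if (n_frames > 1) for (t in 2:n_frames) {
      pos[, , t] <- pos[, , t - 1] + matrix(rnorm(2 * n, 0, g$drift_sd), n, 2)
      # keep the walk well inside the field
      pos[, 1, t] <- pmin(pmax(pos[, 1, t], reach + 1), nr - reach - 1)
      pos[, 2, t] <- pmin(pmax(pos[, 2, t], reach + 1), nc - reach - 1)
    }
    disk <- disk_offsets(g$nucleus_radius)
    annul <- disk_offsets(reach)
    nuclear <- array(g$background, c(nr, nc, n_frames))
    reporters <- setNames(
      lapply(channels, function(ch) array(g$background, c(nr, nc, n_frames))),
      channels)
    masks <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      lab <- matrix(0L, nr, nc)
      nuc_img <- nuclear[, , t]
      rep_imgs <- lapply(reporters, function(a) a[, , t])
      for (i in seq_len(n)) {
        cy <- round(pos[i, 1, t]); cx <- round(pos[i, 2, t])
        ai <- cbind(cy + annul$dy, cx + annul$dx)
        di <- cbind(cy + disk$dy, cx + disk$dx)
        lab[di] <- i
        nuc_img[di] <- g$nuclear_intensity
        for (ch in channels) {
          v <- vals[i, ch, t]
          rep_imgs[[ch]][ai] <- g$nuclear_reporter * 2^v
          rep_imgs[[ch]][di] <- g$nuclear_reporter
        }
      }
      if (noise_sd > 0) {
        nuc_img <- nuc_img + rnorm(nr * nc, 0, noise_sd)
        rep_imgs <- lapply(rep_imgs, function(m)
          m + rnorm(nr * nc, 0, noise_sd))
      }
      nuclear[, , t] <- nuc_img
      for (ch in channels) reporters[[ch]][, , t] <- rep_imgs[[ch]]
      masks[[t]] <- labeled_mask(lab, connectivity = "ground_truth")
    }
    list(nuclear = nuclear, reporters = reporters, times = times,
         masks = masks, cells = cells, positions = pos)
  })
}
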
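#' Dosing schedule for a titration experiment
#'
#' An ordered set of dose additions: at each `time` (minutes from the start
#' of imaging) the bath concentration is raised to `concentration` (molar).
#' Concentrations must increase strictly across steps (a titration).
#' `pre_drug_start` marks when pre-drug imaging begins.
#'
#' @param times strictly increasing vector of dose-addition times (minutes).
#' @param concentrations strictly increasing vector of molar concentrations,
#'   all > 0, same length as `times`.
#' @param pre_drug_start start of pre-drug imaging (minutes); must precede
#'   the first dose.
#' @return An object of class `"dosing_schedule"`: list with `steps`
#'   (`data.frame` of `time`, `concentration`) and `pre_drug_start`.
#' @export
dosing_schedule <- function(times, concentrations, pre_drug_start = 0) {
  if (length(times) != length(concentrations) || length(times) == 0L)
    abort("`times` and `concentrations` must be non-empty and equal length")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
    abort("`times` must be finite and strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0) ||
      is.unsorted(concentrations, strictly = TRUE))
    abort("`concentrations` must be positive and strictly increasing")
  check_number(pre_drug_start, "pre_drug_start", upper = min(times))
  structure(list(
    steps = data.frame(time = times, concentration = concentrations),
    pre_drug_start = pre_drug_start), class = "dosing_schedule")
}

#' @export
print.dosing_schedule <- function(x, ...) {
  cat(sprintf(
    "<dosing_schedule> %d steps, pre-drug imaging from %g min, first dose at %g min\n",
    nrow(x$steps), x$pre_drug_start, x$steps$time[1]))
  invisible(x)
}

#' Default 10-step, 4x dose-titration schedule
#'
#' Twenty minutes of pre-drug imaging, then ten doses added at 60-minute
#' intervals, each roughly 4x the previous: 0.15 nM, 0.6 nM, 2.4 nM, 9.8 nM,
#' 39 nM, 156 nM, 625 nM, 2.5 uM, 10 uM, 40 uM. Together with the untreated
#' baseline this yields 11 dose levels per cell.
#'
#' @return A [dosing_schedule()].
#' @export
default_titration_schedule <- function() {
  conc <- c(0.15e-9, 0.6e-9, 2.4e-9, 9.8e-9, 39e-9, 156e-9, 625e-9,
            2.5e-6, 10e-6, 40e-6)
  dosing_schedule(times = 20 + 60 * (seq_along(conc) - 1),
                  concentrations = conc, pre_drug_start = 0)
}

schedule_end <- function(schedule) max(schedule$steps$time) + 60

check_trajectories <- function(traj) {
  need <- c("cell_id", "channel", "time_min", "log2_cnr")
  if (!is.data.frame(traj) || !all(need %in% names(traj)))
    abort("trajectories must have columns cell_id, channel, time_min, log2_cnr")
  invisible(traj)
}

#' Keep only cells tracked for the full experiment
#'
#' Retains trajectories that span the whole experiment window — from
#' `pre_drug_start` to 60 minutes after the final dose, each endpoint to
#' within one acquisition interval — with no sampling gap
#' longer than `max_gap_intervals` acquisition intervals. The acquisition
#' interval is taken as the median time step unless given.
#'
#' @param trajectories long-format `data.frame` with columns `cell_id`,
#'   `channel`, `time_min`, `log2_cnr`.
#' @param schedule a [dosing_schedule()].
#' @param cadence acquisition interval in minutes; `NULL` to infer.
#' @param max_gap_intervals largest tolerated gap, in acquisition intervals.
#' @return The retained subset (same columns); the number of dropped
#'   trajectories is reported in a message and in `attr(, "n_excluded")`.
#' @export
filter_complete_tracks <- function(trajectories, schedule, cadence = NULL,
                                   max_gap_intervals = 2) {
  check_trajectories(trajectories)
  if (!inherits(schedule, "dosing_schedule"))
    abort("`schedule` must be a dosing_schedule")
  t_end <- schedule_end(schedule)
  key <- paste(trajectories$cell_id, trajectories$channel, sep = "\r")
  keep <- vapply(split(trajectories$time_min, key), function(tt) {
    tt <- sort(tt)
    dt <- if (is.null(cadence)) median(diff(tt)) else cadence
    tt[1] <= schedule$pre_drug_start + dt &&
      tt[length(tt)] >= t_end - dt &&
      (length(tt) < 2L || max(diff(tt)) <= max_gap_intervals * dt)
  }, logical(1))
  sel <- keep[key]
  n_excl <- length(unique(key[!sel]))
  if (n_excl > 0)
    message(n_excl, " trajectory/trajectories excluded as incomplete")
  out <- trajectories[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}

#' Baseline (untreated) activity of one trajectory
#'
#' Mean signal in the `window` minutes immediately before the first dose,
#' i.e. over times in `[first_dose - window, first_dose)`.
#'
#' @param trajectory one cell's trajectory: `data.frame` with `time_min` and
#'   `log2_cnr` (one channel).
#' @param schedule a [dosing_schedule()].
#' @param window pre-dose averaging window in minutes (default 10).
#' @return Single numeric baseline estimate.
#' @export
baseline_activity <- function(trajectory, schedule, window = 10) {
  if (!all(c("time_min", "log2_cnr") %in% names(trajectory)))
    abort("`trajectory` must have columns time_min, log2_cnr")
  t1 <- schedule$steps$time[1]
  sel <- trajectory$time_min >= t1 - window & trajectory$time_min < t1
  if (!any(sel))
    abort("no samples in the pre-dose baseline window",
          class = "scdose_missing_baseline")
  mean(trajectory$log2_cnr[sel])
}

#' Per-dose steady-state responses of one trajectory
#'
#' For each dose step, the mean signal over the closing window of that step's
#' hold period — times in `[step_start + 50, step_start + 60)`, i.e. the last
#' 10 minutes of a 60-minute hold, chosen so fast-relaxing cells have reached
#' their new steady state. The untreated condition ([baseline_activity()]) is
#' attached as dose 0.
#'
#' @inheritParams baseline_activity
#' @param window length-2 offsets (minutes after each dose) delimiting the
#'   averaging window, closed on the left and open on the right.
#' @return `data.frame` with columns `dose`, `response` (first row is the
#'   untreated dose 0).
#' @export
extract_per_dose_response <- function(trajectory, schedule,
                                      window = c(50, 60)) {
  base <- baseline_activity(trajectory, schedule)
  steps <- schedule$steps
  resp <- vapply(seq_len(nrow(steps)), function(k) {
    sel <- trajectory$time_min >= steps$time[k] + window[1] &
      trajectory$time_min < steps$time[k] + window[2]
    if (!any(sel))
      abort(sprintf("no samples in the averaging window of step %d", k),
            class = "scdose_missing_window", step = k)
    mean(trajectory$log2_cnr[sel])
  }, numeric(1))
  data.frame(dose = c(0, steps$concentration), response = c(base, resp))
}

#' Build a per-cell dose-response table from tracked trajectories
#'
#' The bridge from time-domain to dose-domain data: filters complete tracks,
#' then applies [extract_per_dose_response()] per cell and channel. Cells
#' failing extraction (missing baseline or window samples) are dropped with a
#' logged reason.
#'
#' @inheritParams filter_complete_tracks
#' @param filter run [filter_complete_tracks()] first (default `TRUE`).
#' @return Long-format `data.frame` with columns `cell_id`, `channel`,
#'   `dose`, `response` — one row per cell x channel x dose level (the number
#'   of steps plus the untreated condition). Drop reasons are kept in
#'   `attr(, "dropped")`.
#' @export
build_dose_response_table <- function(trajectories, schedule, filter = TRUE) {
  check_trajectories(trajectories)
  if (filter)
    trajectories <- filter_complete_tracks(trajectories, schedule)
  key <- paste(trajectories$cell_id, trajectories$channel, sep = "\r")
  groups <- split(seq_len(nrow(trajectories)), key)
  rows <- list(); dropped <- character(0)
  for (g in names(groups)) {
    sub <- trajectories[groups[[g]], ]
    res <- tryCatch(extract_per_dose_response(sub, schedule),
                    scdose_error = function(e) e)
    if (inherits(res, "condition")) {
      dropped <- c(dropped, sprintf("%s: %s", gsub("\r", "/", g),
                                    conditionMessage(res)))
      next
    }
    rows[[g]] <- data.frame(cell_id = sub$cell_id[1],
                            channel = sub$channel[1],
                            dose = res$dose, response = res$response)
  }
  if (length(dropped))
    message(length(dropped), " trajectory/trajectories dropped during extraction")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), channel = character(0),
               dose = numeric(0), response = numeric(0))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Compare two response distributions by kernel density
#'
#' Gaussian-kernel density estimates of two samples on a shared support
#' (Silverman's rule bandwidth), together with both means and the mean shift.
#' Used to compare single-point against titration responses at a matched
#' dose and time. A formal two-sample test (Kolmogorov-Smirnov) is available
#' behind `test = TRUE`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 5.
#' @param n_grid number of KDE evaluation points.
#' @param test also run [stats::ks.test()]?
#' @return List of class `"dist_comparison"`: `kde_a`, `kde_b` (from
#'   [stats::density()] on the shared support), `mean_a`, `mean_b`, `shift`
#'   (`mean_b - mean_a`) and, if requested, `test`.
#' @export
compare_distributions <- function(values_a, values_b, n_grid = 512,
                                  test = FALSE) {
  for (v in list(values_a, values_b))
    if (!is.numeric(v) || length(v) < 5L || any(!is.finite(v)))
      abort("each sample must be finite numeric of length >= 5")
  bw <- max(stats::bw.nrd0(values_a), stats::bw.nrd0(values_b))
  lo <- min(values_a, values_b) - 3 * bw
  hi <- max(values_a, values_b) + 3 * bw
  out <- list(
    kde_a = density(values_a, bw = stats::bw.nrd0(values_a),
                    from = lo, to = hi, n = n_grid),
    kde_b = density(values_b, bw = stats::bw.nrd0(values_b),
                    from = lo, to = hi, n = n_grid),
    mean_a = mean(values_a), mean_b = mean(values_b),
    shift = mean(values_b) - mean(values_a))
  if (test)
    out$test <- suppressWarnings(ks.test(values_a, values_b))
  structure(out, class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat(sprintf("<dist_comparison> mean A = %.4g, mean B = %.4g, shift = %.4g\n",
              x$mean_a, x$mean_b, x$shift))
  if (!is.null(x$test))
    cat(sprintf("  KS D = %.3g, p = %.3g\n", x$test$statistic, x$test$p.value))
  invisible(x)
}

#' Read or write trajectory tables and dosing schedules
#'
#' Trajectories use a long CSV (`cell_id`, `channel`, `time_min`,
#' `log2_cnr`); schedules use YAML with the layout
#' `{pre_drug_start_min, steps: [{t_min, conc_molar}]}`.
#'
#' @param trajectories trajectory `data.frame` (write).
#' @param schedule a [dosing_schedule()] (write).
#' @param path file path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  check_trajectories(trajectories)
  write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  check_trajectories(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_trajectories
#' @export
write_schedule <- function(schedule, path) {
  if (!inherits(schedule, "dosing_schedule"))
    abort("`schedule` must be a dosing_schedule")
  yaml::write_yaml(list(
    pre_drug_start_min = schedule$pre_drug_start,
    steps = lapply(seq_len(nrow(schedule$steps)), function(i)
      list(t_min = schedule$steps$time[i],
           conc_molar = schedule$steps$concentration[i]))), path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  dosing_schedule(
    times = vapply(raw$steps, `[[`, numeric(1), "t_min"),
    concentrations = vapply(raw$steps, `[[`, numeric(1), "conc_molar"),
    pre_drug_start = raw$pre_drug_start_min)
}
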
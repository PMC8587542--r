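# Pipeline orchestration: read -> filter -> states -> total GRF/GRM ->
# contact -> decomposition -> joint loads (dynamic and/or static), plus the
# force-plate validation path. These functions are the package's "front
# end"; the exec/wbid script is a thin command-line wrapper around them.

#' Run the whole-body inverse-dynamics pipeline
#'
#' @param motion a `motion_sequence` or BVH file path.
#' @param sensors a `sensor_series`, CSV path, or `NULL` (kinematics
#'   derived from the motion stream alone).
#' @param subject a [subject_record()].
#' @param loads list of [external_load()]s (hand-held objects).
#' @param v_th contact threshold speed, m/s.
#' @param v_th_mode `"fixed"` or `"pelvis"` (see [contact_timeline()]).
#' @param filter_cutoff zero-phase low-pass cutoff in Hz, or `NULL` for
#'   none (noiseless synthetic input).
#' @param flavor `"dynamic"`, `"static"` or `"both"`.
#' @param cop_mode per-foot reaction application point (see
#'   [decompose_grf()]).
#' @param imu_offsets per-segment IMU placement offsets (see
#'   [build_states()]).
#' @param output_dir if non-NULL, CSV outputs and a run log are written
#'   there.
#' @return a `wbid_run` bundle: `$model`, `$states`, `$Fg`, `$Mg`,
#'   `$contacts`, `$reactions`, `$dynamic` and/or `$static`
#'   (`joint_loads`), `$peak_ratios` (flavor `"both"`), `$log`.
#' @export
run_pipeline <- function(motion, sensors = NULL, subject, loads = list(),
                         v_th = 1.2, v_th_mode = "fixed",
                         filter_cutoff = NULL,
                         flavor = c("dynamic", "static", "both"),
                         cop_mode = "ankle", imu_offsets = NULL,
                         output_dir = NULL) {
  flavor <- match.arg(flavor)
  if (is.character(motion)) motion <- read_bvh(motion, require_model = TRUE)
  if (is.character(sensors)) sensors <- read_sensor_table(sensors)
  model <- build_body_model(subject)

  states <- build_states(motion, sensors, model,
                         filter_cutoff = filter_cutoff,
                         imu_offsets = imu_offsets)
  Fg <- total_grf(states, model, loads)
  Mg <- total_grm(states, model, loads)
  contacts <- contact_timeline(states, v_th = v_th, v_th_mode = v_th_mode)
  reactions <- decompose_grf(Fg, Mg, contacts, states, model,
                             cop_mode = cop_mode)

  out <- list(model = model, states = states, Fg = Fg, Mg = Mg,
              contacts = contacts, reactions = reactions)
  if (flavor %in% c("dynamic", "both"))
    out$dynamic <- solve_dynamic(states, model, loads, reactions)
  if (flavor %in% c("static", "both"))
    out$static <- solve_static(states, model, loads, reactions)
  if (flavor == "both") {
    out$peak_ratios <- data.frame(
      joint = JOINT_NAMES,
      ratio = vapply(JOINT_NAMES, function(j)
        tryCatch(peak_ratio(out$dynamic, out$static, j),
                 error = function(e) NA_real_), numeric(1)))
  }

  flight <- sum(rownorms(reactions$residual) > 0)
  bw <- model$total_mass * model$g
  big_resid <- sum(rownorms(reactions$residual) > 0.05 * bw)
  out$log <- list(
    n_frames = motion$n_frames, frame_rate = motion$frame_rate,
    v_th = contacts$v_th, v_th_mode = v_th_mode,
    filter_cutoff = filter_cutoff, flavor = flavor, cop_mode = cop_mode,
    flight_frames = flight, large_residual_frames = big_resid,
    derived_segments = states$derived_segments)
  if (big_resid > 0)
    warning(big_resid, " flight frame(s) carry a residual total GRF above ",
            "5% of body weight")

  class(out) <- "wbid_run"
  if (!is.null(output_dir)) export_run(out, output_dir)
  out
}

#' Read a fixture directory written by [write_trial_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `motion`, `sensors`, `subject`, `loads`, `v_th`,
#'   `manifest`.
#' @export
read_trial_fixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  motion <- read_bvh(file.path(dir, "motion.bvh"), require_model = TRUE)
  sensors <- read_sensor_table(file.path(dir, "sensors.csv"))
  loads <- lapply(man$loads, function(l)
    external_load(l$segment, as.numeric(unlist(l$force)),
                  frames = as.integer(unlist(l$frames))))
  list(motion = motion, sensors = sensors,
       subject = subject_record(man$subject$height, man$subject$mass,
                                man$subject$sex),
       loads = loads, v_th = man$v_th, manifest = man)
}

#' Generate and write a synthetic fixture directory
#'
#' @param kind `"stand"`, `"gait"`, `"lift"` or `"weight_shift"`.
#' @param subject a [subject_record()].
#' @param dir output directory.
#' @param seed integer seed (used when `noise` is non-NULL, stored in the
#'   manifest either way).
#' @param noise optional `list(accel_sd, gyro_sd)` to perturb the sensors.
#' @param ... generator parameters passed through.
#' @return the `synthetic_trial`, invisibly; the fixture is on disk.
#' @export
simulate_fixture <- function(kind = c("stand", "gait", "lift",
                                      "weight_shift"),
                             subject, dir, seed = 1L, noise = NULL, ...) {
  kind <- match.arg(kind)
  gen <- switch(kind, stand = generate_stand, gait = generate_gait,
                lift = generate_lift, weight_shift = generate_weight_shift)
  trial <- gen(subject, ..., seed = seed)
  if (!is.null(noise))
    trial <- add_sensor_noise(trial, accel_sd = noise$accel_sd,
                              gyro_sd = noise$gyro_sd, seed = seed)
  write_trial_fixture(trial, dir)
  invisible(trial)
}

#' Validate estimated reactions against force-plate measurements
#'
#' Downsamples the plates to the motion rate if needed, aligns the streams
#' on the total vertical force by cross-correlation, and reports RMSE and
#' rRMSE per component (vertical, anterior-posterior, mediolateral) for the
#' total and per-foot reactions, the layout used for ground-reaction
#' validation tables.
#'
#' @param reactions a `ground_reaction` (plate 1 is compared to the right
#'   foot, plate 2 to the left).
#' @param plates a `forceplate_record`.
#' @param frame_rate motion frame rate, Hz.
#' @param align estimate an integer lag first? (`FALSE` assumes
#'   synchronised streams).
#' @param min_corr alignment acceptance threshold.
#' @return a `wbid_validation`: data frame `$table` with columns signal,
#'   component, rmse, rrmse; `$lag`; plus the aligned series in
#'   `$series`.
#' @export
validate_reactions <- function(reactions, plates, frame_rate,
                               align = TRUE, min_corr = 0.5) {
  if (abs(plates$rate - frame_rate) > 1e-6)
    plates <- downsample_forceplate(plates, frame_rate)
  if (length(plates$plates) < 2)
    stop("need two plates (right, left) for validation")
  meas <- list(right = plates$plates[[1]], left = plates$plates[[2]])
  n_meas <- min(nrow(meas$right$force), nrow(meas$left$force))
  meas_total <- meas$right$force[seq_len(n_meas), , drop = FALSE] +
    meas$left$force[seq_len(n_meas), , drop = FALSE]
  est <- list(total = reactions$total$F, right = reactions$right$F,
              left = reactions$left$F)

  lag <- 0L
  if (align) {
    if (stats::sd(est$total[, 3]) < 1e-9 ||
        stats::sd(meas_total[, 3]) < 1e-9) {
      message("constant vertical landmark; assuming synchronised streams")
    } else {
      lag <- as.integer(align_streams(est$total[, 3], meas_total[, 3],
                                      min_corr = min_corr))
    }
  }
  n_est <- nrow(est$total)
  i_est <- seq_len(n_est)
  i_meas <- i_est + lag
  keep <- i_meas >= 1 & i_meas <= n_meas
  i_est <- i_est[keep]; i_meas <- i_meas[keep]

  comp_names <- c(VE = 3, AP = 1, ML = 2)
  rows <- list()
  series <- list()
  for (sig in c("total", "right", "left")) {
    m <- switch(sig, total = meas_total,
                right = meas$right$force, left = meas$left$force)
    for (cn in names(comp_names)) {
      k <- comp_names[[cn]]
      ref <- m[i_meas, k]; cand <- est[[sig]][i_est, k]
      rows[[length(rows) + 1]] <- data.frame(
        signal = sig, component = cn,
        rmse = rmse(ref, cand),
        rrmse = if (max(abs(ref)) > 0) rrmse(ref, cand) else NA_real_)
    }
    series[[sig]] <- list(measured = m[i_meas, , drop = FALSE],
                          estimated = est[[sig]][i_est, , drop = FALSE])
  }
  structure(list(table = do.call(rbind, rows), lag = lag, series = series),
            class = "wbid_validation")
}

#' @export
print.wbid_validation <- function(x, ...) {
  cat("<wbid_validation> lag =", x$lag, "frames\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# write the run bundle as CSVs + a JSON run log
export_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- run$reactions$n_frames
  fr <- run$log$frame_rate
  df <- data.frame(frame = seq_len(n) - 1L, time = (seq_len(n) - 1L) / fr)
  for (side in c("total", "right", "left")) {
    src <- if (side == "total") run$reactions$total else run$reactions[[side]]
    m <- cbind(src$F, src$M)
    cols <- paste0(side, "_", c("fx", "fy", "fz", "mx", "my", "mz"))
    for (k in seq_along(cols)) df[[cols[k]]] <- m[, k]
  }
  df$contact_r <- run$contacts$right$state
  df$contact_l <- run$contacts$left$state
  utils::write.csv(df, file.path(dir, "reactions.csv"), row.names = FALSE)

  for (fl in c("dynamic", "static")) {
    if (is.null(run[[fl]])) next
    jd <- data.frame(frame = seq_len(n) - 1L)
    for (j in JOINT_NAMES) {
      m <- cbind(run[[fl]]$joints[[j]]$force, run[[fl]]$joints[[j]]$moment)
      cols <- paste0(j, "_", c("fx", "fy", "fz", "mx", "my", "mz"))
      for (k in seq_along(cols)) jd[[cols[k]]] <- m[, k]
    }
    utils::write.csv(jd, file.path(dir, paste0("joint_loads_", fl, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(run$peak_ratios))
    utils::write.csv(run$peak_ratios, file.path(dir, "peak_ratios.csv"),
                     row.names = FALSE)
  jsonlite::write_json(run$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.wbid_run <- function(x, ...) {
  cat(sprintf("<wbid_run> %d frames @ %g Hz, flavor=%s\n",
              x$log$n_frames, x$log$frame_rate, x$log$flavor))
  cat(sprintf("  peak total vertical GRF: %.1f N; double-stance frames: %d\n",
              max(x$Fg[, 3]),
              sum(x$contacts$right$state == "stance" &
                  x$contacts$left$state == "stance")))
  invisible(x)
}
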
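# Synthetic trials with exact ground truth. Motions are prescribed as
# closed-form joint-angle and root trajectories (sums of harmonics,
# gaussian bumps and windowed bursts, all with analytic first and second
# derivatives). Kinematics are propagated exactly down the chain
# (rotations, angular velocity/acceleration, point velocities and
# accelerations), so the truth reactions and joint loads satisfy
# Newton-Euler identically -- no numerical differentiation enters the
# truth. The trial also renders a BVH motion file view and a sensor series
# (IMU at the segment CoM), so the whole ingest pipeline can be exercised
# against the truth.

# ---- trajectory components -------------------------------------------------

traj_const <- function(value) list(type = "const", value = value)
traj_linear <- function(rate) list(type = "linear", rate = rate)
traj_harmonic <- function(amp, freq, phase = 0)
  list(type = "harmonic", amp = amp, freq = freq, phase = phase)
# gaussian bump centred at t0 with width sigma
traj_bump <- function(amp, t0, sigma)
  list(type = "bump", amp = amp, t0 = t0, sigma = sigma)
# gaussian-windowed sinusoid (impact-like transient)
traj_burst <- function(amp, t0, sigma, freq)
  list(type = "burst", amp = amp, t0 = t0, sigma = sigma, freq = freq)

eval_component <- function(comp, t) {
  switch(comp$type,
    const = list(x = rep(comp$value, length(t)), v = numeric(length(t)),
                 a = numeric(length(t))),
    linear = list(x = comp$rate * t, v = rep(comp$rate, length(t)),
                  a = numeric(length(t))),
    harmonic = {
      w <- 2 * pi * comp$freq
      ph <- w * t + comp$phase
      list(x = comp$amp * sin(ph), v = comp$amp * w * cos(ph),
           a = -comp$amp * w^2 * sin(ph))
    },
    bump = {
      u <- t - comp$t0; s2 <- comp$sigma^2
      e <- exp(-u^2 / (2 * s2))
      list(x = comp$amp * e,
           v = comp$amp * e * (-u / s2),
           a = comp$amp * e * (u^2 / s2^2 - 1 / s2))
    },
    burst = {
      u <- t - comp$t0; s2 <- comp$sigma^2; w <- 2 * pi * comp$freq
      e <- exp(-u^2 / (2 * s2)); ep <- -u / s2 * e
      epp <- (u^2 / s2^2 - 1 / s2) * e
      sn <- sin(w * u); cs <- cos(w * u)
      list(x = comp$amp * e * sn,
           v = comp$amp * (ep * sn + e * w * cs),
           a = comp$amp * (epp * sn + 2 * ep * w * cs - e * w^2 * sn))
    },
    stop("unknown trajectory component type: ", comp$type))
}

eval_traj <- function(comps, t) {
  x <- numeric(length(t)); v <- numeric(length(t)); a <- numeric(length(t))
  for (comp in comps) {
    ev <- eval_component(comp, t)
    x <- x + ev$x; v <- v + ev$v; a <- a + ev$a
  }
  list(x = x, v = v, a = a)
}

# ---- exact chain propagation ----------------------------------------------

AXIS_VEC <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))

# joint_trajs: named list(joint -> list(axis = "x"|"y"|"z", comps = list()))
# root_trajs: list(x =, y =, z = component lists) around the standing root.
propagate_chain <- function(model, root_trajs, joint_trajs, t) {
  n <- length(t)
  zero <- matrix(0, n, 3)
  rx <- eval_traj(root_trajs$x, t)
  ry <- eval_traj(root_trajs$y, t)
  rz <- eval_traj(root_trajs$z, t)
  root_p <- cbind(rx$x, ry$x, rz$x + model$root_height)
  root_v <- cbind(rx$v, ry$v, rz$v)
  root_a <- cbind(rx$a, ry$a, rz$a)

  ident <- array(rep(diag(3), n), c(3, 3, n))
  # per segment: R, omega, alpha, and origin (proximal joint) p/v/a
  kin <- list(pelvis = list(R = ident, omega = zero, alpha = zero,
                            p = root_p, v = root_v, a = root_a))
  local_rot <- list(pelvis = ident)
  angles <- list()

  for (jn in names(model$joints)) {
    j <- model$joints[[jn]]
    par <- kin[[j$parent]]
    off <- j$offset
    tr <- joint_trajs[[jn]]
    if (!is.null(tr)) {
      th <- eval_traj(tr$comps, t)
      axis <- AXIS_VEC[[tr$axis]]
      angles[[jn]] <- th$x
    } else {
      th <- list(x = numeric(n), v = numeric(n), a = numeric(n))
      axis <- c(0, 0, 1)
    }
    R <- array(0, c(3, 3, n))
    omega <- matrix(0, n, 3); alpha <- matrix(0, n, 3)
    p <- matrix(0, n, 3); v <- matrix(0, n, 3); a <- matrix(0, n, 3)
    lr <- array(0, c(3, 3, n))
    for (f in seq_len(n)) {
      Rp <- par$R[, , f]
      ro <- drop(Rp %*% off)
      wp <- par$omega[f, ]
      p[f, ] <- par$p[f, ] + ro
      v[f, ] <- par$v[f, ] + cross3(wp, ro)
      a[f, ] <- par$a[f, ] + cross3(par$alpha[f, ], ro) +
        cross3(wp, cross3(wp, ro))
      Rl <- if (is.null(tr)) diag(3) else rot_axis(tr$axis, th$x[f])
      lr[, , f] <- Rl
      R[, , f] <- Rp %*% Rl
      ax_g <- drop(Rp %*% axis)
      omega[f, ] <- wp + th$v[f] * ax_g
      alpha[f, ] <- par$alpha[f, ] + th$a[f] * ax_g +
        th$v[f] * cross3(wp, ax_g)
    }
    kin[[j$child]] <- list(R = R, omega = omega, alpha = alpha,
                           p = p, v = v, a = a)
    local_rot[[j$child]] <- lr
  }
  list(kin = kin, local_rot = local_rot, root_p = root_p, angles = angles)
}

# point fixed in a segment: global position/velocity/acceleration series
segment_point <- function(seg, offset) {
  n <- nrow(seg$p)
  p <- matrix(0, n, 3); v <- matrix(0, n, 3); a <- matrix(0, n, 3)
  for (f in seq_len(n)) {
    ro <- drop(seg$R[, , f] %*% offset)
    w <- seg$omega[f, ]
    p[f, ] <- seg$p[f, ] + ro
    v[f, ] <- seg$v[f, ] + cross3(w, ro)
    a[f, ] <- seg$a[f, ] + cross3(seg$alpha[f, ], ro) +
      cross3(w, cross3(w, ro))
  }
  list(p = p, v = v, a = a)
}

# BVH node names for the 15 segments (writer dialect)
BVH_NODE_OF <- c(pelvis = "Hips", torso = "Chest", head = "Head",
                 upper_arm_r = "RightArm", forearm_r = "RightForeArm",
                 hand_r = "RightHand",
                 upper_arm_l = "LeftArm", forearm_l = "LeftForeArm",
                 hand_l = "LeftHand",
                 thigh_r = "RightUpLeg", shank_r = "RightLeg",
                 foot_r = "RightFoot",
                 thigh_l = "LeftUpLeg", shank_l = "LeftLeg",
                 foot_l = "LeftFoot")

# assemble a synthetic_trial from prescribed trajectories
synth_trial <- function(model, root_trajs, joint_trajs, duration,
                        frame_rate = 120, loads = list(), v_th = 1.2,
                        kind = "custom", params = list(), seed = NULL) {
  n <- as.integer(round(duration * frame_rate))
  t <- (seq_len(n) - 1) / frame_rate
  ch <- propagate_chain(model, root_trajs, joint_trajs, t)

  # exact segment states
  segments <- list(); joint_pos <- list(); sensors_seg <- list()
  for (s in SEGMENT_NAMES) {
    k <- ch$kin[[s]]
    cp <- segment_point(k, model$segments[[s]]$com_offset)
    segments[[s]] <- list(R = k$R, com = cp$p, acc = cp$a,
                          omega = k$omega, alpha = k$alpha)
    sensors_seg[[s]] <- list(position = cp$p, accel = cp$a, gyro = k$omega)
  }
  for (jn in names(model$joints))
    joint_pos[[jn]] <- ch$kin[[model$joints[[jn]]$child]]$p
  markers <- list(); marker_vel <- list()
  for (mk in names(model$markers)) {
    sp <- segment_point(ch$kin[[model$markers[[mk]]$segment]],
                        model$markers[[mk]]$offset)
    markers[[mk]] <- sp$p
    marker_vel[[mk]] <- sp$v
  }
  min_toe <- min(markers$toe_r[, 3], markers$toe_l[, 3])
  if (min_toe < -0.05)
    stop("generator parameters drive a toe ", round(-min_toe, 3),
         " m below the ground plane")

  states <- structure(list(
    frame_rate = frame_rate, n_frames = n, origin = ch$root_p,
    segments = segments, joint_pos = joint_pos,
    markers = markers, marker_vel = marker_vel,
    derived_segments = character()
  ), class = "segment_states")

  # truth mechanics (analytic states end-to-end)
  Fg <- total_grf(states, model, loads)
  Mg <- total_grm(states, model, loads)
  contacts <- contact_timeline(states, v_th = v_th)
  reactions <- decompose_grf(Fg, Mg, contacts, states, model)
  jl <- solve_dynamic(states, model, loads, reactions)

  # motion-sequence view (BVH skeleton with mapped node names)
  joints <- list(); rotations <- list()
  node <- function(s) BVH_NODE_OF[[s]]
  joints[[node("pelvis")]] <- list(
    name = node("pelvis"), parent = NA_character_, offset = c(0, 0, 0),
    channels = c("Xposition", "Yposition", "Zposition",
                 "Yrotation", "Xrotation", "Zrotation"),
    segment = "pelvis", end_site = NULL)
  rotations[[node("pelvis")]] <- ch$local_rot$pelvis
  for (jn in names(model$joints)) {
    j <- model$joints[[jn]]
    nm <- node(j$child)
    joints[[nm]] <- list(
      name = nm, parent = node(j$parent), offset = j$offset,
      channels = c("Yrotation", "Xrotation", "Zrotation"),
      segment = j$child, end_site = NULL)
    rotations[[nm]] <- ch$local_rot[[j$child]]
  }
  joints[[node("head")]]$end_site <-
    c(0, 0, model$segments$head$length)
  for (s in c("hand_r", "hand_l"))
    joints[[node(s)]]$end_site <- c(0, 0, -model$segments[[s]]$length)
  for (s in c("foot_r", "foot_l"))
    joints[[node(s)]]$end_site <-
      model$markers[[sub("foot", "toe", s)]]$offset
  motion <- structure(list(
    frame_rate = frame_rate, n_frames = n, joints = joints,
    joint_order = names(joints), root = node("pelvis"),
    root_position = ch$root_p, rotations = rotations
  ), class = "motion_sequence")

  sensors <- sensor_series(frame_rate, sensors_seg, gravity_included = FALSE)

  structure(list(
    kind = kind, motion = motion, sensors = sensors,
    truth = list(states = states, Fg = Fg, Mg = Mg, contacts = contacts,
                 reactions = reactions, joint_loads = jl,
                 angles = ch$angles),
    loads = loads, model = model, subject = model$subject,
    params = params, v_th = v_th, seed = seed
  ), class = "synthetic_trial")
}

#' Synthetic quiet-standing trial
#'
#' Neutral double stance with optional low-frequency postural sway of the
#' pelvis (lateral at `sway_freq`, anterior-posterior at a slightly lower
#' frequency and 40% of the amplitude). With `sway_amplitude = 0` the
#' subject is perfectly stationary and the truth reaction is the constant
#' `(0, 0, m g)`.
#'
#' @param subject a [subject_record()] (or list with height/mass/sex).
#' @param duration trial length, s.
#' @param sway_amplitude lateral sway amplitude, m.
#' @param sway_freq sway frequency, Hz.
#' @param frame_rate sampling rate, Hz.
#' @param seed stored in the trial for provenance (the noiseless generator
#'   is deterministic; see [add_sensor_noise()]).
#' @return a `synthetic_trial` with full ground truth.
#' @export
generate_stand <- function(subject, duration = 4, sway_amplitude = 0.02,
                           sway_freq = 0.3, frame_rate = 120, seed = NULL) {
  stopifnot(duration > 0)
  model <- build_body_model(subject)
  root <- list(
    x = list(traj_harmonic(0.4 * sway_amplitude, 0.77 * sway_freq,
                           phase = pi / 3)),
    y = list(traj_harmonic(sway_amplitude, sway_freq)),
    z = list())
  synth_trial(model, root, list(), duration, frame_rate,
              kind = "stand",
              params = list(duration = duration,
                            sway_amplitude = sway_amplitude,
                            sway_freq = sway_freq), seed = seed)
}

#' Synthetic gait-like trial
#'
#' A kinematic walking template: antiphase hip flexion harmonics, knee
#' flexion peaking mid-swing (fundamental plus first harmonic), counter-
#' swinging arms, and a small double-frequency vertical pelvis bob, with
#' the pelvis translating forward at `speed`. Toe speeds cross the contact
#' threshold transversally, producing alternating stance/swing with double
#' stance around the reversals. The truth contact timeline applies the
#' same state machine to the analytic marker velocities.
#'
#' @inheritParams generate_stand
#' @param speed forward walking speed, m/s (0.3--2.5).
#' @param cycle_time stride period, s.
#' @param n_cycles number of strides.
#' @param hip_amp hip flexion amplitude, rad.
#' @param knee_amp peak knee flexion, rad.
#' @return a `synthetic_trial`.
#' @export
generate_gait <- function(subject, speed = 0.9, cycle_time = 1.4,
                          n_cycles = 2, hip_amp = 0.22, knee_amp = 0.3,
                          frame_rate = 120, seed = NULL) {
  if (speed < 0.3 || speed > 2.5)
    stop("gait speed must be in [0.3, 2.5] m/s, got ", speed)
  model <- build_body_model(subject)
  f0 <- 1 / cycle_time
  duration <- n_cycles * cycle_time
  # knee template K*(0.5 - 0.5 cos(w t + phi))^2 expanded in harmonics,
  # peaking mid-swing (phi chosen so the peak aligns with peak hip velocity)
  knee <- function(phase) list(
    traj_const(0.375 * knee_amp),
    traj_harmonic(0.5 * knee_amp, f0, phase = phase + pi / 2),
    traj_harmonic(0.125 * knee_amp, 2 * f0, phase = 2 * phase + pi / 2))
  jt <- list(
    hip_r = list(axis = "y", comps = list(traj_harmonic(hip_amp, f0))),
    hip_l = list(axis = "y",
                 comps = list(traj_harmonic(hip_amp, f0, phase = pi))),
    knee_r = list(axis = "y", comps = knee(0)),
    knee_l = list(axis = "y", comps = knee(pi)),
    shoulder_r = list(axis = "y",
                      comps = list(traj_harmonic(0.12, f0, phase = pi))),
    shoulder_l = list(axis = "y", comps = list(traj_harmonic(0.12, f0)))
  )
  root <- list(x = list(traj_linear(speed)),
               y = list(),
               z = list(traj_harmonic(0.01, 2 * f0, phase = pi / 2)))
  synth_trial(model, root, jt, duration, frame_rate,
              kind = "gait",
              params = list(speed = speed, cycle_time = cycle_time,
                            n_cycles = n_cycles, hip_amp = hip_amp,
                            knee_amp = knee_amp), seed = seed)
}

#' Synthetic weight-shift trial (leg lift)
#'
#' Quiet stance with a lateral pelvis shift over the right foot and a
#' left-hip lift bump: the left toe speed stays near (and briefly above)
#' the threshold while the left heel speed rises and falls, exercising
#' both the toe-speed and the heel-acceleration (toe-off vs leg-lift)
#' transition rules and transferring the load fully to the right foot
#' during the shift window.
#'
#' @inheritParams generate_stand
#' @param lift_amp left hip abduction-like lift amplitude, rad.
#' @param lift_sigma bump width, s.
#' @return a `synthetic_trial`.
#' @export
generate_weight_shift <- function(subject, duration = 5, lift_amp = 0.6,
                                  lift_sigma = 0.25, frame_rate = 120,
                                  seed = NULL) {
  model <- build_body_model(subject)
  t_mid <- duration / 2
  root <- list(
    x = list(),
    y = list(traj_bump(-0.06, t_mid, 0.8)),
    z = list())
  jt <- list(
    hip_l = list(axis = "x",
                 comps = list(traj_bump(lift_amp, t_mid, lift_sigma))))
  synth_trial(model, root, jt, duration, frame_rate,
              kind = "weight_shift",
              params = list(duration = duration, lift_amp = lift_amp,
                            lift_sigma = lift_sigma), seed = seed)
}

#' Synthetic stoop-lift trial with a hand-held box
#'
#' Torso and shoulder flexion bumps emulating bending down, lifting a box
#' and standing back up, with both feet planted throughout (double
#' stance). The box acts as an external load split equally between the
#' hands during the grasp window. Small mid-lift "effort" wiggles give the
#' dynamic model its characteristic excursions around the static trend;
#' `impact_transient` adds a short high-frequency burst at the deposit
#' time, visible in the dynamic (but not static) joint moments.
#'
#' @inheritParams generate_stand
#' @param box_mass hand-held mass, kg (default 17).
#' @param phase_durations named durations in s: `lead`, `bend`, `lift`,
#'   `stand`, `tail`.
#' @param bend_angle peak torso flexion, rad.
#' @param squat_depth pelvis drop at mid-lift, m.
#' @param impact_transient add the deposit-impact burst?
#' @return a `synthetic_trial` (with `$loads` carrying the box schedule).
#' @export
generate_lift <- function(subject, box_mass = 17,
                          phase_durations = c(lead = 0.8, bend = 1.2,
                                              lift = 2.5, stand = 1.2,
                                              tail = 0.8),
                          bend_angle = 1.0, squat_depth = 0.03,
                          impact_transient = FALSE,
                          frame_rate = 120, seed = NULL) {
  stopifnot(box_mass >= 0)
  model <- build_body_model(subject)
  pd <- phase_durations
  duration <- sum(pd)
  t_grasp <- pd[["lead"]] + pd[["bend"]]
  t_release <- t_grasp + pd[["lift"]]
  t_mid <- (t_grasp + t_release) / 2
  sigma_bend <- (pd[["bend"]] + pd[["lift"]] + pd[["stand"]]) / 4

  torso_comps <- list(
    traj_bump(bend_angle, t_mid, sigma_bend),
    traj_bump(0.18, t_mid - 0.5, 0.3),      # lift-effort wiggles
    traj_bump(-0.15, t_mid + 0.6, 0.3))
  # the negative-amplitude bump at mid-lift superposes a positive angular
  # acceleration (an "effort" transient) right where the static moment
  # peaks, so the dynamic estimate exceeds the static one there
  shoulder_comps <- list(
    traj_bump(0.6, t_mid, sigma_bend),
    traj_bump(-0.12, t_mid, 0.18))
  if (impact_transient) {
    torso_comps <- c(torso_comps,
                     list(traj_burst(0.02, t_release, 0.12, 9)))
    shoulder_comps <- c(shoulder_comps,
                        list(traj_burst(0.03, t_release, 0.12, 9)))
  }
  jt <- list(
    l5s1 = list(axis = "y", comps = torso_comps),
    shoulder_r = list(axis = "y", comps = shoulder_comps),
    shoulder_l = list(axis = "y", comps = shoulder_comps),
    elbow_r = list(axis = "y",
                   comps = list(traj_bump(-0.4, t_mid, sigma_bend))),
    elbow_l = list(axis = "y",
                   comps = list(traj_bump(-0.4, t_mid, sigma_bend)))
  )
  root <- list(x = list(), y = list(),
               z = list(traj_bump(-squat_depth, t_mid, sigma_bend)))

  n <- as.integer(round(duration * frame_rate))
  fr <- function(tt) max(1L, min(n, as.integer(round(tt * frame_rate)) + 1L))
  loads <- if (box_mass > 0) {
    w <- c(0, 0, -box_mass * 9.81 / 2)
    list(external_load("hand_r", w, frames = c(fr(t_grasp), fr(t_release))),
         external_load("hand_l", w, frames = c(fr(t_grasp), fr(t_release))))
  } else list()

  synth_trial(model, root, jt, duration, frame_rate, loads = loads,
              kind = "lift",
              params = list(box_mass = box_mass, squat_depth = squat_depth,
                            phase_durations = as.list(pd),
                            bend_angle = bend_angle,
                            impact_transient = impact_transient,
                            grasp_window = c(fr(t_grasp), fr(t_release))),
              seed = seed)
}

#' Add seeded Gaussian sensor noise to a trial
#'
#' Perturbs the accelerometer and gyro channels of the sensor series; the
#' truth members are untouched.
#'
#' @param trial a `synthetic_trial`.
#' @param accel_sd accelerometer noise SD, m/s^2.
#' @param gyro_sd gyro noise SD, rad/s.
#' @param seed RNG seed (integer).
#' @return the trial with noisy `$sensors` and the noise spec recorded.
#' @export
add_sensor_noise <- function(trial, accel_sd = 0.2, gyro_sd = 0.01,
                             seed = 1L) {
  stopifnot(accel_sd >= 0, gyro_sd >= 0)
  n <- trial$sensors$n_frames
  out <- trial
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    for (s in names(out$sensors$segments)) {
      out$sensors$segments[[s]]$accel <-
        out$sensors$segments[[s]]$accel + matrix(stats::rnorm(3 * n, 0, accel_sd), n, 3)
      out$sensors$segments[[s]]$gyro <-
        out$sensors$segments[[s]]$gyro + matrix(stats::rnorm(3 * n, 0, gyro_sd), n, 3)
    }
  })
  out$noise_spec <- list(accel_sd = accel_sd, gyro_sd = gyro_sd, seed = seed)
  out
}

#' Render a trial's per-foot truth reactions as a force-plate record
#'
#' Plate 1 is the right foot, plate 2 the left; moments are re-expressed
#' about each plate origin (the mean contact point). Used to exercise the
#' validation path without laboratory data.
#'
#' @param trial a `synthetic_trial`.
#' @param rate output sampling rate, Hz (linear interpolation above the
#'   motion rate).
#' @return a `forceplate_record`.
#' @export
truth_forceplate <- function(trial, rate = NULL) {
  tr <- trial$truth$reactions
  n <- trial$motion$n_frames
  fr <- trial$motion$frame_rate
  t0 <- (seq_len(n) - 1) / fr
  if (is.null(rate)) rate <- fr
  tt <- seq(0, t0[n], by = 1 / rate)
  plates <- list()
  for (side in c("right", "left")) {
    sd <- tr[[side]]
    origin <- colMeans(sd$cop)
    # moment about the plate origin
    M <- sd$M - rowcross3(matrix(origin, n, 3, byrow = TRUE) -
                            trial$truth$states$origin, sd$F)
    interp <- function(m) apply(m, 2, function(x)
      stats::approx(t0, x, xout = tt)$y)
    plates[[if (side == "right") "1" else "2"]] <-
      list(origin = origin, time = tt, force = interp(sd$F),
           moment = interp(M))
  }
  structure(list(plates = plates, rate = rate), class = "forceplate_record")
}

#' Write a complete trial fixture directory
#'
#' Emits `motion.bvh`, `sensors.csv`, per-frame truth CSVs
#' (`truth_reactions.csv`, `truth_joint_moments.csv`, `truth_contacts.csv`)
#' and a `manifest.json` with the generator kind, parameters, subject and
#' seed, so a run is fully reproducible from the directory alone.
#'
#' @param trial a `synthetic_trial`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_fixture <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bvh(trial$motion, file.path(dir, "motion.bvh"))
  write_sensor_table(trial$sensors, file.path(dir, "sensors.csv"))
  tr <- trial$truth$reactions
  n <- trial$motion$n_frames
  df <- data.frame(frame = seq_len(n) - 1L,
                   time = (seq_len(n) - 1L) / trial$motion$frame_rate)
  for (side in c("total", "right", "left")) {
    src <- if (side == "total") tr$total else tr[[side]]
    cols <- paste0(side, "_", c("fx", "fy", "fz", "mx", "my", "mz"))
    m <- cbind(src$F, src$M)
    for (k in seq_along(cols)) df[[cols[k]]] <- m[, k]
  }
  df$contact_r <- tr$contact$right$state
  df$contact_l <- tr$contact$left$state
  utils::write.csv(df, file.path(dir, "truth_reactions.csv"),
                   row.names = FALSE)
  jm <- data.frame(frame = seq_len(n) - 1L)
  for (j in JOINT_NAMES)
    for (k in 1:3)
      jm[[paste0(j, "_m", c("x", "y", "z")[k])]] <-
        trial$truth$joint_loads$joints[[j]]$moment[, k]
  utils::write.csv(jm, file.path(dir, "truth_joint_moments.csv"),
                   row.names = FALSE)
  manifest <- list(kind = trial$kind, params = trial$params,
                   subject = unclass(trial$subject),
                   seed = trial$seed, v_th = trial$v_th,
                   frame_rate = trial$motion$frame_rate,
                   n_frames = n,
                   noise_spec = trial$noise_spec,
                   loads = lapply(trial$loads, function(l)
                     list(segment = l$segment, force = l$force,
                          frames = l$frames)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> kind=%s, %d frames @ %g Hz, subject %.2f m / %.1f kg\n",
              x$kind, x$motion$n_frames, x$motion$frame_rate,
              x$subject$height, x$subject$mass))
  invisible(x)
}
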
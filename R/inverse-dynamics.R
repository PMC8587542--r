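# Recursive Newton-Euler solution for the net force and moment at the 14
# joints. The joint load at joint j is the wrench the proximal (parent-side)
# body applies to the distal segment, with the moment expressed about the
# joint centre. Each segment's proximal load is obtained from its force and
# moment balance once all of its distal joints are solved: top-down over the
# upper body (hands/head -> torso -> L5/S1), bottom-up over the lower body
# (feet -> shanks -> thighs), starting from hand-held loads and per-foot
# ground reactions respectively.

#' Proximal joint load of one segment at one frame
#'
#' Solves the segment's Newton and Euler equations for the wrench at its
#' proximal joint, given the already-solved wrenches at its distal joints
#' and any external loads acting on it. The moment balance is taken about
#' the segment CoM in the global frame; the returned moment is re-expressed
#' about the proximal joint centre.
#'
#' @param state list with `R` (3x3 segment-to-global rotation), `com`,
#'   `acc`, `omega`, `alpha` (3-vectors, global frame).
#' @param spec segment spec from a `body_model` (`mass`, `inertia`).
#' @param prox_pos proximal joint centre position, global, m.
#' @param distal_loads list of solved distal wrenches, each
#'   `list(force, moment, point)` applied by this segment on its child at
#'   `point` (moment about `point`).
#' @param externals list of `list(force, moment, point)` external loads on
#'   this segment (moment a free couple).
#' @param g gravitational acceleration, m/s^2.
#' @return `list(force, moment)` at the proximal joint.
#' @export
segment_balance <- function(state, spec, prox_pos, distal_loads = list(),
                            externals = list(), g = 9.81) {
  m <- spec$mass
  W <- c(0, 0, -m * g)
  Fp <- m * state$acc - W
  for (d in distal_loads) Fp <- Fp + d$force
  for (e in externals) Fp <- Fp - e$force

  Ig <- state$R %*% spec$inertia %*% t(state$R)
  Mcom <- drop(Ig %*% state$alpha) + cross3(state$omega, drop(Ig %*% state$omega))
  Mp <- Mcom - cross3(prox_pos - state$com, Fp)
  for (d in distal_loads)
    Mp <- Mp + d$moment + cross3(d$point - state$com, d$force)
  for (e in externals)
    Mp <- Mp - e$moment - cross3(e$point - state$com, e$force)
  # Mp is the couple about the proximal joint centre: the Euler balance
  # about the CoM reads
  #   Mcom = M_p + (p-c) x F_p + sum_d [-M_d + (d-c) x (-F_d)]
  #          + sum_e [M_e + (x_e-c) x F_e]
  list(force = Fp, moment = Mp)
}

# per-frame state slice for a segment
state_at <- function(states, s, f) {
  seg <- states$segments[[s]]
  list(R = seg$R[, , f], com = seg$com[f, ], acc = seg$acc[f, ],
       omega = seg$omega[f, ], alpha = seg$alpha[f, ])
}

# zero all motion-dependent quantities (static flavour)
zero_motion <- function(states) {
  z <- matrix(0, states$n_frames, 3)
  for (s in names(states$segments)) {
    states$segments[[s]]$acc <- z
    states$segments[[s]]$omega <- z
    states$segments[[s]]$alpha <- z
  }
  states
}

# expand external loads into per-frame per-segment lists
expand_loads <- function(loads, states) {
  lapply(loads, function(ld) c(load_series(ld, states), segment = ld$segment))
}

# solve all 14 joints for one frame; reactions_f: list(right/left =
# list(force, moment_origin, cop) or NULL), origin: pelvic origin position
solve_frame <- function(states, model, f, loads_x, reactions_f) {
  g <- model$g
  solved <- list()
  org <- states$origin[f, ]

  externals_of <- function(s) {
    out <- list()
    for (lx in loads_x) {
      if (!identical(lx$segment, s)) next
      if (all(lx$F[f, ] == 0) && all(lx$M[f, ] == 0)) next
      out[[length(out) + 1]] <- list(force = lx$F[f, ], moment = lx$M[f, ],
                                     point = lx$P[f, ])
    }
    if (s %in% c("foot_r", "foot_l")) {
      side <- if (s == "foot_r") "right" else "left"
      rx <- reactions_f[[side]]
      if (!is.null(rx)) {
        couple <- rx$moment_origin - cross3(rx$cop - org, rx$force)
        out[[length(out) + 1]] <- list(force = rx$force, moment = couple,
                                       point = rx$cop)
      }
    }
    out
  }

  order <- joint_tree(model)
  for (s in c(order$top_down, order$bottom_up)) {
    if (s == "pelvis") next
    jp <- model$segments[[s]]$parent_joint
    dj <- distal_joints(model, s)
    dl <- lapply(dj, function(j) {
      if (is.null(solved[[j]]))
        stop("distal joint ", j, " unsolved before segment ", s)
      c(solved[[j]], list(point = states$joint_pos[[j]][f, ]))
    })
    solved[[jp]] <- segment_balance(
      state_at(states, s, f), model$segments[[s]],
      prox_pos = states$joint_pos[[jp]][f, ],
      distal_loads = dl, externals = externals_of(s), g = g)
  }
  solved
}

new_joint_loads <- function(n, frame_rate, flavor) {
  joints <- stats::setNames(
    lapply(JOINT_NAMES, function(j) list(force = matrix(0, n, 3),
                                         moment = matrix(0, n, 3))),
    JOINT_NAMES)
  structure(list(flavor = flavor, n_frames = n, frame_rate = frame_rate,
                 joints = joints), class = "joint_loads")
}

reactions_at <- function(reactions, f) {
  pick <- function(side) {
    sd <- reactions[[side]]
    if (reactions$contact[[side]]$state[f] != "stance") return(NULL)
    list(force = sd$F[f, ], moment_origin = sd$M[f, ], cop = sd$cop[f, ])
  }
  list(right = pick("right"), left = pick("left"))
}

#' Dynamic net joint loads at all 14 joints
#'
#' Runs the two-directional Newton-Euler recursion per frame: top-down from
#' hand loads through wrists, elbows, shoulders, neck and L5/S1; bottom-up
#' from the per-foot ground reactions through ankles, knees and hips.
#'
#' @param states a `segment_states`.
#' @param model a `body_model`.
#' @param loads list of [external_load()]s (hand-held objects).
#' @param reactions a `ground_reaction` from [decompose_grf()].
#' @return a `joint_loads` (flavor `"dynamic"`): per joint, `force` and
#'   `moment` (n x 3; moment about the joint centre, global frame).
#' @export
solve_dynamic <- function(states, model, loads = list(), reactions) {
  n <- states$n_frames
  out <- new_joint_loads(n, states$frame_rate, "dynamic")
  loads_x <- expand_loads(loads, states)
  for (f in seq_len(n)) {
    sol <- solve_frame(states, model, f, loads_x, reactions_at(reactions, f))
    for (j in JOINT_NAMES) {
      out$joints[[j]]$force[f, ] <- sol[[j]]$force
      out$joints[[j]]$moment[f, ] <- sol[[j]]$moment
    }
  }
  out
}

#' Static net joint loads (accelerations zeroed)
#'
#' The identical recursion with every segment's linear acceleration,
#' angular velocity and angular acceleration set to zero, i.e. a
#' posture-only model: only weights and external loads act. The ground
#' reactions are recomputed under the same zeroing (same contact timeline).
#'
#' @inheritParams solve_dynamic
#' @param reactions a `ground_reaction`; only its contact timeline and
#'   decomposition settings are reused.
#' @return a `joint_loads` (flavor `"static"`).
#' @export
solve_static <- function(states, model, loads = list(), reactions) {
  st <- zero_motion(states)
  Fg <- total_grf(st, model, loads)
  Mg <- total_grm(st, model, loads)
  rx <- decompose_grf(Fg, Mg, reactions$contact, st, model,
                      cop_mode = reactions$cop_mode)
  out <- solve_dynamic(st, model, loads, rx)
  out$flavor <- "static"
  out
}

#' Pelvis residual force (whole-body consistency diagnostic)
#'
#' Applies the pelvis segment balance with all of its distal joint loads
#' (L5/S1 from the top-down chain, both hips from the bottom-up chain).
#' When the reactions are exact the returned "proximal" force and moment
#' are zero: there is no proximal joint above the pelvis to supply them.
#'
#' @param joint_loads a `joint_loads`.
#' @inheritParams solve_dynamic
#' @return list with `force` and `moment` residual matrices (n x 3).
#' @export
whole_body_residual <- function(joint_loads, states, model, loads = list()) {
  n <- states$n_frames
  loads_x <- expand_loads(loads, states)
  rf <- matrix(0, n, 3); rm <- matrix(0, n, 3)
  st <- if (joint_loads$flavor == "static") zero_motion(states) else states
  for (f in seq_len(n)) {
    dl <- lapply(c("l5s1", "hip_r", "hip_l"), function(j)
      list(force = joint_loads$joints[[j]]$force[f, ],
           moment = joint_loads$joints[[j]]$moment[f, ],
           point = st$joint_pos[[j]][f, ]))
    ext <- list()
    for (lx in loads_x) {
      if (!identical(lx$segment, "pelvis")) next
      ext[[length(ext) + 1]] <- list(force = lx$F[f, ], moment = lx$M[f, ],
                                     point = lx$P[f, ])
    }
    res <- segment_balance(state_at(st, "pelvis", f),
                           model$segments$pelvis,
                           prox_pos = st$segments$pelvis$com[f, ],
                           distal_loads = dl, externals = ext, g = model$g)
    rf[f, ] <- res$force
    rm[f, ] <- res$moment
  }
  list(force = rf, moment = rm)
}

#' Peak dynamic-to-static moment ratio at a joint
#'
#' Ratio of the peak net-moment magnitudes, `max_t ||M_dyn|| / max_t
#' ||M_stat||`, quantifying how much a posture-only analysis underestimates
#' the loading.
#'
#' @param dynamic,static `joint_loads` of the same trial.
#' @param joint joint name.
#' @return numeric ratio (> 1 when motion adds load).
#' @export
peak_ratio <- function(dynamic, static, joint) {
  stopifnot(joint %in% JOINT_NAMES)
  pk <- function(jl) max(rownorms(jl$joints[[joint]]$moment))
  ps <- pk(static)
  if (ps == 0) stop("static peak moment at ", joint,
                    " is zero; ratio undefined")
  pk(dynamic) / ps
}

#' @export
print.joint_loads <- function(x, ...) {
  cat(sprintf("<joint_loads> flavor=%s, 14 joints, %d frames\n",
              x$flavor, x$n_frames))
  invisible(x)
}
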
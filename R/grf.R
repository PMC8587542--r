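# Total ground reaction force/moment from whole-body Newton-Euler sums, and
# the per-foot ground contact state machine.
#
# Sign conventions: F_g is the reaction the ground applies to the body
# (vertical positive up); segment weight W_i = (0, 0, -m_i g); all moments
# are taken about the instantaneous pelvic-frame origin (the root
# trajectory), the reference point of the per-frame mechanics.

#' External load specification
#'
#' A force/moment applied to a segment over a frame interval, e.g. a
#' hand-held box.
#'
#' @param segment model segment name carrying the load.
#' @param force 3-vector or n x 3 matrix, N, global frame.
#' @param moment free couple, 3-vector or n x 3, N m.
#' @param point application point: `NULL` for the segment CoM trajectory,
#'   or an n x 3 matrix of global positions.
#' @param frames `c(first, last)` frame indices (1-based, inclusive) during
#'   which the load is active; `NULL` for the whole trial.
#' @return an `external_load`.
#' @export
external_load <- function(segment, force, moment = c(0, 0, 0), point = NULL,
                          frames = NULL) {
  structure(list(segment = segment, force = force, moment = moment,
                 point = point, frames = frames), class = "external_load")
}

# expand an external_load to per-frame F (n x 3), M (n x 3), P (n x 3 global)
load_series <- function(load, states) {
  n <- states$n_frames
  expand <- function(v) if (is.matrix(v)) v else matrix(v, n, 3, byrow = TRUE)
  FF <- expand(load$force); MM <- expand(load$moment)
  PP <- if (is.null(load$point)) states$segments[[load$segment]]$com
        else load$point
  if (!is.null(load$frames)) {
    if (load$frames[1] < 1 || load$frames[2] > n)
      stop("external load interval [", load$frames[1], ", ", load$frames[2],
           "] outside trial of ", n, " frames")
    off <- setdiff(seq_len(n), load$frames[1]:load$frames[2])
    FF[off, ] <- 0; MM[off, ] <- 0
  }
  list(F = FF, M = MM, P = PP)
}

rowcross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total ground reaction force
#'
#' Whole-body force balance: the reaction the ground must supply is the sum
#' over the 15 segments of inertial force minus weight minus external
#' force, `F_g = sum_i (m_i a_i - W_i - F_ex,i)`.
#'
#' @param states a `segment_states`.
#' @param model a `body_model`.
#' @param loads list of [external_load()]s.
#' @return n x 3 matrix, N (vertical component positive up).
#' @export
total_grf <- function(states, model, loads = list()) {
  n <- states$n_frames
  Fg <- matrix(0, n, 3)
  for (s in SEGMENT_NAMES) {
    m <- model$segments[[s]]$mass
    Fg <- Fg + m * states$segments[[s]]$acc
    Fg[, 3] <- Fg[, 3] + m * model$g       # minus W_i = (0,0,-m g)
  }
  for (ld in loads) {
    ls <- load_series(ld, states)
    Fg <- Fg - ls$F
  }
  Fg
}

#' Total ground reaction moment about the pelvic-frame origin
#'
#' `M_g = sum_i (M_i* + l_i x F_i* - l_i x W_i - M_ex,i - l_ex,i x F_ex,i)`
#' with `M_i* = I_i alpha_i + omega_i x (I_i omega_i)` in the global frame
#' and `l` positions relative to the pelvic origin.
#'
#' @inheritParams total_grf
#' @return n x 3 matrix, N m.
#' @export
total_grm <- function(states, model, loads = list()) {
  n <- states$n_frames
  Mg <- matrix(0, n, 3)
  org <- states$origin
  for (s in SEGMENT_NAMES) {
    seg <- states$segments[[s]]
    m <- model$segments[[s]]$mass
    I0 <- model$segments[[s]]$inertia
    l <- seg$com - org
    Fstar <- m * seg$acc
    W <- matrix(c(0, 0, -m * model$g), n, 3, byrow = TRUE)
    Mstar <- matrix(0, n, 3)
    for (f in seq_len(n)) {
      Ig <- seg$R[, , f] %*% I0 %*% t(seg$R[, , f])
      Mstar[f, ] <- Ig %*% seg$alpha[f, ] +
        cross3(seg$omega[f, ], Ig %*% seg$omega[f, ])
    }
    Mg <- Mg + Mstar + rowcross3(l, Fstar) - rowcross3(l, W)
  }
  for (ld in loads) {
    ls <- load_series(ld, states)
    lex <- ls$P - org
    Mg <- Mg - ls$M - rowcross3(lex, ls$F)
  }
  Mg
}

#' Foot contact state machine for one foot
#'
#' Swing-to-stance when the toe speed drops below the threshold `v_th`;
#' stance-to-swing when the toe speed reaches the threshold, or -- to
#' separate toe-off from a leg lift while the toe stays slow -- when the
#' heel tangential acceleration (derivative of heel speed) switches sign
#' from positive to negative, i.e. the heel passes its speed maximum. The
#' heel rule is gated on the heel moving at a substantial fraction of the
#' threshold (`heel_gate`, default `v_th / 2`) so that the slow heel-speed
#' undulations of a loaded stance foot -- or the numerical jitter of a
#' resting one -- cannot terminate stance. The initial state is stance iff
#' the first toe-speed sample is below threshold.
#'
#' @param toe_vel,heel_vel n x 3 velocity traces (m/s), or length-n speed
#'   vectors.
#' @param v_th threshold speed, m/s (default 1.2, the average walking speed
#'   of a healthy adult).
#' @param frame_rate sampling rate, Hz (for the heel-speed derivative).
#' @param heel_gate minimum heel speed for the heel rule, m/s
#'   (default `v_th / 2`).
#' @return a `foot_contact`: `$state` (`"stance"`/`"swing"` per frame),
#'   `$toe_speed`, `$heel_speed`, `$a_heel`, `$v_th`.
#' @export
detect_contact <- function(toe_vel, heel_vel, v_th = 1.2, frame_rate,
                           heel_gate = v_th / 2) {
  toe_speed <- if (is.matrix(toe_vel)) rownorms(toe_vel) else toe_vel
  heel_speed <- if (is.matrix(heel_vel)) rownorms(heel_vel) else heel_vel
  if (length(toe_speed) != length(heel_speed))
    stop("toe and heel traces have unequal lengths (",
         length(toe_speed), " vs ", length(heel_speed), ")")
  if (v_th <= 0) stop("v_th must be positive")
  n <- length(toe_speed)
  a_heel <- differentiate(heel_speed, frame_rate)
  state <- character(n)
  state[1] <- if (toe_speed[1] < v_th) "stance" else "swing"
  for (f in 2:n) {
    if (state[f - 1] == "swing") {
      state[f] <- if (toe_speed[f] < v_th) "stance" else "swing"
    } else {
      if (toe_speed[f] >= v_th) {
        state[f] <- "swing"
      } else if (a_heel[f - 1] > 0 && a_heel[f] < 0 &&
                 heel_speed[f] > heel_gate) {
        state[f] <- "swing"
      } else {
        state[f] <- "stance"
      }
    }
  }
  structure(list(state = state, toe_speed = toe_speed,
                 heel_speed = heel_speed, a_heel = a_heel, v_th = v_th),
            class = "foot_contact")
}

#' Contact timeline for both feet from segment states
#'
#' @param states a `segment_states` (with marker velocities).
#' @param v_th threshold speed, m/s; ignored when `v_th_mode = "pelvis"`.
#' @param v_th_mode `"fixed"` (default) or `"pelvis"`, which sets the
#'   threshold to the trial's mean forward pelvis speed.
#' @param heel_gate see [detect_contact()].
#' @return a `contact_timeline` with `$right`, `$left` ([detect_contact()]
#'   results) and `$v_th`.
#' @export
contact_timeline <- function(states, v_th = 1.2,
                             v_th_mode = c("fixed", "pelvis"),
                             heel_gate = NULL) {
  v_th_mode <- match.arg(v_th_mode)
  if (v_th_mode == "pelvis") {
    v_pel <- differentiate(states$origin, states$frame_rate)
    v_th <- mean(abs(v_pel[, 1]))
    if (v_th <= 0) stop("mean pelvis speed is zero; cannot set v_th")
  }
  if (is.null(heel_gate)) heel_gate <- v_th / 2
  right <- detect_contact(states$marker_vel$toe_r, states$marker_vel$heel_r,
                          v_th, states$frame_rate, heel_gate)
  left <- detect_contact(states$marker_vel$toe_l, states$marker_vel$heel_l,
                         v_th, states$frame_rate, heel_gate)
  structure(list(right = right, left = left, v_th = v_th),
            class = "contact_timeline")
}

# frames of state change, as (frame, from, to)
contact_transitions <- function(foot) {
  s <- foot$state
  idx <- which(s[-1] != s[-length(s)]) + 1L
  data.frame(frame = idx, from = s[idx - 1L], to = s[idx])
}

#' @export
print.contact_timeline <- function(x, ...) {
  cat(sprintf("<contact_timeline> v_th = %.3g m/s; right: %d stance frames, left: %d stance frames of %d\n",
              x$v_th, sum(x$right$state == "stance"),
              sum(x$left$state == "stance"), length(x$right$state)))
  invisible(x)
}
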
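# Per-frame segment kinematic states: pose from forward kinematics of the
# motion stream, centre-of-mass acceleration reconstructed from the
# segment-fixed IMU via the lever-arm relation
#   a_i = a_si - alpha_i x r_si - omega_i x (omega_i x r_si),
# angular velocity from the gyro (or from differentiated orientations when a
# segment carries no sensor), angular acceleration by numerical
# differentiation of omega.

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Forward-backward application (zero phase lag, effectively 4th-order
#' magnitude response). The signal is extended by odd reflection at both
#' ends before filtering so that constant signals pass through unchanged
#' and edge transients stay out of the returned window.
#'
#' @param x numeric vector (one channel).
#' @param cutoff cutoff frequency, Hz (default 10).
#' @param frame_rate sampling rate, Hz.
#' @param order filter order of each pass (default 2).
#' @return filtered vector, same length.
#' @export
lowpass_filter <- function(x, cutoff = 10, frame_rate, order = 2) {
  n <- length(x)
  nyq <- frame_rate / 2
  if (cutoff >= nyq)
    stop("filter cutoff (", cutoff, " Hz) must be below the Nyquist rate (",
         nyq, " Hz)")
  if (n <= 3 * order) stop("series too short to filter: ", n, " samples")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  p <- min(n - 1, max(3 * order, ceiling(10 * frame_rate / cutoff)))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  ext <- c(pre, x, post)
  y <- signal::filter(bf, ext)
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(p + 1):(p + n)]
}

#' Numerical differentiation of a uniformly sampled series
#'
#' Central differences in the interior; second-order one-sided 3-point
#' stencils at the endpoints (exact for quadratics everywhere).
#'
#' @param x numeric vector or n x k matrix (columns differentiated
#'   independently).
#' @param frame_rate sampling rate, Hz.
#' @param order derivative order (>= 1, applied repeatedly).
#' @return same shape as `x`.
#' @export
differentiate <- function(x, frame_rate, order = 1) {
  if (is.matrix(x)) {
    for (o in seq_len(order)) x <- apply(x, 2, diff1, frame_rate = frame_rate)
    return(x)
  }
  for (o in seq_len(order)) x <- diff1(x, frame_rate)
  x
}

diff1 <- function(x, frame_rate) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate, got ", n)
  dt <- 1 / frame_rate
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  d
}

#' Segment CoM acceleration from the segment-fixed IMU
#'
#' Evaluates `a_i = a_si - alpha x r_si - omega x (omega x r_si)` with all
#' vectors in the global frame.
#'
#' @param a_si IMU linear acceleration (gravity-free), 3-vector or n x 3.
#' @param alpha segment angular acceleration, same shape.
#' @param omega segment angular velocity, same shape.
#' @param r_si IMU position relative to the segment CoM (global frame),
#'   3-vector or n x 3.
#' @return CoM acceleration, same shape as `a_si`.
#' @export
com_acceleration <- function(a_si, alpha, omega, r_si) {
  if (!is.matrix(a_si)) {
    return(a_si - cross3(alpha, r_si) - cross3(omega, cross3(omega, r_si)))
  }
  if (!is.matrix(r_si)) r_si <- matrix(r_si, nrow(a_si), 3, byrow = TRUE)
  rowcross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                   a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                   a[, 1] * b[, 2] - a[, 2] * b[, 1])
  a_si - rowcross(alpha, r_si) - rowcross(omega, rowcross(omega, r_si))
}

# map model segment name -> motion joint (BVH node) name
segment_nodes <- function(motion) {
  segs <- vapply(motion$joints, `[[`, character(1), "segment")
  nodes <- names(segs)[!is.na(segs)]
  stats::setNames(nodes, segs[nodes])
}

#' Forward kinematics of a motion sequence over the body model
#'
#' Composes the per-joint rotations from the pelvis root outward, returning
#' global segment orientations, joint-centre positions, segment CoM
#' positions (regression offsets along the segment axes) and the foot
#' toe/heel marker trajectories.
#'
#' @param motion a `motion_sequence` whose joints map onto the 15 segments.
#' @param model a `body_model`.
#' @return list with `rotations` (per segment, 3 x 3 x n), `joint_pos`
#'   (per model joint, n x 3), `com` (per segment, n x 3), `markers`
#'   (per foot marker, n x 3), `origin` (n x 3 pelvis root) in metres,
#'   global frame.
#' @export
forward_kinematics <- function(motion, model) {
  nodes <- segment_nodes(motion)
  missing <- setdiff(SEGMENT_NAMES, names(nodes))
  if (length(missing))
    stop("motion stream does not cover segments: ",
         paste(missing, collapse = ", "))
  n <- motion$n_frames
  R <- list(); pos <- list()
  # traverse joints parents-first (BVH declaration order guarantees it)
  for (nm in motion$joint_order) {
    j <- motion$joints[[nm]]
    arr <- motion$rotations[[nm]]
    if (is.na(j$parent)) {
      R[[nm]] <- arr
      pos[[nm]] <- motion$root_position
    } else {
      Rp <- R[[j$parent]]
      out <- array(0, c(3, 3, n))
      pp <- matrix(0, n, 3)
      for (f in seq_len(n)) {
        out[, , f] <- Rp[, , f] %*% arr[, , f]
        pp[f, ] <- pos[[j$parent]][f, ] + Rp[, , f] %*% j$offset
      }
      R[[nm]] <- out
      pos[[nm]] <- pp
    }
  }

  rotations <- list(); com <- list()
  for (s in SEGMENT_NAMES) {
    nd <- nodes[[s]]
    rotations[[s]] <- R[[nd]]
    cm <- matrix(0, n, 3)
    off <- model$segments[[s]]$com_offset
    for (f in seq_len(n)) cm[f, ] <- pos[[nd]][f, ] + R[[nd]][, , f] %*% off
    com[[s]] <- cm
  }
  joint_pos <- list()
  for (jn in names(model$joints))
    joint_pos[[jn]] <- pos[[nodes[[model$joints[[jn]]$child]]]]
  markers <- list()
  for (mk in names(model$markers)) {
    seg <- model$markers[[mk]]$segment
    off <- model$markers[[mk]]$offset
    nd <- nodes[[seg]]
    mm <- matrix(0, n, 3)
    for (f in seq_len(n)) mm[f, ] <- pos[[nd]][f, ] + R[[nd]][, , f] %*% off
    markers[[mk]] <- mm
  }
  list(rotations = rotations, joint_pos = joint_pos, com = com,
       markers = markers, origin = motion$root_position)
}

# angular velocity from an orientation series: omega = vee(Rdot R^T)
omega_from_rotations <- function(arr, frame_rate) {
  n <- dim(arr)[3]
  flat <- matrix(arr, nrow = 9, ncol = n)
  dflat <- t(differentiate(t(flat), frame_rate))
  om <- matrix(0, n, 3)
  for (f in seq_len(n)) {
    W <- matrix(dflat[, f], 3, 3) %*% t(arr[, , f])
    om[f, ] <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
  }
  om
}

#' Assemble per-frame segment states from motion and sensor streams
#'
#' Pose comes from forward kinematics of the motion stream. Angular
#' velocity comes from the gyro where the segment carries a sensor and from
#' differentiated orientations otherwise (such segments are reported via
#' the `"derived_segments"` attribute). Angular acceleration is the
#' numerical derivative of omega. CoM acceleration applies the IMU
#' lever-arm relation with the configured sensor placement offsets.
#'
#' @param motion a `motion_sequence`.
#' @param sensors a `sensor_series`, or `NULL` to derive everything from
#'   the motion stream.
#' @param model a `body_model`.
#' @param filter_cutoff low-pass cutoff in Hz applied to sensor channels
#'   and marker trajectories before differentiation, or `NULL` to disable
#'   (noiseless input).
#' @param imu_offsets named list of per-segment IMU placement offsets
#'   (metres, segment frame, relative to the CoM). Default: sensors at the
#'   segment CoM.
#' @return a `segment_states` object.
#' @export
build_states <- function(motion, sensors = NULL, model,
                         filter_cutoff = NULL, imu_offsets = NULL) {
  fr <- motion$frame_rate
  n <- motion$n_frames
  if (!is.null(sensors) && sensors$n_frames != n)
    stop("sensor series length (", sensors$n_frames,
         ") does not match motion (", n, ")")
  fk <- forward_kinematics(motion, model)

  smooth <- function(m) {
    if (is.null(filter_cutoff)) return(m)
    apply(m, 2, lowpass_filter, cutoff = filter_cutoff, frame_rate = fr)
  }

  g <- model$g
  derived <- character()
  segments <- list()
  for (s in SEGMENT_NAMES) {
    Rarr <- fk$rotations[[s]]
    sen <- if (!is.null(sensors)) sensors$segments[[s]] else NULL
    if (!is.null(sen)) {
      omega <- smooth(sen$gyro)
      a_si <- smooth(sen$accel)
      if (!is.null(sensors) && isTRUE(sensors$gravity_included))
        a_si[, 3] <- a_si[, 3] - g
    } else {
      derived <- c(derived, s)
      omega <- omega_from_rotations(Rarr, fr)
      a_si <- differentiate(smooth(fk$com[[s]]), fr, order = 2)
    }
    alpha <- differentiate(omega, fr)
    off <- if (!is.null(imu_offsets) && s %in% names(imu_offsets))
      imu_offsets[[s]] else c(0, 0, 0)
    if (!is.null(sen) && any(off != 0)) {
      r_si <- t(vapply(seq_len(n), function(f) drop(Rarr[, , f] %*% off),
                       numeric(3)))
      acc <- com_acceleration(a_si, alpha, omega, r_si)
    } else {
      acc <- if (is.null(sen)) a_si else com_acceleration(a_si, alpha, omega,
                                                          matrix(0, n, 3))
    }
    segments[[s]] <- list(R = Rarr, com = fk$com[[s]], acc = acc,
                          omega = omega, alpha = alpha)
  }

  markers <- lapply(fk$markers, smooth)
  marker_vel <- lapply(markers, differentiate, frame_rate = fr)

  structure(list(
    frame_rate = fr, n_frames = n, origin = fk$origin,
    segments = segments, joint_pos = fk$joint_pos,
    markers = markers, marker_vel = marker_vel,
    derived_segments = derived
  ), class = "segment_states")
}

#' @export
print.segment_states <- function(x, ...) {
  cat(sprintf("<segment_states> 15 segments, %d frames @ %.6g Hz\n",
              x$n_frames, x$frame_rate))
  if (length(x$derived_segments))
    cat("  kinematics derived from motion stream for:",
        paste(x$derived_segments, collapse = ", "), "\n")
  invisible(x)
}
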
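# Biovision Hierarchy (BVH) reading and writing.
#
# BVH files are Y-up; everything inside this package is Z-up with X
# anterior. The permutation C (bvh <- internal): x_bvh = y_int,
# y_bvh = z_int, z_bvh = x_int is applied once at ingest/export, so no
# other module ever sees BVH axes. BVH positions default to centimetres
# (common inertial-mocap export), controlled by `unit_scale`.

C_BVH <- matrix(c(0, 0, 1,   # columns: image of internal e_x, e_y, e_z
                  1, 0, 0,
                  0, 1, 0), 3, 3)

bvh_axis_of <- function(token) {
  switch(token,
    Xrotation = "x", Yrotation = "y", Zrotation = "z",
    Xposition = "px", Yposition = "py", Zposition = "pz",
    stop("unknown channel token: ", token))
}

# default BVH joint-name -> model segment map (writer names first,
# then common Perception-Neuron / CMU aliases)
DEFAULT_SEGMENT_MAP <- c(
  Hips = "pelvis", Chest = "torso", Spine = "torso", Spine3 = "torso",
  Head = "head", Neck = "head",
  RightArm = "upper_arm_r", RightUpperArm = "upper_arm_r",
  RightForeArm = "forearm_r", RightForearm = "forearm_r",
  RightHand = "hand_r",
  LeftArm = "upper_arm_l", LeftUpperArm = "upper_arm_l",
  LeftForeArm = "forearm_l", LeftForearm = "forearm_l",
  LeftHand = "hand_l",
  RightUpLeg = "thigh_r", RightThigh = "thigh_r",
  RightLeg = "shank_r", RightShin = "shank_r",
  RightFoot = "foot_r",
  LeftUpLeg = "thigh_l", LeftThigh = "thigh_l",
  LeftLeg = "shank_l", LeftShin = "shank_l",
  LeftFoot = "foot_l")

#' Read a BVH motion-capture file
#'
#' Parses the HIERARCHY and MOTION blocks, honouring the per-joint Euler
#' channel order declared in the header, and converts everything to the
#' package's internal convention (metres; right-handed Z-up, X-anterior).
#'
#' @param path BVH file path.
#' @param unit_scale metres per BVH position unit (default 0.01 =
#'   centimetres).
#' @param segment_map named character vector mapping BVH joint names to the
#'   15 model segment names.
#' @param require_model if `TRUE`, fail unless every one of the 15 model
#'   segments is covered by a mapped joint (listing unmatched names).
#' @return a `motion_sequence`: `$frame_rate`, `$n_frames`, `$joints`
#'   (named list: `parent`, `offset` m, `channels`, `segment`, optional
#'   `end_site`), `$root`, `$root_position` (n x 3, m), `$rotations`
#'   (per joint, 3 x 3 x n local rotation matrices).
#' @export
read_bvh <- function(path, unit_scale = 0.01,
                     segment_map = DEFAULT_SEGMENT_MAP,
                     require_model = FALSE) {
  lines <- readLines(path, warn = FALSE)
  ntok <- length(lines)
  i <- 1L
  tokline <- function() {
    while (i <= ntok && !nzchar(trimws(lines[i]))) i <<- i + 1L
    if (i > ntok) stop("unexpected end of BVH file: ", path)
    out <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    i <<- i + 1L
    out
  }
  expect <- function(tok, what) {
    if (!identical(tok[1], what))
      stop(sprintf("malformed BVH header at line %d: expected '%s', got '%s'",
                   i - 1L, what, tok[1]))
    tok
  }

  expect(tokline(), "HIERARCHY")
  joints <- list()
  joint_order <- character()
  root_name <- NULL

  parse_joint <- function(parent, header_tok) {
    name <- paste(header_tok[-1], collapse = "_")
    tok <- expect(tokline(), "{")
    off_tok <- expect(tokline(), "OFFSET")
    offset_bvh <- as.numeric(off_tok[2:4])
    if (anyNA(offset_bvh))
      stop("malformed OFFSET at line ", i - 1L)
    ch_tok <- expect(tokline(), "CHANNELS")
    nch <- as.integer(ch_tok[2])
    channels <- ch_tok[3:(2 + nch)]
    for (ch in channels) bvh_axis_of(ch)   # validates tokens
    joints[[name]] <<- list(
      name = name, parent = parent,
      offset = drop(t(C_BVH) %*% offset_bvh) * unit_scale,
      channels = channels,
      segment = if (name %in% names(segment_map)) segment_map[[name]] else NA_character_,
      end_site = NULL)
    joint_order <<- c(joint_order, name)
    repeat {
      tok <- tokline()
      if (tok[1] %in% c("JOINT", "ROOT")) {
        parse_joint(name, tok)
      } else if (identical(tok[1], "End")) {
        expect(tokline(), "{")
        es <- expect(tokline(), "OFFSET")
        joints[[name]]$end_site <<-
          drop(t(C_BVH) %*% as.numeric(es[2:4])) * unit_scale
        expect(tokline(), "}")
      } else if (identical(tok[1], "}")) {
        break
      } else {
        stop("malformed BVH hierarchy at line ", i - 1L, ": '", tok[1], "'")
      }
    }
  }

  tok <- expect(tokline(), "ROOT")
  root_name <- paste(tok[-1], collapse = "_")
  parse_joint(NA_character_, tok)

  expect(tokline(), "MOTION")
  nf_tok <- expect(tokline(), "Frames:")
  n_frames <- as.integer(nf_tok[2])
  ft_tok <- tokline()
  if (!identical(ft_tok[1], "Frame") || !identical(ft_tok[2], "Time:"))
    stop("malformed BVH header at line ", i - 1L, ": expected 'Frame Time:'")
  frame_time <- as.numeric(ft_tok[3])
  if (!is.finite(frame_time) || frame_time <= 0)
    stop("invalid Frame Time: ", ft_tok[3])

  data_lines <- lines[i:length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) < n_frames)
    stop("BVH declares ", n_frames, " frames but has ", length(data_lines))
  vals <- scan(text = paste(data_lines[seq_len(n_frames)], collapse = "\n"),
               quiet = TRUE)
  ncol_expect <- sum(vapply(joints, function(j) length(j$channels), integer(1)))
  mat <- matrix(vals, nrow = n_frames, ncol = ncol_expect, byrow = TRUE)

  root_position <- matrix(0, n_frames, 3)
  rotations <- list()
  col <- 1L
  for (nm in joint_order) {
    j <- joints[[nm]]
    nch <- length(j$channels)
    block <- mat[, col:(col + nch - 1L), drop = FALSE]
    col <- col + nch
    pos_idx <- grep("position$", j$channels)
    rot_idx <- grep("rotation$", j$channels)
    if (length(pos_idx)) {
      p_bvh <- matrix(0, n_frames, 3)
      for (k in pos_idx) {
        ax <- bvh_axis_of(j$channels[k])
        p_bvh[, match(ax, c("px", "py", "pz"))] <- block[, k]
      }
      if (identical(nm, root_name))
        root_position <- p_bvh %*% C_BVH * unit_scale   # (C^T p)^T = p^T C
    }
    order_axes <- vapply(j$channels[rot_idx], bvh_axis_of, character(1))
    ang <- block[, rot_idx, drop = FALSE] * pi / 180
    arr <- array(0, c(3, 3, n_frames))
    for (f in seq_len(n_frames)) {
      Rb <- euler_to_rot(ang[f, ], order_axes)
      arr[, , f] <- t(C_BVH) %*% Rb %*% C_BVH
    }
    rotations[[nm]] <- arr
  }

  if (require_model) {
    segs <- stats::na.omit(vapply(joints, `[[`, character(1), "segment"))
    missing <- setdiff(SEGMENT_NAMES, segs)
    unmatched <- names(joints)[is.na(vapply(joints, `[[`, character(1), "segment"))]
    if (length(missing))
      stop("BVH skeleton does not cover the 15-segment model; missing: ",
           paste(missing, collapse = ", "),
           if (length(unmatched)) paste0("; unmatched joints: ",
                                         paste(unmatched, collapse = ", ")))
  }

  structure(list(
    frame_rate = 1 / frame_time, n_frames = n_frames,
    joints = joints, joint_order = joint_order, root = root_name,
    root_position = root_position, rotations = rotations
  ), class = "motion_sequence")
}

#' Write a `motion_sequence` to a BVH file
#'
#' Emits a standard HIERARCHY/MOTION dialect with
#' `Yrotation Xrotation Zrotation` channels (inertial-mocap style) and
#' positions in the configured unit.
#'
#' @param motion a `motion_sequence`.
#' @param path output path.
#' @param unit_scale metres per BVH position unit (default 0.01).
#' @param digits numeric precision for motion data.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(motion, path, unit_scale = 0.01, digits = 10) {
  js <- motion$joints
  children_of <- function(nm)
    motion$joint_order[vapply(motion$joint_order,
                              function(k) identical(js[[k]]$parent, nm),
                              logical(1))]
  fmt <- function(x) formatC(x, digits = digits, format = "f")

  out <- c("HIERARCHY")
  emit_joint <- function(nm, depth) {
    ind <- strrep("  ", depth)
    kw <- if (is.na(js[[nm]]$parent)) "ROOT" else "JOINT"
    off <- drop(C_BVH %*% js[[nm]]$offset) / unit_scale
    ch <- if (is.na(js[[nm]]$parent))
      "CHANNELS 6 Xposition Yposition Zposition Yrotation Xrotation Zrotation"
    else
      "CHANNELS 3 Yrotation Xrotation Zrotation"
    out <<- c(out,
              paste0(ind, kw, " ", nm),
              paste0(ind, "{"),
              paste0(ind, "  OFFSET ", paste(fmt(off), collapse = " ")),
              paste0(ind, "  ", ch))
    kids <- children_of(nm)
    if (length(kids) == 0) {
      es <- js[[nm]]$end_site
      if (is.null(es)) es <- c(0, 0, 0)
      es <- drop(C_BVH %*% es) / unit_scale
      out <<- c(out,
                paste0(ind, "  End Site"),
                paste0(ind, "  {"),
                paste0(ind, "    OFFSET ", paste(fmt(es), collapse = " ")),
                paste0(ind, "  }"))
    } else {
      for (k in kids) emit_joint(k, depth + 1)
    }
    out <<- c(out, paste0(ind, "}"))
  }
  emit_joint(motion$root, 0)

  n <- motion$n_frames
  rows <- character(n)
  ang_cache <- lapply(motion$joint_order, function(nm) {
    arr <- motion$rotations[[nm]]
    t(vapply(seq_len(n), function(f) {
      Rb <- C_BVH %*% arr[, , f] %*% t(C_BVH)
      rot_to_euler(Rb, "yxz") * 180 / pi
    }, numeric(3)))
  })
  names(ang_cache) <- motion$joint_order
  rootp <- motion$root_position %*% t(C_BVH) / unit_scale  # row-wise C %*% p
  for (f in seq_len(n)) {
    vals <- c(rootp[f, ], ang_cache[[motion$root]][f, ])
    for (nm in setdiff(motion$joint_order, motion$root))
      vals <- c(vals, ang_cache[[nm]][f, ])
    rows[f] <- paste(fmt(vals), collapse = " ")
  }
  out <- c(out, "MOTION",
           paste("Frames:", n),
           paste("Frame Time:", formatC(1 / motion$frame_rate, digits = 12,
                                        format = "f")),
           rows)
  writeLines(out, path)
  invisible(path)
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("<motion_sequence> %d joints, %d frames @ %.6g Hz\n",
              length(x$joints), x$n_frames, x$frame_rate))
  invisible(x)
}
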
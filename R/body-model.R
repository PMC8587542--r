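# 15-segment rigid-body model: pelvis, torso, head, and right/left upper
# arms, forearms, hands, thighs, shanks, feet, linked by 14 joints.
#
# Internal coordinate convention (everywhere in this package): right-handed,
# Z up, X anterior, Y to the subject's left. Segment frames coincide with
# the global frame in the neutral standing pose (arms hanging at the sides);
# limb segments extend along -Z, torso and head along +Z, the foot mainly
# along +X.

SEGMENT_NAMES <- c("pelvis", "torso", "head",
                   "upper_arm_r", "forearm_r", "hand_r",
                   "upper_arm_l", "forearm_l", "hand_l",
                   "thigh_r", "shank_r", "foot_r",
                   "thigh_l", "shank_l", "foot_l")

JOINT_NAMES <- c("l5s1", "neck",
                 "shoulder_r", "elbow_r", "wrist_r",
                 "shoulder_l", "elbow_l", "wrist_l",
                 "hip_r", "knee_r", "ankle_r",
                 "hip_l", "knee_l", "ankle_l")

# segment -> (base segment in the coefficient table, side)
segment_base <- function(name) sub("_(r|l)$", "", name)
segment_side <- function(name) {
  if (grepl("_r$", name)) "r" else if (grepl("_l$", name)) "l" else ""
}

bsip_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "bsip_coefficients.csv", package = "wbid")
      cache <<- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
    }
    cache
  }
})

#' Subject record
#'
#' @param height standing height in metres (0.5--2.5).
#' @param mass body mass in kilograms (20--200).
#' @param sex `"male"` or `"female"`.
#' @return a `subject_record` list.
#' @export
subject_record <- function(height, mass, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.numeric(height) || height <= 0.5 || height >= 2.5)
    stop("subject height must be in (0.5, 2.5) m, got ", height)
  if (!is.numeric(mass) || mass <= 20 || mass >= 200)
    stop("subject mass must be in (20, 200) kg, got ", mass)
  structure(list(height = height, mass = mass, sex = sex),
            class = "subject_record")
}

# Proportions of stature used for the canonical skeleton geometry.
skeleton_proportions <- list(
  hip_halfwidth   = 0.050,   # lateral offset of each hip joint centre
  shoulder_halfw  = 0.1225,  # half biacromial breadth
  shoulder_drop   = 0.90,    # shoulder height as fraction of torso length
  ankle_height    = 0.039,
  foot_ankle_back = 0.25     # ankle sits this fraction of foot length from heel
)

#' Build the scaled 15-segment body model
#'
#' Scales regression-based segment masses, lengths, centre-of-mass offsets
#' and inertia tensors to a subject's stature and body mass, using the
#' sex-specific coefficient table shipped with the package. Segment masses
#' are renormalised so that the 15 segments sum exactly to the subject's
#' mass (the raw regression fractions do not sum to 1, and the ground
#' reaction equations rely on exact mass conservation).
#'
#' @param subject a [subject_record()].
#' @param g gravitational acceleration, m/s^2.
#' @return a `body_model` with `$segments` (15 named specs: `mass`, `length`,
#'   `com_offset`, `inertia`, `parent_joint`, `parent_segment`), `$joints`
#'   (14 named joints with parent/child segments and the joint-centre offset
#'   in the parent segment frame), and foot `$markers` (toe and heel).
#' @export
build_body_model <- function(subject, g = 9.81) {
  if (!inherits(subject, "subject_record"))
    subject <- do.call(subject_record, as.list(subject))
  H <- subject$height
  tab <- bsip_table()
  tab <- tab[tab$sex == subject$sex, ]
  if (nrow(tab) == 0) stop("no coefficients for sex: ", subject$sex)
  rownames(tab) <- tab$segment
  pp <- skeleton_proportions

  # raw masses, then renormalise to the measured body mass
  raw <- vapply(SEGMENT_NAMES, function(s) tab[segment_base(s), "mass_frac"],
                numeric(1))
  masses <- raw / sum(raw) * subject$mass

  seg_dir <- function(name) {
    base <- segment_base(name)
    if (base %in% c("torso", "head")) c(0, 0, 1)
    else if (base == "foot") c(1, 0, 0)
    else c(0, 0, -1)
  }

  segments <- list()
  for (s in SEGMENT_NAMES) {
    base <- segment_base(s)
    L <- tab[base, "length_frac"] * H
    cf <- tab[base, "com_frac"]
    if (base == "foot") {
      # foot frame origin is the ankle; com_frac runs heel->toe
      com <- c((cf - pp$foot_ankle_back) * L, 0, -0.5 * pp$ankle_height * H)
    } else {
      com <- seg_dir(s) * cf * L
    }
    rg <- as.numeric(tab[base, c("rg_x", "rg_y", "rg_z")]) * L
    segments[[s]] <- list(
      name = s, mass = masses[[s]], length = L, com_offset = com,
      inertia = diag(masses[[s]] * rg^2),
      parent_joint = NA_character_, parent_segment = NA_character_)
  }

  len <- function(base) tab[base, "length_frac"] * H
  joints <- list(
    l5s1       = list(parent = "pelvis", child = "torso",
                      offset = c(0, 0, len("pelvis"))),
    neck       = list(parent = "torso", child = "head",
                      offset = c(0, 0, len("torso"))),
    shoulder_r = list(parent = "torso", child = "upper_arm_r",
                      offset = c(0, -pp$shoulder_halfw * H,
                                 pp$shoulder_drop * len("torso"))),
    elbow_r    = list(parent = "upper_arm_r", child = "forearm_r",
                      offset = c(0, 0, -len("upper_arm"))),
    wrist_r    = list(parent = "forearm_r", child = "hand_r",
                      offset = c(0, 0, -len("forearm"))),
    shoulder_l = list(parent = "torso", child = "upper_arm_l",
                      offset = c(0, pp$shoulder_halfw * H,
                                 pp$shoulder_drop * len("torso"))),
    elbow_l    = list(parent = "upper_arm_l", child = "forearm_l",
                      offset = c(0, 0, -len("upper_arm"))),
    wrist_l    = list(parent = "forearm_l", child = "hand_l",
                      offset = c(0, 0, -len("forearm"))),
    hip_r      = list(parent = "pelvis", child = "thigh_r",
                      offset = c(0, -pp$hip_halfwidth * H, 0)),
    knee_r     = list(parent = "thigh_r", child = "shank_r",
                      offset = c(0, 0, -len("thigh"))),
    ankle_r    = list(parent = "shank_r", child = "foot_r",
                      offset = c(0, 0, -len("shank"))),
    hip_l      = list(parent = "pelvis", child = "thigh_l",
                      offset = c(0, pp$hip_halfwidth * H, 0)),
    knee_l     = list(parent = "thigh_l", child = "shank_l",
                      offset = c(0, 0, -len("thigh"))),
    ankle_l    = list(parent = "shank_l", child = "foot_l",
                      offset = c(0, 0, -len("shank")))
  )
  for (j in names(joints)) {
    joints[[j]]$name <- j
    segments[[joints[[j]]$child]]$parent_joint <- j
    segments[[joints[[j]]$child]]$parent_segment <- joints[[j]]$parent
  }

  Lf <- len("foot"); ha <- pp$ankle_height * H
  markers <- list(
    toe_r  = list(segment = "foot_r",
                  offset = c((1 - pp$foot_ankle_back) * Lf, 0, -ha)),
    heel_r = list(segment = "foot_r",
                  offset = c(-pp$foot_ankle_back * Lf, 0, -ha)),
    toe_l  = list(segment = "foot_l",
                  offset = c((1 - pp$foot_ankle_back) * Lf, 0, -ha)),
    heel_l = list(segment = "foot_l",
                  offset = c(-pp$foot_ankle_back * Lf, 0, -ha))
  )

  # pelvis root height in the neutral standing pose
  root_height <- pp$ankle_height * H + len("shank") + len("thigh")

  structure(list(
    subject = subject, g = g,
    segments = segments, joints = joints, markers = markers,
    total_mass = sum(vapply(segments, `[[`, numeric(1), "mass")),
    root_height = root_height
  ), class = "body_model")
}

#' Distal-to-proximal evaluation orders of the two recursion chains
#'
#' The Newton--Euler recursion runs top-down over the upper body (hands and
#' head inward to the torso, whose proximal joint is L5/S1) and bottom-up
#' over the lower body (feet inward to the pelvis).
#'
#' @param model a `body_model`.
#' @return list with `top_down` and `bottom_up` character vectors of segment
#'   names in solve order; together they visit all 15 segments once.
#' @export
joint_tree <- function(model) {
  stopifnot(inherits(model, "body_model"))
  list(
    top_down = c("hand_r", "hand_l", "forearm_r", "forearm_l",
                 "upper_arm_r", "upper_arm_l", "head", "torso"),
    bottom_up = c("foot_r", "foot_l", "shank_r", "shank_l",
                  "thigh_r", "thigh_l", "pelvis")
  )
}

# distal joints of a segment (joints whose parent segment is `s`)
distal_joints <- function(model, s) {
  names(Filter(function(j) identical(j$parent, s), model$joints))
}

#' Export a body model to a human-readable YAML document
#'
#' Individual parameters can be edited and read back with
#' [import_body_model()].
#'
#' @param model a `body_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_body_model <- function(model, path) {
  doc <- list(
    subject = unclass(model$subject), g = model$g,
    segments = lapply(model$segments, function(s) {
      list(mass = s$mass, length = s$length,
           com_offset = as.numeric(s$com_offset),
           inertia_diag = as.numeric(diag(s$inertia)))
    }),
    joints = lapply(model$joints, function(j) {
      list(parent = j$parent, child = j$child,
           offset = as.numeric(j$offset))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read back a body model exported by [export_body_model()]
#'
#' Rebuilds the model from the stored subject record, then overrides any
#' parameters present in the document, so hand-edited values survive.
#'
#' @param path YAML file written by [export_body_model()].
#' @return a `body_model`.
#' @export
import_body_model <- function(path) {
  doc <- yaml::read_yaml(path)
  model <- build_body_model(
    subject_record(doc$subject$height, doc$subject$mass, doc$subject$sex),
    g = doc$g)
  for (s in names(doc$segments)) {
    model$segments[[s]]$mass <- doc$segments[[s]]$mass
    model$segments[[s]]$length <- doc$segments[[s]]$length
    model$segments[[s]]$com_offset <- as.numeric(doc$segments[[s]]$com_offset)
    model$segments[[s]]$inertia <- diag(as.numeric(doc$segments[[s]]$inertia_diag))
  }
  model$total_mass <- sum(vapply(model$segments, `[[`, numeric(1), "mass"))
  model
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %s, %.2f m, %.1f kg (15 segments, 14 joints)\n",
              x$subject$sex, x$subject$height, x$total_mass))
  invisible(x)
}
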
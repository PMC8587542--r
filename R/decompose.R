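# Decomposition of the total ground reaction into right and left foot
# reactions. Single stance is deterministic (the stance foot takes
# everything); flight leaves both feet unloaded and reports the total as a
# residual; double stance is statically indeterminate and is resolved by a
# convex quadratic program that minimises the sum of squared net lower-limb
# joint moments
#   min ||M_ra||^2 + ||M_la||^2 + ||M_rk||^2 + ||M_lk||^2
#       + ||M_rh||^2 + ||M_lh||^2
# over the right-foot wrench (F_rg, M_rg), with the left wrench eliminated
# through the equality constraints F_lg = F_g - F_rg, M_lg = M_g - M_rg,
# subject to both vertical components being non-negative. Each lower-limb
# moment is an affine function of the unknowns (bottom-up Newton-Euler
# through foot, shank, thigh), so the objective is a convex quadratic; the
# two inequality constraints act on a single coordinate, which a tiny
# active-set step solves exactly. A ridge term (1e-12) returns the
# minimum-norm solution when the objective is degenerate.

LOWER_JOINTS <- c("ankle_r", "knee_r", "hip_r", "ankle_l", "knee_l", "hip_l")

# stacked 18-vector of lower-limb net moments at frame f given the
# right-foot reaction wrench x = (F_r, M_r about the pelvic origin)
lower_moment_stack <- function(states, model, f, Fg_f, Mg_f, cop, x) {
  org <- states$origin[f, ]
  legs <- list(
    right = list(F = x[1:3], M = x[4:6], cop = cop$right,
                 chain = c("foot_r", "shank_r", "thigh_r")),
    left = list(F = Fg_f - x[1:3], M = Mg_f - x[4:6], cop = cop$left,
                chain = c("foot_l", "shank_l", "thigh_l"))
  )
  out <- numeric(18)
  k <- 0
  for (leg in legs) {
    couple <- leg$M - cross3(leg$cop - org, leg$F)
    solved <- list()
    ext <- list(list(force = leg$F, moment = couple, point = leg$cop))
    for (s in leg$chain) {
      jp <- model$segments[[s]]$parent_joint
      dj <- distal_joints(model, s)
      dj <- dj[dj %in% names(solved)]
      dl <- lapply(dj, function(j)
        c(solved[[j]], list(point = states$joint_pos[[j]][f, ])))
      solved[[jp]] <- segment_balance(
        state_at(states, s, f), model$segments[[s]],
        prox_pos = states$joint_pos[[jp]][f, ],
        distal_loads = dl,
        externals = if (s == leg$chain[1]) ext else list(),
        g = model$g)
      out[k + 1:3] <- solved[[jp]]$moment
      k <- k + 3
    }
  }
  out
}

# minimise ||A x + b||^2 + reg ||x||^2 s.t. lo <= x[3] <= hi
solve_split_qp <- function(A, b, lo, hi, reg = 1e-12) {
  H <- crossprod(A) + reg * diag(6)
  obj <- function(x) sum((A %*% x + b)^2) + reg * sum(x^2)
  x <- drop(solve(H, -crossprod(A, b)))
  if (x[3] >= lo - 1e-12 && x[3] <= hi + 1e-12) {
    x[3] <- min(max(x[3], lo), hi)
    return(list(x = x, objective = obj(x), active = "none"))
  }
  fix3 <- function(c3) {
    Ar <- A[, -3, drop = FALSE]
    br <- b + c3 * A[, 3]
    y <- drop(solve(crossprod(Ar) + reg * diag(5), -crossprod(Ar, br)))
    append(y, c3, after = 2)
  }
  cand <- list()
  if (is.finite(lo)) cand$lo <- fix3(lo)
  if (is.finite(hi)) cand$hi <- fix3(hi)
  vals <- vapply(cand, obj, numeric(1))
  best <- names(which.min(vals))
  list(x = cand[[best]], objective = vals[[best]], active = best)
}

#' Decompose the total ground reaction into per-foot reactions
#'
#' Per frame: during single stance the stance foot receives the full
#' `(F_g, M_g)`; with no foot in contact both feet are unloaded and the
#' total is reported in `$residual`; during double stance the minimum
#' squared-moment quadratic program (see above) splits the wrench, with
#' hard equality `F_rg + F_lg = F_g`, `M_rg + M_lg = M_g` and non-negative
#' vertical force on each foot.
#'
#' @param Fg,Mg n x 3 total reaction force (N) and moment about the pelvic
#'   origin (N m), from [total_grf()] / [total_grm()].
#' @param contacts a `contact_timeline`.
#' @param states a `segment_states` (lower-body poses feed the QP).
#' @param model a `body_model`.
#' @param cop_mode application point of each foot's reaction: vertical
#'   projection of the ankle centre onto the ground (`"ankle"`, default) or
#'   the foot CoM projection (`"foot_com"`).
#' @param reg ridge regularisation of the QP (minimum-norm tie-break).
#' @return a `ground_reaction`: `$total`, `$right`, `$left` (each with `F`,
#'   `M` about the pelvic origin and `$cop`), `$contact`, `$residual`,
#'   `$qp_objective` (NA outside double stance).
#' @export
decompose_grf <- function(Fg, Mg, contacts, states, model,
                          cop_mode = c("ankle", "foot_com"), reg = 1e-12) {
  cop_mode <- match.arg(cop_mode)
  n <- nrow(Fg)
  zero <- matrix(0, n, 3)
  right <- list(F = zero, M = zero, cop = zero)
  left <- list(F = zero, M = zero, cop = zero)
  residual <- zero
  qp_obj <- rep(NA_real_, n)

  ground_point <- function(side, f) {
    src <- if (cop_mode == "ankle")
      states$joint_pos[[paste0("ankle_", side)]][f, ]
    else states$segments[[paste0("foot_", side)]]$com[f, ]
    c(src[1], src[2], 0)
  }

  for (f in seq_len(n)) {
    sr <- contacts$right$state[f] == "stance"
    sl <- contacts$left$state[f] == "stance"
    cop <- list(right = ground_point("r", f), left = ground_point("l", f))
    right$cop[f, ] <- cop$right
    left$cop[f, ] <- cop$left
    if (sr && sl) {
      if (Fg[f, 3] < -1e-9)
        stop("double-stance decomposition infeasible at frame ", f,
             ": negative total vertical reaction ", Fg[f, 3])
      b <- lower_moment_stack(states, model, f, Fg[f, ], Mg[f, ], cop,
                              numeric(6))
      A <- matrix(0, 18, 6)
      for (k in 1:6) {
        e <- numeric(6); e[k] <- 1
        A[, k] <- lower_moment_stack(states, model, f, Fg[f, ], Mg[f, ],
                                     cop, e) - b
      }
      sol <- solve_split_qp(A, b, lo = 0, hi = max(Fg[f, 3], 0), reg = reg)
      right$F[f, ] <- sol$x[1:3]
      right$M[f, ] <- sol$x[4:6]
      left$F[f, ] <- Fg[f, ] - sol$x[1:3]
      left$M[f, ] <- Mg[f, ] - sol$x[4:6]
      qp_obj[f] <- sol$objective
    } else if (sr) {
      right$F[f, ] <- Fg[f, ]
      right$M[f, ] <- Mg[f, ]
    } else if (sl) {
      left$F[f, ] <- Fg[f, ]
      left$M[f, ] <- Mg[f, ]
    } else {
      residual[f, ] <- Fg[f, ]
    }
  }

  structure(list(
    n_frames = n, total = list(F = Fg, M = Mg),
    right = right, left = left, contact = contacts,
    residual = residual, qp_objective = qp_obj, cop_mode = cop_mode
  ), class = "ground_reaction")
}

#' Evaluate the double-stance objective at an arbitrary split (oracle hook)
#'
#' Computes the sum of squared lower-limb net joint moments for a given
#' right-foot wrench at one frame — the quantity the decomposition QP
#' minimises. Exposed so independent oracles (grids, random feasible
#' points) can score candidate splits.
#'
#' @inheritParams decompose_grf
#' @param f frame index.
#' @param x length-6 vector `(F_rg, M_rg)` (moment about the pelvic origin).
#' @return scalar objective value (N^2 m^2).
#' @export
split_objective <- function(Fg, Mg, states, model, f, x,
                            cop_mode = c("ankle", "foot_com")) {
  cop_mode <- match.arg(cop_mode)
  gp <- function(side) {
    src <- if (cop_mode == "ankle")
      states$joint_pos[[paste0("ankle_", side)]][f, ]
    else states$segments[[paste0("foot_", side)]]$com[f, ]
    c(src[1], src[2], 0)
  }
  cop <- list(right = gp("r"), left = gp("l"))
  sum(lower_moment_stack(states, model, f, Fg[f, ], Mg[f, ], cop, x)^2)
}

#' @export
print.ground_reaction <- function(x, ...) {
  ds <- sum(x$contact$right$state == "stance" &
            x$contact$left$state == "stance")
  cat(sprintf("<ground_reaction> %d frames (%d double stance), peak |Fz| = %.1f N\n",
              x$n_frames, ds, max(abs(x$total$F[, 3]))))
  invisible(x)
}
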
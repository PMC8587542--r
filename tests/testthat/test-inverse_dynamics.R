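# Newton-Euler recursion: closed-form statics, independent oracle,
# symmetry, conservation, and the static flavour.

test_that("static horizontal bar pinned at one end: closed-form wrench", {
  # uniform bar, 2 kg, 0.4 m, lying along +x from the proximal joint
  spec <- list(mass = 2, inertia = diag(3) * 0.01)
  state <- list(R = diag(3), com = c(0.2, 0, 0), acc = c(0, 0, 0),
                omega = c(0, 0, 0), alpha = c(0, 0, 0))
  bal <- segment_balance(state, spec, prox_pos = c(0, 0, 0))
  expect_equal(bal$force, c(0, 0, 2 * 9.81), tolerance = 1e-12)
  expect_equal(sqrt(sum(bal$moment^2)), 2 * 9.81 * 0.2, tolerance = 1e-12)
  expect_equal(bal$moment, c(0, -2 * 9.81 * 0.2, 0), tolerance = 1e-12)
})

test_that("static hand holding half a 17 kg box: wrist carries both weights", {
  model <- build_body_model(default_subject())
  spec <- model$segments$hand_r
  com <- c(0.3, -0.2, 0.9)
  state <- list(R = diag(3), com = com, acc = c(0, 0, 0),
                omega = c(0, 0, 0), alpha = c(0, 0, 0))
  ext <- list(list(force = c(0, 0, -8.5 * 9.81), moment = c(0, 0, 0),
                   point = com))
  bal <- segment_balance(state, spec, prox_pos = com + c(0, 0, 0.07),
                         externals = ext)
  expect_equal(bal$force[3], (spec$mass + 8.5) * 9.81, tolerance = 1e-12)
})

test_that("random dynamic segment matches an independently coded balance", {
  # independent oracle: assemble the wrench sums from scratch with skew
  # matrices and moments taken about the proximal joint directly
  oracle <- function(state, spec, prox, dl, ex, g) {
    W <- c(0, 0, -spec$mass * g)
    Fp <- spec$mass * state$acc - W
    for (d in dl) Fp <- Fp + d$force
    for (e in ex) Fp <- Fp - e$force
    Ig <- state$R %*% spec$inertia %*% t(state$R)
    # Euler about the fixed point prox: Mcom + (c - p) x m a
    lhs <- drop(Ig %*% state$alpha) +
      drop(skew3(state$omega) %*% (Ig %*% state$omega)) +
      drop(skew3(state$com - prox) %*% (spec$mass * state$acc))
    Mp <- lhs - drop(skew3(state$com - prox) %*% W)
    for (d in dl) Mp <- Mp + d$moment + drop(skew3(d$point - prox) %*% d$force)
    for (e in ex) Mp <- Mp - e$moment - drop(skew3(e$point - prox) %*% e$force)
    list(force = Fp, moment = Mp)
  }
  set.seed(21)
  for (k in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    state <- list(R = euler_to_rot(rnorm(3), c("z", "x", "y")),
                  com = rnorm(3), acc = rnorm(3), omega = rnorm(3),
                  alpha = rnorm(3))
    spec <- list(mass = runif(1, 0.5, 10),
                 inertia = diag(runif(3, 0.001, 0.2)))
    prox <- state$com + rnorm(3, 0, 0.3)
    dl <- list(list(force = rnorm(3), moment = rnorm(3),
                    point = state$com + rnorm(3, 0, 0.3)))
    ex <- list(list(force = rnorm(3), moment = rnorm(3),
                    point = state$com + rnorm(3, 0, 0.3)))
    got <- segment_balance(state, spec, prox, dl, ex, g = 9.81)
    want <- oracle(state, spec, prox, dl, ex, 9.81)
    expect_equal(got$force, want$force, tolerance = 1e-10)
    expect_equal(got$moment, want$moment, tolerance = 1e-10)
  }
})

test_that("stationary symmetric stance: left and right moments mirror", {
  run <- get_run("stand_quiet")
  dyn <- run$dynamic
  pairs <- list(c("ankle_r", "ankle_l"), c("knee_r", "knee_l"),
                c("hip_r", "hip_l"), c("shoulder_r", "shoulder_l"),
                c("elbow_r", "elbow_l"), c("wrist_r", "wrist_l"))
  for (p in pairs) {
    mr <- dyn$joints[[p[1]]]$moment
    ml <- dyn$joints[[p[2]]]$moment
    # mirror in y: roll and yaw flip, pitch matches
    expect_lt(max(abs(mr[, 2] - ml[, 2])), 1e-6)
    expect_lt(max(abs(mr[, 1] + ml[, 1])), 1e-6)
    expect_lt(max(abs(mr[, 3] + ml[, 3])), 1e-6)
  }
})

test_that("whole-body force closure and pelvis residual vanish with exact reactions", {
  for (nm in c("stand_sway", "gait")) {
    trial <- get_fixture(nm)
    st <- trial$truth$states
    model <- trial$model
    rx <- trial$truth$reactions
    # sum m a = F_rg + F_lg + sum W + sum F_ex
    lhs <- matrix(0, st$n_frames, 3)
    for (s in names(model$segments))
      lhs <- lhs + model$segments[[s]]$mass * st$segments[[s]]$acc
    rhs <- rx$right$F + rx$left$F
    rhs[, 3] <- rhs[, 3] - model$total_mass * model$g
    expect_lt(max(abs(lhs - rhs)), 1e-6)

    res <- whole_body_residual(trial$truth$joint_loads, st, model,
                               trial$loads)
    expect_lt(max(abs(res$force)), 1e-6)
    expect_lt(max(abs(res$moment)), 1e-6)
  }
})

test_that("static flavour equals dynamic on a stationary trial", {
  run <- get_run("stand_quiet", flavor = "both")
  for (j in names(run$dynamic$joints)) {
    expect_lt(max(abs(run$dynamic$joints[[j]]$moment -
                        run$static$joints[[j]]$moment)), 1e-9)
    expect_lt(max(abs(run$dynamic$joints[[j]]$force -
                        run$static$joints[[j]]$force)), 1e-9)
  }
})

test_that("static flavour is invariant to time reversal of the motion", {
  trial <- get_fixture("lift")
  st <- trial$truth$states
  model <- trial$model
  stat <- solve_static(st, model, trial$loads, trial$truth$reactions)

  rev_states <- st
  idx <- rev(seq_len(st$n_frames))
  for (s in names(rev_states$segments))
    for (fld in c("com", "acc", "omega", "alpha"))
      rev_states$segments[[s]][[fld]] <-
        rev_states$segments[[s]][[fld]][idx, , drop = FALSE]
  for (s in names(rev_states$segments))
    rev_states$segments[[s]]$R <- rev_states$segments[[s]]$R[, , idx]
  for (j in names(rev_states$joint_pos))
    rev_states$joint_pos[[j]] <- rev_states$joint_pos[[j]][idx, , drop = FALSE]
  rev_states$origin <- rev_states$origin[idx, , drop = FALSE]

  rev_loads <- lapply(trial$loads, function(l) {
    l$frames <- sort(st$n_frames + 1L - l$frames)
    l
  })
  ct <- trial$truth$contacts
  ct$right$state <- rev(ct$right$state)
  ct$left$state <- rev(ct$left$state)
  rx <- trial$truth$reactions
  rx$contact <- ct
  stat_rev <- solve_static(rev_states, model, rev_loads, rx)
  for (j in names(stat$joints))
    expect_lt(max(abs(stat$joints[[j]]$moment[idx, ] -
                        stat_rev$joints[[j]]$moment)), 1e-8)
})

test_that("dynamic-static gap appears exactly with segment acceleration", {
  trial <- get_fixture("lift")
  st <- trial$truth$states
  stat <- solve_static(st, trial$model, trial$loads, trial$truth$reactions)
  dyn <- trial$truth$joint_loads
  gap <- rn(dyn$joints$l5s1$moment - stat$joints$l5s1$moment)
  acc <- rn(st$segments$torso$acc)
  # acceleration-driven excursions: large where the torso accelerates,
  # near zero where it (almost) does not
  hi <- max(gap[acc > stats::quantile(acc, 0.75)])
  lo <- max(gap[acc < stats::quantile(acc, 0.05)])
  expect_gt(hi, 1)
  expect_gt(hi, 10 * lo)
})

test_that("peak ratio arithmetic and degenerate guard", {
  run <- get_run("lift", flavor = "both")
  expect_equal(peak_ratio(run$dynamic, run$dynamic, "l5s1"), 1)
  doubled <- run$dynamic
  for (j in names(doubled$joints))
    doubled$joints[[j]]$moment <- 2 * doubled$joints[[j]]$moment
  expect_equal(peak_ratio(doubled, run$dynamic, "l5s1"), 2)
  zero <- run$dynamic
  zero$joints$l5s1$moment[] <- 0
  expect_error(peak_ratio(run$dynamic, zero, "l5s1"), "zero")
})
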
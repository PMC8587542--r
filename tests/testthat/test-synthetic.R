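# Synthetic trial generators: determinism, forward-construction
# consistency, noise injection.

test_that("trials are deterministic: same call, identical members", {
  sub <- default_subject()
  a <- generate_stand(sub, duration = 1.5, sway_amplitude = 0.02, seed = 3)
  b <- generate_stand(sub, duration = 1.5, sway_amplitude = 0.02, seed = 3)
  expect_identical(a$truth$Fg, b$truth$Fg)
  expect_identical(a$sensors$segments, b$sensors$segments)
  expect_identical(a$motion$root_position, b$motion$root_position)
})

test_that("quiet stand truth: constant reaction (0, 0, m g)", {
  trial <- get_fixture("stand_quiet")
  mg <- trial$model$total_mass * trial$model$g
  expect_lt(max(abs(trial$truth$Fg[, 1:2])), 1e-9)
  expect_lt(max(abs(trial$truth$Fg[, 3] - mg)), 1e-9)
})

test_that("swayed stand truth equals the forward-computed m a", {
  sub <- default_subject()
  amp <- 0.02; fq <- 0.3
  trial <- generate_stand(sub, duration = 3, sway_amplitude = amp,
                          sway_freq = fq)
  t <- (seq_len(trial$motion$n_frames) - 1) / trial$motion$frame_rate
  a_y <- -amp * (2 * pi * fq)^2 * sin(2 * pi * fq * t)
  expect_lt(max(abs(trial$truth$Fg[, 2] -
                      trial$model$total_mass * a_y)), 1e-9)
})

test_that("truth satisfies whole-body force closure on every trial kind", {
  for (nm in c("stand_sway", "gait", "lift", "weight_shift")) {
    trial <- get_fixture(nm)
    st <- trial$truth$states
    model <- trial$model
    lhs <- matrix(0, st$n_frames, 3)
    for (s in names(model$segments))
      lhs <- lhs + model$segments[[s]]$mass * st$segments[[s]]$acc
    rhs <- trial$truth$Fg
    rhs[, 3] <- rhs[, 3] - model$total_mass * model$g
    for (ld in trial$loads) {
      n <- st$n_frames
      FF <- matrix(ld$force, n, 3, byrow = TRUE)
      if (!is.null(ld$frames))
        FF[setdiff(seq_len(n), ld$frames[1]:ld$frames[2]), ] <- 0
      rhs <- rhs + FF
    }
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("gait truth: per-foot reactions sum to the total on every frame", {
  trial <- get_fixture("gait")
  rx <- trial$truth$reactions
  expect_lt(max(abs(rx$right$F + rx$left$F + rx$residual - rx$total$F)),
            1e-9)
  # the template produces double stance and no flight
  ct <- trial$truth$contacts
  expect_gt(sum(ct$right$state == "stance" & ct$left$state == "stance"), 20)
  expect_equal(sum(rn(rx$residual) > 0), 0)
})

test_that("gait speed outside the template range is rejected", {
  expect_error(generate_gait(default_subject(), speed = 5), "speed")
})

test_that("lift truth: box load raises the static L5/S1 moment by its lever term", {
  sub <- default_subject()
  with_box <- get_fixture("lift")
  no_box <- generate_lift(sub, box_mass = 0)
  st <- with_box$truth$states
  stat_box <- solve_static(st, with_box$model, with_box$loads,
                           with_box$truth$reactions)
  stat_free <- solve_static(no_box$truth$states, no_box$model, list(),
                            no_box$truth$reactions)
  w <- with_box$params$grasp_window
  f <- round(mean(w))
  # statics oracle: the box adds w_box x lever about L5/S1 (hand CoM arms)
  lever_r <- st$segments$hand_r$com[f, ] - st$joint_pos$l5s1[f, ]
  lever_l <- st$segments$hand_l$com[f, ] - st$joint_pos$l5s1[f, ]
  wbox <- c(0, 0, -17 * 9.81 / 2)
  expected <- -(cross3(lever_r, wbox) + cross3(lever_l, wbox))
  got <- stat_box$joints$l5s1$moment[f, ] - stat_free$joints$l5s1$moment[f, ]
  expect_equal(got, expected, tolerance = 1e-8)
  # outside the grasp window the series agree
  pre <- seq_len(w[1] - 10)
  expect_lt(max(abs(stat_box$joints$l5s1$moment[pre, ] -
                      stat_free$joints$l5s1$moment[pre, ])), 1e-8)
})

test_that("deposit impact produces a dynamic spike absent from static truth", {
  smooth <- get_fixture("lift")
  impact <- get_fixture("lift_impact")
  w <- impact$params$grasp_window
  window <- (w[2] - 40):min(w[2] + 40, impact$motion$n_frames)
  dyn_spike <- max(rn(impact$truth$joint_loads$joints$shoulder_r$moment[window, ]))
  dyn_smooth <- max(rn(smooth$truth$joint_loads$joints$shoulder_r$moment[window, ]))
  expect_gt(dyn_spike, dyn_smooth + 20)
  stat <- solve_static(impact$truth$states, impact$model, impact$loads,
                       impact$truth$reactions)
  expect_lt(max(rn(stat$joints$shoulder_r$moment[window, ])),
            dyn_spike - 20)
})

test_that("sensor noise: seeded, truth untouched, SD as specified", {
  trial <- get_fixture("stand_quiet")
  n1 <- add_sensor_noise(trial, accel_sd = 0.5, gyro_sd = 0.02, seed = 9)
  n2 <- add_sensor_noise(trial, accel_sd = 0.5, gyro_sd = 0.02, seed = 9)
  expect_identical(n1$sensors$segments, n2$sensors$segments)
  expect_identical(n1$truth$Fg, trial$truth$Fg)
  n0 <- add_sensor_noise(trial, accel_sd = 0, gyro_sd = 0, seed = 9)
  expect_equal(n0$sensors$segments, trial$sensors$segments)
  # pooled noise SD within 5% at n >= 10,000 samples
  d <- unlist(lapply(names(trial$sensors$segments), function(s)
    n1$sensors$segments[[s]]$accel - trial$sensors$segments[[s]]$accel))
  expect_gt(length(d), 10000)
  expect_lt(abs(stats::sd(d) - 0.5) / 0.5, 0.05)
})

test_that("ground-penetrating parameters raise a generator error", {
  # a deep squat without knee flexion drives the toes through the floor
  expect_error(generate_lift(default_subject(), squat_depth = 0.3),
               "below the ground")
})
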
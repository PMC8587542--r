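# Filtering, differentiation, the IMU lever-arm relation, and state
# assembly.

test_that("zero-phase filter passes DC unchanged", {
  x <- rep(3.7, 400)
  expect_lt(max(abs(lowpass_filter(x, 10, 120) - x)), 1e-9)
})

test_that("filter attenuation matches the digital frequency response", {
  fr <- 120
  t <- (0:2399) / fr
  mid <- 600:1800
  # passband: < 1% attenuation, zero phase lag
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(x1, 10, fr)
  expect_gt(max(y1[mid]) / 1, 0.99)
  expect_lt(max(abs(y1[mid] - x1[mid])), 0.01)

  # stopband: amplitude equals the squared single-pass digital magnitude
  # frequency-domain oracle: rational transfer function on the unit circle
  bf <- signal::butter(2, 10 / (fr / 2), "low")
  z <- exp(1i * 2 * pi * 50 / fr * (0:(length(bf$b) - 1)))
  H <- sum(bf$b * Conj(z)) / sum(bf$a * Conj(z))
  expected <- Mod(H)^2               # forward-backward = squared magnitude
  x50 <- sin(2 * pi * 50 * t)
  y50 <- lowpass_filter(x50, 10, fr)
  gain <- max(abs(y50[mid]))
  expect_lt(abs(gain - expected) / expected, 0.05)
})

test_that("cutoff at or above Nyquist is a parameter error", {
  expect_error(lowpass_filter(rnorm(100), 60, 120), "Nyquist")
})

test_that("differentiation is exact for polynomials up to degree 2", {
  fr <- 100
  t <- (0:199) / fr
  expect_lt(max(abs(differentiate(2 * t + 1, fr) - 2)), 1e-10)
  d <- differentiate(t^2, fr)
  expect_lt(max(abs(d - 2 * t)), 1e-9)      # includes the endpoints
})

test_that("differentiation error on sin is within the Taylor bound", {
  fr <- 50
  t <- (0:499) / fr
  d <- differentiate(sin(t), fr)
  err <- abs(d - cos(t))[3:498]
  expect_lt(max(err), (1 / fr)^2 / 6 + 1e-12)
  expect_error(differentiate(c(1, 2), fr), "3 samples")
})

test_that("filtering and differentiation commute on band-limited signals", {
  fr <- 120
  t <- (0:1199) / fr
  x <- sin(2 * pi * 1.1 * t) + 0.5 * sin(2 * pi * 3.7 * t)
  a <- differentiate(lowpass_filter(x, 10, fr), fr)
  b <- lowpass_filter(differentiate(x, fr), 10, fr)
  # boundary stencils differ; compare away from the filter's edge window
  core <- 50:(length(x) - 50)
  expect_lt(sqrt(mean((a - b)[core]^2)), 1e-6)
})

test_that("CoM acceleration reduces to the IMU reading when omega = alpha = 0", {
  set.seed(3)
  for (k in 1:20) {
    a_si <- rnorm(3)
    expect_equal(com_acceleration(a_si, c(0, 0, 0), c(0, 0, 0), rnorm(3)),
                 a_si)
  }
})

test_that("centripetal closed form: omega (0,0,2), r (0.1,0,0)", {
  expect_equal(com_acceleration(c(0, 0, 0), c(0, 0, 0), c(0, 0, 2),
                                c(0.1, 0, 0)),
               c(0.4, 0, 0))
})

test_that("lever-arm relation matches an independent cross-product oracle", {
  # independent implementation via skew matrices
  oracle <- function(a_si, al, om, r)
    a_si - skew3(al) %*% r - skew3(om) %*% (skew3(om) %*% r)
  set.seed(8)
  for (k in 1:25) {
    a_si <- rnorm(3); al <- rnorm(3); om <- rnorm(3); r <- rnorm(3)
    expect_equal(com_acceleration(a_si, al, om, r),
                 drop(oracle(a_si, al, om, r)), tolerance = 1e-12)
  }
  # matrix form agrees with row-by-row evaluation
  n <- 7
  A <- matrix(rnorm(3 * n), n, 3); AL <- matrix(rnorm(3 * n), n, 3)
  OM <- matrix(rnorm(3 * n), n, 3); R <- matrix(rnorm(3 * n), n, 3)
  got <- com_acceleration(A, AL, OM, R)
  for (f in 1:n)
    expect_equal(got[f, ], com_acceleration(A[f, ], AL[f, ], OM[f, ], R[f, ]))
})

test_that("forward kinematics: identity pose stacks offsets; hip flexion rotates the knee", {
  trial <- get_fixture("stand_quiet")
  model <- trial$model
  fk <- forward_kinematics(trial$motion, model)
  # identity rotations: knee centre = root + hip offset + thigh drop
  expected_knee <- trial$motion$root_position[1, ] +
    model$joints$hip_r$offset + model$joints$knee_r$offset
  expect_equal(fk$joint_pos$knee_r[1, ], expected_knee, tolerance = 1e-12)
  # CoM positions match the generator's exact propagation
  for (s in names(model$segments))
    expect_lt(max(abs(fk$com[[s]] - trial$truth$states$segments[[s]]$com)),
              1e-9)

  # 90 degree hip flexion swings the knee into the sagittal plane
  mo <- trial$motion
  nfr <- mo$n_frames
  mo$rotations$RightUpLeg <- array(rep(euler_to_rot(-pi / 2, "y"), nfr),
                                   c(3, 3, nfr))
  fk2 <- forward_kinematics(mo, model)
  hip <- fk2$joint_pos$hip_r[1, ]
  knee <- fk2$joint_pos$knee_r[1, ]
  expect_equal(knee - hip,
               c(model$segments$thigh_r$length, 0, 0), tolerance = 1e-9)
})

test_that("stationary pose yields zero accelerations and rates", {
  run <- get_run("stand_quiet")
  for (s in names(run$states$segments)) {
    expect_lt(max(abs(run$states$segments[[s]]$acc)), 1e-9)
    expect_lt(max(abs(run$states$segments[[s]]$omega)), 1e-9)
  }
})

test_that("build_states recovers prescribed angular velocity from sensors", {
  trial <- get_fixture("gait")
  states <- build_states(trial$motion, trial$sensors, trial$model)
  for (s in names(states$segments))
    expect_lt(max(abs(states$segments[[s]]$omega -
                        trial$truth$states$segments[[s]]$omega)), 1e-6)
})

test_that("segments without sensors fall back to motion-derived kinematics", {
  trial <- get_fixture("stand_quiet")
  sensors <- trial$sensors
  sensors$segments$head <- NULL
  states <- build_states(trial$motion, sensors, trial$model)
  expect_equal(states$derived_segments, "head")
  expect_lt(max(abs(states$segments$head$acc)), 1e-6)
})

test_that("gravity-included sensor streams are stripped once", {
  trial <- get_fixture("stand_quiet")
  sensors <- trial$sensors
  g <- trial$model$g
  for (s in names(sensors$segments))
    sensors$segments[[s]]$accel[, 3] <-
      sensors$segments[[s]]$accel[, 3] + g
  sensors$gravity_included <- TRUE
  states <- build_states(trial$motion, sensors, trial$model)
  expect_lt(max(abs(states$segments$pelvis$acc)), 1e-9)
})

test_that("nonzero IMU offsets reconstruct the CoM acceleration", {
  trial <- get_fixture("gait")
  model <- trial$model
  off <- list(thigh_r = c(0.03, 0.01, -0.12))
  # rebuild the sensor stream as if the IMU sat off the CoM
  sensors <- trial$sensors
  st <- trial$truth$states
  n <- st$n_frames
  seg <- st$segments$thigh_r
  r_g <- t(vapply(seq_len(n), function(f) drop(seg$R[, , f] %*% off$thigh_r),
                  numeric(3)))
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sensors$segments$thigh_r$accel <- seg$acc + cr(seg$alpha, r_g) +
    cr(seg$omega, cr(seg$omega, r_g))
  states <- build_states(trial$motion, sensors, model, imu_offsets = off)
  # alpha is differentiated, so allow a small numerical budget
  expect_lt(max(abs(states$segments$thigh_r$acc - seg$acc)), 5e-3)
  expect_lt(stats::median(abs(states$segments$thigh_r$acc - seg$acc)), 1e-4)
})
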
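# BVH, sensor-table and force-plate I/O, and stream alignment.

make_bvh_text <- function(channels = "Zrotation Xrotation Yrotation",
                          angles = "0.0 0.0 0.0") {
  c("HIERARCHY",
    "ROOT Hips",
    "{",
    "  OFFSET 0.0 95.0 0.0",
    "  CHANNELS 6 Xposition Yposition Zposition Yrotation Xrotation Zrotation",
    paste("  JOINT Chest"),
    "  {",
    "    OFFSET 0.0 16.5 0.0",
    paste("    CHANNELS 3", channels),
    "    End Site",
    "    {",
    "      OFFSET 0.0 51.0 0.0",
    "    }",
    "  }",
    "}",
    "MOTION",
    "Frames: 1",
    "Frame Time: 0.008333333",
    paste("1.0 2.0 3.0 0.0 0.0 0.0", angles))
}

test_that("minimal BVH parses: zero rotations are identity, offsets scaled", {
  path <- withr::local_tempfile(fileext = ".bvh")
  writeLines(make_bvh_text(), path)
  mo <- read_bvh(path)
  expect_equal(mo$frame_rate, 1 / 0.008333333, tolerance = 1e-9)
  expect_equal(mo$n_frames, 1L)
  # BVH is Y-up in cm; internal is Z-up in m
  expect_equal(mo$joints$Hips$offset, c(0, 0, 0.95))
  expect_equal(mo$joints$Chest$offset, c(0, 0, 0.165))
  expect_equal(mo$rotations$Hips[, , 1], diag(3))
  expect_equal(mo$rotations$Chest[, , 1], diag(3))
  # root translation converted the same way
  expect_equal(mo$root_position[1, ], c(0.03, 0.01, 0.02))
})

test_that("declared channel order is honoured: 90 deg about BVH Z", {
  path <- withr::local_tempfile(fileext = ".bvh")
  writeLines(make_bvh_text(angles = "90.0 0.0 0.0"), path)
  mo <- read_bvh(path)
  # BVH Z maps to the internal anterior (x) axis
  expect_equal(mo$rotations$Chest[, , 1],
               euler_to_rot(pi / 2, "x"), tolerance = 1e-12)
})

test_that("unit factor scales positions exactly", {
  path <- withr::local_tempfile(fileext = ".bvh")
  writeLines(make_bvh_text(), path)
  m_cm <- read_bvh(path, unit_scale = 0.01)
  m_m <- read_bvh(path, unit_scale = 1.0)
  expect_equal(m_m$joints$Chest$offset, m_cm$joints$Chest$offset * 100)
  expect_equal(m_m$root_position, m_cm$root_position * 100)
})

test_that("malformed headers and unknown channels raise parse errors", {
  path <- withr::local_tempfile(fileext = ".bvh")
  writeLines(sub("HIERARCHY", "HIERARCH", make_bvh_text()), path)
  expect_error(read_bvh(path), "HIERARCHY")
  writeLines(sub("Zrotation", "Qrotation", make_bvh_text()), path)
  expect_error(read_bvh(path), "unknown channel")
})

test_that("BVH write-then-read round-trips generator joint angles", {
  trial <- get_fixture("gait")
  path <- withr::local_tempfile(fileext = ".bvh")
  write_bvh(trial$motion, path)
  mo <- read_bvh(path, require_model = TRUE)
  expect_equal(mo$n_frames, trial$motion$n_frames)
  for (nm in trial$motion$joint_order) {
    expect_equal(mo$joints[[nm]]$offset, trial$motion$joints[[nm]]$offset,
                 tolerance = 1e-9)
    expect_lt(max(abs(mo$rotations[[nm]] - trial$motion$rotations[[nm]])),
              1e-9)
  }
  expect_lt(max(abs(mo$root_position - trial$motion$root_position)), 1e-9)
})

test_that("skeletons not covering the model are rejected with names", {
  path <- withr::local_tempfile(fileext = ".bvh")
  writeLines(make_bvh_text(), path)
  expect_error(read_bvh(path, require_model = TRUE), "missing")
})

test_that("sensor tables round-trip and interpolate short gaps", {
  trial <- get_fixture("stand_quiet")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_table(trial$sensors, path)
  back <- read_sensor_table(path)
  expect_equal(back$frame_rate, trial$sensors$frame_rate, tolerance = 1e-9)
  for (s in names(trial$sensors$segments))
    for (q in c("position", "accel", "gyro"))
      expect_lt(max(abs(back$segments[[s]][[q]] -
                          trial$sensors$segments[[s]][[q]])), 1e-9)

  # all-zero acceleration columns survive as zeros
  expect_true(all(back$segments$pelvis$accel == 0))

  # one missing frame inside the tolerated gap: linear interpolation
  df <- utils::read.csv(path)
  df$pelvis_px[10] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  filled <- read_sensor_table(path)
  expect_equal(filled$segments$pelvis$position[10, 1],
               (df$pelvis_px[9] + df$pelvis_px[11]) / 2, tolerance = 1e-12)

  # a gap longer than max_gap is a data-quality error
  df$pelvis_px[20:45] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_sensor_table(path), "gap")

  # missing columns are a schema error (on an otherwise clean table)
  write_sensor_table(trial$sensors, path)
  df2 <- utils::read.csv(path)
  df2$pelvis_wz <- NULL
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_sensor_table(path), "missing required columns")
})

test_that("force-plate records parse, keep native rate, and reject bad blocks", {
  path <- withr::local_tempfile(fileext = ".txt")
  t960 <- seq(0, 0.5, by = 1 / 960)
  block <- function(id, origin) {
    c(paste("PLATE", id, "ORIGIN", paste(origin, collapse = " ")),
      "time,fx,fy,fz,mx,my,mz",
      paste(t960, 0, 0, 400, 0, 0, 0, sep = ","))
  }
  writeLines(c(block(1, c(0, -0.15, 0)), block(2, c(0, 0.15, 0))), path)
  rec <- read_forceplate(path)
  expect_equal(rec$rate, 960, tolerance = 1e-6)
  expect_equal(length(rec$plates), 2L)
  expect_true(all(rec$plates[["1"]]$force[, 3] == 400))
  expect_equal(rec$plates[["2"]]$origin, c(0, 0.15, 0))
  expect_equal(nrow(rec$plates[["1"]]$force), length(t960))

  # empty second block names the plate
  writeLines(c(block(1, c(0, -0.15, 0)),
               "PLATE 2 ORIGIN 0 0.15 0", "time,fx,fy,fz,mx,my,mz"), path)
  expect_error(read_forceplate(path), "plate 2")

  # non-monotone time is a format error
  bad <- block(1, c(0, 0, 0))
  bad[4] <- bad[3]
  writeLines(bad, path)
  expect_error(read_forceplate(path), "non-monotone")
})

test_that("downsampling 960 Hz plates to 120 Hz preserves constant forces", {
  path <- withr::local_tempfile(fileext = ".txt")
  t960 <- seq(0, 1, by = 1 / 960)
  writeLines(c("PLATE 1 ORIGIN 0 0 0", "time,fx,fy,fz,mx,my,mz",
               paste(t960, 0, 0, 400, 0, 0, 0, sep = ",")), path)
  rec <- downsample_forceplate(read_forceplate(path), 120)
  expect_equal(rec$rate, 120)
  expect_lt(max(abs(rec$plates[["1"]]$force[, 3] - 400)), 1e-6)
})

test_that("stream alignment finds constructed lags and rejects noise", {
  t <- seq(0, 10, by = 1 / 120)
  x <- sin(2 * pi * 0.5 * t) + 0.2 * sin(2 * pi * 1.3 * t)
  expect_equal(as.integer(align_streams(x, x)), 0L)
  # y delayed by 12 samples: y[i + 12] = x[i]
  y <- c(rep(x[1], 12), x)
  expect_equal(as.integer(align_streams(x, y)), 12L)
  set.seed(42)
  expect_error(align_streams(rnorm(500), rnorm(500)), "alignment failed")
})
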
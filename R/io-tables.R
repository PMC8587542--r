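# Delimited-table I/O: per-segment sensor series (position, linear
# acceleration, angular velocity in the global frame) and force-plate
# records. Column layouts are this package's documented CSV dialects; all
# values are SI once read.

#' Construct a sensor series container
#'
#' @param frame_rate sampling rate, Hz.
#' @param segments named list; each element a list with `position`,
#'   `accel`, `gyro` (n x 3 matrices, SI, global frame).
#' @param gravity_included whether `accel` still contains +g (see
#'   [build_states()]).
#' @return a `sensor_series`.
#' @export
sensor_series <- function(frame_rate, segments, gravity_included = FALSE) {
  n <- nrow(segments[[1]]$position)
  for (s in names(segments)) {
    if (!all(vapply(segments[[s]], nrow, integer(1)) == n))
      stop("sensor series lengths differ for segment ", s)
    if (!s %in% SEGMENT_NAMES)
      stop("unknown segment in sensor series: ", s)
  }
  structure(list(frame_rate = frame_rate, n_frames = n, segments = segments,
                 gravity_included = gravity_included),
            class = "sensor_series")
}

sensor_quantities <- c(p = "position", a = "accel", w = "gyro")

#' Write a sensor series to CSV
#'
#' One row per frame; columns `frame`, `time`, then
#' `<segment>_<q><axis>` with `q` in `p` (position, m), `a` (linear
#' acceleration, m/s^2), `w` (angular velocity, rad/s) and axis `x`,`y`,`z`.
#'
#' @param sensors a `sensor_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_table <- function(sensors, path) {
  n <- sensors$n_frames
  df <- data.frame(frame = seq_len(n) - 1L,
                   time = (seq_len(n) - 1L) / sensors$frame_rate)
  for (s in names(sensors$segments)) {
    for (q in names(sensor_quantities)) {
      m <- sensors$segments[[s]][[sensor_quantities[[q]]]]
      for (k in 1:3)
        df[[paste0(s, "_", q, c("x", "y", "z")[k])]] <- m[, k]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sensor-series CSV
#'
#' Inverse of [write_sensor_table()]. Short runs of missing values are
#' linearly interpolated; a gap longer than `max_gap` seconds is a
#' data-quality error.
#'
#' @param path CSV path.
#' @param max_gap longest tolerated missing-data gap, seconds.
#' @param gravity_included passed through to the returned series.
#' @return a `sensor_series`.
#' @export
read_sensor_table <- function(path, max_gap = 0.1, gravity_included = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "time") %in% names(df)))
    stop("sensor table is missing required columns: frame, time")
  n <- nrow(df)
  frame_rate <- if (n > 1) 1 / stats::median(diff(df$time)) else NA_real_
  max_run <- max(1L, floor(max_gap * frame_rate))

  fill <- function(x, col) {
    if (!anyNA(x)) return(x)
    r <- rle(is.na(x))
    if (any(r$values & r$lengths > max_run))
      stop("missing-data gap longer than ", max_gap, " s in column ", col)
    ok <- !is.na(x)
    stats::approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
  }

  seg_cols <- grep("_(p|a|w)(x|y|z)$", names(df), value = TRUE)
  segs <- unique(sub("_(p|a|w)(x|y|z)$", "", seg_cols))
  segments <- list()
  for (s in segs) {
    rec <- list()
    for (q in names(sensor_quantities)) {
      cols <- paste0(s, "_", q, c("x", "y", "z"))
      if (!all(cols %in% names(df)))
        stop("sensor table is missing required columns: ",
             paste(setdiff(cols, names(df)), collapse = ", "))
      m <- as.matrix(df[cols])
      for (k in 1:3) m[, k] <- fill(m[, k], cols[k])
      rec[[sensor_quantities[[q]]]] <- unname(m)
    }
    segments[[s]] <- rec
  }
  sensor_series(frame_rate, segments, gravity_included = gravity_included)
}

#' Write a force-plate record
#'
#' Text format: for each plate a header line
#' `PLATE <id> ORIGIN <x> <y> <z>` followed by CSV rows
#' `time,fx,fy,fz,mx,my,mz` (SI, global frame, moments about the plate
#' origin).
#'
#' @param rec a `forceplate_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forceplate <- function(rec, path) {
  out <- character()
  for (k in seq_along(rec$plates)) {
    p <- rec$plates[[k]]
    out <- c(out,
             paste("PLATE", k, "ORIGIN", paste(p$origin, collapse = " ")),
             "time,fx,fy,fz,mx,my,mz",
             apply(cbind(p$time, p$force, p$moment), 1,
                   function(r) paste(formatC(r, digits = 10, format = "g"),
                                     collapse = ",")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a force-plate record
#'
#' @param path file written in the [write_forceplate()] dialect.
#' @return a `forceplate_record`: `$plates`, each with `origin` (m),
#'   `time` (s, strictly increasing, native rate), `force` (N),
#'   `moment` (N m); `$rate` native sampling rate.
#' @export
read_forceplate <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^PLATE ", lines)
  if (!length(heads)) stop("no PLATE blocks found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  plates <- list()
  for (k in seq_along(heads)) {
    htok <- strsplit(trimws(lines[heads[k]]), "\\s+")[[1]]
    id <- htok[2]
    origin <- as.numeric(htok[4:6])
    if (heads[k] + 2L > bounds[k + 1L] - 1L)
      stop("force-plate block for plate ", id, " is empty")
    body <- lines[(heads[k] + 2L):(bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0)
      stop("force-plate block for plate ", id, " is empty")
    m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
    if (anyNA(m) || any(!is.finite(m)))
      stop("non-finite values in force-plate block ", id)
    tm <- m[, 1]
    if (any(diff(tm) <= 0))
      stop("non-monotone time vector in force-plate block ", id)
    plates[[id]] <- list(origin = origin, time = tm,
                         force = m[, 2:4, drop = FALSE],
                         moment = m[, 5:7, drop = FALSE])
  }
  rate <- 1 / stats::median(diff(plates[[1]]$time))
  structure(list(plates = plates, rate = rate), class = "forceplate_record")
}

#' Downsample a force-plate record to the motion frame rate
#'
#' Applies the zero-phase low-pass filter first, then decimates (integer
#' rate ratios) or polyphase-resamples (otherwise).
#'
#' @param rec a `forceplate_record`.
#' @param to_rate target rate, Hz.
#' @param cutoff low-pass cutoff, Hz (default 10).
#' @return a `forceplate_record` at `to_rate`.
#' @export
downsample_forceplate <- function(rec, to_rate, cutoff = 10) {
  q <- rec$rate / to_rate
  out <- rec
  for (id in names(rec$plates)) {
    p <- rec$plates[[id]]
    filt <- function(m) apply(m, 2, lowpass_filter, cutoff = cutoff,
                              frame_rate = rec$rate)
    f <- filt(p$force); mo <- filt(p$moment)
    if (abs(q - round(q)) < 1e-9) {
      idx <- seq(1, length(p$time), by = round(q))
      out$plates[[id]] <- list(origin = p$origin, time = p$time[idx],
                               force = f[idx, , drop = FALSE],
                               moment = mo[idx, , drop = FALSE])
    } else {
      rs <- function(m) apply(m, 2, function(x)
        as.numeric(signal::resample(x, p = 1000, q = round(1000 * q))))
      f2 <- rs(f); m2 <- rs(mo)
      out$plates[[id]] <- list(origin = p$origin,
                               time = p$time[1] + (seq_len(nrow(f2)) - 1) / to_rate,
                               force = f2, moment = m2)
    }
  }
  out$rate <- to_rate
  out
}

#' Integer-lag alignment of two streams by cross-correlation
#'
#' Returns the integer lag `l` maximising the normalised cross-correlation,
#' such that `y[i + l]` aligns with `x[i]`; i.e. if `y` is `x` delayed by
#' 12 samples, the lag is +12. Used to synchronise motion and force-plate
#' streams through a shared landmark trajectory (typically a vertical
#' coordinate or the vertical force).
#'
#' @param x,y numeric vectors covering an overlapping window.
#' @param max_lag largest |lag| searched (default: a third of the shorter
#'   series).
#' @param min_corr alignment fails if the peak correlation is below this.
#' @return integer lag, with the peak correlation as attribute `"corr"`.
#' @export
align_streams <- function(x, y, max_lag = NULL, min_corr = 0.5) {
  nx <- length(x); ny <- length(y)
  if (is.null(max_lag)) max_lag <- floor(min(nx, ny) / 3)
  lags <- -max_lag:max_lag
  cors <- vapply(lags, function(l) {
    ix <- seq_len(min(nx, ny - l))
    ix <- ix[ix >= 1 - l & ix + l <= ny & ix <= nx]
    if (length(ix) < 8) return(NA_real_)
    xs <- x[ix]; ys <- y[ix + l]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  if (all(is.na(cors))) stop("stream alignment failed: no usable overlap")
  best <- which.max(cors)
  if (cors[best] < min_corr)
    stop(sprintf(paste0("stream alignment failed: peak normalised ",
                        "cross-correlation %.3f below threshold %.3f"),
                 cors[best], min_corr))
  structure(lags[best], corr = cors[best])
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> %d segments, %d frames @ %.6g Hz\n",
              length(x$segments), x$n_frames, x$frame_rate))
  invisible(x)
}
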
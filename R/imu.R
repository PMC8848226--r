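# IMU sample streams: timestamped gyroscope / accelerometer / magnetometer
# triplets, and the plain CSV dialect used to exchange them
# (header t,gx,gy,gz,ax,ay,az,mx,my,mz).

IMU_COLUMNS <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")

#' IMU sample stream
#'
#' A data frame of timestamped inertial samples: `t` in seconds (strictly
#' increasing), gyroscope `gx,gy,gz` in deg/s (head frame), accelerometer
#' `ax,ay,az` in units of g (measures the gravity direction when static),
#' magnetometer `mx,my,mz` as a normalized field vector.
#'
#' @param t numeric vector of sample times, seconds, strictly increasing.
#' @param gyro n x 3 matrix of angular rates, deg/s.
#' @param accel n x 3 matrix of specific force, g.
#' @param mag n x 3 matrix of normalized magnetic field.
#' @return a data frame of class `imu_stream` with columns
#'   `t,gx,gy,gz,ax,ay,az,mx,my,mz`.
#' @export
imu_stream <- function(t, gyro, accel, mag) {
  t <- as.numeric(t)
  n <- length(t)
  gyro <- as.matrix(gyro); accel <- as.matrix(accel); mag <- as.matrix(mag)
  if (n < 1L) abort_validation("empty IMU stream")
  for (nm in c("gyro", "accel", "mag")) {
    m <- get(nm)
    if (nrow(m) != n || ncol(m) != 3L || any(!is.finite(m)))
      abort_validation(nm, " must be a finite ", n, " x 3 matrix")
  }
  if (n > 1L && any(diff(t) <= 0))
    abort_validation("IMU timestamps must be strictly increasing")
  out <- data.frame(t = t,
                    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                    mx = mag[, 1], my = mag[, 2], mz = mag[, 3])
  class(out) <- c("imu_stream", "data.frame")
  out
}

as_imu_stream <- function(df) {
  if (!all(IMU_COLUMNS %in% names(df)))
    abort_validation("IMU data must have columns ", paste(IMU_COLUMNS, collapse = ","))
  imu_stream(df$t,
             cbind(df$gx, df$gy, df$gz),
             cbind(df$ax, df$ay, df$az),
             cbind(df$mx, df$my, df$mz))
}

#' Read / write an IMU stream as CSV
#'
#' The dialect is a plain comma-separated file with header
#' `t,gx,gy,gz,ax,ay,az,mx,my,mz`, '.' decimal, UTF-8.
#'
#' @param path file path.
#' @return `read_imu_csv` returns an [imu_stream()]; `write_imu_csv`
#'   returns `path` invisibly.
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) abort_validation("IMU file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_imu_stream(df)
}

#' @rdname read_imu_csv
#' @param stream an [imu_stream()].
#' @export
write_imu_csv <- function(stream, path) {
  write.csv(as.data.frame(stream), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.imu_stream <- function(x, ...) {
  dur <- if (nrow(x) > 1L) diff(range(x$t)) else 0
  cat(sprintf("<imu_stream> %d samples spanning %.2f s\n", nrow(x), dur))
  NextMethod()
}
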
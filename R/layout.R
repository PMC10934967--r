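#' Sensor channel layout
#'
#' Maps flat channel indices to (sensor site, modality, axis) triads for a
#' body-worn IMU montage.  The default montage mirrors a five-sensor setup
#' (both wrists, both upper arms, trunk), each sensor contributing a
#' tri-axial accelerometer and a tri-axial gyroscope, i.e. 30 channels.
#' Channels are sensor-major: for each sensor, accelerometer x/y/z then
#' gyroscope x/y/z.
#'
#' @param n_sensors number of IMU sensors (default 5).
#' @param sites character vector of site names, length `n_sensors`.  Sites
#'   containing `"L."` / `"R."` are tagged as left / right side; others as
#'   central.
#' @return a `sensor_layout`: data frame with columns `channel`, `sensor`,
#'   `site`, `side` (`"L"`, `"R"`, `"C"`), `modality` (`"accel"`, `"gyro"`)
#'   and `axis` (`"x"`, `"y"`, `"z"`).
#' @examples
#' layout <- sensor_layout()
#' nrow(layout)  # 30 channels
#' @export
sensor_layout <- function(n_sensors = 5,
                          sites = default_sites(n_sensors)) {
  stopifnot(n_sensors >= 1, length(sites) == n_sensors)
  side <- ifelse(grepl("^L\\.", sites), "L",
                 ifelse(grepl("^R\\.", sites), "R", "C"))
  df <- do.call(rbind, lapply(seq_len(n_sensors), function(s) {
    data.frame(
      sensor = s, site = sites[s], side = side[s],
      modality = rep(c("accel", "gyro"), each = 3),
      axis = rep(c("x", "y", "z"), 2),
      stringsAsFactors = FALSE
    )
  }))
  df <- cbind(channel = seq_len(nrow(df)), df)
  class(df) <- c("sensor_layout", "data.frame")
  df
}

default_sites <- function(n_sensors) {
  base <- c("L.Wrist", "R.Wrist", "L.UpperArm", "R.UpperArm", "Trunk")
  if (n_sensors <= 5) base[seq_len(n_sensors)]
  else c(base, paste0("Extra", seq_len(n_sensors - 5)))
}

#' Channel indices of one (sensor, modality) triad
#' @keywords internal
triad_channels <- function(layout, sensor, modality) {
  layout$channel[layout$sensor == sensor & layout$modality == modality]
}

#' All (sensor, modality) triads of a layout
#'
#' @param layout a [sensor_layout()].
#' @return data frame with one row per triad and a list-column `channels`.
#' @keywords internal
layout_triads <- function(layout) {
  key <- unique(layout[, c("sensor", "modality", "side")])
  key$channels <- lapply(seq_len(nrow(key)), function(i) {
    triad_channels(layout, key$sensor[i], key$modality[i])
  })
  bad <- vapply(key$channels, length, 1L) != 3L
  if (any(bad)) stop("layout does not partition channels into 3-axis triads")
  if (sum(vapply(key$channels, length, 1L)) != nrow(layout)) {
    stop("layout channels are not fully covered by (sensor, modality) triads")
  }
  rownames(key) <- NULL
  key
}
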
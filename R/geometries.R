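# Built-in study geometries: the four-sensor cube layout (sensor
# coordinates as fractions of the cube edge H) and the 12-position
# water-tank array with its single source.

#' Cube-array geometry
#'
#' Four sensors on the lateral faces of a cube of edge `H_mm`:
#' (H/2, 0, 3H/4), (0, H/2, H/2), (H/2, H, H/2), (H, H/2, H/4).
#'
#' @param H_mm Cube edge, mm (> 0).
#' @return A [sensor_array()] in meters.
#' @export
cube_geometry <- function(H_mm) {
  stopifnot(is.numeric(H_mm), length(H_mm) == 1L, H_mm > 0)
  H <- H_mm * MM_TO_M
  sensor_array(rbind(
    c(H / 2, 0,     3 * H / 4),
    c(0,     H / 2, H / 2),
    c(H / 2, H,     H / 2),
    c(H,     H / 2, H / 4)
  ))
}

#' The three simulated source positions of the cube study
#'
#' @return 3 x 3 matrix, one source per row, m.
#' @export
cube_sources <- function() {
  rbind(
    c(100, 100, 100),
    c(100, 180, 150),
    c(80,  100, 180)
  ) * MM_TO_M
}

#' Extended cube layout with additional sensors
#'
#' The four face sensors of [cube_geometry()] plus up to eight cube
#' corners, for timing studies with 4-12 sensors.
#'
#' @param H_mm Cube edge, mm.
#' @param n_sensors Number of sensors, 4 to 12.
#' @return A [sensor_array()] in meters.
#' @export
cube_geometry_n <- function(H_mm, n_sensors = 4L) {
  stopifnot(n_sensors >= 4L, n_sensors <= 12L)
  base <- cube_geometry(H_mm)$positions
  H <- H_mm * MM_TO_M
  corners <- H * rbind(
    c(0, 0, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1),
    c(1, 1, 1), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)
  )
  sensor_array(rbind(base, corners)[seq_len(n_sensors), , drop = FALSE])
}

#' Water-tank geometry: 12 receiver positions and the source
#'
#' The 12 reception points and single source of the tank experiment, all
#' referenced to the lower corner of the tank (printed in cm, returned
#' in m).
#'
#' @return List with `array` (a 12-sensor [sensor_array()]) and
#'   `source` (3-vector, m).
#' @export
tank_geometry <- function() {
  sensors_cm <- rbind(
    c(70.5, 53.0, 31.0),
    c(70.5, 40.5, 31.0),
    c(56.5, 40.5, 31.0),
    c(42.5, 40.5, 31.0),
    c(42.5, 53.0, 31.0),
    c(42.5, 65.0, 31.0),
    c(56.5, 65.0, 31.0),
    c(70.5, 65.0, 31.0),
    c(70.5, 65.0, 43.0),
    c(70.5, 40.5, 43.0),
    c(42.5, 40.5, 43.0),
    c(42.5, 65.0, 43.0)
  )
  list(array = sensor_array(sensors_cm * CM_TO_M),
       source = c(54.0, 53.0, 38.0) * CM_TO_M)
}

#' Sensor groups of the tank study
#'
#' The ten sensor groupings evaluated in the tank experiment (six
#' four-sensor groups, then 6, 8, 10 and all 12 sensors).
#'
#' @return Named list of sensor index vectors.
#' @export
tank_groups <- function() {
  list(
    g1  = c(2L, 4L, 6L, 8L),
    g2  = c(9L, 10L, 11L, 12L),
    g3  = c(6L, 8L, 9L, 12L),
    g4  = c(2L, 4L, 10L, 11L),
    g5  = c(3L, 4L, 9L, 11L),
    g6  = c(1L, 4L, 9L, 12L),
    g7  = c(2L, 5L, 7L, 9L, 11L, 12L),
    g8  = c(1L, 3L, 4L, 6L, 7L, 8L, 10L, 11L),
    g9  = c(1L, 3L, 4L, 5L, 7L, 8L, 9L, 10L, 11L, 12L),
    g10 = 1:12
  )
}
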
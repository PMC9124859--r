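#' Sensor array constructor
#'
#' Bundles electrode names with their positions on the scalp sphere. Positions
#' are stored as Cartesian coordinates in meters with `|position| == head_radius`
#' for every sensor (coordinate frame: x to the right ear, y to the nasion,
#' z to the vertex).
#'
#' @param names character vector of unique electrode labels (10-10 style).
#' @param positions numeric matrix, one row per sensor, columns x/y/z in meters.
#' @param head_radius scalar scalp-sphere radius in meters.
#' @return an object of class `sensor_array`.
#' @export
sensor_array <- function(names, positions, head_radius = 0.092) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (length(names) != nrow(positions) || ncol(positions) != 3L)
    stop("`positions` must be a length(names) x 3 matrix")
  if (anyDuplicated(names)) stop("electrode names must be unique")
  r <- sqrt(rowSums(positions^2))
  if (any(abs(r - head_radius) > 1e-9 * head_radius))
    stop("all sensor positions must lie on the scalp sphere (|pos| == head_radius)")
  structure(list(names = as.character(names), positions = positions,
                 head_radius = head_radius),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d electrodes on a %.1f mm scalp sphere\n",
              length(x$names), 1000 * x$head_radius))
  cat("  ", paste(utils::head(x$names, 12), collapse = " "),
      if (length(x$names) > 12) "..." else "", "\n")
  invisible(x)
}

# spherical linear interpolation between two unit vectors
slerp <- function(p, q, t) {
  ang <- acos(max(-1, min(1, sum(p * q))))
  if (ang < 1e-12) return(matrix(rep(p, length(t)), ncol = 3, byrow = TRUE))
  s <- sin(ang)
  out <- outer(sin((1 - t) * ang) / s, p) + outer(sin(t * ang) / s, q)
  out / sqrt(rowSums(out^2))
}

# point on the equatorial (head-circumference) ring: azimuth `az` degrees from
# the nasion, side -1 = left / +1 = right; ring inclination 72 deg from vertex
ring_point <- function(az, side) {
  a <- az * pi / 180
  incl <- 72 * pi / 180
  c(side * sin(incl) * sin(a), sin(incl) * cos(a), cos(incl))
}

# midline point: `ang` degrees from the vertex, positive towards the nasion
midline_point <- function(ang) {
  a <- ang * pi / 180
  c(0, sin(a), cos(a))
}

#' Default 64-channel 10-10 montage
#'
#' Builds the 64 electrode positions of the extended 10-10 system used by the
#' BCI2000 64-channel cap: the full 10-10 set minus Nz, F9, F10, FT9, FT10,
#' A1, A2, TP9, TP10, P9 and P10. Positions are generated geometrically: the
#' head-circumference ring lies at 72 degrees inclination from the vertex with
#' electrodes every 18 degrees of azimuth, midline electrodes sit on the
#' nasion-inion arc at 18-degree steps, and interior rows are great-circle
#' interpolations between their ring endpoint and their midline electrode.
#' T9/T10 (below the ears) and Iz (below the inion) extend their arcs by one
#' further 18-degree step. The construction is exactly mirror-symmetric about
#' the mid-sagittal plane.
#'
#' @param head_radius scalp-sphere radius in meters (default 0.092).
#' @return a [sensor_array] with 64 electrodes.
#' @export
#' @examples
#' m <- default_montage()
#' length(m$names)  # 64
default_montage <- function(head_radius = 0.092) {
  nm <- character(0); pos <- NULL
  add <- function(names, pts) {
    nm <<- c(nm, names)
    pos <<- rbind(pos, pts)
  }
  # ring azimuths (degrees from nasion) for the lateral ring electrodes
  ring_az <- c(Fp = 18, AF = 36, F = 54, FT = 72, T = 90, TP = 108, P = 126,
               PO = 144, O = 162)
  # midline electrodes: degrees from vertex (positive anterior)
  mid_ang <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
               CPz = -18, Pz = -36, POz = -54, Oz = -72)
  for (i in seq_along(mid_ang)) add(names(mid_ang)[i], matrix(midline_point(mid_ang[i]), 1))
  add("Iz", matrix(midline_point(-90), 1))

  # ring-only rows
  add(c("Fp1", "Fp2"), rbind(ring_point(18, -1), ring_point(18, +1)))
  add(c("O1", "O2"),   rbind(ring_point(162, -1), ring_point(162, +1)))

  # interior rows: ring endpoint -> midline electrode, equal-fraction steps
  rows <- list(
    list(ring = "AF", mid = "AFz", left  = c(AF7 = 0, AF3 = 0.5),
                                   right = c(AF8 = 0, AF4 = 0.5)),
    list(ring = "F", mid = "Fz",  left  = c(F7 = 0, F5 = .25, F3 = .5, F1 = .75),
                                  right = c(F8 = 0, F6 = .25, F4 = .5, F2 = .75)),
    list(ring = "FT", mid = "FCz", left  = c(FT7 = 0, FC5 = .25, FC3 = .5, FC1 = .75),
                                   right = c(FT8 = 0, FC6 = .25, FC4 = .5, FC2 = .75)),
    list(ring = "T", mid = "Cz",  left  = c(T7 = 0, C5 = .25, C3 = .5, C1 = .75),
                                  right = c(T8 = 0, C6 = .25, C4 = .5, C2 = .75)),
    list(ring = "TP", mid = "CPz", left  = c(TP7 = 0, CP5 = .25, CP3 = .5, CP1 = .75),
                                   right = c(TP8 = 0, CP6 = .25, CP4 = .5, CP2 = .75)),
    list(ring = "P", mid = "Pz",  left  = c(P7 = 0, P5 = .25, P3 = .5, P1 = .75),
                                  right = c(P8 = 0, P6 = .25, P4 = .5, P2 = .75)),
    list(ring = "PO", mid = "POz", left  = c(PO7 = 0, PO3 = 0.5),
                                   right = c(PO8 = 0, PO4 = 0.5))
  )
  for (rw in rows) {
    mp <- midline_point(mid_ang[[rw$mid]])
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else +1
      rp <- ring_point(ring_az[[rw$ring]], sgn)
      fr <- rw[[side]]
      add(names(fr), slerp(rp, mp, fr))
    }
  }
  # T9/T10: one 18-degree step beyond T7/T8 on the coronal arc (below the ears)
  add(c("T9", "T10"), rbind(c(-cos(18 * pi / 180), 0, -sin(18 * pi / 180)),
                            c(+cos(18 * pi / 180), 0, -sin(18 * pi / 180))))
  sensor_array(nm, pos * head_radius, head_radius)
}

# names of the electrodes the 64-channel cap omits from the full 10-10 set
excluded_1010_labels <- function() {
  c("Nz", "F9", "F10", "FT9", "FT10", "A1", "A2", "TP9", "TP10", "P9", "P10")
}
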
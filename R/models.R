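#' Parabolic-cap herniation volume model
#'
#' Assuming the displacement varies parabolically with distance from the
#' craniectomy edge across a circular opening of radius `r`, the volume
#' change is `dV = pi * r^2 * dy_max / 2` (the integral of the parabolic
#' profile over the disc). With r = 35 mm and dy_max = 25 mm this gives
#' about 48,000 mm^3 (48 ml).
#'
#' @param r opening radius in mm (> 0).
#' @param dy_max maximum displacement in mm (>= 0).
#' @return Predicted volume in mm^3.
#' @export
parabolic_cap_volume <- function(r, dy_max) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(dy_max < 0)) stop("dy_max must be non-negative")
  pi * r^2 * dy_max / 2
}

#' Cylindrical herniation volume model with edge restriction
#'
#' The expansion is taken as a cylinder over the opening --
#' `dV = effective_area * dy_max` -- where the effective area shrinks
#' the opening by an annulus of width `edge_restriction` (the
#' equivalent-circle radius reduced by that amount), representing
#' restricted expansion near the craniectomy edge. With zero restriction
#' this is the pure cylinder, exactly twice the parabolic-cap prediction
#' for the same radius and displacement; it systematically overestimates
#' measured volumes.
#'
#' @param area opening area in mm^2 (> 0).
#' @param dy_max maximum displacement in mm (>= 0).
#' @param edge_restriction annulus width in mm (>= 0, smaller than the
#'   equivalent radius).
#' @return Predicted volume in mm^3.
#' @export
cylindrical_model <- function(area, dy_max, edge_restriction = 0) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(dy_max < 0)) stop("dy_max must be non-negative")
  if (any(edge_restriction < 0)) stop("edge_restriction must be non-negative")
  r_eq <- sqrt(area / pi)
  if (any(edge_restriction >= r_eq))
    stop("edge_restriction must be smaller than the equivalent radius")
  pi * (r_eq - edge_restriction)^2 * dy_max
}
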
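# Planar muscle geometry: belly thickness t, fascicle length L and
# pennation angle theta related by t = L sin(theta).

#' Pennation angle from thickness and fascicle length
#'
#' Planar right-triangle model: `theta = asin(thickness / fascicle_length)`
#' in degrees.  For a soleus with 44 mm fascicles, a 15 mm belly gives
#' ~20 deg and a 15% thicker belly (17.25 mm) gives ~23 deg.
#'
#' @param thickness belly thickness, mm (0 < thickness <= fascicle_length).
#' @param fascicle_length fascicle length, mm.
#' @return pennation angle, degrees.
#' @export
pennation_from_thickness <- function(thickness, fascicle_length) {
  if (any(thickness <= 0) || any(fascicle_length <= 0)) {
    stopf("thickness and fascicle_length must be positive")
  }
  if (any(thickness > fascicle_length)) {
    stopf("thickness cannot exceed fascicle length")
  }
  asin(thickness / fascicle_length) * 180 / pi
}

#' Fascicle length from thickness at fixed pennation
#'
#' `L = thickness / sin(pennation)`.  Holding pennation at asin(15/44) while
#' thickening the belly by 15% lengthens the fascicle from 44 to ~51 mm.
#'
#' @param thickness belly thickness, mm.
#' @param pennation pennation angle, degrees, in (0, 90].
#' @return fascicle length, mm.
#' @export
fascicle_from_thickness <- function(thickness, pennation) {
  if (any(thickness <= 0)) stopf("thickness must be positive")
  if (any(pennation <= 0) || any(pennation > 90)) {
    stopf("pennation must lie in (0, 90] degrees")
  }
  thickness / sin(pennation * pi / 180)
}

#' Worked soleus geometry example
#'
#' Effect of a 15% thickness change on pennation (at fixed fascicle length)
#' and on fascicle length (at fixed pennation), for a 44 mm fascicle /
#' 15 mm belly soleus.
#' @param thickness,fascicle_length baseline geometry, mm.
#' @param change fractional thickness change (default +0.15).
#' @return data.frame with the baseline and changed configurations.
#' @export
geometry_example <- function(thickness = 15, fascicle_length = 44,
                             change = 0.15) {
  t2 <- thickness * (1 + change)
  p1 <- pennation_from_thickness(thickness, fascicle_length)
  p2 <- pennation_from_thickness(t2, fascicle_length)
  l2 <- fascicle_from_thickness(t2, p1)
  data.frame(
    case = c("baseline", "thicker, fixed fascicle", "thicker, fixed pennation"),
    thickness_mm = c(thickness, t2, t2),
    fascicle_mm = c(fascicle_length, fascicle_length, l2),
    pennation_deg = c(p1, p2, p1))
}
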
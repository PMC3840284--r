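#' Chamber geometry for a circular touch response surface
#'
#' Describes the response surface of the operant chamber: a circular response
#' area displayed on a touch panel, containing two circular response keys used
#' during the choice phase. Coordinates throughout the package are continuous
#' planar metres with the origin at the centre of the response area. Defaults
#' correspond to a 22-cm response area with 5-cm keys whose centres are 10 cm
#' apart.
#'
#' @param response_area_diameter Diameter of the circular response area, m.
#' @param key_diameter Diameter of each response key, m.
#' @param key_center_separation Distance between the two key centres, m.
#' @param key_center_height_offset Vertical offset of the key centres from the
#'   response-area centre, m (informational; keys are modelled on the
#'   horizontal midline by default).
#'
#' @return A list of class `"ae_geometry"`.
#' @examples
#' chamber_geometry()
#' @export
chamber_geometry <- function(response_area_diameter = 0.22,
                             key_diameter = 0.05,
                             key_center_separation = 0.10,
                             key_center_height_offset = 0) {
  if (!is.numeric(response_area_diameter) || response_area_diameter <= 0) {
    ae_abort("`response_area_diameter` must be a positive number.",
             "aeforage_error_invalid_argument")
  }
  if (key_diameter >= response_area_diameter) {
    ae_abort("`key_diameter` must be smaller than `response_area_diameter`.",
             "aeforage_error_invalid_argument")
  }
  # both keys must fit inside the response area
  half_span <- key_center_separation / 2 + key_diameter / 2
  if (sqrt(half_span^2 + key_center_height_offset^2) >
      response_area_diameter / 2 + 1e-12) {
    ae_abort("Keys do not fit inside the response area.",
             "aeforage_error_invalid_argument")
  }
  structure(
    list(
      response_area_diameter = response_area_diameter,
      key_diameter = key_diameter,
      key_center_separation = key_center_separation,
      key_center_height_offset = key_center_height_offset
    ),
    class = "ae_geometry"
  )
}

#' Construct peck events
#'
#' A peck event is one touch on the response surface: planar coordinates
#' (metres, origin at the response-area centre) and a simulated clock time
#' (seconds). Vectorised over all three arguments.
#'
#' @param x,y Coordinates on the response surface, m.
#' @param t Simulated clock time, s (non-negative).
#' @param geometry Optional [chamber_geometry()]; when supplied, pecks outside
#'   the response area raise an error.
#'
#' @return A tibble with columns `x`, `y`, `t`.
#' @examples
#' peck_events(x = c(0, 0.05), y = c(0, 0), t = c(0, 0.3))
#' @export
peck_events <- function(x, y, t, geometry = NULL) {
  if (any(t < 0)) {
    ae_abort("Peck times must be non-negative.", "aeforage_error_invalid_argument")
  }
  out <- tibble(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t))
  if (!is.null(geometry)) {
    r <- geometry$response_area_diameter / 2
    if (any(out$x^2 + out$y^2 > r^2 + 1e-12)) {
      ae_abort("Peck outside the response area.", "aeforage_error_invalid_behavior")
    }
  }
  out
}

#' Energy expenditure of a movement
#'
#' Computes the energy expended by a movement of a body of mass `M` over a
#' straight-line distance `D` in elapsed time `T` as `E = M * D^2 / T^2`
#' (joules). This is the general form of the interresponse-energy statistic;
#' see [compute_ire()] for the per-response version under the unit-mass
#' convention.
#'
#' @param mass Body mass, kg (> 0).
#' @param distance Distance moved, m (>= 0).
#' @param time Elapsed time, s (> 0).
#'
#' @return Energy, J. Vectorised.
#' @examples
#' energy_expenditure(mass = 1, distance = 0.05, time = 0.1) # 0.25 J
#' @export
energy_expenditure <- function(mass, distance, time) {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    ae_abort("`mass` must be positive.", "aeforage_error_invalid_argument")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    ae_abort("`time` must be positive.", "aeforage_error_invalid_argument")
  }
  if (any(!is.finite(distance)) || any(distance < 0)) {
    ae_abort("`distance` must be non-negative.", "aeforage_error_invalid_argument")
  }
  mass * distance^2 / time^2
}

#' Interresponse energy of a peck pair
#'
#' The interresponse distance (IRD) is the straight-line distance between the
#' locations of two consecutive pecks; the interresponse time (IRT) is the
#' elapsed time between them. The interresponse energy is
#' `IRE = IRD^2 / IRT^2`, energy per unit body mass reported in joules under
#' the convention that the subject's mass is constant within an experiment and
#' set to 1.
#'
#' @param first,second Single-row peck events (see [peck_events()]), or any
#'   lists with numeric `x`, `y`, `t` fields. `second$t` must exceed
#'   `first$t`.
#' @param mass Body mass, kg; retained for generality, default 1.
#'
#' @return A one-row tibble with columns `ird` (m), `irt` (s), `ire` (J) and
#'   `mass` (kg).
#' @examples
#' p <- peck_events(x = c(0, 0.1), y = c(0, 0), t = c(0, 0.2))
#' compute_ire(p[1, ], p[2, ]) # ire = 0.25 J
#' @export
compute_ire <- function(first, second, mass = 1) {
  irt <- second$t - first$t
  if (!is.finite(irt) || irt <= 0) {
    ae_abort("`second` must occur strictly after `first`.",
             "aeforage_error_invalid_argument")
  }
  ird <- sqrt((second$x - first$x)^2 + (second$y - first$y)^2)
  tibble(ird = ird, irt = irt, ire = mass * ird^2 / irt^2, mass = mass)
}

#' Minimum interresponse distance to meet an AE requirement
#'
#' For a given adjusting-energy requirement `a` and interresponse time `irt`,
#' the boundary distance is `irt * sqrt(a)`: the infimum IRD at which the
#' interresponse energy reaches `a`. Reinforcement requires the IRE to be
#' strictly greater than the requirement, so the boundary itself does not
#' reinforce. For example, a 0.25 J requirement needs an IRD above 0.05 m at
#' an IRT of 0.1 s, and above 0.1 m at 0.2 s.
#'
#' @param ae_requirement AE requirement, J (>= 0).
#' @param irt Interresponse time, s (> 0).
#'
#' @return Boundary IRD, m. Vectorised.
#' @examples
#' min_ird_to_meet(0.25, 0.1) # 0.05 m
#' min_ird_to_meet(0.25, 0.2) # 0.10 m
#' @export
min_ird_to_meet <- function(ae_requirement, irt) {
  if (any(!is.finite(ae_requirement)) || any(ae_requirement < 0)) {
    ae_abort("`ae_requirement` must be non-negative.",
             "aeforage_error_invalid_argument")
  }
  if (any(!is.finite(irt)) || any(irt <= 0)) {
    ae_abort("`irt` must be positive.", "aeforage_error_invalid_argument")
  }
  irt * sqrt(ae_requirement)
}

# Key centres on the response surface; side is "left" (AE key) or "right"
# (FR key). Used to place choice-phase pecks in event logs.
key_center <- function(geometry, side) {
  s <- geometry$key_center_separation / 2
  x <- if (identical(side, "left")) -s else s
  c(x = x, y = geometry$key_center_height_offset)
}
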
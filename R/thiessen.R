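#' Assign grid cells to stations by Thiessen (nearest-neighbour) zoning
#'
#' Every cell joins the zone of the station minimizing Euclidean distance;
#' exact ties go to the station with the lowest id. The resulting zones are
#' the Thiessen polygons of the station set, so the assignment is a
#' partition of the cells.
#'
#' @param stations data.frame with columns `id`, `x`, `y` (distinct
#'   locations).
#' @param cells data.frame with columns `x`, `y`.
#' @return Vector (length `nrow(cells)`) of station ids.
#' @export
build_thiessen_zones <- function(stations, cells) {
  if (is.null(stations) || nrow(stations) == 0)
    stop("configuration error: no stations supplied", call. = FALSE)
  if (anyDuplicated(stations[, c("x", "y")]))
    stop("station locations must be distinct", call. = FALSE)
  st <- stations[order(stations$id), , drop = FALSE]
  d2 <- outer(cells$x, st$x, "-")^2 + outer(cells$y, st$y, "-")^2
  idx <- apply(d2, 1, which.min)  # first minimum = lowest id after ordering
  st$id[idx]
}
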
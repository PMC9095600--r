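#' Group counties of a zone into yield levels
#'
#' Counties are ranked in descending mean statistical yield and split into
#' high/medium/low groups at the 33% and 67% quantile positions of the
#' descending order; the representative county of each group sits at the
#' 17%, 50% and 83% quantile position respectively. Quantile positions use
#' the convention round(q (n - 1)) (0-indexed, half-up) on the descending
#' list. With fewer than three counties the zone falls back to a single
#' group represented by the median county, flagged via `fallback`.
#'
#' @param counties data.frame with columns `county` (id) and `mean_yield`
#'   (kg/ha); ties in yield are broken by county id.
#' @return List with `groups` (named list high/medium/low of county ids),
#'   `representatives` (named vector of county ids), `order` (the descending
#'   ranking) and `fallback`.
#' @export
group_counties_by_yield <- function(counties) {
  stopifnot(all(c("county", "mean_yield") %in% names(counties)))
  ord <- order(-counties$mean_yield, counties$county)
  ids <- counties$county[ord]
  n <- length(ids)
  if (n == 0) stop("no counties to group", call. = FALSE)
  if (n < 3) {
    med <- ids[round_half_up(0.5 * (n - 1)) + 1]
    return(list(groups = list(all = ids),
                representatives = c(all = med),
                order = ids, fallback = TRUE))
  }
  pos <- round_half_up(c(0.17, 0.50, 0.83) * (n - 1)) + 1
  p0 <- seq_len(n) - 1
  high <- ids[p0 <= (n - 1) * 0.33]
  medium <- ids[p0 > (n - 1) * 0.33 & p0 <= (n - 1) * 0.67]
  low <- ids[p0 > (n - 1) * 0.67]
  list(groups = list(high = high, medium = medium, low = low),
       representatives = c(high = ids[pos[1]], medium = ids[pos[2]],
                           low = ids[pos[3]]),
       order = ids, fallback = FALSE)
}
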
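#' Inter-zonal centroid distance matrix
#'
#' Euclidean distances between zone centroids on the planar km grid. The
#' diagonal is left as `NA`: intra-zonal trip lengths need their own
#' estimate (see [intrazonal_lattice()] and [intrazonal_circle()]) because a
#' centroid-to-centroid distance of zero would let same-zone flows escape
#' the deterrence function entirely.
#'
#' @param zones zone data.frame (`zone_id`, `x_km`, `y_km`) or a [region()].
#' @return Symmetric n x n matrix in km with zone_ids as dimnames and `NA`
#'   on the diagonal.
#' @export
centroid_distances <- function(zones) {
  if (inherits(zones, "region")) zones <- zones$zones
  if (nrow(zones) < 2)
    stop("invalid-input: need at least 2 zones", call. = FALSE)
  if (anyDuplicated(zones$zone_id))
    stop("invalid-input: duplicate zone_id", call. = FALSE)
  if (!all(is.finite(zones$x_km)) || !all(is.finite(zones$y_km)))
    stop("invalid-input: non-finite coordinates", call. = FALSE)
  cm <- as.matrix(stats::dist(cbind(zones$x_km, zones$y_km)))
  dimnames(cm) <- list(zones$zone_id, zones$zone_id)
  diag(cm) <- NA_real_
  cm
}

#' Intra-zonal distance: random points in an equivalent circle
#'
#' Mean distance between two uniformly random points in a circle whose area
#' equals the zone's: `(128 / (45 * pi)) * r` with `r = sqrt(area / pi)`.
#' Depends only on zone size, so it tends to overestimate the true shopping
#' distance in large zones dense with stores; used as the fallback when a
#' zone has no stores.
#'
#' @param area zone area in km^2 (vectorised).
#' @return Distance in km.
#' @export
intrazonal_circle <- function(area) {
  if (any(area <= 0))
    stop("invalid-argument: area must be positive", call. = FALSE)
  128 / (45 * pi) * sqrt(area / pi)
}

#' Intra-zonal distance: nearest store on a lattice
#'
#' Expected distance from a uniformly located consumer to the nearest
#' retailer when the zone's stores are arranged on a lattice (the
#' arrangement that spreads stores out most evenly): `0.427 / sqrt(lambda)`
#' with store density `lambda = n_stores / area` in stores per km^2.
#'
#' @param area zone area in km^2.
#' @param n_stores store count in the zone (>= 1).
#' @return Distance in km.
#' @export
intrazonal_lattice <- function(area, n_stores) {
  if (any(area <= 0))
    stop("invalid-argument: area must be positive", call. = FALSE)
  if (any(n_stores < 1))
    stop("fallback-required: zone has no stores; use intrazonal_circle",
         call. = FALSE)
  lambda <- n_stores / area
  0.427 * lambda^(-0.5)
}

#' Build the full cost matrix for a region
#'
#' Off-diagonal entries are centroid-to-centroid Euclidean distances; the
#' diagonal holds the intra-zonal estimate. With the lattice method, zones
#' without stores fall back to the circle formula so every diagonal entry is
#' strictly positive.
#'
#' @param reg a [region()].
#' @param intrazonal_method `"lattice"` (default) or `"circle"`.
#' @return Strictly positive symmetric matrix in km, zone_ids as dimnames.
#' @export
build_cost_matrix <- function(reg, intrazonal_method = c("lattice", "circle")) {
  stopifnot(inherits(reg, "region"))
  intrazonal_method <- match.arg(intrazonal_method)
  cm <- centroid_distances(reg$zones)
  area <- reg$zones$area_km2
  nst <- as.numeric(table(factor(reg$stores$zone_id,
                                 levels = reg$zones$zone_id)))
  d <- if (intrazonal_method == "circle") {
    intrazonal_circle(area)
  } else {
    ifelse(nst >= 1, 0.427 * (nst / area)^(-0.5), intrazonal_circle(area))
  }
  diag(cm) <- d
  cm
}

#' Restrict a region to a buffer around a focal zone
#'
#' Keeps the focal zone and every zone whose centroid lies within `radius`
#' km of the focal centroid, the device used to keep per-outbreak gravity
#' models small while preserving fine zoning: one buffered model per
#' reported illness location. Stores are filtered to the retained zones and
#' brands left without stores are dropped (their revenue totals with them).
#'
#' @param reg a [region()].
#' @param focal_zone zone_id at the buffer centre.
#' @param radius buffer radius, km (> 0).
#' @return A [region()] restricted to the buffer.
#' @export
buffer_zones <- function(reg, focal_zone, radius) {
  stopifnot(inherits(reg, "region"))
  if (radius <= 0)
    stop("invalid-argument: radius must be positive", call. = FALSE)
  i <- match(focal_zone, reg$zones$zone_id)
  if (is.na(i))
    stop("not-found: unknown focal_zone '", focal_zone, "'", call. = FALSE)
  d <- sqrt((reg$zones$x_km - reg$zones$x_km[i])^2 +
            (reg$zones$y_km - reg$zones$y_km[i])^2)
  keep <- d <= radius
  zones <- reg$zones[keep, , drop = FALSE]
  stores <- reg$stores[reg$stores$zone_id %in% zones$zone_id, , drop = FALSE]
  brands <- reg$brands[reg$brands$brand_id %in% stores$brand_id, , drop = FALSE]
  region(zones, brands, stores)
}
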
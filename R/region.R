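#' Construct a study region from zone, brand and store tables
#'
#' A region bundles the three tables every downstream stage works from:
#' postal zones (planar centroids in km, area, population), retail brands
#' (yearly revenue totals), and individual stores assigned to zones.
#'
#' Per-store revenue follows the equal-split convention: a brand's total
#' revenue divided by its store count. If the store table carries a `weight`
#' column and no `revenue` column, revenues are instead apportioned within
#' each brand proportionally to the weights (a stand-in for store-size data).
#'
#' @param zones data.frame with columns `zone_id`, `x_km`, `y_km`,
#'   `area_km2`, `population`.
#' @param brands data.frame with columns `brand_id`, `total_revenue`.
#' @param stores data.frame with columns `store_id`, `brand_id`, `zone_id`
#'   and either `revenue` or `weight` (or neither, in which case the equal
#'   split is applied).
#' @return An object of class `region`: a list with validated `zones`,
#'   `brands` and `stores` data.frames.
#' @export
region <- function(zones, brands, stores) {
  zones <- as.data.frame(zones, stringsAsFactors = FALSE)
  brands <- as.data.frame(brands, stringsAsFactors = FALSE)
  stores <- as.data.frame(stores, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("schema-error: ", what, " table missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(zones, c("zone_id", "x_km", "y_km", "area_km2", "population"), "zones")
  need(brands, c("brand_id", "total_revenue"), "brands")
  need(stores, c("store_id", "brand_id", "zone_id"), "stores")
  if (nrow(zones) == 0L) stop("schema-error: zones table has no rows", call. = FALSE)
  if (nrow(brands) == 0L) stop("schema-error: brands table has no rows", call. = FALSE)

  zones$zone_id <- as.character(zones$zone_id)
  brands$brand_id <- as.character(brands$brand_id)
  stores$zone_id <- as.character(stores$zone_id)
  stores$brand_id <- as.character(stores$brand_id)
  stores$store_id <- as.character(stores$store_id)

  if (anyDuplicated(zones$zone_id))
    stop("invalid-input: duplicate zone_id", call. = FALSE)
  if (anyDuplicated(brands$brand_id))
    stop("invalid-input: duplicate brand_id", call. = FALSE)
  if (!all(is.finite(zones$x_km)) || !all(is.finite(zones$y_km)))
    stop("invalid-input: non-finite zone coordinates", call. = FALSE)
  if (any(zones$area_km2 <= 0))
    stop("invalid-input: zone areas must be strictly positive", call. = FALSE)
  if (any(zones$population < 0))
    stop("invalid-input: negative population", call. = FALSE)
  if (any(brands$total_revenue < 0))
    stop("invalid-input: negative brand revenue", call. = FALSE)

  bad_zone <- setdiff(stores$zone_id, zones$zone_id)
  if (length(bad_zone))
    stop("referential-integrity-error: store references unknown zone_id: ",
         paste(utils::head(bad_zone, 3L), collapse = ", "), call. = FALSE)
  bad_brand <- setdiff(stores$brand_id, brands$brand_id)
  if (length(bad_brand))
    stop("referential-integrity-error: store references unknown brand_id: ",
         paste(utils::head(bad_brand, 3L), collapse = ", "), call. = FALSE)

  if (!"revenue" %in% names(stores)) {
    tot <- stats::setNames(brands$total_revenue, brands$brand_id)
    if ("weight" %in% names(stores)) {
      if (any(stores$weight < 0))
        stop("invalid-input: negative store weight", call. = FALSE)
      wsum <- tapply(stores$weight, stores$brand_id, sum)
      stores$revenue <- tot[stores$brand_id] * stores$weight /
        as.numeric(wsum[stores$brand_id])
    } else {
      cnt <- table(stores$brand_id)
      stores$revenue <- tot[stores$brand_id] /
        as.numeric(cnt[stores$brand_id])
    }
  }
  if (any(stores$revenue < 0))
    stop("invalid-input: negative store revenue", call. = FALSE)

  structure(list(zones = zones, brands = brands, stores = stores),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat("Study region:", nrow(x$zones), "zones,", nrow(x$brands), "brands,",
      nrow(x$stores), "stores\n")
  cat("  total retail revenue:",
      format(sum(x$brands$total_revenue), big.mark = ","), "\n")
  cat("  total population:   ",
      format(sum(x$zones$population), big.mark = ","), "\n")
  invisible(x)
}

#' Generate a seeded synthetic study region
#'
#' Emulates a German county at postal-zone resolution: zone centroids are
#' scattered uniformly over a square bounding box and zone areas come from a
#' Voronoi-style partition of the box (areas are positive and sum to the box
#' area); populations are log-uniform so zone sizes are heavy-tailed like
#' real postal zones; each brand operates a sampled number of stores, placed
#' population-weighted across zones after every zone has received one store
#' (every postal zone of the emulated county contains food retail, so all
#' zones both generate and attract flows). Per-store revenue is the brand
#' total divided by the brand's store count.
#'
#' Deterministic for a fixed seed.
#'
#' @param n_zones number of postal zones (>= 2).
#' @param n_brands number of retail brands (>= 1).
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @param bbox_km side length of the square study area, km.
#' @param pop_range length-2 positive range for zone populations (log-uniform).
#' @param stores_per_brand_range length-2 integer range of stores per brand.
#' @param revenue_range length-2 positive range for brand yearly revenue
#'   totals (log-uniform; currency units).
#' @return A [region()] object.
#' @examples
#' reg <- generate_synthetic_region(n_zones = 10, n_brands = 3, seed = 1)
#' reg
#' @export
generate_synthetic_region <- function(n_zones = 49, n_brands = 10, seed = 1,
                                      bbox_km = 30,
                                      pop_range = c(1000, 20000),
                                      stores_per_brand_range = c(5, 20),
                                      revenue_range = c(50e6, 500e6)) {
  if (n_zones < 2 || n_brands < 1)
    stop("invalid-argument: need n_zones >= 2 and n_brands >= 1", call. = FALSE)
  if (any(pop_range <= 0) || any(stores_per_brand_range <= 0) ||
      any(revenue_range <= 0) || bbox_km <= 0)
    stop("invalid-argument: ranges and bbox_km must be positive", call. = FALSE)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  zone_id <- sprintf("Z%02d", seq_len(n_zones))
  x <- stats::runif(n_zones, 0, bbox_km)
  y <- stats::runif(n_zones, 0, bbox_km)

  # Voronoi-style areas: nearest-centroid assignment on a fine grid; cell
  # counts partition the box exactly, so areas sum to bbox_km^2.
  ngrid <- 200L
  gx <- (seq_len(ngrid) - 0.5) * bbox_km / ngrid
  gpts <- expand.grid(gx = gx, gy = gx)
  d2 <- outer(gpts$gx, x, "-")^2 + outer(gpts$gy, y, "-")^2
  owner <- max.col(-d2, ties.method = "first")
  cells <- tabulate(owner, nbins = n_zones)
  cells[cells == 0L] <- 1L  # degenerate near-coincident centroids keep area > 0
  area <- cells / sum(cells) * bbox_km^2

  lu <- function(n, rng) exp(stats::runif(n, log(rng[1]), log(rng[2])))
  population <- round(lu(n_zones, pop_range))
  population[population < 1] <- 1

  brand_id <- sprintf("B%02d", seq_len(n_brands))
  total_revenue <- lu(n_brands, revenue_range)

  n_stores <- sample(stores_per_brand_range[1]:stores_per_brand_range[2],
                     n_brands, replace = TRUE)
  store_brand <- rep(brand_id, n_stores)
  n_total <- length(store_brand)
  store_brand <- store_brand[sample.int(n_total)]

  # first pass guarantees coverage of every zone; remainder follows population
  store_zone <- character(n_total)
  n_cover <- min(n_zones, n_total)
  store_zone[seq_len(n_cover)] <- sample(zone_id, n_cover)
  if (n_total > n_cover)
    store_zone[(n_cover + 1L):n_total] <-
      sample(zone_id, n_total - n_cover, replace = TRUE,
             prob = population / sum(population))

  stores <- data.frame(
    store_id = sprintf("S%03d", seq_len(n_total)),
    brand_id = store_brand,
    zone_id = store_zone,
    stringsAsFactors = FALSE
  )

  region(
    zones = data.frame(zone_id = zone_id, x_km = x, y_km = y,
                       area_km2 = area, population = population,
                       stringsAsFactors = FALSE),
    brands = data.frame(brand_id = brand_id, total_revenue = total_revenue,
                        stringsAsFactors = FALSE),
    stores = stores
  )
}

#' Zonal retail revenue marginal
#'
#' The production marginal of the gravity model: for each zone the sum of the
#' revenues of the stores located there.
#'
#' @param reg a [region()].
#' @return Named numeric vector `O` over zones, in zone-table order;
#'   `sum(O)` equals the sum of brand revenue totals.
#' @export
zone_revenues <- function(reg) {
  stopifnot(inherits(reg, "region"))
  O <- stats::setNames(numeric(nrow(reg$zones)), reg$zones$zone_id)
  if (nrow(reg$stores)) {
    agg <- tapply(reg$stores$revenue, reg$stores$zone_id, sum)
    O[names(agg)] <- as.numeric(agg)
  }
  O
}

#' Zonal consumption potential marginal
#'
#' The attraction marginal: each zone's consumption potential is its
#' population share of total retail revenue, `D_j = pop_j / sum(pop) * REV`,
#' assuming equal mean food spend per person across zones. By construction
#' `sum(D) = sum(O)`, as the doubly constrained model requires.
#'
#' @param reg a [region()].
#' @return Named numeric vector `D` over zones.
#' @export
consumption_potentials <- function(reg) {
  stopifnot(inherits(reg, "region"))
  pop <- reg$zones$population
  if (sum(pop) <= 0)
    stop("invalid-input: total population must be positive", call. = FALSE)
  REV <- sum(zone_revenues(reg))
  stats::setNames(pop / sum(pop) * REV, reg$zones$zone_id)
}

#' Brand-by-zone market share matrix
#'
#' Row-stochastic matrix whose entry (b, r) is the share of brand b's revenue
#' generated by its stores in zone r. These are the brand-to-retailer-zone
#' transition probabilities of the supply network.
#'
#' @param reg a [region()].
#' @return Matrix, brands x zones, rows summing to 1.
#' @export
brand_zone_shares <- function(reg) {
  stopifnot(inherits(reg, "region"))
  zid <- reg$zones$zone_id
  bid <- reg$brands$brand_id
  M <- matrix(0, nrow = length(bid), ncol = length(zid),
              dimnames = list(bid, zid))
  if (nrow(reg$stores)) {
    agg <- tapply(reg$stores$revenue,
                  list(factor(reg$stores$brand_id, levels = bid),
                       factor(reg$stores$zone_id, levels = zid)),
                  sum)
    agg[is.na(agg)] <- 0
    M[] <- agg
  }
  tot <- rowSums(M)
  if (any(tot <= 0))
    stop("invalid-input: brand with zero zonal revenue: ",
         paste(bid[tot <= 0], collapse = ", "), call. = FALSE)
  M / tot
}
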
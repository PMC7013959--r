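#' Construct a layered food supply network
#'
#' Internal constructor shared by [build_network_A()] and
#' [build_network_B()]. Transient nodes are the brands followed by the
#' retailer zones with positive production; absorbing nodes are all consumer
#' zones. The transition structure is held in Markov canonical form: `P_Q`
#' (transient-to-transient) and `P_R` (transient-to-absorbing).
#'
#' @noRd
new_supply_network <- function(brand_shares, retail_to_consumer, label) {
  brands <- rownames(brand_shares)
  zones <- colnames(brand_shares)
  if (is.null(brands) || is.null(zones))
    stop("invalid-input: brand_shares must carry brand/zone dimnames",
         call. = FALSE)
  if (any(abs(rowSums(brand_shares) - 1) > 1e-8))
    stop("invalid-input: brand_shares rows must sum to 1", call. = FALSE)

  # retailer zones that sell nothing can receive no contaminated goods
  active <- zones[colSums(brand_shares) > 0]
  nb <- length(brands); nr <- length(active); nc <- length(zones)
  transient <- c(brands, paste0("R:", active))

  P_Q <- matrix(0, nb + nr, nb + nr, dimnames = list(transient, transient))
  P_Q[brands, paste0("R:", active)] <- brand_shares[, active, drop = FALSE]

  P_R <- matrix(0, nb + nr, nc, dimnames = list(transient, zones))
  P_R[paste0("R:", active), ] <- retail_to_consumer[active, , drop = FALSE]

  out <- sort(c(rowSums(P_Q) + rowSums(P_R)))
  if (any(abs(out - 1) > 1e-8))
    stop("invalid-input: transient rows must have unit total outflow",
         call. = FALSE)

  structure(list(transient_ids = transient, absorbing_ids = zones,
                 brand_ids = brands, retailer_zone_ids = active,
                 P_Q = P_Q, P_R = P_R, label = label),
            class = "supply_network")
}

#' Build the gravity-informed supply network (network A)
#'
#' Three layers: each brand distributes to retailer zones in proportion to
#' its zonal market shares, and each retailer zone sells to consumer zones
#' with the calibrated gravity flow probabilities. Retailer zones with zero
#' production are excluded from the transient set.
#'
#' @param brand_shares row-stochastic brands x zones matrix
#'   ([brand_zone_shares()]).
#' @param P_flow row-stochastic zones x zones flow probability matrix
#'   ([flow_probabilities()]); all-zero rows allowed for zero-production
#'   zones.
#' @return A `supply_network`.
#' @export
build_network_A <- function(brand_shares, P_flow) {
  P_flow <- as.matrix(P_flow)
  if (!identical(dim(P_flow), rep(ncol(brand_shares), 2L)) &&
      !(nrow(P_flow) == ncol(brand_shares) && ncol(P_flow) == ncol(brand_shares)))
    stop("invalid-input: P_flow must be square over the zones of brand_shares",
         call. = FALSE)
  if (is.null(rownames(P_flow))) dimnames(P_flow) <- list(colnames(brand_shares),
                                                          colnames(brand_shares))
  if (!identical(rownames(P_flow), colnames(brand_shares)))
    stop("invalid-input: zone ordering of P_flow and brand_shares differs",
         call. = FALSE)
  rs <- rowSums(P_flow)
  if (any(rs > 0 & abs(rs - 1) > 1e-8))
    stop("invalid-input: nonzero P_flow rows must sum to 1", call. = FALSE)
  sellers <- colnames(brand_shares)[colSums(brand_shares) > 0]
  if (any(rs[sellers] <= 0))
    stop("invalid-input: selling zone with all-zero flow row", call. = FALSE)
  new_supply_network(brand_shares, P_flow, label = "A")
}

#' Build the intra-zonal baseline network (network B)
#'
#' The co-location baseline: identical brand-to-retailer layer, but every
#' retailer zone sells exclusively to its own consumer zone (`p(F_ii) = 1`),
#' encoding the assumption that consumers shop only where they live.
#'
#' @inheritParams build_network_A
#' @return A `supply_network`.
#' @export
build_network_B <- function(brand_shares) {
  zones <- colnames(brand_shares)
  I <- diag(length(zones))
  dimnames(I) <- list(zones, zones)
  new_supply_network(brand_shares, I, label = "B")
}

#' @export
print.supply_network <- function(x, ...) {
  cat(sprintf("Food supply network %s: %d brands -> %d retailer zones -> %d consumer zones\n",
              x$label, length(x$brand_ids), length(x$retailer_zone_ids),
              length(x$absorbing_ids)))
  invisible(x)
}

#' Absorption probability matrix of a supply network
#'
#' `A = (I - P_Q)^{-1} P_R`: entry (q, c) is the probability that a food
#' item starting at transient node q is eventually consumed in consumer zone
#' c. Computed by linear solve, not explicit inversion; for the layered
#' brand/retailer structure `P_Q` is nilpotent of order 2, so this equals
#' `(I + P_Q) P_R`.
#'
#' @param net a `supply_network`.
#' @return Matrix, transient nodes x consumer zones; brand rows sum to 1.
#' @export
absorbing_matrix <- function(net) {
  stopifnot(inherits(net, "supply_network"))
  n <- nrow(net$P_Q)
  A <- tryCatch(solve(diag(n) - net$P_Q, net$P_R),
                error = function(e)
                  stop("internal-error: singular (I - P_Q) system: ",
                       conditionMessage(e), call. = FALSE))
  dimnames(A) <- list(net$transient_ids, net$absorbing_ids)
  A
}

#' Market-share prior over brand sources
#'
#' Without outbreak-specific intelligence the prior probability that a brand
#' is the contamination source is taken as its relative market share,
#' `rev_i / sum(rev)`.
#'
#' @param brands data.frame with `brand_id`, `total_revenue`, or a
#'   [region()].
#' @return Named probability vector over brands, summing to 1.
#' @export
market_share_prior <- function(brands) {
  if (inherits(brands, "region")) brands <- brands$brands
  rev <- brands$total_revenue
  if (sum(rev) <= 0)
    stop("invalid-input: total revenue must be positive", call. = FALSE)
  if (any(rev < 0))
    stop("invalid-input: negative revenue", call. = FALSE)
  stats::setNames(rev / sum(rev), brands$brand_id)
}
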
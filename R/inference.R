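#' Log-likelihood of illness observations under a candidate source brand
#'
#' Contaminated units travel independently, so the likelihood of the
#' observation multiset factorises over illnesses: each observation at
#' consumer zone o contributes the absorption probability `A[brand, o]`.
#' Returns `-Inf` when any observed zone is unreachable from the brand — a
#' brand with no market presence feeding a contaminated zone is ruled out
#' exactly, not floored.
#'
#' @param absorb absorption matrix from [absorbing_matrix()].
#' @param theta character vector (multiset) of observed consumer zone_ids.
#' @param brand brand_id row of `absorb`.
#' @return Scalar log-probability (possibly `-Inf`).
#' @export
log_likelihood <- function(absorb, theta, brand) {
  if (!brand %in% rownames(absorb))
    stop("not-found: unknown brand '", brand, "'", call. = FALSE)
  unknown <- setdiff(unique(theta), colnames(absorb))
  if (length(unknown))
    stop("invalid-input: observation at unknown zone(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  counts <- table(theta)
  a <- absorb[brand, names(counts)]
  if (any(a == 0)) return(-Inf)
  sum(as.numeric(counts) * log(a))
}

#' Posterior distribution over candidate source brands
#'
#' Bayes' rule with the market-share prior: posterior mass of each brand is
#' proportional to `prior * likelihood`, evaluated stably in log space with
#' max-subtraction before exponentiation (a 500-illness product underflows
#' double precision otherwise). Brands with zero likelihood keep posterior
#' exactly 0.
#'
#' @param absorb absorption matrix ([absorbing_matrix()]).
#' @param theta observation multiset (character vector of zone_ids).
#' @param prior named prior vector over brands.
#' @return Object of class `posterior_result`: `probabilities` (named,
#'   sums to 1), `log_likelihoods`, `estimate` (maximum-posterior brand,
#'   lowest index on ties), `rank_of` (competition rank per brand).
#' @export
posterior_over_brands <- function(absorb, theta, prior) {
  brands <- names(prior)
  if (is.null(brands) || !all(brands %in% rownames(absorb)))
    stop("invalid-input: prior must be named by brands present in absorb",
         call. = FALSE)
  ll <- vapply(brands, function(b) log_likelihood(absorb, theta, b),
               numeric(1))
  lp <- log(prior) + ll
  if (all(!is.finite(lp)))
    stop("no-feasible-source: every brand has zero posterior mass",
         call. = FALSE)
  m <- max(lp[is.finite(lp)])
  w <- exp(lp - m)
  w[!is.finite(lp)] <- 0
  p <- w / sum(w)

  rank_of <- vapply(p, function(pi) 1L + sum(p > pi), integer(1))
  structure(list(probabilities = p, log_likelihoods = ll,
                 estimate = brands[which.max(p)], rank_of = rank_of),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, digits = 3, ...) {
  cat("Posterior over source brands (MAP:", x$estimate, ")\n")
  print(round(sort(x$probabilities, decreasing = TRUE), digits))
  invisible(x)
}

#' Maximum-posterior source estimate
#'
#' The brand attaining the maximum posterior probability; ties resolve to
#' the lowest brand index (a fixed, documented convention).
#'
#' @param post a `posterior_result`.
#' @return brand_id.
#' @export
estimate_source <- function(post) {
  stopifnot(inherits(post, "posterior_result"))
  post$estimate
}

#' Competition rank of the true source in the posterior
#'
#' `1 +` the number of brands with strictly greater posterior mass, so tied
#' brands share the best rank.
#'
#' @param post a `posterior_result`.
#' @param true_source brand_id of the true source.
#' @return Integer rank >= 1.
#' @export
rank_of_true <- function(post, true_source) {
  stopifnot(inherits(post, "posterior_result"))
  r <- post$rank_of[true_source]
  if (is.na(r))
    stop("not-found: unknown brand '", true_source, "'", call. = FALSE)
  as.integer(r)
}
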
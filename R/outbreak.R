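#' Simulate one foodborne outbreak on a supply network
#'
#' Monte Carlo draw of an outbreak with a prescribed spread: a source brand
#' is drawn from the prior, `n_unique` distinct consumer zones are sampled
#' without replacement with probabilities proportional to the source's
#' absorption row, one illness is placed in each selected zone, and the
#' remaining `n_ill - n_unique` illnesses are distributed multinomially over
#' the selected zones with renormalised absorption probabilities. This keeps
#' the relative path probabilities of the independent-unit transmission
#' model while meeting the uniqueness constraint exactly. Illness order is
#' shuffled so prefixes of the observation list are unbiased.
#'
#' If a drawn source reaches fewer than `n_unique` zones it is redrawn (at
#' most 100 times) before failing.
#'
#' @param net_truth `supply_network` assumed to carry the true transmission
#'   probabilities.
#' @param prior named prior probability vector over brands
#'   ([market_share_prior()]).
#' @param n_ill total illnesses generated (default 500).
#' @param n_unique required number of distinct contaminated consumer zones.
#' @param seed integer seed; the outbreak is reproducible given it.
#' @return Object of class `outbreak`: `true_source`, `observations`
#'   (character vector of consumer zone_ids, length `n_ill`), `n_ill`,
#'   `n_unique`, `seed`.
#' @export
simulate_outbreak <- function(net_truth, prior, n_ill = 500L, n_unique,
                              seed) {
  absorb <- absorbing_matrix(net_truth)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  out <- simulate_outbreak_impl(absorb, prior, n_ill, n_unique)
  out$seed <- as.integer(seed)
  out
}

simulate_outbreak_impl <- function(absorb, prior, n_ill, n_unique) {
  if (n_unique < 1 || n_ill < n_unique)
    stop("invalid-argument: need 1 <= n_unique <= n_ill", call. = FALSE)
  brands <- intersect(names(prior), rownames(absorb))
  if (length(brands) == 0)
    stop("invalid-input: prior brands not present in network", call. = FALSE)

  source <- NULL
  for (try in seq_len(100L)) {
    cand <- names(prior)[sample.int(length(prior), 1L, prob = prior)]
    if (sum(absorb[cand, ] > 0) >= n_unique) { source <- cand; break }
  }
  if (is.null(source))
    stop("infeasible-spread: no sampled source reaches ", n_unique,
         " consumer zones (100 attempts)", call. = FALSE)

  p <- stats::setNames(as.numeric(absorb[source, ]), colnames(absorb))
  support <- names(p)[p > 0]
  sel <- support[sample.int(length(support), n_unique, prob = p[support])]
  w <- p[sel] / sum(p[sel])
  counts <- rep(1L, n_unique)
  if (n_ill > n_unique)
    counts <- counts + as.integer(stats::rmultinom(1L, n_ill - n_unique, w))
  obs <- rep(sel, counts)
  obs <- obs[sample.int(length(obs))]

  structure(list(true_source = source, observations = obs,
                 n_ill = as.integer(n_ill), n_unique = as.integer(n_unique)),
            class = "outbreak")
}

#' @export
print.outbreak <- function(x, ...) {
  cat(sprintf("Outbreak: %d illnesses over %d consumer zones (source %s)\n",
              x$n_ill, x$n_unique, x$true_source))
  invisible(x)
}

#' Simulate a batch of independent outbreaks
#'
#' Per-outbreak seeds are derived deterministically from the master seed, so
#' the whole batch is reproducible and individual outbreaks can be re-run in
#' isolation.
#'
#' @inheritParams simulate_outbreak
#' @param n_outbreaks number of outbreaks.
#' @return List of [simulate_outbreak()] results (empty for
#'   `n_outbreaks = 0`).
#' @export
simulate_batch <- function(net_truth, prior, n_outbreaks, n_ill = 500L,
                           n_unique, seed) {
  if (n_outbreaks < 0)
    stop("invalid-argument: n_outbreaks must be >= 0", call. = FALSE)
  if (n_outbreaks == 0) return(list())
  absorb <- absorbing_matrix(net_truth)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_outbreaks)
  lapply(seq_len(n_outbreaks), function(i) {
    set.seed(sub_seeds[i])
    out <- simulate_outbreak_impl(absorb, prior, n_ill, n_unique)
    out$seed <- sub_seeds[i]
    out
  })
}
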
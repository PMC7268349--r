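#' Negative-binomial log mass with a continuous extension in the count
#'
#' Read sampling from a sequencing library is modelled as negative binomial:
#' the number of reads \code{k} for one guide in a bin, given \code{n} total
#' reads in that bin and the guide's expected fraction \code{p_guide} of the
#' bin, has log mass
#' \deqn{\log\binom{k+n-1}{k} + n\log q + k\log(1-q), \quad q = 1 - p_{guide}.}
#' Because a depth-scaled pseudocount is added to observed counts before
#' evaluation, \code{k} may be non-integer; the binomial coefficient is
#' therefore evaluated through \code{lgamma}, which agrees with
#' \code{dnbinom(k, size = n, prob = q, log = TRUE)} at integer \code{k}.
#'
#' @param k reads for the guide in the bin (non-negative, possibly
#'   non-integer after pseudocounting).
#' @param n total reads in the bin (the NB \emph{size}).
#' @param p_guide expected fraction of the bin's reads belonging to the
#'   guide, in \code{(0, 1)}; values at 0 or 1 yield \code{-Inf}.
#' @return log probability mass (vectorised over the arguments).
#' @examples
#' nb_log_pmf(2, 5, p_guide = 0.5)          # log(15/128)
#' dnbinom(2, size = 5, prob = 0.5, log = TRUE)
#' @export
nb_log_pmf <- function(k, n, p_guide) {
  q <- 1 - p_guide
  out <- lgamma(k + n) - lgamma(n) - lgamma(k + 1) +
    n * log(q) + k * log1p(-q)
  out[p_guide <= 0 | p_guide >= 1] <- -Inf
  out
}

#' Expected per-bin read fraction for a guide at a given expression shift
#'
#' The expected fraction of bin \code{b}'s cells (and hence reads) carrying
#' guide \code{g} is the guide's unsorted-library fraction scaled by its
#' relative enrichment in the bin:
#' \deqn{P_b(g \mid \mu) = \frac{r_{0g}}{R_0} \times \frac{S(b,\mu)}{S(b,0)}}
#' where \eqn{S(b,\mu)} is \code{\link{bin_occupancy}}. At \code{mu = 0} this
#' is just the library fraction. A guide absent from the unsorted library has
#' expected fraction 0 everywhere and cannot be quantified.
#'
#' @param lib_fraction the guide's fraction of the unsorted library,
#'   \code{r0g / R0}.
#' @param bins a \code{\link{sorting_bins}} data frame.
#' @param mu mean expression shift in SD units.
#' @return numeric vector of expected read fractions, one per bin.
#' @export
expected_read_fraction <- function(lib_fraction, bins, mu) {
  lib_fraction * bin_occupancy(bins, mu) / bins$fraction
}

# Profile log-likelihood for one guide over candidate shifts `mu`.
# counts: pseudocounted per-bin counts; bin_totals: R_b; terms constant in mu
# (the lgamma triple) are dropped, so values are comparable only across mu.
guide_loglik <- function(mu, counts, bin_totals, lib_fraction, bins) {
  vapply(mu, function(m) {
    p <- lib_fraction * bin_occupancy(bins, m) / bins$fraction
    # infeasible shifts (an expected fraction at/over 1) get a finite,
    # monotone penalty so optimize() is steered back without NA/Inf
    if (any(p >= 1)) return(-1e9 * (1 + sum(pmax(p - 1, 0))))
    p <- pmax(p, 1e-300)  # occupancy underflow at extreme shifts
    sum(bin_totals * log1p(-p) + counts * log(p))
  }, numeric(1))
}

#' Maximum-likelihood mean expression shift for a single guide
#'
#' Maximises the summed negative-binomial log likelihood of the guide's
#' per-bin read counts over the mean shift \code{mu}, using Brent-style
#' bounded one-dimensional optimisation (\code{\link[stats]{optimize}}).
#' Counts are first regularised with a depth-scaled pseudocount,
#' \code{pseudocount} reads per million reads of coverage in the bin, which
#' acts as a prior favouring \code{mu = 0} for poorly covered guides.
#'
#' @param counts named numeric vector of raw per-bin read counts, names
#'   matching \code{bins$bin_id}.
#' @param bin_totals named numeric vector of total reads per bin.
#' @param lib_fraction the guide's unsorted-library fraction.
#' @param bins a \code{\link{sorting_bins}} data frame.
#' @param pseudocount pseudocounts added per million reads of bin coverage
#'   (default 10).
#' @param mu_limits search interval in SD units (default \code{c(-5, 5)}).
#' @param tol convergence tolerance for the optimiser (default \code{1e-4}).
#' @return list with \code{mu_hat}, \code{ll_ratio} (log likelihood at
#'   \code{mu_hat} minus at 0; never negative) and \code{unquantifiable}.
#' @export
estimate_guide_mu <- function(counts, bin_totals, lib_fraction, bins,
                              pseudocount = 10, mu_limits = c(-5, 5),
                              tol = 1e-4) {
  counts <- counts[bins$bin_id]
  bin_totals <- bin_totals[bins$bin_id]
  if (!is.finite(lib_fraction) || lib_fraction <= 0)
    return(list(mu_hat = 0, ll_ratio = 0, unquantifiable = TRUE))
  k <- counts + pseudocount * bin_totals / 1e6
  f <- function(m) guide_loglik(m, k, bin_totals, lib_fraction, bins)
  opt <- stats::optimize(f, interval = mu_limits, maximum = TRUE, tol = tol)
  ll0 <- f(0)
  if (!is.finite(opt$objective) || opt$objective <= ll0)
    return(list(mu_hat = 0, ll_ratio = 0, unquantifiable = FALSE))
  list(mu_hat = opt$maximum, ll_ratio = opt$objective - ll0,
       unquantifiable = FALSE)
}
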
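#' Construct a validated set of sorting bins from cumulative quantile bounds
#'
#' FACS gates are described by the cumulative fraction of sorted cells they
#' capture: a bin spanning quantiles \code{startQ}--\code{endQ} holds
#' \code{endQ - startQ} of all cells. Because the inference model works in a
#' quantile-normalised standard-normal expression space, each quantile bound
#' is mapped to its standard-normal Z bound via \code{qnorm}; a bound of 0
#' maps to \code{-Inf} and a bound of 1 to \code{+Inf}.
#'
#' @param bin_id character vector of bin labels (unique within an experiment).
#' @param startQ,endQ numeric vectors of cumulative quantile bounds in
#'   \code{[0, 1]}, with \code{startQ < endQ} per bin. Bins may not overlap
#'   in quantile space; they need not tile the distribution (an unsorted
#'   middle is allowed).
#' @param startZ,endZ optional standard-normal bounds. When supplied they are
#'   validated against the quantiles (\code{|pnorm(Z) - Q| <= 1e-6}); when
#'   absent they are computed as \code{qnorm(Q)}.
#' @param experiment_id optional experiment label, recycled to the number of
#'   bins; validation is applied within each experiment.
#'
#' @return A data frame of class \code{"sorting_bins"} with columns
#'   \code{experiment_id}, \code{bin_id}, \code{startQ}, \code{endQ},
#'   \code{startZ}, \code{endZ} and \code{fraction} (\code{endQ - startQ}).
#' @examples
#' sorting_bins(c("low", "high"), startQ = c(0, 0.9), endQ = c(0.1, 1))
#' @export
sorting_bins <- function(bin_id, startQ, endQ, startZ = NULL, endZ = NULL,
                         experiment_id = "expt") {
  n <- length(bin_id)
  if (length(startQ) != n || length(endQ) != n)
    stop("bin_id, startQ and endQ must have equal length")
  experiment_id <- rep_len(as.character(experiment_id), n)
  bin_id <- as.character(bin_id)
  startQ <- as.numeric(startQ)
  endQ <- as.numeric(endQ)

  bad_range <- which(startQ < 0 | endQ > 1 | !is.finite(startQ) | !is.finite(endQ))
  if (length(bad_range))
    stop("quantile bounds outside [0, 1] for bin(s): ",
         paste(bin_id[bad_range], collapse = ", "))
  bad_order <- which(startQ >= endQ)
  if (length(bad_order))
    stop("startQ must be < endQ for bin(s): ",
         paste(bin_id[bad_order], collapse = ", "))

  if (is.null(startZ)) startZ <- stats::qnorm(startQ) else {
    startZ <- as.numeric(startZ)
    chk <- abs(stats::pnorm(startZ) - startQ) > 1e-6
    if (any(chk))
      stop("startZ inconsistent with startQ for bin(s): ",
           paste(bin_id[chk], collapse = ", "))
  }
  if (is.null(endZ)) endZ <- stats::qnorm(endQ) else {
    endZ <- as.numeric(endZ)
    chk <- abs(stats::pnorm(endZ) - endQ) > 1e-6
    if (any(chk))
      stop("endZ inconsistent with endQ for bin(s): ",
           paste(bin_id[chk], collapse = ", "))
  }

  bins <- data.frame(experiment_id = experiment_id, bin_id = bin_id,
                     startQ = startQ, endQ = endQ,
                     startZ = startZ, endZ = endZ,
                     fraction = endQ - startQ,
                     stringsAsFactors = FALSE)

  for (ex in unique(bins$experiment_id)) {
    b <- bins[bins$experiment_id == ex, ]
    if (anyDuplicated(b$bin_id))
      stop("duplicate bin_id within experiment ", ex)
    o <- order(b$startQ)
    b <- b[o, ]
    if (nrow(b) > 1) {
      ovl <- which(b$startQ[-1] < b$endQ[-nrow(b)] - 1e-12)
      if (length(ovl))
        stop("overlapping bins in experiment ", ex, ": ",
             paste(unique(c(b$bin_id[ovl], b$bin_id[ovl + 1])), collapse = ", "))
    }
    if (sum(b$fraction) > 1 + 1e-9)
      stop("bin fractions exceed 1 in experiment ", ex)
  }
  class(bins) <- c("sorting_bins", "data.frame")
  bins
}

#' Expected occupancy of a sorting bin under a shifted expression distribution
#'
#' For cells whose (quantile-normalised) expression follows Normal(mu, 1),
#' the expected fraction falling inside a bin with standard-normal bounds
#' \code{[startZ, endZ]} is \code{pnorm(endZ - mu) - pnorm(startZ - mu)}.
#' At \code{mu = 0} this is exactly the bin's fraction of sorted cells.
#'
#' @param bins a \code{\link{sorting_bins}} data frame (or any data frame
#'   with \code{startZ}/\code{endZ} columns).
#' @param mu mean expression shift in SD units of the overall distribution
#'   (scalar or vector; vectorised over \code{mu} when \code{bins} has one
#'   row, otherwise over bins per scalar \code{mu}).
#' @return numeric vector of occupancies in \code{[0, 1]}.
#' @examples
#' b <- sorting_bins("top", 0.9, 1)
#' bin_occupancy(b, 0)    # 0.1
#' bin_occupancy(b, 0.5)  # enriched
#' @export
bin_occupancy <- function(bins, mu) {
  stats::pnorm(bins$endZ - mu) - stats::pnorm(bins$startZ - mu)
}
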
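#' Configuration for a simulated sorting screen
#'
#' Captures every rate and size needed to generate a synthetic screen with
#' known ground truth. The defaults mirror a realistic pooled CRISPR screen:
#' guide abundances are Poisson with mean 1000 (library construction noise),
#' one sorted cell per unit of abundance in expectation, sequencing at 10
#' reads per sorted cell, and six 10\% sorting gates on the two tails of the
#' expression distribution.
#'
#' Two perturbation modes are supported. \code{"mean"}: every cell carrying
#' an effective guide expresses Normal(\code{mu}, 1), a whole-distribution
#' shift. \code{"proportion"}: a fraction \code{r} of cells responds by
#' shifting to Normal(1, 1) while the rest stay at Normal(0, 1); the
#' population-average effect is then \code{r * 1} SD.
#'
#' @param n_elements number of targeted elements (effective ones first).
#' @param guides_per_element guides tiling each element (default 5).
#' @param n_controls negative-control guides (default 1000).
#' @param library_mean Poisson mean of guide abundance (default 1000).
#' @param read_depth_factor sequencing reads per sorted cell (default 10).
#' @param bins a \code{\link{sorting_bins}} layout (default: six 10\%
#'   extreme bins, three per tail).
#' @param mode \code{"mean"} or \code{"proportion"}.
#' @param effects vector of true effects for the effective elements: mean
#'   shifts in SD units, either sign (\code{mode = "mean"}), or responder
#'   fractions in \code{(0, 1]} (\code{mode = "proportion"}). Remaining
#'   elements are ineffective (effect 0).
#' @return list of class \code{"screen_config"}.
#' @export
screen_config <- function(n_elements = 200, guides_per_element = 5,
                          n_controls = 1000, library_mean = 1000,
                          read_depth_factor = 10, bins = default_bins(),
                          mode = c("mean", "proportion"),
                          effects = seq(0.01, 1, by = 0.01)) {
  mode <- match.arg(mode)
  if (length(effects) > n_elements)
    stop("more effects than elements")
  if (mode == "proportion" && (any(effects < 0) || any(effects > 1)))
    stop("responder fractions must lie in [0, 1]")
  stopifnot(library_mean >= 0, read_depth_factor > 0, guides_per_element >= 1)
  structure(list(n_elements = n_elements,
                 guides_per_element = guides_per_element,
                 n_controls = n_controls, library_mean = library_mean,
                 read_depth_factor = read_depth_factor, bins = bins,
                 mode = mode, effects = effects),
            class = "screen_config")
}

#' Six 10\% sorting bins on the distribution extremes
#'
#' Three contiguous 10\% gates per tail: quantiles 0--30\% and 70--100\%,
#' leaving the middle 40\% unsorted.
#'
#' @param experiment_id experiment label (default \code{"expt"}).
#' @return a \code{\link{sorting_bins}} data frame with bins A--F.
#' @export
default_bins <- function(experiment_id = "expt") {
  sorting_bins(bin_id = c("A", "B", "C", "D", "E", "F"),
               startQ = c(0, .1, .2, .7, .8, .9),
               endQ = c(.1, .2, .3, .8, .9, 1),
               experiment_id = experiment_id)
}

#' Simulate per-guide library abundances
#'
#' @param n_guides number of guides.
#' @param library_mean Poisson mean abundance.
#' @return integer vector \code{A_g ~ Poisson(library_mean)}.
#' @export
simulate_library <- function(n_guides, library_mean = 1000) {
  stats::rpois(n_guides, library_mean)
}

#' Simulate sorting of cells into expression bins
#'
#' The number of cells carrying each guide is \code{S_g ~ Poisson(A_g)}.
#' Each cell's expression is Normal(\code{mu_g}, 1) (mean mode) or a
#' two-component mixture Normal(1, 1) with probability \code{r_g} else
#' Normal(0, 1) (proportion mode); a cell lands in a bin when its expression
#' falls between the bin's Z bounds. Cells are assigned to bins by a
#' multinomial draw over the per-bin occupancy probabilities (plus the
#' unsorted remainder), which is distributionally identical to simulating
#' every cell's expression individually.
#'
#' @param abundances per-guide abundances \code{A_g}.
#' @param bins a \code{\link{sorting_bins}} layout.
#' @param mu per-guide mean shifts (mean mode), or NULL.
#' @param responder_fraction per-guide responder fractions (proportion
#'   mode), or NULL. Exactly one of \code{mu}/\code{responder_fraction} must
#'   be given.
#' @param responder_shift expression shift of responder cells (default 1 SD).
#' @return matrix of cell counts, guides x bins (named by bin_id), with the
#'   total sorted cells per guide as attribute \code{"cells"}.
#' @export
simulate_sorted_cells <- function(abundances, bins, mu = NULL,
                                  responder_fraction = NULL,
                                  responder_shift = 1) {
  n <- length(abundances)
  if (is.null(mu) == is.null(responder_fraction))
    stop("give exactly one of mu or responder_fraction")
  S_g <- stats::rpois(n, abundances)

  # partition the whole expression axis into the bins plus the uncaptured
  # gaps between them, so that realized cumulative quantile bounds can be
  # recovered exactly from the segment counts
  o <- order(bins$startZ)
  edges <- unique(c(-Inf, as.vector(rbind(bins$startZ[o], bins$endZ[o])), Inf))
  seg <- data.frame(startZ = edges[-length(edges)], endZ = edges[-1])
  seg <- seg[seg$startZ < seg$endZ, ]
  bin_seg <- match(paste(bins$startZ, bins$endZ),
                   paste(seg$startZ, seg$endZ))

  probs <- if (!is.null(mu)) {
    t(vapply(mu, function(m) bin_occupancy(seg, m), numeric(nrow(seg))))
  } else {
    t(vapply(responder_fraction, function(r)
      r * bin_occupancy(seg, responder_shift) +
        (1 - r) * bin_occupancy(seg, 0), numeric(nrow(seg))))
  }
  seg_counts <- matrix(0L, n, nrow(seg))
  for (i in seq_len(n)) {
    if (S_g[i] == 0) next
    seg_counts[i, ] <- stats::rmultinom(1, S_g[i], probs[i, ])[, 1]
  }
  out <- seg_counts[, bin_seg, drop = FALSE]
  dimnames(out) <- list(NULL, bins$bin_id)
  attr(out, "cells") <- S_g
  attr(out, "segment_totals") <- colSums(seg_counts)
  attr(out, "bin_segment") <- bin_seg
  out
}

#' Simulate sequencing reads from sorted cells
#'
#' Reads per guide per bin are negative binomial with size equal to
#' \code{read_depth_factor} times the total cells sorted into the bin and
#' expected guide fraction equal to the guide's share of the bin's cells
#' (\code{prob = 1 - S_bg / sum(S_b)}), the same sampling law the inference
#' assumes. The unsorted library is sequenced analogously from the guide
#' abundances.
#'
#' @param cell_counts guides x bins matrix from
#'   \code{\link{simulate_sorted_cells}}.
#' @param abundances per-guide abundances (for the unsorted library).
#' @param read_depth_factor reads per sorted cell (default 10).
#' @return list with \code{reads} (guides x bins matrix) and
#'   \code{unsorted} (vector).
#' @export
simulate_reads <- function(cell_counts, abundances, read_depth_factor = 10) {
  reads <- matrix(0L, nrow(cell_counts), ncol(cell_counts),
                  dimnames = dimnames(cell_counts))
  for (j in seq_len(ncol(cell_counts))) {
    tot <- sum(cell_counts[, j])
    if (tot == 0) {
      warning("bin ", colnames(cell_counts)[j],
              " received no cells; zero reads")
      next
    }
    frac <- cell_counts[, j] / tot
    pos <- frac > 0
    reads[pos, j] <- stats::rnbinom(sum(pos),
                                    size = read_depth_factor * tot,
                                    prob = 1 - frac[pos])
  }
  tot_a <- sum(abundances)
  unsorted <- integer(length(abundances))
  pos <- abundances > 0
  unsorted[pos] <- stats::rnbinom(sum(pos),
                                  size = read_depth_factor * tot_a,
                                  prob = 1 - abundances[pos] / tot_a)
  list(reads = reads, unsorted = unsorted)
}

#' Simulate a complete sorting screen with known ground truth
#'
#' Runs the full generative model — library abundances, cell sorting, read
#' sampling — for a \code{\link{screen_config}} and formats the result as
#' inference-ready inputs.
#'
#' @param config a \code{\link{screen_config}}.
#' @param seed integer seed; the single RNG stream drives library, sorting
#'   and reads in that order, so runs are exactly reproducible.
#' @param experiment_id experiment label stamped on the outputs.
#' @param record_bins \code{"realized"} (default) reports each gate's
#'   \emph{observed} cell fractions as the bin quantile bounds — what a
#'   sorter records during the experiment, and what the inference's
#'   quantile normalisation expects; \code{"nominal"} reports the design
#'   fractions instead.
#' @return list with \code{counts} (guide count table: guide_id,
#'   is_negative_control, element_label, one column per bin, unsorted,
#'   experiment_id), \code{bins}, and \code{truth} (per element:
#'   element_id, is_effective, true_effect, average_effect — the mean shift
#'   itself, or responder fraction times the responder shift).
#' @examples
#' sim <- simulate_screen(screen_config(n_elements = 4, n_controls = 10,
#'                                      effects = c(0.5, 1)), seed = 1)
#' str(sim$truth)
#' @export
simulate_screen <- function(config, seed = NULL, experiment_id = "expt",
                            record_bins = c("realized", "nominal")) {
  record_bins <- match.arg(record_bins)
  stopifnot(inherits(config, "screen_config"))
  if (!is.null(seed)) set.seed(seed)
  n_eff <- length(config$effects)
  n_el <- config$n_elements
  gpe <- config$guides_per_element
  n_target <- n_el * gpe
  n_tot <- n_target + config$n_controls

  element_id <- sprintf("E%03d", seq_len(n_el))
  el_effect <- c(config$effects, rep(0, n_el - n_eff))
  guide_el <- rep(element_id, each = gpe)
  guide_effect <- c(rep(el_effect, each = gpe), rep(0, config$n_controls))
  guide_id <- c(sprintf("%s_g%d", guide_el, rep(seq_len(gpe), n_el)),
                sprintf("ctrl_%04d", seq_len(config$n_controls)))
  is_ctrl <- rep(c(FALSE, TRUE), c(n_target, config$n_controls))

  bins <- config$bins
  bins$experiment_id <- experiment_id
  A_g <- simulate_library(n_tot, config$library_mean)
  cells <- if (config$mode == "mean")
    simulate_sorted_cells(A_g, bins, mu = guide_effect)
  else
    simulate_sorted_cells(A_g, bins, responder_fraction = guide_effect)
  rd <- simulate_reads(cells, A_g, config$read_depth_factor)
  if (record_bins == "realized") {
    seg_tot <- attr(cells, "segment_totals")
    bin_seg <- attr(cells, "bin_segment")
    cum <- cumsum(seg_tot) / sum(seg_tot)
    startQ <- c(0, cum)[bin_seg]
    endQ <- cum[bin_seg]
    bins <- sorting_bins(bins$bin_id, startQ, endQ,
                         experiment_id = experiment_id)
  }

  counts <- data.frame(guide_id = guide_id,
                       is_negative_control = is_ctrl,
                       element_label = c(guide_el,
                                         rep(NA_character_,
                                             config$n_controls)),
                       experiment_id = experiment_id,
                       stringsAsFactors = FALSE)
  counts <- cbind(counts, as.data.frame(rd$reads))
  counts$unsorted <- rd$unsorted

  truth <- data.frame(element_id = element_id,
                      experiment_id = experiment_id,
                      is_effective = el_effect != 0,
                      true_effect = el_effect,
                      average_effect = if (config$mode == "mean") el_effect
                                       else el_effect * 1,
                      stringsAsFactors = FALSE)
  list(counts = counts, bins = bins, truth = truth, config = config)
}

#' The reference two-experiment recovery simulation
#'
#' A standard benchmark screen: 200 elements with 5 guides each, 1000
#' negative controls, six 10\% extreme bins, 10x read depth. Half the
#' elements are effective with a dense grid of true effects — mean shifts
#' 0.01 to 1.00 SD in 0.01 steps (\code{mode = "mean"}) or responder
#' fractions 1\% to 100\% in 1\% steps (\code{mode = "proportion"}) — and
#' half are ineffective, so recovery, sensitivity and false-positive
#' calibration can all be read off one run.
#'
#' @param mode \code{"mean"} or \code{"proportion"}.
#' @param seed integer seed.
#' @return as \code{\link{simulate_screen}}.
#' @export
simulate_reference_screen <- function(mode = c("mean", "proportion"),
                                      seed = NULL) {
  mode <- match.arg(mode)
  effects <- seq(0.01, 1, by = 0.01)  # shifts in SD, or responder fractions
  cfg <- screen_config(n_elements = 200, guides_per_element = 5,
                       n_controls = 1000, library_mean = 1000,
                       read_depth_factor = 10, bins = default_bins(),
                       mode = mode, effects = effects)
  simulate_screen(cfg, seed = seed,
                  experiment_id = paste0(mode, "_screen"))
}
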
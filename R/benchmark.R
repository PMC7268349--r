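#' Run the reference recovery benchmark end to end
#'
#' For each seed, simulates the reference screen
#' (\code{\link{simulate_reference_screen}}), fits guide shifts, aggregates
#' annotated elements, applies BH at \code{fdr_threshold}, and scores
#' recovery against the simulator's ground truth.
#'
#' @param mode \code{"mean"} or \code{"proportion"}.
#' @param seeds integer vector of simulation seeds (one screen per seed).
#' @param fdr_threshold significance cutoff on the two-tailed FDR
#'   (default 0.01).
#' @param n_draws null-model draws (default 10000).
#' @return data frame with one row per seed: \code{true_positives} (of the
#'   100 effective elements), \code{false_positives} (ineffective elements
#'   among significant calls), \code{pearson_r} (true vs inferred effect,
#'   effective elements only), \code{slope} (regression of inferred on true
#'   effect), \code{min_detected_effect} (smallest true effect among
#'   significant effective elements).
#' @examples
#' \donttest{
#' benchmark_reference_screen("mean", seeds = 1)
#' }
#' @export
benchmark_reference_screen <- function(mode = c("mean", "proportion"),
                                       seeds = 1:5, fdr_threshold = 0.01,
                                       n_draws = 10000) {
  mode <- match.arg(mode)
  rows <- lapply(seeds, function(s) {
    sim <- simulate_reference_screen(mode, seed = s)
    fit <- sortshift(sim$counts, sim$bins)
    el <- element_stats(fit, by = "annotation", n_draws = n_draws, seed = s)
    m <- merge(el, sim$truth, by = c("element_id", "experiment_id"))
    eff <- m[m$is_effective, ]
    hit <- eff$fdr_either < fdr_threshold
    data.frame(seed = s,
               true_positives = sum(hit),
               false_positives = sum(m$fdr_either < fdr_threshold &
                                       !m$is_effective),
               pearson_r = stats::cor(eff$average_effect, eff$effect_z),
               slope = stats::coef(stats::lm(eff$effect_z ~
                                               eff$average_effect))[[2]],
               min_detected_effect = if (any(hit))
                 min(eff$average_effect[hit]) else NA_real_)
  })
  do.call(rbind, rows)
}
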
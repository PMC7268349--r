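#' Build a symmetric tail-anchored bin configuration
#'
#' Sorting-gate layouts under study are symmetric about the median and
#' contiguous from each tail inward: the outermost pair (A/F) always sits at
#' the distribution extremes, with optional second (B/E) and third (C/D)
#' pairs stacking toward the centre. A configuration is described by the
#' widths of the bins on one tail, outermost first, as percent of the
#' distribution.
#'
#' @param tail_widths numeric vector of 1--3 bin widths in percent,
#'   outermost first; total coverage \code{2 * sum(tail_widths)} must not
#'   exceed 100.
#' @param label optional label; default e.g. \code{"A5_B10_C20"}.
#' @return list of class \code{"bin_configuration"} with \code{label},
#'   \code{n_bins}, \code{coverage} (percent) and \code{bins}, a
#'   \code{\link{sorting_bins}} layout.
#' @examples
#' bin_configuration(25)          # two quartile bins
#' bin_configuration(c(5, 10, 20))  # the six-bin A5_B10_C20 layout
#' @export
bin_configuration <- function(tail_widths, label = NULL) {
  tail_widths <- as.numeric(tail_widths)
  if (length(tail_widths) < 1 || length(tail_widths) > 3)
    stop("tail_widths must list 1 to 3 bin widths per tail")
  if (any(tail_widths <= 0)) stop("bin widths must be positive")
  if (2 * sum(tail_widths) > 100 + 1e-9)
    stop("bins overlap at the centre: total coverage ",
         2 * sum(tail_widths), "% exceeds 100%")
  w <- tail_widths / 100
  lower_edges <- cumsum(c(0, w))
  upper_edges <- rev(1 - lower_edges)
  k <- length(w)
  startQ <- c(lower_edges[seq_len(k)], upper_edges[seq_len(k)])
  endQ <- c(lower_edges[seq_len(k) + 1], upper_edges[seq_len(k) + 1])
  ids <- if (k == 1) c("A", "F") else if (k == 2) c("A", "B", "E", "F")
         else c("A", "B", "C", "D", "E", "F")
  bins <- sorting_bins(ids, startQ, endQ)  # already ascending in quantile
  if (is.null(label))
    label <- paste(paste0(c("A", "B", "C")[seq_len(k)],
                          formatC(tail_widths, format = "fg")),
                   collapse = "_")
  structure(list(label = label, n_bins = 2L * k,
                 coverage = 2 * sum(tail_widths), bins = bins),
            class = "bin_configuration")
}

#' Expand width specifications into validated bin configurations
#'
#' @param specs list of numeric vectors of tail widths (see
#'   \code{\link{bin_configuration}}), optionally named (names become
#'   labels).
#' @return list of \code{bin_configuration} objects.
#' @export
enumerate_configurations <- function(specs) {
  if (!is.list(specs)) specs <- list(specs)
  labels <- names(specs)
  lapply(seq_along(specs), function(i)
    bin_configuration(specs[[i]],
                      label = if (!is.null(labels) && nzchar(labels[i]))
                        labels[i] else NULL))
}

#' The built-in panel of candidate sorting-gate layouts
#'
#' Uniform-width layouts at 5, 10, 12.5, 15, 25 and 50 percent per bin with
#' 2, 4 and 6 bins (where total coverage permits), plus the graduated
#' six-bin A5_B10_C20 layout (5\% outer, 10\% middle, 20\% inner per tail).
#'
#' @return named list of \code{\link{bin_configuration}} objects.
#' @export
builtin_configurations <- function() {
  specs <- list()
  for (w in c(5, 10, 12.5, 15, 25, 50)) {
    for (k in 1:3) {
      if (2 * k * w > 100 + 1e-9) next
      specs[[paste0("uniform", w, "x", 2 * k)]] <- rep(w, k)
    }
  }
  specs[["A5_B10_C20"]] <- c(5, 10, 20)
  enumerate_configurations(specs)
}

#' Evaluate one bin configuration by simulation
#'
#' Repeatedly simulates a challenging screen (small effects), sorts it into
#' the configuration's gates, runs the full guide and element inference, and
#' measures (i) the Pearson correlation between true and inferred effect
#' sizes over the effective elements and (ii) the number of true positives —
#' effective elements significant at the FDR threshold. Replicate
#' \code{r} uses seed \code{base_seed + r} so the study is reproducible and
#' configurations see matched screens.
#'
#' @param config a \code{\link{bin_configuration}}.
#' @param n_replicates simulated screens to average over (default 10).
#' @param base_seed seed base; replicate r uses \code{base_seed + r}.
#' @param n_effective,n_ineffective elements with and without effect
#'   (defaults 1000 and 1000); effects are spread over
#'   \code{effect_range} evenly.
#' @param effect_range range of true mean shifts (default
#'   \code{c(0.01, 0.1)}, ten distinct values).
#' @param fdr_threshold significance cutoff for true positives (default
#'   0.01).
#' @param n_draws null-model draws (default 10000).
#' @param guides_per_element,n_controls,library_mean,read_depth_factor
#'   passed to \code{\link{screen_config}}.
#' @return one-row data frame of class \code{"design_evaluation"}: label,
#'   n_bins, coverage, pearson_r, pearson_r_sem, true_positives, tp_sem,
#'   n_replicates.
#' @export
evaluate_configuration <- function(config, n_replicates = 10, base_seed = 1,
                                   n_effective = 1000, n_ineffective = 1000,
                                   effect_range = c(0.01, 0.1),
                                   fdr_threshold = 0.01, n_draws = 10000,
                                   guides_per_element = 5, n_controls = 1000,
                                   library_mean = 1000,
                                   read_depth_factor = 10) {
  stopifnot(inherits(config, "bin_configuration"))
  effects <- rep(seq(effect_range[1], effect_range[2],
                     length.out = round(diff(effect_range) / 0.01) + 1),
                 length.out = n_effective)
  cfg <- screen_config(n_elements = n_effective + n_ineffective,
                       guides_per_element = guides_per_element,
                       n_controls = n_controls, library_mean = library_mean,
                       read_depth_factor = read_depth_factor,
                       bins = config$bins, mode = "mean", effects = effects)
  reps <- vapply(seq_len(n_replicates), function(r) {
    sim <- simulate_screen(cfg, seed = base_seed + r)
    fit <- sortshift(sim$counts, sim$bins)
    el <- element_stats(fit, by = "annotation", n_draws = n_draws,
                        seed = base_seed + r)
    m <- merge(el, sim$truth, by = c("element_id", "experiment_id"))
    eff <- m[m$is_effective, ]
    c(r = stats::cor(eff$average_effect, eff$effect_z),
      tp = sum(eff$fdr_either < fdr_threshold))
  }, numeric(2))
  data.frame(label = config$label, n_bins = config$n_bins,
             coverage = config$coverage,
             pearson_r = mean(reps["r", ]),
             pearson_r_sem = stats::sd(reps["r", ]) / sqrt(n_replicates),
             true_positives = mean(reps["tp", ]),
             tp_sem = stats::sd(reps["tp", ]) / sqrt(n_replicates),
             n_replicates = n_replicates,
             stringsAsFactors = FALSE)
}

#' Rank evaluated bin configurations
#'
#' Orders a table of \code{\link{evaluate_configuration}} results by a
#' metric (descending), breaking ties by the other metric and then by
#' label, and marks the recommended (best) configuration per bin count.
#'
#' @param evaluations data frame of stacked evaluation rows (>= 2).
#' @param metric \code{"pearson_r"} (default) or \code{"true_positives"}.
#' @return the evaluations sorted best-first with columns \code{rank} and
#'   \code{recommended} added.
#' @export
rank_configurations <- function(evaluations,
                                metric = c("pearson_r", "true_positives")) {
  metric <- match.arg(metric)
  if (nrow(evaluations) < 2) stop("need at least 2 evaluations to rank")
  other <- setdiff(c("pearson_r", "true_positives"), metric)
  o <- order(-evaluations[[metric]], -evaluations[[other]],
             evaluations$label)
  out <- evaluations[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  best_per_k <- tapply(seq_len(nrow(out)), out$n_bins, min)
  out$recommended <- seq_len(nrow(out)) %in% best_per_k
  rownames(out) <- NULL
  out
}
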